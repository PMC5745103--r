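## File I/O: multi-page float TIFF stacks with a JSON metadata sidecar,
## tab-separated boundary/profile/metric tables (0-based indices at the
## text interface), PNG colour images, profile plots and run manifests.

#' Write a three-channel stack to multi-page TIFFs
#'
#' One 32-bit float multi-page TIFF per channel plus a JSON metadata
#' sidecar. Float TIFF storage is only well-defined for values in
#' `[0, 1]`, so each stack is scaled by its global maximum and the
#' scale factor recorded in the sidecar (re-applied on read).
#'
#' @param stack An [mdoct_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir, prefix = "channel") {
  stopifnot(inherits(stack, "mdoct_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  scales <- numeric(3); offsets <- numeric(3)
  for (c in 1:3) {
    a <- stack$channels[[c]]
    off <- min(a)
    sc <- max(max(a) - off, 1e-12)
    scales[c] <- sc; offsets[c] <- off
    pages <- lapply(seq_len(dim(a)[3]),
                    function(j) pmin(pmax((a[, , j] - off) / sc, 0), 1))
    f <- file.path(dir, sprintf("%s_%d.tif", prefix, c))
    suppressWarnings(tiff::writeTIFF(pages, f, bits.per.sample = 32,
                                     reduce = FALSE))
    files <- c(files, f)
  }
  meta <- list(pitch_um = stack$pitch_um,
               channel_azimuths_deg = stack$channel_azimuths_deg,
               pattern = unclass(stack$pattern),
               registered = stack$registered,
               intensity_scales = scales,
               intensity_offsets = offsets,
               azimuth_convention = "A-scan i (0-based) at 360*i/N degrees")
  mf <- file.path(dir, sprintf("%s_metadata.json", prefix))
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read a three-channel stack written by [write_stack()]
#'
#' Also accepts plain multi-page TIFF triplets without a sidecar, in
#' which case default metadata is applied with a warning.
#'
#' @param dir Directory holding the files.
#' @param prefix File name prefix used at write time.
#' @return An [mdoct_stack()].
#' @export
read_stack <- function(dir, prefix = "channel") {
  files <- file.path(dir, sprintf("%s_%d.tif", prefix, 1:3))
  if (!all(file.exists(files))) stop("unreadable stack: missing channel TIFFs")
  mf <- file.path(dir, sprintf("%s_metadata.json", prefix))
  meta <- if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE)
  else {
    warning("no metadata sidecar found; applying defaults")
    list(pitch_um = 3.5, channel_azimuths_deg = c(90, 210, 330),
         pattern = NULL, registered = FALSE, intensity_scales = rep(1, 3),
         intensity_offsets = rep(0, 3))
  }
  channels <- vector("list", 3)
  for (c in 1:3) {
    pages <- tiff::readTIFF(files[c], all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent page sizes in ", files[c])
    a <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
    for (j in seq_along(pages)) a[, , j] <- pages[[j]]
    channels[[c]] <- a * meta$intensity_scales[c] +
      (meta$intensity_offsets %||% rep(0, 3))[c]
  }
  pat <- if (!is.null(meta$pattern))
    scan_pattern(meta$pattern$kind, meta$pattern$ascans_per_bscan,
                 meta$pattern$bscans, meta$pattern$fov_degrees)
  else scan_pattern("linear", ascans_per_bscan = dim(channels[[1]])[2],
                    bscans = dim(channels[[1]])[3])
  mdoct_stack(channels, pat, pitch_um = meta$pitch_um %||% 3.5,
              channel_azimuths_deg = meta$channel_azimuths_deg %||% c(90, 210, 330),
              registered = isTRUE(meta$registered))
}

#' Write a boundary table
#'
#' Tab-separated text: one row per A-scan with 0-based A-scan index and
#' 0-based boundary rows plus vessel flags.
#'
#' @param boundaries List with `ilm`, `rpe` (vectors or 1-column
#'   matrices) and optional `flags`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_boundary_table <- function(boundaries, path) {
  ilm <- as.vector(boundaries$ilm); rpe <- as.vector(boundaries$rpe)
  flags <- as.vector(boundaries$flags %||% rep(FALSE, length(ilm)))
  df <- data.frame(ascan_0based = seq_along(ilm) - 1L,
                   ilm_row_0based = ilm - 1, rpe_row_0based = rpe - 1,
                   vessel_flag = as.integer(flags))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# retinal boundaries; indices 0-based (row 0 = most anterior)", con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a boundary table written by [write_boundary_table()]
#' @param path File path.
#' @return List with 1-based `ilm`, `rpe` vectors and logical `flags`.
#' @export
read_boundary_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(ilm = df$ilm_row_0based + 1, rpe = df$rpe_row_0based + 1,
       flags = df$vessel_flag == 1L)
}

#' Write a directional profile table
#'
#' Columns: azimuth plus raw/normalized/smoothed intensity per channel
#' (1 + 9 columns), tab-separated.
#'
#' @param profiles A `directional_profiles` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(profiles, path) {
  stopifnot(inherits(profiles, "directional_profiles"))
  df <- data.frame(azimuth_deg = profiles$azimuth)
  for (c in 1:3) {
    df[[sprintf("raw_ch%d", c)]] <- profiles$raw[, c]
    df[[sprintf("normalized_ch%d", c)]] <- profiles$normalized[, c]
    df[[sprintf("smoothed_ch%d", c)]] <- profiles$smoothed[, c]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s window profiles; %d B-scans averaged; channels cyan/magenta/yellow",
                     profiles$preset, profiles$n_averaged_bscans), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an RGB image to PNG
#' @param rgb Array `rows x cols x 3` in `[0, 1]`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Plot azimuthal profiles (linear and polar)
#'
#' Writes a two-panel PNG: normalized smoothed intensity versus azimuth,
#' and the matching polar plot (intensity as radius).
#'
#' @param profiles A `directional_profiles` object.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "directional_profiles"))
  cols <- c("cyan3", "magenta3", "gold2")
  grDevices::png(path, width = 1200, height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  graphics::matplot(profiles$azimuth, profiles$smoothed, type = "l", lty = 1,
                    col = cols, lwd = 2, xlab = "azimuth (deg)",
                    ylab = "normalized intensity",
                    main = sprintf("%s window", profiles$preset))
  th <- profiles$azimuth * pi / 180
  graphics::plot(NULL, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = "", ylab = "", main = "polar")
  for (c in 1:3)
    graphics::lines(profiles$smoothed[, c] * cos(th),
                    profiles$smoothed[, c] * sin(th), col = cols[c], lwd = 2)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON manifest with the configuration, seed and a content hash of the
#' configuration block, for reproducibility bookkeeping.
#'
#' @param config Named list of run parameters.
#' @param seed Integer seed used.
#' @param files Character vector of files the run wrote.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, seed, files, path) {
  payload <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = config, seed = seed,
                   config_hash = sprintf("%08x", sum(utf8ToInt(payload) *
                                                       seq_along(utf8ToInt(payload)) %% 2147483647)),
                   files = files,
                   written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
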