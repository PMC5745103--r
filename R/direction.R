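## Layer-anchored directional-reflectivity quantification: evaluation
## windows, RPE-normalized smoothed azimuthal profiles, circular peak and
## sector detection, additive colour fusion (cyan/magenta/yellow),
## intensity MIP/average compensation, and en-face colour projections.

#' Layer-anchored evaluation window
#'
#' Per-A-scan inclusive row interval `[top, bottom]` of constant depth,
#' anchored on a segmented boundary. Presets follow the quantification
#' protocol:
#' \describe{
#'   \item{isos_cost}{20 px deep (~70 um at 3.5 um pitch), anchored on
#'     the RPE and shifted ten pixels anterior so the directionally
#'     invariant RPE signal is excluded: rows `[RPE - 29, RPE - 10]`.}
#'   \item{rnfl}{15 px deep (~53 um), anchored on the ILM and shifted
#'     three pixels posterior to exclude specular reflections at the
#'     vitreous/retina transition: rows `[ILM + 3, ILM + 17]`.}
#' }
#'
#' @param anchor_rows Per-A-scan anchor boundary rows (ILM or RPE).
#' @param preset `"isos_cost"`, `"rnfl"`, or `"custom"`.
#' @param shift Signed offset of the window's anchor-near edge from the
#'   anchor (custom preset; negative = anterior).
#' @param depth Window depth in pixels (custom preset).
#' @param image_depth Total image depth (bounds check).
#' @return Object of class `eval_window` with `top` and `bottom`
#'   per-A-scan row vectors.
#' @export
eval_window <- function(anchor_rows, preset = c("isos_cost", "rnfl", "custom"),
                        shift = NULL, depth = NULL, image_depth = NULL) {
  preset <- match.arg(preset)
  anchor_rows <- round(anchor_rows)
  if (preset == "isos_cost") {
    bottom <- anchor_rows - 10L
    top <- bottom - 19L
    depth <- 20L
  } else if (preset == "rnfl") {
    top <- anchor_rows + 3L
    bottom <- top + 14L
    depth <- 15L
  } else {
    stopifnot(!is.null(shift), !is.null(depth))
    if (depth < 1) stop("window depth must be >= 1")
    if (shift >= 0) { top <- anchor_rows + shift; bottom <- top + depth - 1L }
    else { bottom <- anchor_rows + shift; top <- bottom - depth + 1L }
  }
  if (any(top < 1) || (!is.null(image_depth) && any(bottom > image_depth)))
    stop("window out of bounds")
  structure(list(top = as.integer(top), bottom = as.integer(bottom),
                 depth = as.integer(depth), preset = preset),
            class = "eval_window")
}

#' Mean window intensity per A-scan
#'
#' Arithmetic mean of linear intensity over the window rows of each
#' A-scan.
#'
#' @param bscan Linear-intensity matrix `depth x ascans`.
#' @param window An [eval_window()].
#' @return Numeric vector, one mean per A-scan.
#' @export
window_mean <- function(bscan, window) {
  stopifnot(inherits(window, "eval_window"), ncol(bscan) == length(window$top))
  if (any(window$top < 1) || any(window$bottom > nrow(bscan)))
    stop("window out of bounds")
  vapply(seq_len(ncol(bscan)), function(j)
    mean(bscan[window$top[j]:window$bottom[j], j]), numeric(1))
}

## Median RPE-band mean of a B-scan: 10-px band centred on the RPE row.
#' @keywords internal
rpe_band_median <- function(bscan, rpe_rows, band = 10L) {
  half_up <- band %/% 2L
  rpe_rows <- round(rpe_rows)
  vals <- vapply(seq_len(ncol(bscan)), function(j) {
    rows <- max(1L, rpe_rows[j] - half_up):min(nrow(bscan), rpe_rows[j] + band - half_up - 1L)
    mean(bscan[rows, j])
  }, numeric(1))
  stats::median(vals)
}

#' Normalize a window profile to the RPE
#'
#' Divides the profile by the B-scan-median mean intensity of a 10-px
#' band centred on the RPE (the directionally invariant reference), then
#' rescales to maximum 1 for display. Scale-invariant: doubling both the
#' signal and the RPE leaves the output unchanged.
#'
#' @param profile Raw window-mean profile.
#' @param rpe_band_mean The RPE normalizer (e.g. [rpe_band_median()]'s
#'   value), or a B-scan plus RPE rows via `bscan`/`rpe_rows`.
#' @param bscan,rpe_rows Alternative inputs to compute the normalizer.
#' @param rescale Rescale to max 1 after RPE division.
#' @return Normalized profile.
#' @export
normalize_to_rpe <- function(profile, rpe_band_mean = NULL, bscan = NULL,
                             rpe_rows = NULL, rescale = TRUE) {
  if (is.null(rpe_band_mean)) {
    stopifnot(!is.null(bscan), !is.null(rpe_rows))
    rpe_band_mean <- rpe_band_median(bscan, rpe_rows)
  }
  if (!is.finite(rpe_band_mean) || rpe_band_mean <= 0)
    stop("non-positive RPE normalizer")
  out <- profile / rpe_band_mean
  if (rescale && max(out) > 0) out <- out / max(out)
  out
}

#' Smooth an azimuthal profile (lowess / loess)
#'
#' Locally weighted regression: degree 1 for `"lowess"`, degree 2 for
#' `"loess"`. Circumpapillary profiles are circular, so the profile is
#' wrap-padded by `span * N` samples on each side before smoothing and
#' cropped afterwards.
#'
#' @param profile Numeric profile (>= 10 samples).
#' @param method `"lowess"` or `"loess"`.
#' @param span Smoother span as a fraction of the data in `(0, 1]`.
#' @param circular Wrap-pad for circular (CP) profiles.
#' @return Smoothed profile, same length.
#' @export
smooth_profile <- function(profile, method = c("lowess", "loess"),
                           span = 0.05, circular = TRUE) {
  method <- match.arg(method)
  n <- length(profile)
  if (n < 10) stop("too few samples to smooth")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  pad <- if (circular) min(n, max(3L, ceiling(span * n))) else 0L
  y <- if (pad > 0) c(profile[(n - pad + 1L):n], profile, profile[1:pad]) else profile
  x <- seq_along(y)
  eff_span <- span * n / length(y)
  sm <- if (method == "lowess") {
    stats::lowess(x, y, f = eff_span, iter = 2)$y
  } else {
    fit <- stats::loess(y ~ x, span = eff_span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, x)
  }
  sm[(pad + 1L):(pad + n)]
}

#' Per-channel azimuthal window profiles of a CP stack
#'
#' For each channel: window means averaged over `n_bscans` consecutive
#' B-scans, normalized to the RPE, then smoothed. The azimuth axis comes
#' from the scan pattern.
#'
#' @param stack A registered [mdoct_stack()].
#' @param boundaries List with `ilm` and `rpe` matrices
#'   (`ascans x bscans`), e.g. [segment_stack()] output or phantom truth
#'   anchors.
#' @param preset Window preset (`"isos_cost"` or `"rnfl"`).
#' @param n_bscans B-scans to average (10 by default; fewer available =>
#'   uses all with a warning).
#' @param method,span Smoothing parameters, see [smooth_profile()].
#' @return Object of class `directional_profiles`: list with `azimuth`
#'   and per channel `raw`, `normalized`, `smoothed` matrices
#'   (`ascans x 3`), plus display colours.
#' @export
azimuthal_profiles <- function(stack, boundaries, preset = "isos_cost",
                               n_bscans = 10L, method = "lowess", span = 0.05) {
  stopifnot(inherits(stack, "mdoct_stack"))
  if (!stack$registered) stop("stack must be registered")
  nb_avail <- dim(stack$channels[[1]])[3]
  if (nb_avail < n_bscans) {
    warning(sprintf("only %d B-scans available (%d requested)", nb_avail, n_bscans))
    n_bscans <- nb_avail
  }
  n <- dim(stack$channels[[1]])[2]
  depth <- dim(stack$channels[[1]])[1]
  circular <- stack$pattern$kind == "circumpapillary"
  az <- scan_azimuths(stack$pattern)
  raw <- norm <- sm <- matrix(0, n, 3)
  for (c in 1:3) {
    acc <- numeric(n); normacc <- 0
    for (j in seq_len(n_bscans)) {
      b <- get_bscan(stack, c, j)
      anchor <- if (preset == "isos_cost") boundaries$rpe[, j] else boundaries$ilm[, j]
      w <- eval_window(anchor, preset, image_depth = depth)
      acc <- acc + window_mean(b, w)
      normacc <- normacc + rpe_band_median(b, boundaries$rpe[, j])
    }
    raw[, c] <- acc / n_bscans
    norm[, c] <- normalize_to_rpe(raw[, c], rpe_band_mean = normacc / n_bscans)
    sm[, c] <- smooth_profile(norm[, c], method, span, circular)
  }
  structure(list(azimuth = az, raw = raw, normalized = norm, smoothed = sm,
                 colors = c("cyan", "magenta", "yellow"),
                 n_averaged_bscans = n_bscans, preset = preset,
                 circular = circular),
            class = "directional_profiles")
}

## ---------------------------------------------------------------------
## Peak / sector detection

#' Circular peak detection with prominence
#'
#' Local maxima of a circular profile whose prominence (height above the
#' higher of the two saddle minima separating the peak from higher
#' terrain) exceeds `prominence` times the profile range.
#'
#' @param y Numeric circular profile.
#' @param azimuth Matching azimuths (degrees); defaults to uniform
#'   `[0, 360)`.
#' @param prominence Minimum prominence as a fraction of `diff(range(y))`.
#' @return Data frame with `azimuth`, `height`, `prominence`, ordered by
#'   decreasing height.
#' @export
find_circular_peaks <- function(y, azimuth = NULL, prominence = 0.1) {
  n <- length(y)
  azimuth <- azimuth %||% ((seq_len(n) - 1) / n * 360)
  rng <- diff(range(y))
  if (rng == 0) stop("no peaks above threshold: constant profile")
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1))
  cand <- which(y > y[prv] & y >= y[nxt])
  if (!length(cand)) stop("no peaks above threshold")
  prom <- vapply(cand, function(i) {
    ## walk both ways to the first strictly higher sample
    lo_l <- y[i]; j <- i
    repeat {
      j <- prv[j]
      if (j == i || y[j] > y[i]) break
      lo_l <- min(lo_l, y[j])
    }
    lo_r <- y[i]; j <- i
    repeat {
      j <- nxt[j]
      if (j == i || y[j] > y[i]) break
      lo_r <- min(lo_r, y[j])
    }
    if (lo_l == y[i] && lo_r == y[i]) return(y[i] - min(y))  # global max
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= prominence * rng
  if (!any(keep)) stop("no peaks above threshold")
  out <- data.frame(azimuth = azimuth[cand[keep]], height = y[cand[keep]],
                    prominence = prom[keep])
  out[order(-out$height), , drop = FALSE]
}

#' Detect directional sectors from smoothed profiles
#'
#' Finds the prominent circular peaks of each channel's smoothed profile
#' and summarizes: per-channel peak azimuths, circular separations
#' between the primary peaks of the channel pairs (photoreceptor-type
#' directionality: one lobe per channel, ~120 degrees apart for the
#' equilateral beam triangle), and within-channel separations when a
#' channel has two lobes (RNFL-type, ~180 degrees).
#'
#' @param profiles A `directional_profiles` object.
#' @param prominence Peak prominence threshold (fraction of range).
#' @param max_peaks Keep at most this many peaks per channel.
#' @return Object of class `sector_summary`: list with `peaks` (list of
#'   per-channel azimuth vectors), `channel_separations` (circular
#'   distances between primary peaks of channel pairs 1-2, 2-3, 3-1),
#'   `within_separations` (per channel, between its two strongest peaks,
#'   `NA` if single-lobed), and `sector_count`.
#' @export
detect_sectors <- function(profiles, prominence = 0.1, max_peaks = 2L) {
  stopifnot(inherits(profiles, "directional_profiles"))
  peaks <- vector("list", 3)
  for (c in 1:3) {
    p <- find_circular_peaks(profiles$smoothed[, c], profiles$azimuth,
                             prominence)
    peaks[[c]] <- utils::head(p$azimuth, max_peaks)
  }
  prim <- vapply(peaks, `[`, numeric(1), 1)
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
  chsep <- apply(pairs, 1, function(pr) circ_dist(prim[pr[1]], prim[pr[2]]))
  names(chsep) <- c("1-2", "2-3", "3-1")
  wsep <- vapply(peaks, function(p)
    if (length(p) >= 2) circ_dist(p[1], p[2]) else NA_real_, numeric(1))
  structure(list(peaks = peaks, channel_separations = chsep,
                 within_separations = wsep,
                 sector_count = sum(lengths(peaks))),
            class = "sector_summary")
}

#' @export
print.sector_summary <- function(x, ...) {
  for (c in 1:3)
    cat(sprintf("channel %d peaks: %s deg\n", c,
                paste(round(x$peaks[[c]], 1), collapse = ", ")))
  cat("channel separations (primary peaks):",
      paste(round(x$channel_separations, 1), collapse = ", "), "deg\n")
  if (any(!is.na(x$within_separations)))
    cat("within-channel lobe separations:",
        paste(round(x$within_separations, 1), collapse = ", "), "deg\n")
  invisible(x)
}

#' Dominant-channel sectors of a profile set
#'
#' Labels every azimuth with the channel of highest smoothed intensity
#' and counts the contiguous circular runs — the number of colour
#' sectors a colour-averaged image shows.
#'
#' @param profiles A `directional_profiles` object.
#' @return List with `labels` (per-azimuth channel index) and
#'   `n_sectors` (circular run count).
#' @export
dominant_channel_sectors <- function(profiles) {
  lab <- max.col(profiles$smoothed, ties.method = "first")
  r <- rle(lab)
  n <- length(r$values)
  if (n > 1 && r$values[1] == r$values[n]) n <- n - 1  # circular merge
  list(labels = lab, n_sectors = n)
}

## ---------------------------------------------------------------------
## Colour fusion and projections

#' Display scaling for colour fusion
#'
#' Log-compresses linear intensity (10 log10 with a floor at the 0.1th
#' percentile of positive values), clips to the 1st..99.5th percentile
#' and scales to `[0, 1]`.
#'
#' @param img Linear-intensity matrix (or array).
#' @param lo,hi Clip quantiles.
#' @return Same shape, values in `[0, 1]`.
#' @export
display_scale <- function(img, lo = 0.01, hi = 0.995) {
  x <- log_scale(img)
  q <- stats::quantile(x, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim(img) %||% length(img)))
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

#' @keywords internal
tinted_channels <- function(stack, bscan, scaled) {
  stopifnot(inherits(stack, "mdoct_stack"))
  if (!stack$registered) stop("stack must be registered for colour fusion")
  imgs <- lapply(1:3, function(c) get_bscan(stack, c, bscan))
  if (scaled) {
    ## joint scaling so channel intensities stay comparable
    q <- stats::quantile(log_scale(do.call(cbind, imgs)), c(0.01, 0.995),
                         names = FALSE)
    imgs <- lapply(imgs, function(im)
      pmin(pmax((log_scale(im) - q[1]) / max(q[2] - q[1], 1e-12), 0), 1))
  }
  imgs
}

## tint matrix: rows = channels (cyan, magenta, yellow), cols = RGB
.tints <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))

#' Colour-averaged fusion of the three channels
#'
#' Tints channel 1 cyan, channel 2 magenta, channel 3 yellow and
#' averages the tinted images per RGB component. Equal channel
#' intensities yield an achromatic (grey) pixel; dominance of one
#' channel yields its hue.
#'
#' @param stack A registered [mdoct_stack()].
#' @param bscan B-scan index.
#' @param scaled Apply [display_scale()] first (set `FALSE` if the input
#'   is already display-scaled to `[0, 1]`).
#' @return Array `depth x ascans x 3` (RGB).
#' @export
color_average <- function(stack, bscan = 1L, scaled = TRUE) {
  imgs <- tinted_channels(stack, bscan, scaled)
  d <- dim(imgs[[1]])
  out <- array(0, c(d, 3))
  for (comp in 1:3)
    out[, , comp] <- (.tints[1, comp] * imgs[[1]] + .tints[2, comp] * imgs[[2]] +
                        .tints[3, comp] * imgs[[3]]) / 3
  out
}

#' Colour maximum-intensity fusion
#'
#' Per-pixel, per-RGB-component maximum of the tinted channel images.
#' Componentwise >= [color_average()] everywhere.
#'
#' @inheritParams color_average
#' @return Array `depth x ascans x 3` (RGB).
#' @export
color_mip <- function(stack, bscan = 1L, scaled = TRUE) {
  imgs <- tinted_channels(stack, bscan, scaled)
  d <- dim(imgs[[1]])
  out <- array(0, c(d, 3))
  for (comp in 1:3)
    out[, , comp] <- pmax(.tints[1, comp] * imgs[[1]], .tints[2, comp] * imgs[[2]],
                          .tints[3, comp] * imgs[[3]])
  out
}

#' Intensity maximum projection across channels
#'
#' Per-pixel maximum of the three linear-intensity channels: directional
#' reflectivity compensation — whichever channel sees the structure best
#' supplies the pixel.
#'
#' @param stack A registered [mdoct_stack()].
#' @param bscan B-scan index.
#' @return Linear-intensity matrix.
#' @export
intensity_mip <- function(stack, bscan = 1L) {
  stopifnot(inherits(stack, "mdoct_stack"))
  if (!stack$registered) stop("stack must be registered")
  pmax(get_bscan(stack, 1, bscan), get_bscan(stack, 2, bscan),
       get_bscan(stack, 3, bscan))
}

#' Intensity average across channels
#'
#' Per-pixel mean of the three linear-intensity channels — threefold
#' angular compounding, the input to the speckle-reduction metrics.
#'
#' @inheritParams intensity_mip
#' @return Linear-intensity matrix.
#' @export
intensity_average <- function(stack, bscan = 1L) {
  stopifnot(inherits(stack, "mdoct_stack"))
  if (!stack$registered) stop("stack must be registered")
  (get_bscan(stack, 1, bscan) + get_bscan(stack, 2, bscan) +
     get_bscan(stack, 3, bscan)) / 3
}

#' En-face colour MIP of a boundary-anchored slab
#'
#' For every (A-scan, B-scan) position, takes the per-channel maximum
#' intensity over a slab of rows anchored to a boundary (e.g. ~25 um —
#' 7 px at 3.5 um pitch — just anterior of the HFL lower boundary),
#' display-scales the three en-face images jointly and fuses them as a
#' colour MIP.
#'
#' @param stack A registered [mdoct_stack()] volume.
#' @param boundary `ascans x bscans` anchor rows.
#' @param top_offset Signed offset of the slab top from the anchor.
#' @param thickness_px Slab thickness in pixels (> 0).
#' @return Array `ascans x bscans x 3` (RGB en-face map).
#' @export
enface_color_mip <- function(stack, boundary, top_offset = 0L,
                             thickness_px = 7L) {
  stopifnot(inherits(stack, "mdoct_stack"))
  if (!stack$registered) stop("stack must be registered")
  if (thickness_px < 1) stop("slab thickness must be >= 1 pixel")
  d <- dim(stack$channels[[1]])
  if (!all(dim(boundary) == d[2:3])) stop("boundary/volume dimension mismatch")
  top <- round(boundary) + top_offset
  if (any(top < 1) || any(top + thickness_px - 1 > d[1]))
    stop("slab outside volume")
  ef <- lapply(1:3, function(c) {
    E <- matrix(0, d[2], d[3])
    for (j in seq_len(d[3])) for (i in seq_len(d[2]))
      E[i, j] <- max(stack$channels[[c]][top[i, j]:(top[i, j] + thickness_px - 1L), i, j])
    E
  })
  q <- stats::quantile(log_scale(do.call(cbind, ef)), c(0.01, 0.995),
                       names = FALSE)
  ef <- lapply(ef, function(E)
    pmin(pmax((log_scale(E) - q[1]) / max(q[2] - q[1], 1e-12), 0), 1))
  out <- array(0, c(d[2], d[3], 3))
  for (comp in 1:3)
    out[, , comp] <- pmax(.tints[1, comp] * ef[[1]], .tints[2, comp] * ef[[2]],
                          .tints[3, comp] * ef[[3]])
  out
}
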