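## Graph-based retinal boundary segmentation: an exact dynamic-programming
## shortest path through a per-pixel cost image, with a hard limit on the
## row jump between neighbouring A-scans.

## Log display scaling used by cost construction: 10*log10 with a floor
## at a low quantile of the positive values (linear OCT intensity spans
## orders of magnitude; edges are far better conditioned in log scale).
#' @keywords internal
log_scale <- function(img, floor_quantile = 1e-3) {
  pos <- img[img > 0]
  fl <- if (length(pos)) stats::quantile(pos, floor_quantile, names = FALSE)
        else .Machine$double.eps
  10 * log10(pmax(img, fl))
}

#' Gradient cost image for boundary search
#'
#' Cost in `[0, 1]`, low at vertical edges of the requested polarity.
#' The image is log-scaled and lightly blurred (Gaussian `sigma`), the
#' signed central vertical gradient is taken (positive = intensity
#' increasing with depth), oriented by `polarity`, min-max normalized
#' and inverted. A constant image yields uniform cost 1.
#'
#' @param bscan Linear-intensity matrix `depth x ascans`.
#' @param polarity `"dark_to_bright"` (e.g. vitreous to ILM) or
#'   `"bright_to_dark"`.
#' @param sigma Blur standard deviation in pixels.
#' @return Cost matrix, same shape, values in `[0, 1]`.
#' @export
gradient_cost <- function(bscan, polarity = c("dark_to_bright", "bright_to_dark"),
                          sigma = 2) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(bscan), all(is.finite(bscan)))
  B <- gaussian_blur(log_scale(bscan), sigma)
  n <- nrow(B)
  up <- B[c(1, seq_len(n - 1)), , drop = FALSE]
  dn <- B[c(seq_len(n)[-1], n), , drop = FALSE]
  g <- (dn - up) / 2
  if (polarity == "bright_to_dark") g <- -g
  rng <- range(g)
  if (rng[2] == rng[1]) return(matrix(1, nrow(bscan), ncol(bscan)))
  1 - (g - rng[1]) / (rng[2] - rng[1])
}

#' Minimum-cost boundary path
#'
#' Exact dynamic-programming shortest path from the left to the right
#' image edge: one row per column, successive columns differing by at
#' most `jump_limit` rows. Path cost is the sum of visited pixel costs.
#' Ties are broken toward the smaller row index.
#'
#' @param cost Cost matrix `depth x ascans`.
#' @param jump_limit Maximum |row difference| between adjacent columns.
#' @return Integer vector of row indices, one per column, with attribute
#'   `"cost"` (total path cost).
#' @export
find_boundary <- function(cost, jump_limit = 2L) {
  stopifnot(is.matrix(cost), nrow(cost) >= 1, ncol(cost) >= 1)
  jump_limit <- as.integer(jump_limit)
  nr <- nrow(cost); nc <- ncol(cost)
  D <- cost[, 1]
  ptr <- matrix(0L, nr, nc)
  offs <- seq.int(-jump_limit, jump_limit)
  for (j in seq_len(nc)[-1]) {
    best <- rep(Inf, nr); bestprev <- integer(nr)
    for (o in offs) {                      # increasing o => increasing prev row
      prev <- seq_len(nr) + o
      ok <- prev >= 1L & prev <= nr
      cand <- rep(Inf, nr)
      cand[ok] <- D[prev[ok]]
      upd <- cand < best                   # strict: keeps smallest prev row on ties
      best[upd] <- cand[upd]
      bestprev[upd] <- prev[upd]
    }
    D <- best + cost[, j]
    ptr[, j] <- bestprev
  }
  path <- integer(nc)
  path[nc] <- which.min(D)                 # which.min -> smallest row on ties
  if (nc > 1) for (j in nc:2) path[j - 1] <- ptr[path[j], j]
  structure(path, cost = sum(cost[cbind(path, seq_len(nc))]))
}

## Presence check: with no retina the row-mean profile of the linear
## image is flat up to noise. Contrast is (max - min) of the row means
## in units of the profile's own noise scale.
#' @keywords internal
profile_contrast <- function(bscan) {
  m <- rowMeans(bscan)
  noise <- stats::mad(diff(m)) / sqrt(2)
  if (noise == 0) noise <- .Machine$double.eps
  (max(m) - min(m)) / noise
}

#' Segment the inner limiting membrane (ILM)
#'
#' Topmost strong dark-to-bright edge: the DP path through the
#' dark-to-bright gradient cost with a small anterior row bias so the
#' vitreous/retina transition wins over deeper edges of equal strength.
#'
#' @param bscan Linear-intensity matrix `depth x ascans`.
#' @param jump_limit Maximum row jump between A-scans.
#' @param sigma Cost blur sigma.
#' @param anterior_bias Cost added per normalized row depth (biases the
#'   path anteriorly).
#' @param min_profile_snr Reject images whose row-mean contrast (in
#'   noise units) is below this — no retina present.
#' @return Integer row per A-scan (class `mdoct_boundary`).
#' @export
segment_ilm <- function(bscan, jump_limit = 2L, sigma = 2,
                        anterior_bias = 0.15, min_profile_snr = 12) {
  if (profile_contrast(bscan) < min_profile_snr)
    stop("segmentation-failed: no retinal structure detected")
  cost <- gradient_cost(bscan, "dark_to_bright", sigma)
  bias <- (seq_len(nrow(cost)) - 1) / max(nrow(cost) - 1, 1)
  cost <- cost + anterior_bias * bias
  find_boundary(cost, jump_limit)
}

#' Segment the retinal pigment epithelium (RPE)
#'
#' Path through the maximum-brightness band: cost is one minus the
#' normalized blurred log intensity, restricted below the ILM, with a
#' small posterior bias so the bright RPE band wins over the (thick)
#' RNFL. Vessel-shadow columns — where the intensity in a band around
#' the path falls below `vessel_frac` of the band's B-scan median — are
#' flagged and the boundary linearly interpolated across them.
#'
#' @param bscan Linear-intensity matrix.
#' @param ilm Optional per-A-scan ILM rows (estimated if missing).
#' @param jump_limit Maximum row jump between A-scans.
#' @param sigma Blur sigma.
#' @param min_offset Minimum rows below the ILM to search.
#' @param posterior_bias Cost subtracted per normalized row depth.
#' @param vessel_frac Shadow flagging threshold (fraction of the median
#'   band intensity).
#' @param min_profile_snr Presence threshold, as in [segment_ilm()].
#' @return Numeric row per A-scan with attribute `"flags"` (logical,
#'   TRUE where the column was vessel-flagged and interpolated).
#' @export
segment_rpe <- function(bscan, ilm = NULL, jump_limit = 2L, sigma = 2,
                        min_offset = 25L, posterior_bias = 0.05,
                        vessel_frac = 0.35, min_profile_snr = 12) {
  if (profile_contrast(bscan) < min_profile_snr)
    stop("segmentation-failed: no retinal structure detected")
  if (is.null(ilm)) ilm <- segment_ilm(bscan, jump_limit, sigma)
  B <- gaussian_blur(log_scale(bscan), sigma)
  rng <- range(B)
  cost <- if (rng[2] > rng[1]) 1 - (B - rng[1]) / (rng[2] - rng[1])
          else matrix(1, nrow(B), ncol(B))
  bias <- (seq_len(nrow(cost)) - 1) / max(nrow(cost) - 1, 1)
  cost <- cost - posterior_bias * bias
  ## exclude rows above ILM + min_offset
  nr <- nrow(cost)
  lim <- pmin(ilm + min_offset, nr)
  mask <- matrix(seq_len(nr), nr, ncol(cost)) <
    matrix(lim, nr, ncol(cost), byrow = TRUE)
  cost[mask] <- 2
  path <- find_boundary(cost, jump_limit)
  ## vessel flagging on a band around the path
  half <- 4L
  nc <- ncol(bscan)
  band <- vapply(seq_len(nc), function(j) {
    rows <- max(1L, path[j] - half):min(nr, path[j] + half)
    mean(bscan[rows, j])
  }, numeric(1))
  flags <- band < vessel_frac * stats::median(band)
  out <- as.numeric(path)
  if (any(flags) && !all(flags)) {
    idx <- seq_len(nc)
    out[flags] <- stats::approx(idx[!flags], out[!flags], xout = idx[flags],
                                rule = 2)$y
  }
  structure(out, flags = flags, cost = attr(path, "cost"))
}

#' Segment ILM and RPE for every B-scan of a stack
#'
#' @param stack An [mdoct_stack()].
#' @param channel Channel to segment on (default 1; for a fused or
#'   registered stack the channels share geometry).
#' @param ... Passed to [segment_ilm()] / [segment_rpe()].
#' @return List with `ilm` and `rpe` (matrices `ascans x bscans`) and
#'   `flags` (vessel flags, same shape).
#' @export
segment_stack <- function(stack, channel = 1L, ...) {
  stopifnot(inherits(stack, "mdoct_stack"))
  nb <- dim(stack$channels[[1]])[3]
  n <- dim(stack$channels[[1]])[2]
  ilm <- matrix(0, n, nb); rpe <- matrix(0, n, nb)
  flags <- matrix(FALSE, n, nb)
  for (j in seq_len(nb)) {
    b <- get_bscan(stack, channel, j)
    ilm[, j] <- segment_ilm(b, ...)
    r <- segment_rpe(b, ilm = ilm[, j], ...)
    rpe[, j] <- r
    flags[, j] <- attr(r, "flags")
  }
  list(ilm = ilm, rpe = rpe, flags = flags)
}
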