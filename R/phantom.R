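## Forward simulator: three-channel retinal phantoms with known layer
## boundaries, azimuth-dependent layer reflectance, fully developed
## speckle, additive background noise, vessel shadows and per-channel
## depth offsets; optionally raw spectral fringes for exercising the
## SD-OCT reconstruction chain.

#' Multi-channel B-scan stack container
#'
#' @param channels List of three numeric arrays `depth x ascans x bscans`
#'   (matrices are promoted to single-B-scan arrays), linear intensity.
#' @param pattern The [scan_pattern()] the stack was acquired with.
#' @param pitch_um Axial pixel pitch in micrometres.
#' @param channel_azimuths_deg Pupil entry azimuths of the channels.
#' @param registered Logical: channels share a common depth origin.
#' @param truth Optional `phantom_truth` the stack was rendered from.
#' @return Object of class `mdoct_stack`.
#' @export
mdoct_stack <- function(channels, pattern, pitch_um = 3.5,
                        channel_azimuths_deg = c(90, 210, 330),
                        registered = FALSE, truth = NULL) {
  stopifnot(length(channels) == 3)
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, c(dim(ch), 1L))
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  d <- dim(channels[[1]])
  for (ch in channels) if (!identical(dim(ch), d))
    stop("all channels must share dimensions")
  structure(list(channels = channels, pattern = pattern, pitch_um = pitch_um,
                 channel_azimuths_deg = channel_azimuths_deg,
                 registered = registered, truth = truth),
            class = "mdoct_stack")
}

#' @export
print.mdoct_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("mdoct_stack: 3 channels, %d depth px x %d A-scans x %d B-scans (%s)\n",
              d[1], d[2], d[3], x$pattern$kind),
      sprintf("  pitch %g um, registered: %s, truth: %s\n", x$pitch_um,
              x$registered, !is.null(x$truth)), sep = "")
  invisible(x)
}

#' Extract one B-scan
#' @param stack An `mdoct_stack`.
#' @param channel Channel index 1..3.
#' @param bscan B-scan index.
#' @return Numeric matrix `depth x ascans`.
#' @export
get_bscan <- function(stack, channel, bscan = 1L) {
  stopifnot(inherits(stack, "mdoct_stack"))
  stack$channels[[channel]][, , bscan]
}

## ---------------------------------------------------------------------
## Ground truth

#' Phantom ground truth
#'
#' Layer interface rows per A-scan (and per B-scan for raster volumes),
#' vessel positions, per-channel depth offsets and the axial pitch.
#' A smooth azimuthal undulation is applied to all interfaces so the
#' retina is not artificially flat; raster volumes get a foveal pit
#' (inner interfaces converge onto the ONL near the volume centre).
#'
#' @param pattern A [scan_pattern()].
#' @param interfaces Named anterior interface rows, see
#'   [default_interfaces()].
#' @param depth_px Imaging depth in pixels.
#' @param undulation_px Amplitude of the smooth interface undulation.
#' @param undulation_cycles Cycles of undulation per revolution.
#' @param vessels Data frame with columns `azimuth_deg`, `halfwidth_deg`
#'   (circumpapillary vessel shadow positions); `NULL` for none.
#' @param channel_depth_offsets Integer axial offsets (pixels) emulating
#'   sample-arm length mismatch between the three channels.
#' @param pitch_um Axial pixel pitch, micrometres.
#' @param foveal_pit Add a foveal depression (raster patterns).
#' @return Object of class `phantom_truth` with element `boundaries`
#'   (array `ascans x layers x bscans`) and `anchors` (list with
#'   per-A-scan `ilm` and `rpe` anchor rows, the targets of automated
#'   segmentation: the ILM interface and the bright centre row of the
#'   RPE band).
#' @export
phantom_truth <- function(pattern,
                          interfaces = default_interfaces(),
                          depth_px = 280L,
                          undulation_px = 4,
                          undulation_cycles = 2,
                          vessels = default_vessels(),
                          channel_depth_offsets = c(0L, 0L, 0L),
                          pitch_um = 3.5,
                          foveal_pit = (pattern$kind == "raster")) {
  stopifnot(inherits(pattern, "scan_pattern"))
  if (any(diff(interfaces) <= 0)) stop("interfaces must be strictly increasing")
  if (max(interfaces) >= depth_px) stop("interfaces must lie within depth")
  n <- pattern$ascans_per_bscan
  nb <- pattern$bscans
  nl <- length(interfaces)
  az <- scan_azimuths(pattern)
  und <- round(undulation_px * sin(undulation_cycles * az * pi / 180 + 0.7))
  b <- array(0L, c(n, nl, nb), dimnames = list(NULL, names(interfaces), NULL))
  for (k in seq_len(nl)) b[, k, ] <- interfaces[k] + und
  if (foveal_pit) {
    cx <- (n + 1) / 2; cy <- (nb + 1) / 2
    rx <- n / 6; ry <- max(nb / 6, 1)
    inner <- intersect(c("ILM", "RNFL", "GCL_OPL", "HFL"), names(interfaces))
    onl <- if ("ONL" %in% names(interfaces)) interfaces[["ONL"]] else max(interfaces)
    for (j in seq_len(nb)) {
      r2 <- ((seq_len(n) - cx) / rx)^2 + ((j - cy) / ry)^2
      pit <- exp(-r2 / 2)  # 1 at the pit centre
      for (nm in inner) {
        row0 <- b[, nm, j]
        b[, nm, j] <- as.integer(round(row0 + pit * (onl - 2 - row0)))
      }
      ## keep strict ordering after the pinch
      for (k in 2:nl) b[, k, j] <- pmax(b[, k, j], b[, k - 1, j] + 1L)
    }
  }
  if (any(b < 1L) || any(b > depth_px)) stop("boundaries leave the image")
  rpe_half <- if (all(c("RPE", "choroid") %in% names(interfaces)))
    (interfaces[["choroid"]] - interfaces[["RPE"]] - 1L) %/% 2L else 0L
  anchors <- list()
  if ("ILM" %in% names(interfaces)) anchors$ilm <- b[, "ILM", , drop = FALSE]
  if ("RPE" %in% names(interfaces)) anchors$rpe <- b[, "RPE", , drop = FALSE] + rpe_half
  shadow_row <- if ("ILM" %in% names(interfaces))
    unname(interfaces["ILM"] + 15L) else min(interfaces)
  structure(list(boundaries = b, depth_px = as.integer(depth_px),
                 vessels = vessels,
                 vessel_shadow_row = shadow_row,
                 channel_depth_offsets = as.integer(channel_depth_offsets),
                 pitch_um = pitch_um,
                 anchors = anchors),
            class = "phantom_truth")
}

#' Default circumpapillary vessel layout
#'
#' Two retinal vessels casting shadows below the inner retina.
#' @return Data frame with `azimuth_deg` and `halfwidth_deg`.
#' @export
default_vessels <- function() {
  data.frame(azimuth_deg = c(55, 230), halfwidth_deg = c(2, 2))
}

#' Truth anchor rows for one B-scan
#' @param truth A `phantom_truth`.
#' @param which `"ilm"` or `"rpe"`.
#' @param bscan B-scan index.
#' @return Per-A-scan anchor rows.
#' @export
truth_anchor <- function(truth, which = c("ilm", "rpe"), bscan = 1L) {
  which <- match.arg(which)
  truth$anchors[[which]][, 1, bscan]
}

## Azimuth of every (A-scan, B-scan) position: circumpapillary scans use
## the scan azimuth; linear/raster scans use the polar angle about the
## scan centre (the fovea), which is what drives the radially oriented
## photoreceptor/HFL directionality there.
#' @keywords internal
azimuth_field <- function(pattern) {
  n <- pattern$ascans_per_bscan; nb <- pattern$bscans
  if (pattern$kind == "circumpapillary") {
    matrix(scan_azimuths(pattern), n, nb)
  } else {
    cx <- (n + 1) / 2; cy <- (nb + 1) / 2
    dx <- seq_len(n) - cx
    dy <- seq_len(nb) - cy
    wrap360(outer(dx, dy, function(x, y) atan2(y, x) * 180 / pi))
  }
}

## ---------------------------------------------------------------------
## Rendering

## Expected (pre-speckle, pre-noise) intensity image of one channel and
## one B-scan: piecewise-constant in depth by layer, scaled per A-scan by
## the layer's directional gain at that azimuth, vessel columns
## attenuated below the vessel row.
#' @keywords internal
expected_intensity_bscan <- function(truth, layers, azimuths, channel_azimuth,
                                     bscan = 1L, shadow_factor = 0.2,
                                     apply_vessels = TRUE) {
  n <- dim(truth$boundaries)[1]
  nl <- dim(truth$boundaries)[2]
  depth <- truth$depth_px
  stopifnot(length(layers) == nl, length(azimuths) == n)
  ## layer index image: number of interfaces at or above each row
  L <- matrix(0L, depth, n)
  rowidx <- matrix(seq_len(depth), depth, n)
  for (k in seq_len(nl))
    L <- L + (rowidx >= matrix(truth$boundaries[, k, bscan], depth, n, byrow = TRUE))
  ## per-layer, per-A-scan expected intensity
  A <- matrix(0, nl, n)
  for (k in seq_len(nl))
    A[k, ] <- layers[[k]]$base_reflectivity *
      directional_gain(layers[[k]], azimuths, channel_azimuth)
  E <- matrix(0, depth, n)
  inside <- L > 0L
  colidx <- matrix(rep(seq_len(n), each = depth), depth, n)
  E[inside] <- A[L[inside] + nl * (colidx[inside] - 1L)]
  if (apply_vessels && !is.null(truth$vessels) && nrow(truth$vessels) > 0) {
    shadow_rows <- truth$vessel_shadow_row:depth
    for (v in seq_len(nrow(truth$vessels))) {
      cols <- which(circ_dist(azimuths, truth$vessels$azimuth_deg[v]) <=
                      truth$vessels$halfwidth_deg[v])
      if (length(cols)) E[shadow_rows, cols] <- E[shadow_rows, cols] * shadow_factor
    }
  }
  E
}

#' Expected intensity field of the phantom
#'
#' The noise-free, speckle-free intensity a channel would record:
#' the analytic profile that windowed means converge to. Depth offsets
#' are applied so the field matches the rendered channel geometry.
#'
#' @param truth A [phantom_truth()].
#' @param layers Layer list, see [default_retina_layers()].
#' @param pattern The [scan_pattern()].
#' @param channel Channel index 1..3.
#' @param channel_azimuths_deg Pupil entry azimuths.
#' @param bscan B-scan index.
#' @param shadow_factor Multiplicative vessel shadow attenuation.
#' @return Matrix `depth x ascans`.
#' @export
expected_intensity_field <- function(truth, layers, pattern, channel = 1L,
                                     channel_azimuths_deg = c(90, 210, 330),
                                     bscan = 1L, shadow_factor = 0.2) {
  azf <- azimuth_field(pattern)
  E <- expected_intensity_bscan(truth, layers, azf[, bscan],
                                channel_azimuths_deg[channel], bscan,
                                shadow_factor)
  shift_rows(E, truth$channel_depth_offsets[channel])
}

#' Render a three-channel phantom stack
#'
#' For every channel and pixel the expected intensity (layer base
#' reflectivity times the layer's directional gain at the local azimuth)
#' is multiplied by unit-mean exponential speckle — fully developed
#' speckle, independent across channels unless `speckle_rho > 0` — and
#' zero-mean Gaussian background noise is added everywhere (the vitreous
#' above the ILM therefore contains noise only). Vessel columns are
#' attenuated below the vessel row, and each channel is shifted axially
#' by its depth offset before the noise is added.
#'
#' @param truth A [phantom_truth()].
#' @param geometry A [beam_geometry()] (channel azimuths).
#' @param pattern The [scan_pattern()].
#' @param layers Layer list, see [default_retina_layers()].
#' @param seed Integer seed fixing all randomness.
#' @param speckle Multiply by exponential speckle.
#' @param speckle_rho Shared-component speckle mixing fraction in
#'   `[0, 1]`: 0 gives channel-independent speckle, 1 fully common.
#' @param noise_sd Standard deviation of the additive Gaussian
#'   background noise (linear intensity units).
#' @param shadow_factor Vessel shadow attenuation factor.
#' @return An [mdoct_stack()] carrying `truth`.
#' @export
render_multichannel <- function(truth, geometry = beam_geometry(),
                                pattern, layers = default_retina_layers(),
                                seed = 1L, speckle = TRUE, speckle_rho = 0,
                                noise_sd = 0.05, shadow_factor = 0.2) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(pattern, "scan_pattern"))
  if (dim(truth$boundaries)[1] != pattern$ascans_per_bscan ||
      dim(truth$boundaries)[3] != pattern$bscans)
    stop("pattern/truth size mismatch")
  if (speckle_rho < 0 || speckle_rho > 1) stop("speckle_rho must be in [0, 1]")
  set.seed(as.integer(seed))
  depth <- truth$depth_px
  n <- pattern$ascans_per_bscan; nb <- pattern$bscans
  azf <- azimuth_field(pattern)
  phic <- geometry$channel_azimuths_deg
  channels <- vector("list", 3)
  for (c in 1:3) channels[[c]] <- array(0, c(depth, n, nb))
  for (j in seq_len(nb)) {
    shared <- if (speckle && speckle_rho > 0)
      matrix(stats::rexp(depth * n), depth, n) else NULL
    for (c in 1:3) {
      E <- expected_intensity_bscan(truth, layers, azf[, j], phic[c], j,
                                    shadow_factor)
      img <- E
      if (speckle) {
        S <- matrix(stats::rexp(depth * n), depth, n)
        if (!is.null(shared)) S <- (1 - speckle_rho) * S + speckle_rho * shared
        img <- img * S
      }
      img <- shift_rows(img, truth$channel_depth_offsets[c])
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(depth * n, sd = noise_sd), depth, n)
      channels[[c]][, , j] <- img
    }
  }
  mdoct_stack(channels, pattern, pitch_um = truth$pitch_um,
              channel_azimuths_deg = phic,
              registered = all(truth$channel_depth_offsets == 0L),
              truth = truth)
}

## ---------------------------------------------------------------------
## Raw spectral fringes

#' Synthesize raw spectral fringes for the phantom
#'
#' Each A-scan spectrum is a Gaussian source envelope times
#' `1 + sum_r 2 sqrt(R_r) cos(2 k z_r + a2 (k - k0)^2 + a3 (k - k0)^3)`,
#' sampled on a grid uniform in wavelength (hence non-uniform in
#' wavenumber). Reflectivities `R_r` are taken from the phantom's
#' expected-intensity column (scaled to keep the fringe modulation well
#' below the envelope); reflector depths map to reconstruction depth
#' pixels via the uniform-k grid the reconstruction resamples onto.
#'
#' @param truth A [phantom_truth()] (single B-scan patterns).
#' @param geometry A [beam_geometry()] (source centre/bandwidth and
#'   channel azimuths).
#' @param pattern The [scan_pattern()].
#' @param layers Layer list.
#' @param dispersion_coeffs `c(a2, a3)` phase coefficients, rad per
#'   (rad/um)^2 and (rad/um)^3.
#' @param seed Seed for the optional detector noise.
#' @param n_spectral Spectral pixels per A-scan.
#' @param reflectivity_scale Linear-intensity to reflectivity scaling.
#' @param detector_noise_sd Additive Gaussian detector noise (counts).
#' @return Object of class `spectral_frameset`: list of per-channel
#'   spectra matrices (`ascans x spectral pixels`), `wavelength_grid_nm`,
#'   `dispersion_coeffs`, `k0` (rad/um) and the envelope.
#' @export
render_spectra <- function(truth, geometry = beam_geometry(), pattern,
                           layers = default_retina_layers(),
                           dispersion_coeffs = c(0, 0), seed = 1L,
                           n_spectral = 1024L, reflectivity_scale = 1e-4,
                           detector_noise_sd = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(as.integer(seed))
  n <- pattern$ascans_per_bscan
  lam0 <- geometry$center_wavelength_nm * 1e-3           # um
  fwhm <- geometry$bandwidth_fwhm_nm * 1e-3
  lam <- seq(lam0 - fwhm, lam0 + fwhm, length.out = n_spectral)  # uniform in lambda
  k <- 2 * pi / lam                                      # rad/um, decreasing
  k0 <- 2 * pi / lam0
  kuni <- seq(min(k), max(k), length.out = n_spectral)
  dk <- kuni[2] - kuni[1]
  z_per_px <- pi / (n_spectral * dk)                     # um per depth pixel
  if (truth$depth_px >= n_spectral / 2)
    stop("aliasing error: reflector depths exceed the unambiguous range")
  env <- 1000 * exp(-4 * log(2) * (lam - lam0)^2 / fwhm^2)
  psi <- dispersion_coeffs[1] * (k - k0)^2 + dispersion_coeffs[2] * (k - k0)^3
  phase <- exp(1i * psi)
  azf <- azimuth_field(pattern)
  phic <- geometry$channel_azimuths_deg
  spectra <- vector("list", 3)
  for (c in 1:3) {
    E <- expected_intensity_bscan(truth, layers, azf[, 1], phic[c], 1L)
    E <- shift_rows(E, truth$channel_depth_offsets[c])
    rows <- which(rowSums(E) > 0)
    S <- matrix(rep(env, n), n, n_spectral, byrow = TRUE)
    if (length(rows)) {
      z <- (rows - 1) * z_per_px
      M <- exp(2i * outer(k, z))                           # n_spectral x reflectors
      amp <- 2 * sqrt(E[rows, , drop = FALSE] * reflectivity_scale)
      U <- M %*% amp                                       # n_spectral x ascans
      S <- S * t(1 + Re(phase * U))
    }
    if (detector_noise_sd > 0)
      S <- S + matrix(stats::rnorm(length(S), sd = detector_noise_sd), nrow(S))
    spectra[[c]] <- pmax(S, 0)
  }
  structure(list(spectra = spectra, wavelength_grid_nm = lam * 1e3,
                 dispersion_coeffs = dispersion_coeffs, k0 = k0,
                 envelope = env, z_per_px_um = z_per_px),
            class = "spectral_frameset")
}

#' Single-reflector phantom truth
#'
#' Minimal truth with one thin isotropic reflector band, for exercising
#' the reconstruction chain. A small depth undulation keeps the frame
#' laterally non-uniform (a perfectly uniform frame is annihilated by
#' mean spectrum subtraction).
#'
#' @param depth_row Anterior row of the reflector (1-based).
#' @param pattern A [scan_pattern()].
#' @param depth_px Imaging depth.
#' @param reflectivity Linear reflectivity of the band.
#' @param undulation_px Depth undulation amplitude.
#' @return List with `truth` and `layers` ready for [render_spectra()].
#' @export
single_reflector_phantom <- function(depth_row, pattern, depth_px = 400L,
                                     reflectivity = 1, undulation_px = 3) {
  truth <- phantom_truth(pattern,
                         interfaces = c(refl = as.integer(depth_row),
                                        below = as.integer(depth_row) + 2L),
                         depth_px = depth_px, undulation_px = undulation_px,
                         vessels = NULL)
  layers <- list(refl = layer_model("refl", reflectivity, "isotropic"),
                 below = layer_model("below", 0, "isotropic"))
  list(truth = truth, layers = layers)
}
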