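## Standard SD-OCT reconstruction: mean spectrum subtraction, lambda-to-k
## resampling, numerical dispersion compensation, FFT.

#' Reconstruction configuration
#'
#' @param resample_interpolation `"cubic-spline"` (default) or `"linear"`.
#' @param dispersion_coeffs `c(a2, a3)` compensation phase coefficients,
#'   rad per (rad/um)^2 and (rad/um)^3 (applied with opposite sign to the
#'   fringe phase).
#' @param window Spectral apodization: `"hann"` (default) or `"none"`.
#' @param zero_pad_factor Zero-padding factor, one of 1, 2, 4.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(resample_interpolation = c("cubic-spline", "linear"),
                         dispersion_coeffs = c(0, 0),
                         window = c("hann", "none"),
                         zero_pad_factor = 1L) {
  resample_interpolation <- match.arg(resample_interpolation)
  window <- match.arg(window)
  if (!zero_pad_factor %in% c(1L, 2L, 4L))
    stop("zero_pad_factor must be 1, 2 or 4")
  structure(list(resample_interpolation = resample_interpolation,
                 dispersion_coeffs = dispersion_coeffs, window = window,
                 zero_pad_factor = as.integer(zero_pad_factor)),
            class = "recon_config")
}

#' Mean spectrum subtraction
#'
#' Removes the per-spectral-pixel mean over the A-scans of a frame — the
#' dominant DC/reference term of the interferogram.
#'
#' @param spectra Matrix `ascans x spectral pixels`.
#' @return Matrix of the same shape with zero column means.
#' @export
mean_spectrum_subtract <- function(spectra) {
  stopifnot(is.matrix(spectra))
  if (nrow(spectra) < 2)
    stop("mean spectrum subtraction needs >= 2 A-scans per frame")
  sweep(spectra, 2, colMeans(spectra))
}

#' Resample a spectrum from wavelength to uniform wavenumber
#'
#' Maps `k = 2 pi / lambda` and interpolates onto a uniform k grid
#' spanning `[k_min, k_max]` with the same number of points (endpoints
#' preserved).
#'
#' @param spectrum Numeric vector, or matrix `ascans x spectral pixels`.
#' @param wavelength_grid_nm Strictly monotone wavelength grid (nm).
#' @param interpolation `"cubic-spline"` or `"linear"`.
#' @return List with `spectrum` (same shape as input) and `k_grid`
#'   (rad/um, increasing).
#' @export
resample_lambda_to_k <- function(spectrum, wavelength_grid_nm,
                                 interpolation = c("cubic-spline", "linear")) {
  interpolation <- match.arg(interpolation)
  d <- diff(wavelength_grid_nm)
  if (!(all(d > 0) || all(d < 0))) stop("wavelength grid must be strictly monotone")
  k <- 2 * pi / (wavelength_grid_nm * 1e-3)  # rad/um
  ord <- order(k)
  ks <- k[ord]
  one <- is.null(dim(spectrum))
  S <- if (one) matrix(spectrum, 1) else spectrum
  if (ncol(S) != length(k)) stop("spectrum/grid length mismatch")
  kuni <- seq(ks[1], ks[length(ks)], length.out = length(ks))
  out <- matrix(0, nrow(S), ncol(S))
  for (i in seq_len(nrow(S))) {
    y <- S[i, ord]
    out[i, ] <- if (interpolation == "linear")
      stats::approx(ks, y, xout = kuni, rule = 2)$y
    else
      stats::spline(ks, y, xout = kuni, method = "natural")$y
  }
  list(spectrum = if (one) out[1, ] else out, k_grid = kuni)
}

#' Numerical dispersion compensation
#'
#' Multiplies the analytic (complex) spectrum on a uniform k grid by the
#' pure phase `exp(-i (a2 (k - k0)^2 + a3 (k - k0)^3))`; the magnitude
#' spectrum is unchanged.
#'
#' @param complex_spectrum_k Complex vector or matrix (`ascans x pixels`).
#' @param k_grid Uniform wavenumber grid (rad/um).
#' @param coeffs `c(a2, a3)`.
#' @param k0 Centre wavenumber; defaults to the grid midpoint.
#' @return Compensated complex spectrum, same shape.
#' @export
dispersion_compensate <- function(complex_spectrum_k, k_grid, coeffs,
                                  k0 = NULL) {
  k0 <- k0 %||% mean(range(k_grid))
  ph <- exp(-1i * (coeffs[1] * (k_grid - k0)^2 + coeffs[2] * (k_grid - k0)^3))
  if (is.null(dim(complex_spectrum_k))) complex_spectrum_k * ph
  else sweep(complex_spectrum_k, 2, ph, `*`)
}

## Reconstruct one frame (ascans x spectral px) to linear A-scan
## magnitudes (depth x ascans).
#' @keywords internal
reconstruct_frame <- function(frame, wavelength_grid_nm, config, k0 = NULL) {
  frame <- mean_spectrum_subtract(frame)
  rs <- resample_lambda_to_k(frame, wavelength_grid_nm,
                             config$resample_interpolation)
  S <- rs$spectrum
  npix <- ncol(S)
  if (config$window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, npix - 1) / (npix - 1))
    S <- sweep(S, 2, w, `*`)
  }
  zp <- config$zero_pad_factor
  nfft <- npix * zp
  depth <- npix %/% 2L * zp
  out <- matrix(0, depth, nrow(S))
  for (i in seq_len(nrow(S))) {
    cs <- analytic_signal(S[i, ])
    cs <- dispersion_compensate(cs, rs$k_grid, config$dispersion_coeffs, k0)
    padded <- c(cs, complex(real = rep(0, nfft - npix)))
    out[, i] <- Mod(stats::fft(padded))[seq_len(depth)]
  }
  out
}

#' Reconstruct a spectral frame set to intensity A-scans
#'
#' Runs the full chain — mean spectrum subtraction, lambda-to-k
#' resampling, apodization, analytic-signal construction, numerical
#' dispersion compensation, FFT — per channel. Each A-scan is the
#' magnitude of the positive-frequency half of the FFT, so a frame with
#' `P` spectral pixels reconstructs to `P/2 * zero_pad_factor` depth
#' pixels. With zero padding, depth pixel spacing shrinks accordingly.
#'
#' @param frameset A `spectral_frameset` from [render_spectra()] (or a
#'   compatible list with `spectra` and `wavelength_grid_nm`).
#' @param config A [recon_config()].
#' @param pattern Optional [scan_pattern()] to attach to the output.
#' @return An [mdoct_stack()] of linear-intensity B-scans.
#' @export
reconstruct <- function(frameset, config = recon_config(), pattern = NULL) {
  stopifnot(!is.null(frameset$spectra), !is.null(frameset$wavelength_grid_nm))
  k0 <- frameset$k0 %||% NULL
  channels <- lapply(frameset$spectra, function(fr)
    reconstruct_frame(fr, frameset$wavelength_grid_nm, config, k0))
  if (is.null(pattern))
    pattern <- scan_pattern("linear", ascans_per_bscan = ncol(channels[[1]]))
  mdoct_stack(channels, pattern, registered = FALSE)
}
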