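## Small shared numerics: circular arithmetic, separable Gaussian blur,
## analytic signal, sub-pixel peak refinement.

#' Circular distance between azimuths
#'
#' Shortest angular distance between two azimuths, in degrees.
#'
#' @param a,b Azimuths in degrees (vectors recycle).
#' @return Distance in `[0, 180]` degrees.
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' @keywords internal
wrap360 <- function(a) ((a %% 360) + 360) %% 360

## Replicate-padded 1D convolution along matrix rows (axis = 1) or
## columns (axis = 2) with a symmetric kernel.
#' @keywords internal
conv_sep <- function(img, kernel, axis) {
  w <- (length(kernel) - 1L) %/% 2L
  n <- if (axis == 1L) nrow(img) else ncol(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(kernel)) {
    off <- j - 1L - w
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    out <- out + kernel[j] * (if (axis == 1L) img[idx, , drop = FALSE]
                              else img[, idx, drop = FALSE])
  }
  out
}

#' Gaussian blur of a B-scan
#'
#' Separable Gaussian smoothing with replicated edges.
#'
#' @param img Numeric matrix (depth x A-scans).
#' @param sigma Standard deviation in pixels; 0 returns the input.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma = 2) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  w <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  conv_sep(conv_sep(img, k, 1L), k, 2L)
}

#' Analytic signal of a real vector
#'
#' FFT-based construction: zero the negative frequencies, double the
#' positive ones. The real part of the result equals the input.
#'
#' @param x Real numeric vector.
#' @return Complex vector, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Quadratic (three-point) sub-sample peak interpolation around index i
## of vector y; returns fractional offset in [-0.5, 0.5].
#' @keywords internal
subpixel_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(0)
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

## Shift matrix rows by an integer amount (positive = towards larger row
## index, i.e. posteriorly), filling vacated rows with `fill`.
#' @keywords internal
shift_rows <- function(img, dz, fill = 0) {
  dz <- as.integer(round(dz))
  n <- nrow(img)
  out <- matrix(fill, n, ncol(img))
  if (dz >= n || dz <= -n) return(out)
  if (dz >= 0) out[(1 + dz):n, ] <- img[1:(n - dz), , drop = FALSE]
  else out[1:(n + dz), ] <- img[(1 - dz):n, , drop = FALSE]
  out
}

## Shift a single column vector by integer dz, zero fill.
#' @keywords internal
shift_vec <- function(x, dz, fill = 0) {
  dz <- as.integer(round(dz))
  n <- length(x)
  out <- rep(fill, n)
  if (dz >= n || dz <= -n) return(out)
  if (dz >= 0) out[(1 + dz):n] <- x[1:(n - dz)] else out[1:(n + dz)] <- x[(1 - dz):n]
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
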