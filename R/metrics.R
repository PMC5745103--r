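## Speckle-reduction performance metrics: SNR, CNR and ENL over paired
## signal/background regions of interest.
##
##   SNR = 10 log10( mu_s,lin^2 / sigma_b,lin^2 )      (linear data)
##   CNR = (mu_s,log - mu_b,log) / sqrt(sigma_s,log^2 + sigma_b,log^2)
##   ENL = mu_s,log^2 / sigma_s,log^2                  (log data)
##
## Signal ROIs sit in a homogeneous part of the image (the RNFL band);
## background ROIs sit in the noise region above the ILM. Log data is
## 10*log10 of linear intensity referenced to a floor at a low quantile
## of the positive values — i.e. dB above the image noise floor, the
## scale log OCT images are displayed on (ENL is not shift-invariant,
## so the reference matters and is part of the metric definition here).

#' ROI statistics
#'
#' Means and standard deviations of a signal/background ROI pair on
#' linear and log-scaled data.
#'
#' @param image Linear-intensity matrix.
#' @param signal_roi,background_roi Each a vector/list `c(row, col,
#'   height, width)`: top-left corner (1-based) and extent.
#' @param log_floor_quantile Floor quantile for the log transform.
#' @return Object of class `roi_stats` with fields `mu_s_lin`,
#'   `sigma_b_lin`, `mu_s_log`, `sigma_s_log`, `mu_b_log`, `sigma_b_log`.
#' @export
roi_stats <- function(image, signal_roi, background_roi,
                      log_floor_quantile = 1e-3) {
  ex <- function(roi) {
    roi <- as.integer(unlist(roi))
    stopifnot(length(roi) == 4)
    if (roi[1] < 1 || roi[2] < 1 || roi[1] + roi[3] - 1 > nrow(image) ||
        roi[2] + roi[4] - 1 > ncol(image))
      stop("ROI outside image")
    image[roi[1]:(roi[1] + roi[3] - 1L), roi[2]:(roi[2] + roi[4] - 1L)]
  }
  s_lin <- ex(signal_roi); b_lin <- ex(background_roi)
  ## log data: dB above the image noise floor
  pos <- image[image > 0]
  fl <- if (length(pos)) stats::quantile(pos, log_floor_quantile, names = FALSE)
        else .Machine$double.eps
  logimg <- 10 * log10(pmax(image, fl) / fl)
  ex_log <- function(roi) {
    roi <- as.integer(unlist(roi))
    logimg[roi[1]:(roi[1] + roi[3] - 1L), roi[2]:(roi[2] + roi[4] - 1L)]
  }
  s_log <- ex_log(signal_roi); b_log <- ex_log(background_roi)
  structure(list(mu_s_lin = mean(s_lin), sigma_b_lin = stats::sd(b_lin),
                 mu_s_log = mean(s_log), sigma_s_log = stats::sd(s_log),
                 mu_b_log = mean(b_log), sigma_b_log = stats::sd(b_log)),
            class = "roi_stats")
}

#' Signal-to-noise ratio in dB
#'
#' `10 log10(mu_s_lin^2 / sigma_b_lin^2)`: mean linear signal intensity
#' against the standard deviation of the linear background.
#'
#' @param stats A `roi_stats`, or the signal mean when `sigma_b_lin` is
#'   given.
#' @param sigma_b_lin Background standard deviation (scalar form).
#' @return SNR in dB.
#' @export
snr_db <- function(stats, sigma_b_lin = NULL) {
  if (inherits(stats, "roi_stats")) {
    mu <- stats$mu_s_lin; sb <- stats$sigma_b_lin
  } else { mu <- stats; sb <- sigma_b_lin }
  if (is.null(sb) || !is.finite(sb) || sb <= 0)
    stop("undefined metric: background standard deviation must be > 0")
  10 * log10(mu^2 / sb^2)
}

#' Contrast-to-noise ratio
#'
#' `(mu_s_log - mu_b_log) / sqrt(sigma_s_log^2 + sigma_b_log^2)` on
#' log-scaled data. Antisymmetric under swapping the ROIs.
#'
#' @param stats A `roi_stats`, or `mu_s_log` with the remaining values
#'   given positionally.
#' @param mu_b_log,sigma_s_log,sigma_b_log Scalar form components.
#' @return Dimensionless CNR.
#' @export
cnr <- function(stats, mu_b_log = NULL, sigma_s_log = NULL,
                sigma_b_log = NULL) {
  if (inherits(stats, "roi_stats")) {
    ms <- stats$mu_s_log; mb <- stats$mu_b_log
    ss <- stats$sigma_s_log; sb <- stats$sigma_b_log
  } else { ms <- stats; mb <- mu_b_log; ss <- sigma_s_log; sb <- sigma_b_log }
  v <- ss^2 + sb^2
  if (!is.finite(v) || v <= 0) stop("undefined metric: both ROI variances are zero")
  (ms - mb) / sqrt(v)
}

#' Equivalent number of looks
#'
#' `mu_s_log^2 / sigma_s_log^2` of a homogeneous log-scaled signal ROI:
#' increases with the number of independent speckle realizations
#' averaged.
#'
#' @param stats A `roi_stats`, or `mu_s_log` when `sigma_s_log` is given.
#' @param sigma_s_log Signal log standard deviation (scalar form).
#' @return Dimensionless ENL.
#' @export
enl <- function(stats, sigma_s_log = NULL) {
  if (inherits(stats, "roi_stats")) {
    mu <- stats$mu_s_log; ss <- stats$sigma_s_log
  } else { mu <- stats; ss <- sigma_s_log }
  if (is.null(ss) || !is.finite(ss) || ss <= 0)
    stop("undefined metric: constant signal ROI")
  mu^2 / ss^2
}

#' Evaluate SNR, CNR and ENL over paired ROIs
#'
#' Computes the metrics for each signal/background ROI pair and reports
#' their means (the protocol: five 100 x 50 pixel ROI pairs per image).
#'
#' @param image Linear-intensity matrix.
#' @param signal_rois,background_rois Lists of `c(row, col, height,
#'   width)` ROIs, equal length.
#' @param log_floor_quantile Floor quantile for the log transform.
#' @return Object of class `speckle_metrics`: list with `snr_db`, `cnr`,
#'   `enl` (means over pairs), `n_rois` and `per_roi` (data frame).
#' @export
evaluate_image <- function(image, signal_rois, background_rois,
                           log_floor_quantile = 1e-3) {
  if (length(signal_rois) != length(background_rois))
    stop("signal and background ROI lists must pair up")
  per <- lapply(seq_along(signal_rois), function(i) {
    st <- roi_stats(image, signal_rois[[i]], background_rois[[i]],
                    log_floor_quantile)
    data.frame(roi = i, snr_db = snr_db(st), cnr = cnr(st), enl = enl(st))
  })
  per <- do.call(rbind, per)
  structure(list(snr_db = mean(per$snr_db), cnr = mean(per$cnr),
                 enl = mean(per$enl), n_rois = nrow(per), per_roi = per),
            class = "speckle_metrics")
}

#' @export
print.speckle_metrics <- function(x, ...) {
  cat(sprintf("SNR %.2f dB, CNR %.3f, ENL %.2f (mean over %d ROIs)\n",
              x$snr_db, x$cnr, x$enl, x$n_rois))
  invisible(x)
}

#' Place phantom metric ROIs
#'
#' Automatic ROI placement on a phantom B-scan: signal ROIs inside the
#' truth RNFL band, background ROIs in the vitreous above the ILM, both
#' spread across the lateral axis and avoiding vessel columns.
#'
#' @param truth A [phantom_truth()] (needs RNFL/GCL_OPL interfaces).
#' @param n Number of ROI pairs.
#' @param height,width ROI extent in pixels (depth x lateral).
#' @param bscan B-scan index.
#' @return List with `signal` and `background` ROI lists for
#'   [evaluate_image()].
#' @export
place_phantom_rois <- function(truth, n = 5L, height = 50L, width = 100L,
                               bscan = 1L) {
  b <- truth$boundaries
  stopifnot(all(c("RNFL", "GCL_OPL", "ILM") %in% colnames(b)))
  nasc <- dim(b)[1]
  if (n * width > nasc) stop("not enough A-scans for the requested ROIs")
  cols <- round(seq(1, nasc - width + 1, length.out = n))
  sig <- bg <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cols[i]:(cols[i] + width - 1L)
    rn_top <- max(b[cs, "RNFL", bscan])
    rn_bot <- min(b[cs, "GCL_OPL", bscan]) - 1L
    if (rn_bot - rn_top + 1L < height)
      stop("RNFL band thinner than the requested ROI height")
    sig[[i]] <- c(rn_top + ((rn_bot - rn_top + 1L) - height) %/% 2L, cols[i],
                  height, width)
    bg_bot <- min(b[cs, "ILM", bscan]) - 3L
    if (bg_bot < height) stop("not enough background rows above the ILM")
    bg[[i]] <- c(bg_bot - height + 1L, cols[i], height, width)
  }
  list(signal = sig, background = bg)
}
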