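## Turn-key phantom experiments: each runs the full processing chain on
## a freshly rendered phantom and returns the measured quantities. These
## back the `report` CLI command and the acceptance experiments.

#' Photoreceptor sector experiment
#'
#' Renders a circumpapillary phantom whose IS/OS and COST bands carry
#' single-lobe von Mises directionality, runs the full chain
#' (segmentation, IS/OS-COST evaluation window, RPE normalization,
#' lowess smoothing, circular peak detection) and measures the circular
#' separations between the per-channel peak azimuths, which the
#' equilateral beam triangle places ~120 degrees apart.
#'
#' @param seed Integer seed.
#' @param ascans A-scans per B-scan.
#' @param n_bscans Consecutive B-scans rendered and averaged.
#' @param kappa Von Mises concentration of the photoreceptor bands.
#' @param use_truth_boundaries Anchor windows on phantom truth instead
#'   of the automated segmentation.
#' @param span Smoothing span.
#' @return List with `profiles`, `sectors`, `separations` (three
#'   pairwise circular separations, degrees), `n_sectors`
#'   (dominant-channel colour sector count) and `stack`.
#' @export
experiment_photoreceptor_sectors <- function(seed = 1L, ascans = 1024L,
                                             n_bscans = 10L, kappa = 1.5,
                                             use_truth_boundaries = FALSE,
                                             span = 0.05) {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = ascans,
                      bscans = n_bscans)
  truth <- phantom_truth(pat)
  layers <- default_retina_layers(photoreceptor_kappa = kappa)
  stack <- render_multichannel(truth, pattern = pat, layers = layers,
                               seed = seed)
  bounds <- if (use_truth_boundaries)
    list(ilm = matrix(truth$anchors$ilm[, 1, ], ncol = n_bscans),
         rpe = matrix(truth$anchors$rpe[, 1, ], ncol = n_bscans))
  else segment_stack(stack)
  profiles <- azimuthal_profiles(stack, bounds, preset = "isos_cost",
                                 n_bscans = n_bscans, span = span)
  sectors <- detect_sectors(profiles, max_peaks = 1L)
  dom <- dominant_channel_sectors(profiles)
  list(profiles = profiles, sectors = sectors,
       separations = sectors$channel_separations,
       n_sectors = dom$n_sectors, stack = stack)
}

#' RNFL two-lobe experiment
#'
#' Renders a circumpapillary phantom with a bilobed (cos^2) RNFL, runs
#' the RNFL window chain and measures each channel's two intensity
#' lobes, expected ~180 degrees apart.
#'
#' @inheritParams experiment_photoreceptor_sectors
#' @param modulation RNFL modulation depth m.
#' @return List with `profiles`, `sectors`, `lobe_separations` (per
#'   channel, degrees) and `peaks_per_channel`.
#' @export
experiment_rnfl_lobes <- function(seed = 1L, ascans = 1024L, n_bscans = 10L,
                                  modulation = 0.6,
                                  use_truth_boundaries = FALSE, span = 0.05) {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = ascans,
                      bscans = n_bscans)
  truth <- phantom_truth(pat)
  layers <- default_retina_layers(rnfl_modulation = modulation)
  stack <- render_multichannel(truth, pattern = pat, layers = layers,
                               seed = seed)
  bounds <- if (use_truth_boundaries)
    list(ilm = matrix(truth$anchors$ilm[, 1, ], ncol = n_bscans),
         rpe = matrix(truth$anchors$rpe[, 1, ], ncol = n_bscans))
  else segment_stack(stack)
  profiles <- azimuthal_profiles(stack, bounds, preset = "rnfl",
                                 n_bscans = n_bscans, span = span)
  sectors <- detect_sectors(profiles, max_peaks = 2L)
  list(profiles = profiles, sectors = sectors,
       lobe_separations = sectors$within_separations,
       peaks_per_channel = lengths(sectors$peaks))
}

#' Speckle/noise averaging experiment
#'
#' For each seed, renders a single-B-scan circumpapillary phantom with
#' channel-independent speckle and background noise, computes SNR, CNR
#' and ENL (five 100 x 50 ROI pairs: signal in the RNFL band,
#' background above the ILM) for each channel and for the three-channel
#' intensity average, and reports the SNR improvement of the average
#' over the mean single-channel SNR. With independent Gaussian
#' background noise the expected improvement is 10 log10(3) ~ 4.77 dB.
#'
#' @param seeds Integer vector of seeds (one phantom per seed).
#' @param ascans A-scans per B-scan.
#' @param noise_sd Background noise standard deviation.
#' @return List with `delta_snr_db` (mean over seeds), `per_seed` data
#'   frame, and mean `single` / `averaged` metric summaries.
#' @export
experiment_snr_averaging <- function(seeds = 1:10, ascans = 1024L,
                                     noise_sd = 0.05) {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = ascans,
                      bscans = 1L)
  roi_w <- min(100L, as.integer(ascans) %/% 5L)
  rows <- lapply(seeds, function(s) {
    truth <- phantom_truth(pat)
    stack <- render_multichannel(truth, pattern = pat, seed = s,
                                 noise_sd = noise_sd)
    rois <- place_phantom_rois(truth, width = roi_w)
    per_ch <- lapply(1:3, function(c)
      evaluate_image(get_bscan(stack, c), rois$signal, rois$background))
    avg <- evaluate_image(intensity_average(stack), rois$signal,
                          rois$background)
    data.frame(seed = s,
               snr_single = mean(vapply(per_ch, `[[`, numeric(1), "snr_db")),
               cnr_single = mean(vapply(per_ch, `[[`, numeric(1), "cnr")),
               enl_single = mean(vapply(per_ch, `[[`, numeric(1), "enl")),
               snr_avg = avg$snr_db, cnr_avg = avg$cnr, enl_avg = avg$enl)
  })
  per_seed <- do.call(rbind, rows)
  per_seed$delta_snr <- per_seed$snr_avg - per_seed$snr_single
  list(delta_snr_db = mean(per_seed$delta_snr), per_seed = per_seed,
       single = colMeans(per_seed[, c("snr_single", "cnr_single", "enl_single")]),
       averaged = colMeans(per_seed[, c("snr_avg", "cnr_avg", "enl_avg")]))
}

#' Directional compensation experiment
#'
#' On the standard photoreceptor phantom, compares the azimuthal
#' max/min ratio of the IS/OS-COST window profile of the intensity MIP
#' against the same ratio for each single channel: the MIP flattens the
#' directional modulation, so its ratio must be smaller.
#'
#' @inheritParams experiment_photoreceptor_sectors
#' @return List with `mip_ratio`, `channel_ratios` (length 3) and the
#'   smoothed profiles used.
#' @export
experiment_directional_compensation <- function(seed = 1L, ascans = 1024L,
                                                n_bscans = 4L, kappa = 1.5,
                                                span = 0.05) {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = ascans,
                      bscans = n_bscans)
  truth <- phantom_truth(pat)
  layers <- default_retina_layers(photoreceptor_kappa = kappa)
  stack <- render_multichannel(truth, pattern = pat, layers = layers,
                               seed = seed)
  bounds <- segment_stack(stack)
  ratio_of <- function(prof) max(prof) / min(prof)
  smooth_mean_profile <- function(get_img) {
    acc <- numeric(ascans)
    for (j in seq_len(n_bscans)) {
      w <- eval_window(bounds$rpe[, j], "isos_cost",
                       image_depth = truth$depth_px)
      acc <- acc + window_mean(get_img(j), w)
    }
    smooth_profile(acc / n_bscans, span = span, circular = TRUE)
  }
  ch_prof <- lapply(1:3, function(c)
    smooth_mean_profile(function(j) get_bscan(stack, c, j)))
  mip_prof <- smooth_mean_profile(function(j) intensity_mip(stack, j))
  list(mip_ratio = ratio_of(mip_prof),
       channel_ratios = vapply(ch_prof, ratio_of, numeric(1)),
       mip_profile = mip_prof, channel_profiles = ch_prof)
}
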