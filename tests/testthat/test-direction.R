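test_that("window presets implement the anchored row arithmetic exactly", {
  rpe <- c(220L, 224L, 230L)
  w <- eval_window(rpe, "isos_cost", image_depth = 280L)
  expect_equal(w$top, rpe - 29L)
  expect_equal(w$bottom, rpe - 10L)
  expect_true(all(w$bottom - w$top + 1L == 20L))
  ilm <- c(55L, 60L, 62L)
  w2 <- eval_window(ilm, "rnfl", image_depth = 280L)
  expect_equal(w2$top, ilm + 3L)
  expect_equal(w2$bottom, ilm + 17L)
  expect_true(all(w2$bottom - w2$top + 1L == 15L))
  expect_error(eval_window(c(20L, 25L), "isos_cost"), "out of bounds")
  expect_error(eval_window(10L, "custom", shift = 2, depth = 0), "depth")
})

test_that("window means and RPE normalization behave as stated", {
  img <- matrix(0.7, 100, 5)
  w <- eval_window(rep(80L, 5), "isos_cost", image_depth = 100L)
  expect_equal(window_mean(img, w), rep(0.7, 5))
  # zeros below a bright band stay zero
  img2 <- matrix(0, 100, 5); img2[80:89, ] <- 3
  expect_equal(window_mean(img2, w), rep(0, 5))
  # scale invariance of the normalized profile
  s <- small_cp_stack(ascans = 128L, seed = 41L)
  b <- get_bscan(s$stack, 1)
  rpe <- truth_anchor(s$truth, "rpe")
  wm <- window_mean(b, eval_window(rpe, "isos_cost", image_depth = nrow(b)))
  n1 <- normalize_to_rpe(wm, bscan = b, rpe_rows = rpe)
  n2 <- normalize_to_rpe(3 * wm, bscan = 3 * b, rpe_rows = rpe)
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_equal(max(n1), 1)
  # profile equal to the RPE band itself normalizes to ~1 before rescale
  flat <- matrix(1.3, 100, 5)
  expect_equal(normalize_to_rpe(rep(1.3, 5), bscan = flat,
                                rpe_rows = rep(80, 5), rescale = FALSE),
               rep(1, 5))
  expect_error(normalize_to_rpe(wm, rpe_band_mean = 0), "non-positive")
})

test_that("profile smoothing preserves structure and suppresses noise", {
  n <- 720L
  az <- (seq_len(n) - 1) / n * 360
  expect_equal(smooth_profile(rep(2, n), span = 0.1), rep(2, n),
               tolerance = 1e-9)
  # peak location of a pure cosine moves < 2 degrees
  y <- cos((az - 123) * pi / 180)
  for (m in c("lowess", "loess")) {
    sm <- smooth_profile(y, method = m, span = 0.1)
    expect_lt(circ_dist(az[which.max(sm)], 123), 2)
  }
  # white noise variance drops at least 5-fold (Monte Carlo)
  set.seed(5)
  ratios <- replicate(10, {
    e <- rnorm(n)
    stats::var(e) / stats::var(smooth_profile(e, span = 0.05))
  })
  expect_gt(mean(ratios), 5)
  expect_error(smooth_profile(1:5), "few samples")
})

test_that("circular peak detection finds constructed lobes", {
  n <- 720L
  az <- (seq_len(n) - 1) / n * 360
  three <- vapply(c(90, 210, 330), function(phc)
    exp(1.5 * (cos((az - phc) * pi / 180) - 1)), numeric(n))
  prof <- structure(list(azimuth = az, raw = three, normalized = three,
                         smoothed = three,
                         colors = c("cyan", "magenta", "yellow"),
                         n_averaged_bscans = 1L, preset = "isos_cost",
                         circular = TRUE), class = "directional_profiles")
  s <- detect_sectors(prof, max_peaks = 1L)
  expect_equal(unname(s$channel_separations), rep(120, 3), tolerance = 0.5)
  # bilobed: two peaks 180 degrees apart
  two <- matrix(0.4 + 0.6 * cos((az - 30) * pi / 180)^2, n, 3)
  prof2 <- prof; prof2$smoothed <- two
  s2 <- detect_sectors(prof2, max_peaks = 2L)
  expect_equal(unname(s2$within_separations), rep(180, 3), tolerance = 0.5)
  expect_error(find_circular_peaks(rep(1, 100)), "no peaks")
})

test_that("rotating the azimuth origin rotates detected peaks accordingly", {
  s <- small_cp_stack(ascans = 512L, seed = 42L, bscans = 2L)
  bounds <- list(ilm = matrix(s$truth$anchors$ilm[, 1, ], ncol = 2),
                 rpe = matrix(s$truth$anchors$rpe[, 1, ], ncol = 2))
  pr <- azimuthal_profiles(s$stack, bounds, "isos_cost", n_bscans = 2)
  pk <- detect_sectors(pr, max_peaks = 1L)
  roll <- 128L  # = 90 degrees at 512 A-scans
  rolled <- s$stack
  idx <- c((roll + 1L):512L, 1:roll)
  for (c in 1:3) rolled$channels[[c]] <- s$stack$channels[[c]][, idx, , drop = FALSE]
  bounds_r <- lapply(bounds, function(m) m[idx, , drop = FALSE])
  pr_r <- azimuthal_profiles(rolled, bounds_r, "isos_cost", n_bscans = 2)
  pk_r <- detect_sectors(pr_r, max_peaks = 1L)
  for (c in 1:3)
    expect_lt(circ_dist(pk_r$peaks[[c]][1], pk$peaks[[c]][1] - 90), 2.5)
})

test_that("additive colour math matches the cyan/magenta/yellow scheme", {
  mk <- function(v1, v2, v3) mdoct_stack(
    list(matrix(v1, 4, 4), matrix(v2, 4, 4), matrix(v3, 4, 4)),
    scan_pattern("linear", ascans_per_bscan = 4L), registered = TRUE)
  # equal intensities -> achromatic grey at 2/3 of the common value
  ca <- color_average(mk(0.9, 0.9, 0.9), scaled = FALSE)
  expect_equal(ca[1, 1, ], rep(0.6, 3))
  expect_true(all(abs(ca[, , 1] - ca[, , 2]) < 1e-12) &&
                all(abs(ca[, , 2] - ca[, , 3]) < 1e-12))
  # single channel -> its tint
  c1 <- color_average(mk(1, 0, 0), scaled = FALSE)
  expect_equal(c1[1, 1, ], c(0, 1, 1) / 3)
  cm <- color_mip(mk(1, 0, 0), scaled = FALSE)
  expect_equal(cm[1, 1, ], c(0, 1, 1))
  # equal channels under MIP keep the full value in every component
  cm2 <- color_mip(mk(0.8, 0.8, 0.8), scaled = FALSE)
  expect_equal(cm2[1, 1, ], rep(0.8, 3))
  # all-zero input stays black
  expect_true(all(color_average(mk(0, 0, 0), scaled = FALSE) == 0))
  # MIP dominates the average componentwise
  s <- small_cp_stack(ascans = 64L, seed = 43L)
  expect_true(all(color_mip(s$stack) - color_average(s$stack) > -1e-12))
  # unregistered stacks are refused
  un <- mk(1, 1, 1); un$registered <- FALSE
  expect_error(color_average(un), "registered")
})

test_that("intensity MIP and average obey order statistics", {
  s <- small_cp_stack(ascans = 128L, seed = 44L)
  mip <- intensity_mip(s$stack)
  avg <- intensity_average(s$stack)
  for (c in 1:3) expect_true(all(mip >= get_bscan(s$stack, c)))
  expect_true(all(mip - avg > -1e-12))
  same <- s$stack
  same$channels[[2]] <- same$channels[[1]]; same$channels[[3]] <- same$channels[[1]]
  expect_equal(intensity_mip(same), get_bscan(same, 1))
  expect_equal(intensity_average(same), get_bscan(same, 1))
})

test_that("three-channel averaging reduces speckle variance about threefold", {
  set.seed(6)
  base <- matrix(1, 200, 200)
  singles <- replicate(3, base * matrix(rexp(4e4), 200, 200),
                       simplify = FALSE)
  avg <- (singles[[1]] + singles[[2]] + singles[[3]]) / 3
  ratio <- stats::var(as.vector(singles[[1]])) / stats::var(as.vector(avg))
  expect_gt(ratio, 2.5); expect_lt(ratio, 3.6)
})

test_that("the intensity MIP flattens directional modulation", {
  dc <- experiment_directional_compensation(seed = 45L, ascans = 512L,
                                            n_bscans = 2L)
  expect_true(all(dc$mip_ratio < dc$channel_ratios))
})

test_that("en-face colour MIP of the HFL slab shows the channel sectors", {
  pat <- scan_pattern("raster", ascans_per_bscan = 96L, bscans = 48L)
  truth <- phantom_truth(pat)
  st <- render_multichannel(truth, pattern = pat, seed = 46L)
  hfl <- matrix(truth$boundaries[, "HFL", ], ncol = 48)
  ef <- enface_color_mip(st, hfl, top_offset = 1L, thickness_px = 7L)
  expect_equal(dim(ef), c(96L, 48L, 3L))
  expect_error(enface_color_mip(st, hfl, thickness_px = 0L), "thickness")
  expect_error(enface_color_mip(st, hfl, top_offset = -1000L), "slab")
  # each channel dominates the annulus sector facing its pupil entry
  cx <- (96 + 1) / 2; cy <- (48 + 1) / 2
  ang <- outer(seq_len(96) - cx, seq_len(48) - cy,
               function(x, y) atan2(y, x) * 180 / pi) %% 360
  rad <- sqrt(outer((seq_len(96) - cx)^2, (seq_len(48) - cy)^2, `+`))
  slab_max <- function(c) {
    E <- matrix(0, 96, 48)
    for (j in 1:48) for (i in 1:96) {
      r0 <- hfl[i, j] + 1L
      E[i, j] <- max(st$channels[[c]][r0:(r0 + 6L), i, j])
    }
    E
  }
  E <- lapply(1:3, slab_max)
  phis <- c(90, 210, 330)
  in_annulus <- rad > 6 & rad < 24
  for (c in 1:3) {
    sector <- in_annulus & circ_dist(ang, phis[c]) < 40
    means <- vapply(E, function(e) mean(e[sector]), numeric(1))
    expect_equal(which.max(means), c)
  }
})

test_that("a uniform volume yields a uniform en-face map", {
  pat <- scan_pattern("raster", ascans_per_bscan = 16L, bscans = 8L)
  ch <- array(0.5, c(40, 16, 8))
  st <- mdoct_stack(list(ch, ch, ch), pat, registered = TRUE)
  ef <- enface_color_mip(st, matrix(10, 16, 8), thickness_px = 5L)
  expect_true(all(abs(ef - ef[1, 1, 1]) < 1e-12) || all(ef == 0))
})
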