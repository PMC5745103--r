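test_that("directional gain matches its closed forms", {
  pr <- layer_model("ISOS", 1, "photoreceptor_vonmises", concentration = 1.5)
  expect_equal(directional_gain(pr, 90, 90), 1)           # peak normalization
  expect_equal(directional_gain(pr, 270, 90), exp(-3), tolerance = 1e-12)
  rn <- layer_model("RNFL", 1, "rnfl_bilobed", modulation_depth = 1)
  expect_equal(directional_gain(rn, 180, 90), 0, tolerance = 1e-12)  # cos^2 null
  rn2 <- layer_model("RNFL", 1, "rnfl_bilobed", modulation_depth = 0.5)
  expect_equal(directional_gain(rn2, 150, 90), 0.5 + 0.5 * cos(pi / 3)^2)
  hf <- layer_model("HFL", 1, "hfl_onesided", concentration = 2)
  expect_equal(directional_gain(hf, 90 + 120, 90), 0)     # far side invisible
  expect_equal(directional_gain(hf, 90, 90), 1)
  expect_error(layer_model("x", 1, "photoreceptor_vonmises", concentration = -1),
               "parameter error")
  expect_error(layer_model("x", 1, "rnfl_bilobed", modulation_depth = 1.2),
               "parameter error")
})

test_that("azimuthal mean gain matches closed-form constants", {
  az <- seq(0, 360, length.out = 20001)[-20001]
  num_mean <- function(l) mean(directional_gain(l, az, 33))
  expect_equal(num_mean(layer_model("i", 1, "isotropic")), 1, tolerance = 1e-9)
  # von Mises: mean = exp(-kappa) * I0(kappa)
  k <- 1.5
  expect_equal(num_mean(layer_model("p", 1, "photoreceptor_vonmises",
                                    concentration = k)),
               exp(-k) * besselI(k, 0), tolerance = 1e-6)
  # bilobed: mean = 1 - m/2
  expect_equal(num_mean(layer_model("r", 1, "rnfl_bilobed",
                                    modulation_depth = 0.6)),
               1 - 0.3, tolerance = 1e-6)
  # clipped cosine, p = 2: mean = 1/4
  expect_equal(num_mean(layer_model("h", 1, "hfl_onesided",
                                    concentration = 2)),
               0.25, tolerance = 1e-6)
})

test_that("truth boundaries stay strictly ordered and in range", {
  for (kind in c("circumpapillary", "raster")) {
    pat <- scan_pattern(kind, ascans_per_bscan = 64L,
                        bscans = if (kind == "raster") 12L else 1L)
    truth <- phantom_truth(pat)
    b <- truth$boundaries
    for (j in seq_len(dim(b)[3]))
      expect_true(all(apply(b[, , j], 1, function(r) all(diff(r) > 0))))
    expect_true(all(b >= 1 & b <= truth$depth_px))
  }
  expect_error(phantom_truth(scan_pattern("linear", ascans_per_bscan = 8L),
                             interfaces = c(a = 10L, b = 10L, c = 30L)),
               "increasing")
})

test_that("default pitch is consistent with the stated window depths", {
  truth <- phantom_truth(scan_pattern("circumpapillary",
                                      ascans_per_bscan = 8L))
  expect_equal(20 * truth$pitch_um, 70)          # IS/OS-COST window ~70 um
  expect_lt(abs(15 * truth$pitch_um - 53), 0.75)  # RNFL window ~53 um
})

test_that("rendering is deterministic and respects degenerate inputs", {
  s1 <- small_cp_stack(ascans = 64L, seed = 9L)
  s2 <- small_cp_stack(ascans = 64L, seed = 9L)
  for (c in 1:3) expect_identical(s1$stack$channels[[c]], s2$stack$channels[[c]])
  # all-zero reflectivity, no noise -> all-zero output
  zero_layers <- lapply(default_retina_layers(), function(l) {
    l$base_reflectivity <- 0; l
  })
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = 32L)
  truth <- phantom_truth(pat)
  st <- render_multichannel(truth, pattern = pat, layers = zero_layers,
                            seed = 1, noise_sd = 0)
  expect_true(all(st$channels[[1]] == 0))
  expect_error(render_multichannel(truth,
                                   pattern = scan_pattern("circumpapillary",
                                                          ascans_per_bscan = 16L),
                                   seed = 1),
               "mismatch")
})

test_that("background region is pure Gaussian noise of the stated sigma", {
  sd0 <- 0.07
  s <- small_cp_stack(ascans = 512L, seed = 3L, noise_sd = sd0)
  bg_rows <- 1:(min(s$truth$boundaries[, "ILM", 1]) - 2L)
  bg <- get_bscan(s$stack, 1)[bg_rows, ]
  n <- length(bg)
  expect_lt(abs(mean(bg)), 3 * sd0 / sqrt(n))
  expect_lt(abs(stats::sd(bg) - sd0), 3 * sd0 / sqrt(n))
})

test_that("speckle is unit-mean exponential on a uniform layer", {
  s <- small_cp_stack(ascans = 512L, seed = 5L, noise_sd = 0)
  tr <- s$truth
  # choroid: isotropic base 0.3, below all vessels' influence is multiplicative
  rows <- (max(tr$boundaries[, "choroid", 1]) + 2L):tr$depth_px
  x <- get_bscan(s$stack, 2)[rows, ]
  x <- x / 0.3
  expect_lt(abs(mean(x) - 1), 4 / sqrt(length(x)))
  # exponential: sd == mean
  expect_lt(abs(stats::sd(x) - 1), 0.03)
})

test_that("windowed mean of a per-channel render peaks near its entry azimuth", {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = 360L)
  truth <- phantom_truth(pat, vessels = NULL)
  st <- render_multichannel(truth, pattern = pat, seed = 2,
                            speckle = FALSE, noise_sd = 0)
  az <- scan_azimuths(pat)
  for (c in 1:3) {
    E <- expected_intensity_field(truth, default_retina_layers(), pat, c)
    w <- eval_window(truth$anchors$rpe[, 1, 1], "isos_cost",
                     image_depth = truth$depth_px)
    wm <- window_mean(get_bscan(st, c), w)
    expect_equal(wm, window_mean(E, w), tolerance = 1e-12)
    expect_lt(circ_dist(az[which.max(wm)], c(90, 210, 330)[c]), 10)
  }
})

test_that("vessel columns are attenuated below the vessel row", {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = 360L)
  truth <- phantom_truth(pat)
  truth_nv <- phantom_truth(pat, vessels = NULL)
  layers <- default_retina_layers()
  E <- expected_intensity_field(truth, layers, pat, 1)
  E0 <- expected_intensity_field(truth_nv, layers, pat, 1)
  az <- scan_azimuths(pat)
  vcol <- which.min(circ_dist(az, truth$vessels$azimuth_deg[1]))
  deep <- truth$vessel_shadow_row + 5L
  shallow <- truth$vessel_shadow_row - 5L
  expect_equal(E[deep, vcol] / E0[deep, vcol], 0.2, tolerance = 1e-12)
  expect_equal(E[shallow, vcol], E0[shallow, vcol], tolerance = 1e-12)
})

test_that("channel depth offsets shift the rendered retina", {
  s <- small_cp_stack(ascans = 64L, seed = 4L, offsets = c(0L, 12L, -7L),
                      speckle = FALSE, noise_sd = 0)
  r2 <- get_bscan(s$stack, 2)
  E2 <- expected_intensity_field(s$truth, default_retina_layers(),
                                 s$pattern, channel = 2)
  expect_equal(r2, E2, tolerance = 1e-12)    # field already carries the shift
  expect_true(all(r2[1:12, ] == 0))          # vacated rows are background
  expect_false(isTRUE(s$stack$registered))
})
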