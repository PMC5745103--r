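pat64 <- scan_pattern("linear", ascans_per_bscan = 64L)

test_that("mean spectrum subtraction zeroes column means and rejects 1-A-scan frames", {
  set.seed(1)
  f <- matrix(runif(20 * 16), 20, 16)
  out <- mean_spectrum_subtract(f)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # constant frame -> zeros; zero-mean pair unchanged
  expect_true(all(mean_spectrum_subtract(matrix(3, 4, 5)) == 0))
  s <- runif(8)
  expect_equal(mean_spectrum_subtract(rbind(s, -s)), rbind(s, -s),
               ignore_attr = TRUE)
  expect_error(mean_spectrum_subtract(matrix(1, 1, 8)), ">= 2 A-scans")
})

test_that("lambda-to-k resampling recovers tones that are pure in k", {
  n <- 512L
  lam <- seq(790, 890, length.out = n)          # nm, uniform in lambda
  k <- 2 * pi / (lam * 1e-3)                    # rad/um
  z <- 80 * pi / (n * (max(k) - min(k)) / (n - 1))  # depth pixel 80
  fringe <- cos(2 * k * z)                      # chirped in lambda, pure in k
  rs <- resample_lambda_to_k(fringe, lam)
  expect_equal(length(rs$spectrum), n)
  expect_true(all(abs(diff(diff(rs$k_grid))) < 1e-9))
  spec <- Mod(stats::fft(rs$spectrum * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))))
  expect_equal(which.max(spec[1:(n / 2)]) - 1L, 80L)
  # constant spectrum stays constant; already-uniform grid is a no-op
  expect_equal(resample_lambda_to_k(rep(2, n), lam)$spectrum, rep(2, n),
               tolerance = 1e-9)
  kuni_lam <- 2 * pi / seq(7, 8, length.out = 64)  # uniform in k by construction
  y <- sin(seq_len(64) / 5)
  expect_equal(resample_lambda_to_k(y, rev(kuni_lam) * 1e3)$spectrum,
               rev(y), tolerance = 1e-6)
  expect_error(resample_lambda_to_k(y, c(1, 3, 2, 4)), "monotone")
})

test_that("dispersion compensation is a pure phase", {
  set.seed(2)
  kg <- seq(7, 8, length.out = 128)
  cs <- complex(real = rnorm(128), imaginary = rnorm(128))
  out <- dispersion_compensate(cs, kg, c(30, 5))
  expect_equal(Mod(out), Mod(cs), tolerance = 1e-12)       # magnitude preserved
  expect_equal(sum(Mod(out)^2), sum(Mod(cs)^2), tolerance = 1e-12)  # Parseval
  expect_equal(dispersion_compensate(cs, kg, c(0, 0)), cs) # identity
})

test_that("single phantom reflectors reconstruct at their depth", {
  for (d in c(60L, 120L, 240L, 340L)) {
    sr <- single_reflector_phantom(d, pat64)
    fs <- render_spectra(sr$truth, pattern = pat64, layers = sr$layers)
    st <- reconstruct(fs, recon_config())
    est <- apply(st$channels[[1]][, , 1], 2, which.max)
    expect_lte(max(abs(est - sr$truth$boundaries[, "refl", 1])), 1L)
  }
})

test_that("reflector depth versus located peak has unit slope", {
  deps <- c(60L, 120L, 180L, 240L, 300L)
  located <- vapply(deps, function(d) {
    sr <- single_reflector_phantom(d, pat64)
    fs <- render_spectra(sr$truth, pattern = pat64, layers = sr$layers)
    st <- reconstruct(fs, recon_config())
    mean(apply(st$channels[[1]][, , 1], 2, which.max))
  }, numeric(1))
  slope <- stats::coef(stats::lm(located ~ deps))[2]
  expect_lt(abs(slope - 1), 0.02)
})

test_that("dispersion broadens the peak and compensation restores it", {
  sr <- single_reflector_phantom(150, pat64)
  a2 <- 150
  clean <- reconstruct(render_spectra(sr$truth, pattern = pat64,
                                      layers = sr$layers),
                       recon_config())$channels[[1]][, 1, 1]
  fs <- render_spectra(sr$truth, pattern = pat64, layers = sr$layers,
                       dispersion_coeffs = c(a2, 0))
  unc <- reconstruct(fs, recon_config())$channels[[1]][, 1, 1]
  comp <- reconstruct(fs, recon_config(dispersion_coeffs = c(a2, 0)))$channels[[1]][, 1, 1]
  expect_lt(max(unc), 0.8 * max(clean))      # dispersed peak collapses
  expect_equal(max(comp), max(clean), tolerance = 0.1)
  fwhm <- function(a) sum(a > max(a) / 2)
  expect_gt(fwhm(unc), fwhm(clean))
  expect_lte(fwhm(comp), fwhm(clean) + 1L)
})

test_that("the chain is deterministic and zero in equals zero out", {
  sr <- single_reflector_phantom(100, pat64)
  fs <- render_spectra(sr$truth, pattern = pat64, layers = sr$layers)
  s1 <- reconstruct(fs, recon_config())
  s2 <- reconstruct(fs, recon_config())
  expect_identical(s1$channels, s2$channels)
  # spectra identically zero -> flat zero A-scans
  fs0 <- fs
  for (c in 1:3) fs0$spectra[[c]][] <- 0
  expect_true(all(reconstruct(fs0, recon_config())$channels[[1]] == 0))
  # output depth is half the spectral pixels times the padding factor
  expect_equal(dim(s1$channels[[1]])[1], 512L)
  zp <- reconstruct(fs, recon_config(zero_pad_factor = 2L))
  expect_equal(dim(zp$channels[[1]])[1], 1024L)
  expect_error(recon_config(zero_pad_factor = 3L))
})

test_that("two reflectors 40 px apart resolve as two peaks", {
  pat <- scan_pattern("linear", ascans_per_bscan = 32L)
  truth <- phantom_truth(pat, interfaces = c(r1 = 120L, g1 = 122L,
                                             r2 = 160L, g2 = 162L),
                         depth_px = 400L, undulation_px = 3, vessels = NULL)
  layers <- list(r1 = layer_model("r1", 1, "isotropic"),
                 g1 = layer_model("g1", 0, "isotropic"),
                 r2 = layer_model("r2", 1, "isotropic"),
                 g2 = layer_model("g2", 0, "isotropic"))
  fs <- render_spectra(truth, pattern = pat, layers = layers)
  a <- reconstruct(fs, recon_config())$channels[[1]][, 1, 1]
  pks <- which(a > 0.5 * max(a))
  expect_true(any(abs(pks - 121) <= 3) && any(abs(pks - 161) <= 3))
})
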