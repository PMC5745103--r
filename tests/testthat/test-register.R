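test_that("identity and round-trip properties of apply_rigid", {
  s <- small_cp_stack(ascans = 128L, seed = 31L)
  b <- get_bscan(s$stack, 1)
  expect_identical(apply_rigid(b, rigid_transform(0, 0, 0)), b)
  # integer shift then inverse restores exactly
  tf <- rigid_transform(7, -3, 0)
  back <- apply_rigid(apply_rigid(b, tf), rigid_transform(-7, 3, 0))
  core <- 30:250
  expect_lt(max(abs(back[core, 10:110] - b[core, 10:110])), 1e-9)
  # fractional shift round trip preserves the band-limited structure;
  # single-pixel bands at Nyquist are necessarily attenuated by linear
  # interpolation, so compare at the blur scale registration works on
  ssm <- small_cp_stack(ascans = 128L, seed = 31L, speckle = FALSE,
                        noise_sd = 0)
  bs <- get_bscan(ssm$stack, 1)
  half <- apply_rigid(apply_rigid(bs, rigid_transform(3.5, 0, 0)),
                      rigid_transform(-3.5, 0, 0))
  expect_gt(stats::cor(as.vector(gaussian_blur(half, 1)[core, ]),
                       as.vector(gaussian_blur(bs, 1)[core, ])), 0.99)
  expect_error(rigid_transform(theta = 10), "theta")
})

test_that("estimate_rigid recovers injected shifts on speckled phantoms", {
  s <- small_cp_stack(ascans = 256L, seed = 32L)
  b <- get_bscan(s$stack, 1)
  expect_error(estimate_rigid(b, matrix(1, nrow(b), ncol(b))), "no-content")
  id <- estimate_rigid(b, b, theta_max = 0)
  expect_lt(abs(id$dz), 0.25); expect_lt(abs(id$dx), 0.25)
  set.seed(1)
  for (shift in list(c(7L, 0L), c(-20L, 5L), c(33L, -8L))) {
    mov <- apply_rigid(b, rigid_transform(shift[1], shift[2], 0))
    est <- estimate_rigid(b, mov, theta_max = 0)
    expect_lt(abs(est$dz + shift[1]), 0.5)
    expect_lt(abs(est$dx + shift[2]), 0.5)
  }
})

test_that("register_triplet removes phantom depth offsets", {
  s <- small_cp_stack(ascans = 256L, seed = 33L, offsets = c(0L, 8L, -5L))
  reg <- register_triplet(s$stack, theta_max = 0)
  expect_true(reg$registered)
  expect_lt(abs(reg$transforms[[1]]$dz + 8), 0.5)
  expect_lt(abs(reg$transforms[[2]]$dz - 5), 0.5)
  expect_equal(dim(reg$channels[[2]]), dim(s$stack$channels[[2]]))
  # residual alignment of the retina itself: RPE rows agree across channels
  rpe1 <- segment_rpe(get_bscan(reg, 1))
  rpe2 <- segment_rpe(get_bscan(reg, 2))
  expect_lte(median(abs(rpe1 - rpe2)), 1)
  # already-aligned phantom: near-identity transforms
  s0 <- small_cp_stack(ascans = 256L, seed = 34L)
  reg0 <- register_triplet(s0$stack, theta_max = 0)
  expect_lt(max(abs(c(reg0$transforms[[1]]$dz, reg0$transforms[[2]]$dz))), 0.5)
})

test_that("flattening puts the ILM on one row and is invertible", {
  s <- small_cp_stack(ascans = 128L, seed = 35L)
  b <- get_bscan(s$stack, 1)
  ilm <- truth_anchor(s$truth, "ilm")
  fl <- flatten_bscan(b, ilm)
  expect_equal(stats::var(ilm + fl$shifts), 0)
  expect_identical(unflatten_bscan(fl$image, fl$shifts)[40:260, ],
                   b[40:260, ])
  # already-flat boundary: zero shifts
  fl0 <- flatten_bscan(b, rep(60, ncol(b)))
  expect_true(all(fl0$shifts == 0L))
  # linear ramp flattens to zero variance
  ramp <- round(seq(40, 80, length.out = ncol(b)))
  flr <- flatten_bscan(b, ramp)
  expect_equal(stats::var(ramp + flr$shifts), 0)
  expect_error(flatten_bscan(b, rep(1e4, ncol(b))), "range")
})

test_that("volume fusion preserves identical inputs and mean intensity", {
  s <- small_cp_stack(ascans = 96L, seed = 36L, speckle = FALSE, noise_sd = 0)
  st <- s$stack
  # make all three channels identical
  st$channels[[2]] <- st$channels[[1]]; st$channels[[3]] <- st$channels[[1]]
  ilm <- matrix(truth_anchor(s$truth, "ilm"), ncol = 1)
  fused <- fuse_volume(st, list(ilm, ilm, ilm), "mean")
  core <- 10:(s$truth$depth_px - 10)  # flatten shifts zero-fill the edge rows
  expect_equal(fused$volume[core, , 1], get_bscan(st, 1)[core, ],
               tolerance = 1e-12)
  # mean fusion of the real channels preserves mean intensity within 1%
  st2 <- s$stack
  f2 <- fuse_volume(st2, list(ilm, ilm, ilm), "mean")
  m_in <- mean(vapply(1:3, function(c) mean(st2$channels[[c]]), numeric(1)))
  expect_lt(abs(mean(f2$volume) - m_in) / m_in, 0.01)
  # max mode dominates mean mode voxelwise
  f3 <- fuse_volume(st2, list(ilm, ilm, ilm), "max")
  expect_true(all(f3$volume - f2$volume > -1e-12))
  # fused surface tracks channel-1 truth
  rpe_est <- segment_ilm(f2$volume[, , 1])
  expect_lte(median(abs(rpe_est - truth_anchor(s$truth, "ilm"))), 1)
})
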