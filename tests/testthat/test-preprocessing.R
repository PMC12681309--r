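test_that("resampling is exact for identity and constant fields", {
  set.seed(2)
  v <- voxel_volume(array(runif(16 * 16 * 4), c(16, 16, 4)), c(1, 1, 2))
  same <- resample_to_grid(v, v)
  expect_equal(same$data, v$data, tolerance = 1e-12)
  lo <- voxel_volume(array(3.7, c(8, 8, 2)), c(2, 2, 4))
  hi <- resample_to_grid(lo, v)
  expect_equal(vol_values(hi), rep(3.7, 16 * 16 * 4))
  expect_warning(
    resample_to_grid(voxel_volume(array(1, c(8, 8, 1)), c(2, 2, 8)), v),
    "degenerate")
})

test_that("a smooth quadratic field survives down/up-sampling within 1%", {
  f <- quadratic_b1_field(0.1)
  half <- c(100, 100, 10)
  tgt <- voxel_volume(array(0, c(256, 256, 4)), c(0.8, 0.8, 2))
  src <- voxel_volume(array(0, c(96, 96, 4)), c(256 * 0.8 / 96, 256 * 0.8 / 96, 2))
  fld <- polynomial_field(2, f$coefficients, scale_mm = half)
  lo <- evaluate_field(fld, src)
  truth <- evaluate_field(fld, tgt)
  res <- resample_to_grid(lo, tgt)
  expect_lt(max(abs(res$data - truth$data) / abs(truth$data)), 0.01)
})

test_that("polynomial field fitting recovers constants, denoises, and projects", {
  v <- voxel_volume(array(2.5, c(12, 12, 6)))
  for (deg in 0:3) {
    sm <- smooth_field(v, degree = deg)
    expect_equal(vol_values(sm), rep(2.5, length(vol_values(v))), tolerance = 1e-9)
  }
  # degree-2 truth + 2% noise: polynomial smoothing recovers it well under
  # the noise level
  grid <- voxel_volume(array(0, c(24, 24, 8)))
  truth <- evaluate_field(quadratic_b1_field(0.15), grid)
  set.seed(3)
  noisy <- voxel_volume(truth$data + rnorm(length(truth$data), 0, 0.02),
                        truth$spacing)
  sm <- smooth_field(noisy, degree = 2)
  rmse <- sqrt(mean((sm$data - truth$data)^2))
  expect_lt(rmse, 0.02 / 3)
  # too few voxels for the requested degree: reduced with a warning
  tiny <- voxel_volume(array(1, c(2, 5, 1)))
  ws <- capture_warnings(f <- fit_smooth_field(tiny, degree = 3))
  expect_true(all(grepl("reduced", ws)))
  expect_lt(f$degree, 3)
  # projection: fitting the evaluated field again reproduces it
  ev <- evaluate_field(fit_smooth_field(noisy, 2), noisy)
  ev2 <- evaluate_field(fit_smooth_field(ev, 2), ev)
  expect_equal(ev2$data, ev$data, tolerance = 1e-8)
})

test_that("denoising is identity at strength 0, smooths noise, preserves means", {
  spec <- default_t2star_phantom(snr = 30, seed = 5)
  st <- simulate_phantom_study(spec)
  s2 <- apply_mask(st$s2_scan$TE_0.03, background_mask(st$s2_scan$TE_0.03, 0.1))
  expect_identical(denoise(s2, strength = 0), s2)
  dn <- denoise(s2, strength = 1)
  vois <- tube_vois(st$truth, margin_voxels = 2, segments = 1)
  before <- voi_stats(s2, vois); after <- voi_stats(dn, vois)
  expect_true(all(before$sd / after$sd >= 2))
  expect_true(all(abs(after$mean - before$mean) / before$mean < 0.01))
  # pure noise volume: variance must drop
  set.seed(6)
  pure <- voxel_volume(array(abs(rnorm(16 * 16 * 4)), c(16, 16, 4)))
  expect_lt(var(vol_values(denoise(pure, 1))), var(vol_values(pure)))
})

test_that("subtraction images highlight fast-relaxing tissue and propagate masks", {
  p2 <- default_protocols()$measurement_2
  a <- voxel_volume(array(2, c(4, 4, 2)))
  expect_equal(vol_values(subtraction_image(a, a)), rep(0, 32))
  # short T2* loses more signal between echoes at equal S0
  short_t <- list(t1 = 800, t2star = 3, s0 = 1)
  long_t <- list(t1 = 800, t2star = 30, s0 = 1)
  sub <- function(tp) spgr_signal(tp, p2$tr, p2$fa, 0.03) -
    spgr_signal(tp, p2$tr, p2$fa, 2.46)
  expect_gt(sub(short_t), sub(long_t))
  # masked voxels in either input are masked in the output
  b <- voxel_volume(array(1, c(4, 4, 2)),
                    mask = array(c(FALSE, rep(TRUE, 31)), c(4, 4, 2)))
  out <- subtraction_image(a, b)
  expect_false(out$mask[1, 1, 1])
  expect_error(subtraction_image(a, voxel_volume(array(1, c(4, 4, 3)))), "grid")
})

test_that("the preprocessing chain is a no-op for noiseless mapping", {
  spec <- default_t2star_phantom()
  st <- simulate_phantom_study(spec, noiseless = TRUE)
  plain <- map_t2star(st$s2_scan, "dual", te2 = 0.03, te3 = 2.46)
  s2 <- apply_mask(st$s2_scan$TE_0.03, background_mask(st$s2_scan$TE_0.03, 0.1))
  s3 <- apply_mask(st$s2_scan$TE_2.46, background_mask(st$s2_scan$TE_0.03, 0.1))
  chained <- dual_echo_t2star(denoise(s2, 1), denoise(s3, 1), 0.03, 2.46)
  sel <- chained$mask
  expect_equal(chained$data[sel], plain$data[sel], tolerance = 1e-12)
})

test_that("alignment check flags an integer shift", {
  set.seed(8)
  base <- array(0, c(16, 16, 4))
  base[6:10, 6:10, 2:3] <- 5
  base <- base + array(abs(rnorm(length(base), 0, 0.1)), dim(base))
  a <- voxel_volume(base)
  shifted <- voxel_volume(array(c(base[-1, , ], base[1, , ]), dim(base)))
  expect_warning(check_alignment(a, shifted), "misaligned")
  expect_silent(check_alignment(a, a))
})
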