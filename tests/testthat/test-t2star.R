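p2 <- default_protocols()$measurement_2

vol_of <- function(x, dims = c(4, 4, 2)) voxel_volume(array(x, dims))

test_that("dual-echo closed form inverts the log ratio and flags degeneracies", {
  # S2/S3 = e with spacing 2.43 ms gives exactly 2.43 ms
  m <- dual_echo_t2star(vol_of(exp(1)), vol_of(1), te2 = 0.03, te3 = 2.46)
  expect_equal(vol_values(m), rep(2.43, 32))
  # equal echoes (infinite T2*) are invalid
  m2 <- dual_echo_t2star(vol_of(1), vol_of(1), 0.03, 2.46)
  expect_identical(sum(m2$mask), 0L)
  # noiseless forward model is recovered to numerical precision
  tp <- list(t1 = 800, t2star = 5, s0 = 3)
  s2 <- vol_of(spgr_signal(tp, p2$tr, p2$fa, 0.03))
  s3 <- vol_of(spgr_signal(tp, p2$tr, p2$fa, 2.46))
  m3 <- dual_echo_t2star(s2, s3, 0.03, 2.46)
  expect_equal(vol_values(m3), rep(5, 32), tolerance = 1e-9)
  # grid mismatch and bad echo order are refused
  expect_error(dual_echo_t2star(vol_of(2), vol_of(1, c(4, 4, 3)), 0.03, 2.46),
               "grid")
  expect_error(dual_echo_t2star(vol_of(2), vol_of(1), 2.46, 0.03), "te3 > te2")
  # cap is applied and flagged
  mc <- dual_echo_t2star(vol_of(1.001), vol_of(1), 0.03, 2.46, t2_cap = 100)
  expect_true(all(vol_values(mc) == 100))
  expect_true(all(attr(mc, "clipped")))
})

test_that("dual-echo equals the two-point log-linear fit exactly", {
  s2 <- 7.3; s3 <- 2.1; te <- c(0.03, 2.46)
  fit <- stats::lm(log(c(s2, s3)) ~ te)
  m <- dual_echo_t2star(vol_of(s2, c(1, 1, 1)), vol_of(s3, c(1, 1, 1)),
                        te[1], te[2])
  expect_equal(vol_values(m), -1 / unname(stats::coef(fit)[2]), tolerance = 1e-12)
})

test_that("mono-exponential fit is exact on noiseless decays and guards inputs", {
  tes <- c(0.03, 2.46, 4.92)
  f <- monoexp_fit(echo_series(tes, 100 * exp(-tes / 3)))
  expect_equal(f$s0, 100, tolerance = 1e-6)
  expect_equal(f$t2star, 3, tolerance = 1e-6)
  expect_true(f$valid)
  expect_error(monoexp_fit(echo_series(c(1, 2), c(5, 3))), "at least 3")
  # non-positive magnitudes beyond tolerance invalidate the fit
  bad <- monoexp_fit(echo_series(tes, c(100, 0, 0)))
  expect_false(bad$valid)
  expect_equal(tidy(f)$term, c("s0", "t2star"))
  expect_true(glance(f)$valid)
})

test_that("mono-exponential fit is unbiased at high SNR (Gaussian noise)", {
  tes <- c(0.03, 2.46, 4.92)
  set.seed(1)
  est <- replicate(1000, {
    s <- pmax(100 * exp(-tes / 5) + rnorm(3, 0, 1), 1e-6)
    monoexp_fit(echo_series(tes, s))$t2star
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 5), 3 * se)
})

test_that("ETsME reference fit recovers fast and slow noiseless decays", {
  tes <- etsme_echo_times()
  expect_length(tes, 26)
  expect_equal(range(tes), c(0.03, 12.3))
  for (t2 in c(1.5, 20)) {
    ref <- etsme_reference(echo_series(tes, 50 * exp(-tes / t2)))
    expect_equal(as.numeric(ref), t2, tolerance = 1e-6)
  }
  # restricting to the shifted first echoes still identifies a fast decay
  ref_s <- etsme_reference(echo_series(tes, 50 * exp(-tes / 1.5)),
                           shifted_only = TRUE)
  expect_equal(as.numeric(ref_s), 1.5, tolerance = 1e-6)
})

test_that("ETsME is less biased than dual-echo TE3 = 2.46 for long T2* under noise", {
  snr <- 50; n_rep <- 200
  t2_true <- 20
  tes <- etsme_echo_times()
  tp_ets <- list(t1 = 1000, t2star = t2_true, s0 = 1)
  mu_ets <- spgr_signal(tp_ets, tr = 13, fa = 12, te = tes)
  sigma_ets <- spgr_signal(tp_ets, tr = 13, fa = 12, te = 0) / snr
  set.seed(7)
  ets_est <- replicate(n_rep, {
    sig <- rician_sample(mu_ets, sigma_ets, length(tes))
    as.numeric(etsme_reference(echo_series(tes, sig), nonlinear = FALSE))
  })
  ets_bias <- abs(mean(ets_est, na.rm = TRUE) - t2_true) / t2_true
  dual_bias <- abs(dual_echo_bias_pct(t2_true, 2.46, p2, snr = snr,
                                      n_rep = n_rep, n_vox = 1, seed = 7)) / 100
  expect_lt(ets_bias, dual_bias)
})

test_that("all three mapping methods agree exactly on noiseless volumes", {
  spec <- default_t2star_phantom()
  st <- simulate_phantom_study(spec, noiseless = TRUE)
  truth <- st$truth$t2star
  for (m in list(map_t2star(st$s2_scan, "dual", te2 = 0.03, te3 = 2.46),
                 map_t2star(st$s2_scan, "dual", te2 = 0.03, te3 = 4.92),
                 map_t2star(st$s2_scan, "3te"))) {
    sel <- m$mask & truth$mask
    expect_gt(sum(sel), 1000)
    expect_lt(max(abs(m$data[sel] - truth$data[sel]) / truth$data[sel]), 1e-6)
  }
})

test_that("under Rician noise TE3 = 4.92 overestimates very short T2* while 2.46 does not", {
  b492 <- dual_echo_bias_pct(1, 4.92, p2, snr = 50, seed = 7)
  b246 <- dual_echo_bias_pct(1, 2.46, p2, snr = 50, seed = 7)
  expect_gt(b492, 10)
  expect_lt(abs(b246), 10)
})
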