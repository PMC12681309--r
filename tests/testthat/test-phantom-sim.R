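test_that("default phantoms match their design ranges and are deterministic", {
  p_t2 <- default_t2star_phantom()
  expect_identical(nrow(p_t2$tubes), 7L)
  expect_equal(range(p_t2$tubes$t2star), c(1, 20))
  expect_true(all(p_t2$tubes$t1 == 1000))
  p_t1 <- default_t1_phantom()
  expect_identical(nrow(p_t1$tubes), 10L)
  expect_equal(range(p_t1$tubes$t1), c(300, 1300))
  expect_identical(default_t1_phantom(), default_t1_phantom())
  expect_error(check_tubes_public <- phantom_spec(
    tubes = dplyr::bind_rows(tube_spec("a", 0, 0, 5, 500, 10),
                             tube_spec("b", 4, 0, 5, 500, 10))), "overlap")
})

test_that("rendered truth voxelizes tube geometry within the discretization bound", {
  tub <- tube_spec("t", 0, 0, radius = 4 * 0.8, t1 = 700, t2star = 10)
  spec <- phantom_spec(dims = c(32, 32, 8), tubes = tub)
  truth <- render_truth(spec)
  n_in <- sum(truth$label$data > 0)
  expected <- pi * 4^2 * 8  # r = 4 voxels, full depth
  expect_lt(abs(n_in - expected) / expected, 0.05)
  expect_equal(unique(truth$t1$data[truth$label$data > 0]), 700)
  # background: parameter maps invalid, s0 zero
  expect_false(any(truth$t1$mask[truth$label$data == 0]))
  expect_true(all(truth$s0$data[truth$label$data == 0] == 0))
  # zero tubes -> all background
  empty <- phantom_spec(dims = c(8, 8, 2), tubes = tub[0, ])
  expect_true(all(render_truth(empty)$label$data == 0))
  # degree-0 field with coefficient 1 gives a constant B1 of 1
  expect_true(all(render_truth(spec)$b1$data == 1))
  specq <- phantom_spec(dims = c(32, 32, 8), tubes = tub,
                        b1_field = quadratic_b1_field(0.1))
  b1 <- render_truth(specq)$b1
  expect_gt(max(b1$data), 1.05)
  expect_lt(min(b1$data), 1.0)
})

test_that("scan simulation is seeded, exact at sigma 0, and Rician-calibrated", {
  spec <- tiny_phantom()
  truth <- render_truth(spec)
  p2 <- default_protocols()$measurement_2
  noiseless <- simulate_scan(truth, p2, noise_sigma = 0, seed = 1)
  mu <- spgr_signal(list(t1 = 500, t2star = 3, s0 = 1), p2$tr, p2$fa, 0.03)
  sel <- truth$label$data == 1
  expect_equal(unique(noiseless$TE_0.03$data[sel]), mu, tolerance = 1e-12)
  a <- simulate_scan(truth, p2, noise_sigma = 0.01, seed = 42)
  b <- simulate_scan(truth, p2, noise_sigma = 0.01, seed = 42)
  expect_identical(a$TE_0.03$data, b$TE_0.03$data)
  expect_false(identical(a$TE_0.03$data,
                         simulate_scan(truth, p2, 0.01, seed = 43)$TE_0.03$data))
  # high-SNR Rician mean approaches the noiseless mean within 1%
  set.seed(9)
  draws <- rician_sample(mu, mu / 50, 1e4)
  expect_lt(abs(mean(draws) - mu) / mu, 0.01)
})

test_that("inversion-recovery simulation has the analytic null and recovery points", {
  spec <- tiny_phantom(t1 = c(600, 1000))
  truth <- render_truth(spec)
  sel1 <- truth$label$data == 1
  # null point at TI = T1 * ln 2 for ideal inversion
  null_ti <- 600 * log(2)
  ir <- simulate_ir_series(truth, tis = c(30, null_ti, 3000, 99000),
                           noise_sigma = 0, seed = 1)
  expect_lt(max(ir[[sprintf("TI_%g", null_ti)]]$data[sel1]), 1e-10)
  # full recovery approaches A = s0 * exp(-te/t2star)
  a_exp <- 1 * exp(-0.03 / spec$tubes$t2star[1])
  expect_equal(unique(ir$TI_99000$data[sel1]), a_exp, tolerance = 1e-4)
  expect_error(simulate_ir_series(truth, tis = c(100, 50)), "ascending")
})

test_that("ir_fit closes the loop on noiseless simulated tube series", {
  spec <- default_t1_phantom()
  truth <- render_truth(spec)
  tis <- default_tis()
  ir <- simulate_ir_series(truth, tis, noise_sigma = 0, seed = 1)
  vois <- tube_vois(truth, margin_voxels = 2, segments = 1)
  for (i in seq_len(nrow(vois))) {
    sig <- voi_series(ir, "TI", tis, vois$voxels[[i]])
    fit <- ir_fit(inversion_series(tis, sig))
    expect_equal(fit$t1, spec$tubes$t1[vois$tube[i]], tolerance = 1e-3)
  }
})

test_that("study simulation derives the channel noise from the target SNR", {
  spec <- default_t2star_phantom(snr = 50)
  st <- simulate_phantom_study(spec)
  truth <- st$truth
  p2 <- st$protocols$p2
  mu0 <- mean(spgr_signal(list(t1 = 1000,
                               t2star = truth$t2star$data[truth$label$data > 0],
                               s0 = 1), p2$tr, p2$fa, p2$tes[1]))
  expect_equal(mu0 / st$sigma, 50, tolerance = 1e-6)
})
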