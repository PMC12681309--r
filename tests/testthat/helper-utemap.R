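# Shared test helpers: independent oracles and small fixtures.

# Brute-force Bloch steady-state oracle for the ideally spoiled gradient
# echo: iterate RF tip + T1 relaxation to a fixed point, independent of the
# closed-form implementation.
bloch_spgr <- function(t1, t2star, s0, tr, fa, te, tol = 1e-12,
                       max_iter = 1e6L) {
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  mz <- 1
  for (i in seq_len(max_iter)) {
    mz_new <- 1 + (mz * cos(a) - 1) * e1
    if (abs(mz_new - mz) < tol) break
    mz <- mz_new
  }
  s0 * mz * sin(a) * exp(-te / t2star)
}

# Rician magnitude samples around a noiseless mean
rician_sample <- function(mean, sigma, n) {
  sqrt((mean + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# tissue-level replicate simulation of the dual-echo estimator: returns the
# mean percent bias of the VOI-mean T2* over n_rep replicates
dual_echo_bias_pct <- function(t2star, te3, protocol, snr = 50, n_rep = 200,
                               n_vox = 200, t1 = 1000, seed = 7, te2 = 0.03,
                               t2_cap = 100) {
  set.seed(seed)
  tp <- list(t1 = t1, t2star = t2star, s0 = 1)
  sigma <- spgr_signal(tp, protocol$tr, protocol$fa, 0) / snr
  mu2 <- spgr_signal(tp, protocol$tr, protocol$fa, te2)
  mu3 <- spgr_signal(tp, protocol$tr, protocol$fa, te3)
  est <- vapply(seq_len(n_rep), function(r) {
    m2 <- rician_sample(mu2, sigma, n_vox)
    m3 <- rician_sample(mu3, sigma, n_vox)
    ok <- m2 > m3 & m3 > 0
    mean(pmin((te3 - te2) / log(m2[ok] / m3[ok]), t2_cap))
  }, numeric(1))
  100 * (mean(est) - t2star) / t2star
}

# small two-tube phantom for fast pipeline tests
tiny_phantom <- function(t1 = c(500, 1000), t2star = c(3, 20), snr = 50,
                         seed = 1L) {
  tubes <- dplyr::bind_rows(
    tube_spec("a", -8, 0, radius = 4, t1 = t1[1], t2star = t2star[1]),
    tube_spec("b", 8, 0, radius = 4, t1 = t1[2], t2star = t2star[2]))
  phantom_spec(dims = c(32, 32, 8), tubes = tubes, snr = snr, seed = seed)
}

# VOI-mean echo/inversion series from a simulated multi-volume set
voi_series <- function(volset, prefix, times, voxels) {
  vapply(times, function(t) {
    v <- vol_data(volset[[sprintf("%s_%g", prefix, t)]])[voxels]
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

# per-VOI ETsME reference T2* values for a truth set
etsme_reference_by_voi <- function(truth, vois, noise_sigma, seed,
                                   tes = etsme_echo_times()) {
  ets <- simulate_etsme_series(truth, tes = tes, noise_sigma = noise_sigma,
                               seed = seed)
  vapply(seq_len(nrow(vois)), function(i) {
    sig <- voi_series(ets, "TE", tes, vois$voxels[[i]])
    as.numeric(etsme_reference(echo_series(tes, sig)))
  }, numeric(1))
}

# per-VOI inversion-recovery reference T1 values
ir_reference_by_voi <- function(truth, vois, noise_sigma, seed,
                                tis = default_tis()) {
  ir <- simulate_ir_series(truth, tis = tis, noise_sigma = noise_sigma,
                           seed = seed)
  vapply(seq_len(nrow(vois)), function(i) {
    sig <- voi_series(ir, "TI", tis, vois$voxels[[i]])
    ir_fit(inversion_series(tis, sig))$t1
  }, numeric(1))
}
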