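#' Tube specification table
#'
#' Tubes of a digital multi-tube phantom are rows of a tibble with columns
#' `label`, `cx`, `cy` (in-plane center, mm, in the center-aligned frame),
#' `radius` (mm), `t1` (ms), `t2star` (ms), `s0` (arbitrary units). Tubes
#' are cylinders spanning the full slice stack and must not overlap.
#'
#' @param label tube label
#' @param cx,cy center, mm
#' @param radius radius, mm, > 0
#' @param t1,t2star relaxation times, ms, > 0
#' @param s0 proton-density signal, default 1
#' @return a one-row tibble (bind rows to build a phantom)
#' @export
tube_spec <- function(label, cx, cy, radius, t1, t2star, s0 = 1) {
  stopifnot(radius > 0, t1 > 0, t2star > 0, s0 >= 0)
  tibble::tibble(label = as.character(label), cx = cx, cy = cy, radius = radius,
                 t1 = t1, t2star = t2star, s0 = s0)
}

check_tubes <- function(tubes) {
  req <- c("label", "cx", "cy", "radius", "t1", "t2star", "s0")
  if (!all(req %in% names(tubes)))
    stop("tube table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  n <- nrow(tubes)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((tubes$cx[i] - tubes$cx[j])^2 + (tubes$cy[i] - tubes$cy[j])^2)
    if (d < tubes$radius[i] + tubes$radius[j])
      stop("tubes '", tubes$label[i], "' and '", tubes$label[j], "' overlap",
           call. = FALSE)
  }
  invisible(tubes)
}

#' Digital phantom specification
#'
#' Full state of the simulator: grid geometry, the tube table, background
#' proton density, the smooth B1+ field, the image SNR, and the seed.
#' Identical spec + seed reproduce identical simulated volumes.
#'
#' @param dims grid dimensions (default 64 x 64 x 16)
#' @param spacing voxel size, mm (default 0.8 isotropic, matching the
#'   high-resolution UTE acquisitions the simulator emulates)
#' @param tubes a tube tibble (see [tube_spec()])
#' @param background_s0 proton density outside the tubes (default 0)
#' @param b1_field a [polynomial_field()] for the relative transmit scale, or
#'   `NULL` for a uniform field of 1
#' @param snr image SNR at the first echo (TE ~ 0) of the dual-echo scan:
#'   mean noiseless tube magnitude divided by the Gaussian channel SD
#' @param seed integer seed for noise generation
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(dims = c(64, 64, 16), spacing = c(0.8, 0.8, 0.8),
                         tubes, background_s0 = 0, b1_field = NULL,
                         snr = 50, seed = 1L) {
  stopifnot(length(dims) == 3, all(dims >= 1), all(spacing > 0), snr > 0)
  check_tubes(tubes)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 tubes = tubes, background_s0 = background_s0,
                 b1_field = b1_field, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid @ %s mm, %d tubes, SNR %g, seed %d\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              nrow(x$tubes), x$snr, x$seed))
  print(x$tubes)
  invisible(x)
}

ring_tubes <- function(labels, t1, t2star, ring_radius, tube_radius, s0 = 1) {
  n <- length(labels)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(label = labels,
                 cx = ring_radius * cos(ang), cy = ring_radius * sin(ang),
                 radius = tube_radius, t1 = t1, t2star = t2star, s0 = s0)
}

#' Default T2* phantom
#'
#' Seven tubes on a ring covering T2* from 1 to 20 ms (1/2/3/5/8/12/20 ms,
#' denser at the fast-relaxing end, matching the target range of
#' musculoskeletal UTE tissue), common T1 of 1000 ms, on a 64 x 64 x 16 grid
#' at 0.8 mm isotropic spacing with a uniform B1+ field.
#'
#' @param snr image SNR (see [phantom_spec()]); default 50
#' @param seed noise seed
#' @return a [phantom_spec()]
#' @export
default_t2star_phantom <- function(snr = 50, seed = 7L) {
  t2 <- c(1, 2, 3, 5, 8, 12, 20)
  tubes <- ring_tubes(sprintf("t2star_%gms", t2), t1 = 1000, t2star = t2,
                      ring_radius = 16, tube_radius = 5)
  phantom_spec(tubes = tubes, snr = snr, seed = seed)
}

#' Default T1 phantom
#'
#' Ten tubes on a ring with T1 evenly spanning 300-1300 ms
#' (300/411/522/633/744/856/967/1078/1189/1300 ms), common T2* of 30 ms
#' (slow-relaxing gel analogue), uniform B1+ field.
#'
#' @inheritParams default_t2star_phantom
#' @return a [phantom_spec()]
#' @export
default_t1_phantom <- function(snr = 50, seed = 11L) {
  t1 <- round(seq(300, 1300, length.out = 10))
  tubes <- ring_tubes(sprintf("t1_%dms", t1), t1 = t1, t2star = 30,
                      ring_radius = 17, tube_radius = 4)
  phantom_spec(tubes = tubes, snr = snr, seed = seed)
}

#' Smooth quadratic B1+ inhomogeneity field
#'
#' A center-weighted quadratic transmit profile
#' `1 + amplitude * (1 - (x^2 + y^2 + z^2) * 2/3)` on normalized coordinates
#' scaled so the field averages roughly 1 with peak-to-edge variation of
#' about `2 * amplitude`, emulating the smooth transmit inhomogeneity of a
#' knee coil at 3 T.
#'
#' @param amplitude relative peak deviation (e.g. 0.1 for ~±10%)
#' @return a [polynomial_field()] of degree 2
#' @export
quadratic_b1_field <- function(amplitude = 0.1) {
  ex <- monomial_exponents(2)
  coef <- numeric(nrow(ex))
  coef[rowSums(ex) == 0] <- 1 + amplitude
  coef[ex$i == 2 | ex$j == 2 | ex$k == 2] <- -amplitude * 2 / 3
  polynomial_field(2, coef)
}

#' Render ground-truth parameter volumes of a phantom
#'
#' Voxelizes the tube geometry (a voxel belongs to a tube if its center lies
#' inside the tube circle) and evaluates the B1+ field. Parameter maps (`t1`,
#' `t2star`) are valid inside tubes only; `s0` carries the background value
#' outside; `label` holds the 1-based tube index (0 = background).
#'
#' @param spec a [phantom_spec()]
#' @return a [volume_set()] with members `t1`, `t2star`, `s0`, `b1`, `label`
#' @export
render_truth <- function(spec) {
  check_tubes(spec$tubes)
  d <- spec$dims
  xs <- axis_coords(d[1], spec$spacing[1])
  ys <- axis_coords(d[2], spec$spacing[2])
  gx <- matrix(rep(xs, times = d[2]), d[1], d[2])
  gy <- matrix(rep(ys, each = d[1]), d[1], d[2])
  lab2d <- matrix(0L, d[1], d[2])
  for (k in seq_len(nrow(spec$tubes))) {
    inside <- (gx - spec$tubes$cx[k])^2 + (gy - spec$tubes$cy[k])^2 <=
      spec$tubes$radius[k]^2
    lab2d[inside] <- k
  }
  lab <- array(rep(lab2d, d[3]), d)
  t1 <- t2s <- array(NA_real_, d)
  s0 <- array(spec$background_s0, d)
  sel <- lab > 0L
  t1[sel] <- spec$tubes$t1[lab[sel]]
  t2s[sel] <- spec$tubes$t2star[lab[sel]]
  s0[sel] <- spec$tubes$s0[lab[sel]]
  ref <- voxel_volume(s0, spec$spacing)
  b1 <- if (is.null(spec$b1_field)) voxel_volume(array(1, d), spec$spacing)
        else evaluate_field(spec$b1_field, ref)
  volume_set(
    t1 = voxel_volume(t1, spec$spacing),
    t2star = voxel_volume(t2s, spec$spacing),
    s0 = ref,
    b1 = b1,
    label = voxel_volume(array(as.numeric(lab), d), spec$spacing)
  )
}

rician <- function(mean, sigma) {
  if (sigma <= 0) return(abs(mean))
  n <- length(mean)
  sqrt((mean + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# noiseless SPGR magnitude array for one TE over a truth set
forward_means <- function(truth, protocol, te) {
  d <- vol_dim(truth$s0)
  mu <- array(0, d)
  sel <- truth$t1$mask & truth$t2star$mask
  fa_eff <- truth$b1$data[sel] * protocol$fa
  mu[sel] <- spgr_signal(list(t1 = truth$t1$data[sel],
                              t2star = truth$t2star$data[sel],
                              s0 = truth$s0$data[sel]),
                         tr = protocol$tr, fa = fa_eff, te = te)
  mu
}

#' Channel noise SD for a target image SNR
#'
#' Converts an image SNR (mean noiseless tube magnitude at the scan's first
#' echo divided by channel SD) into the Gaussian channel SD used by the
#' Rician noise model. One scanner-level SD is shared by every scan of a
#' study.
#'
#' @param truth a [render_truth()] set
#' @param protocol the scan whose first echo defines the SNR (the dual-echo
#'   scan by convention)
#' @param snr target SNR
#' @return channel SD in signal units
#' @export
noise_sigma_for_snr <- function(truth, protocol, snr) {
  mu <- forward_means(truth, protocol, protocol$tes[1])
  sel <- truth$label$data > 0
  mean(mu[sel]) / snr
}

#' Simulate one SPGR/UTE scan of a phantom
#'
#' Per voxel and echo the noiseless magnitude is the SPGR steady-state signal
#' with effective flip angle `b1 * fa`; Rician magnitude noise is added as
#' `sqrt((mean + g1)^2 + g2^2)` with `g ~ N(0, noise_sigma^2)`. The noise
#' floor this produces (not Gaussian noise) is what biases log-ratio T2*
#' estimators at long TE3 — simulating it faithfully matters.
#'
#' @param truth a [render_truth()] volume set
#' @param protocol an [acquisition_protocol()]
#' @param noise_sigma Gaussian channel SD (0 = noiseless)
#' @param seed integer seed; identical seed gives identical volumes
#' @return a [volume_set()] with one magnitude volume per echo, named
#'   `TE_<te>`
#' @export
simulate_scan <- function(truth, protocol, noise_sigma = 0, seed = 1L) {
  d <- vol_dim(truth$s0)
  set.seed(seed)
  vols <- list()
  for (te in protocol$tes) {
    mu <- forward_means(truth, protocol, te)
    mag <- array(rician(mu, noise_sigma), d)
    vols[[echo_name(te)]] <- voxel_volume(mag, truth$s0$spacing)
  }
  volume_set(vols)
}

#' Simulate an inversion-recovery UTE series
#'
#' Ideal-inversion three-parameter magnitude model per voxel:
#' `|A - B exp(-TI/T1)|` with `A = S0_scan` (the scan's steady-state
#' amplitude at the acquisition echo) and `B = (1 + inv_eff) * A`
#' (`inv_eff = 1` is a perfect inversion), then Rician noise.
#'
#' @param truth a [render_truth()] set
#' @param tis inversion times, ms, ascending (default 22 values, 30-8000 ms,
#'   log-spaced)
#' @param protocol readout protocol (its first TE applies T2* weighting to A)
#' @param inv_eff inversion efficiency in (0, 1]
#' @param noise_sigma Gaussian channel SD
#' @param seed integer seed
#' @return a [volume_set()] with one volume per TI, named `TI_<ti>`
#' @export
simulate_ir_series <- function(truth, tis = default_tis(), protocol = NULL,
                               inv_eff = 1, noise_sigma = 0, seed = 1L) {
  if (any(diff(tis) <= 0)) stop("`tis` must be ascending", call. = FALSE)
  if (is.null(protocol))
    protocol <- acquisition_protocol(tr = 4.4, fa = 6, tes = 0.03,
                                     label = "IR-UTE readout")
  d <- vol_dim(truth$s0)
  a <- array(0, d)
  sel <- truth$t1$mask & truth$t2star$mask
  a[sel] <- truth$s0$data[sel] * exp(-protocol$tes[1] / truth$t2star$data[sel])
  t1 <- truth$t1$data
  set.seed(seed)
  vols <- list()
  for (ti in tis) {
    mu <- array(0, d)
    mu[sel] <- abs(a[sel] * (1 - (1 + inv_eff) * exp(-ti / t1[sel])))
    vols[[sprintf("TI_%g", ti)]] <- voxel_volume(array(rician(mu, noise_sigma), d),
                                                 truth$s0$spacing)
  }
  volume_set(vols)
}

#' Default inversion times: 22 TIs from 30 to 8000 ms, log-spaced
#' @return numeric vector, ms
#' @export
default_tis <- function() round(exp(seq(log(30), log(8000), length.out = 22)), 1)

#' Simulate an ETsME reference acquisition
#'
#' The echo-train shifted multi-echo scheme is steady-state in T1 (fixed
#' TR/FA), so its unique echo times are simulated as one multi-echo scan.
#'
#' @param truth a [render_truth()] set
#' @param tes echo times, default [etsme_echo_times()]
#' @param tr,fa readout parameters (defaults 13 ms / 12 degrees)
#' @param noise_sigma Gaussian channel SD
#' @param seed integer seed
#' @return a [volume_set()] with one volume per echo
#' @export
simulate_etsme_series <- function(truth, tes = etsme_echo_times(), tr = 13,
                                  fa = 12, noise_sigma = 0, seed = 1L) {
  protocol <- acquisition_protocol(tr = tr, fa = fa, tes = tes, label = "ETsME")
  simulate_scan(truth, protocol, noise_sigma = noise_sigma, seed = seed)
}

#' Simulate a complete two-scan mapping study
#'
#' Renders the truth, derives the channel noise SD from the spec's SNR (on
#' the dual-echo scan's first echo), and simulates both UTE scans. Seeds for
#' the two scans are derived from the spec seed.
#'
#' @param spec a [phantom_spec()]
#' @param protocols named list with the low-flip scan first and the dual-echo
#'   scan second (default [default_protocols()])
#' @param noiseless force `noise_sigma = 0`
#' @return a list with `truth`, `s1_scan`, `s2_scan`, `sigma`, `protocols`
#' @export
simulate_phantom_study <- function(spec, protocols = default_protocols(),
                                   noiseless = FALSE) {
  truth <- render_truth(spec)
  p1 <- protocols[[1]]; p2 <- protocols[[2]]
  sigma <- if (noiseless) 0 else noise_sigma_for_snr(truth, p2, spec$snr)
  list(truth = truth,
       s1_scan = simulate_scan(truth, p1, noise_sigma = sigma, seed = spec$seed),
       s2_scan = simulate_scan(truth, p2, noise_sigma = sigma, seed = spec$seed + 1L),
       sigma = sigma, protocols = list(p1 = p1, p2 = p2))
}
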