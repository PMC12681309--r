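#' Echo series
#'
#' A set of echo times with matching magnitudes, either for one voxel or for
#' a region-mean decay curve.
#'
#' @param tes echo times in ms, strictly ascending, length >= 2
#' @param signals magnitudes >= 0, same length as `tes`
#' @return an object of class `echo_series`
#' @export
echo_series <- function(tes, signals) {
  tes <- as.numeric(tes); signals <- as.numeric(signals)
  if (length(tes) < 2L) stop("an echo series needs at least 2 echoes", call. = FALSE)
  if (any(diff(tes) <= 0)) stop("`tes` must be strictly ascending", call. = FALSE)
  if (length(signals) != length(tes)) stop("`signals` and `tes` lengths differ", call. = FALSE)
  if (any(signals < 0, na.rm = TRUE)) stop("magnitudes must be >= 0", call. = FALSE)
  structure(list(tes = tes, signals = signals), class = "echo_series")
}

#' Dual-echo T2* map
#'
#' Voxelwise closed-form T2* from the logarithmic ratio of two echoes:
#' `T2* = (te3 - te2) / ln(S2/S3)`. Voxels where `S3 <= 0` or `S2 <= S3`
#' (non-decaying magnitudes, infinite or negative T2*) are marked invalid.
#' Estimates above `t2_cap` are clipped to `t2_cap` and flagged in the
#' `"clipped"` attribute (a logical array) but stay in the map, so downstream
#' region statistics may include or exclude them.
#'
#' @param s2 magnitude volume at the earlier echo `te2`
#' @param s3 magnitude volume at the later echo `te3`, same grid
#' @param te2,te3 echo times in ms, `te3 > te2 >= 0`
#' @param t2_cap upper cap in ms (default 100)
#' @return a `voxel_volume` of T2* in ms with attribute `"clipped"`
#' @export
dual_echo_t2star <- function(s2, s3, te2, te3, t2_cap = 100) {
  if (!(te3 > te2) || te2 < 0) stop("need te3 > te2 >= 0", call. = FALSE)
  stop_if_grid_mismatch(s2, s3, "echo volumes")
  valid <- s2$mask & s3$mask & s3$data > 0 & s2$data > s3$data
  t2 <- array(NA_real_, dim = vol_dim(s2))
  t2[valid] <- (te3 - te2) / log(s2$data[valid] / s3$data[valid])
  clipped <- array(FALSE, dim = vol_dim(s2))
  clipped[valid] <- t2[valid] > t2_cap
  t2[clipped] <- t2_cap
  out <- voxel_volume(t2, s2$spacing, mask = valid)
  attr(out, "clipped") <- clipped
  out
}

# weighted log-linear mono-exponential fit on vectors; returns c(s0, t2star)
# or NAs when inestimable. Weights ~ signal^2 make the log-domain LS
# approximate the signal-domain LS at high SNR.
loglin_fit <- function(tes, signals, weighted = TRUE) {
  ok <- is.finite(signals) & signals > 0
  if (sum(ok) < 2L) return(c(NA_real_, NA_real_, NA_real_))
  x <- tes[ok]; y <- log(signals[ok])
  w <- if (weighted) signals[ok]^2 else rep(1, sum(ok))
  sw <- sum(w)
  xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) return(c(NA_real_, NA_real_, NA_real_))
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  if (slope >= 0) return(c(NA_real_, NA_real_, NA_real_))
  s0 <- exp(yb - slope * xb)
  resid <- sqrt(sum((signals[ok] - s0 * exp(slope * x))^2))
  c(s0, -1 / slope, resid)
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of `S(te) = S0 * exp(-te / T2*)` to an echo series.
#' The default fitter is weighted log-linear least squares (weights
#' proportional to the squared signal), which is deterministic and cannot
#' fail to converge; `nonlinear = TRUE` refines the estimate with
#' Levenberg-Marquardt in the signal domain (used for reference fits).
#' Non-positive magnitudes are dropped as invalid rather than clamped; if
#' fewer than 3 positive samples remain the fit is returned invalid.
#'
#' @param series an [echo_series()] with at least 3 echoes
#' @param weighted use signal^2 weights in the log-domain fit
#' @param nonlinear refine with [minpack.lm::nlsLM()]
#' @return an object of class `monoexp_fit`: list with `s0`, `t2star`,
#'   `residual` (RSS norm), `n_used`, `valid`
#' @export
monoexp_fit <- function(series, weighted = TRUE, nonlinear = FALSE) {
  stopifnot(inherits(series, "echo_series"))
  if (length(series$tes) < 3L)
    stop("mono-exponential fit needs at least 3 echoes", call. = FALSE)
  est <- loglin_fit(series$tes, series$signals, weighted = weighted)
  n_used <- sum(is.finite(series$signals) & series$signals > 0)
  valid <- n_used >= 3L && all(is.finite(est))
  if (valid && nonlinear) {
    df <- data.frame(te = series$tes, s = series$signals)
    df <- df[is.finite(df$s) & df$s > 0, ]
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ s0 * exp(-te / t2), data = df,
                        start = list(s0 = est[1], t2 = est[2]),
                        lower = c(0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      est <- c(cf[["s0"]], cf[["t2"]],
               sqrt(sum(stats::residuals(fit)^2)))
    }
  }
  structure(list(s0 = est[1], t2star = est[2], residual = est[3],
                 n_used = n_used, valid = valid),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("<monoexp_fit> S0 = %.4g, T2* = %.4g ms (%d echoes%s)\n",
              x$s0, x$t2star, x$n_used, if (x$valid) "" else ", INVALID"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.monoexp_fit <- function(x, ...) {
  tibble::tibble(term = c("s0", "t2star"), estimate = c(x$s0, x$t2star))
}

#' @exportS3Method generics::glance
glance.monoexp_fit <- function(x, ...) {
  tibble::tibble(s0 = x$s0, t2star = x$t2star, residual = x$residual,
                 n_used = x$n_used, valid = x$valid)
}

#' Echo times of the echo-train shifted multi-echo (ETsME) reference scheme
#'
#' The reference acquisition repeats a multi-echo scan while sliding the
#' first echo across the ultrashort range, densely sampling early decay; the
#' later echoes stay fixed. Defaults: 22 shifted first echoes from 0.03 to
#' 1.5 ms plus fixed echoes at 4.92/7.38/9.84/12.3 ms.
#'
#' @param n_shift number of shifted first echoes
#' @param first_range range (ms) covered by the shifted first echo
#' @param fixed fixed later echo times (ms); `NULL` to use only shifted echoes
#' @return sorted unique echo times in ms
#' @export
etsme_echo_times <- function(n_shift = 22, first_range = c(0.03, 1.5),
                             fixed = c(4.92, 7.38, 9.84, 12.3)) {
  sort(unique(c(seq(first_range[1], first_range[2], length.out = n_shift), fixed)))
}

#' ETsME reference T2*
#'
#' Mono-exponential fit over the full ETsME echo set. The dense early
#' samples anchor fast decays; by default the fixed later echoes are
#' included, `shifted_only = TRUE` restricts the fit to the sliding first
#' echoes (<= `first_max` ms).
#'
#' @param series an [echo_series()] built from ETsME samples
#' @param shifted_only drop echoes later than `first_max`
#' @param first_max upper end of the shifted-echo range, ms
#' @param nonlinear refine the fit nonlinearly (default TRUE: reference
#'   quality over speed)
#' @return T2* in ms; the full fit is attached as attribute `"fit"`
#' @export
etsme_reference <- function(series, shifted_only = FALSE, first_max = 1.5,
                            nonlinear = TRUE) {
  stopifnot(inherits(series, "echo_series"))
  if (shifted_only) {
    keep <- series$tes <= first_max + 1e-9
    series <- echo_series(series$tes[keep], series$signals[keep])
  }
  fit <- monoexp_fit(series, nonlinear = nonlinear)
  structure(fit$t2star, fit = fit)
}

#' Voxelwise T2* mapping over a multi-echo scan
#'
#' Applies either the dual-echo closed form (`method = "dual"`, echoes `te2`
#' and `te3`) or a voxelwise weighted log-linear mono-exponential fit over
#' all echoes (`method = "3te"`) to a [volume_set()] of per-echo magnitude
#' volumes named `TE_<te>` (as produced by [simulate_scan()]).
#'
#' @param scan a `volume_set` with one magnitude volume per echo
#' @param method `"dual"` or `"3te"`
#' @param te2,te3 echo times (ms) selecting the dual-echo pair; defaults to
#'   the first and second available echo
#' @param t2_cap cap in ms, see [dual_echo_t2star()]
#' @return a `voxel_volume` of T2* (ms)
#' @export
map_t2star <- function(scan, method = c("dual", "3te"), te2 = NULL, te3 = NULL,
                       t2_cap = 100) {
  method <- match.arg(method)
  tes <- scan_echo_times(scan)
  if (method == "dual") {
    if (is.null(te2)) te2 <- tes[1]
    if (is.null(te3)) te3 <- tes[2]
    s2 <- scan[[echo_name(te2)]]
    s3 <- scan[[echo_name(te3)]]
    if (is.null(s2) || is.null(s3))
      stop("requested echoes not present in scan: ", te2, ", ", te3, call. = FALSE)
    return(dual_echo_t2star(s2, s3, te2, te3, t2_cap = t2_cap))
  }
  if (length(tes) < 3L) stop("'3te' mapping needs >= 3 echoes", call. = FALSE)
  dims <- vol_dim(scan[[1]])
  nvox <- prod(dims)
  sig <- vapply(tes, function(te) as.vector(scan[[echo_name(te)]]$data), numeric(nvox))
  msk <- vapply(tes, function(te) as.vector(scan[[echo_name(te)]]$mask), logical(nvox))
  pos <- sig > 0 & msk
  valid <- rowSums(pos) == length(tes)
  # vectorized weighted log-linear fit across voxels (weights = signal^2)
  t2 <- rep(NA_real_, nvox)
  if (any(valid)) {
    s <- sig[valid, , drop = FALSE]
    y <- log(s)
    w <- s^2
    sw <- rowSums(w)
    x <- matrix(tes, nrow = sum(valid), ncol = length(tes), byrow = TRUE)
    xb <- rowSums(w * x) / sw
    yb <- rowSums(w * y) / sw
    sxx <- rowSums(w * (x - xb)^2)
    slope <- rowSums(w * (x - xb) * (y - yb)) / sxx
    est <- ifelse(slope < 0 & sxx > 0, -1 / slope, NA_real_)
    t2[valid] <- est
  }
  valid <- valid & is.finite(t2)
  clipped <- valid & t2 > t2_cap
  t2[clipped] <- t2_cap
  out <- voxel_volume(array(t2, dims), scan[[1]]$spacing, mask = array(valid, dims))
  attr(out, "clipped") <- array(clipped, dims)
  out
}

echo_name <- function(te) sprintf("TE_%g", te)

scan_echo_times <- function(scan) {
  nm <- names(scan)
  tes <- suppressWarnings(as.numeric(sub("^TE_", "", nm)))
  if (any(is.na(tes))) stop("scan volumes must be named TE_<te>", call. = FALSE)
  sort(tes)
}
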