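#' Acquisition protocol for one SPGR/UTE scan
#'
#' @param tr repetition time in ms, > 0
#' @param fa nominal flip angle in degrees, in (0, 180)
#' @param tes echo times in ms, strictly ascending, all >= 0, first < `tr`
#' @param label free-text scan label
#' @return an object of class `acquisition_protocol`
#' @examples
#' # the shipped default pair: see default_protocols()
#' acquisition_protocol(tr = 9.24, fa = 11, tes = c(0.03, 2.46, 4.92))
#' @export
acquisition_protocol <- function(tr, fa, tes, label = "") {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("`tr` must be > 0 ms", call. = FALSE)
  if (!is.numeric(fa) || length(fa) != 1L || fa <= 0 || fa >= 180)
    stop("`fa` must be in (0, 180) degrees", call. = FALSE)
  tes <- as.numeric(tes)
  if (!length(tes) || any(tes < 0) || any(diff(tes) <= 0))
    stop("`tes` must be ascending echo times >= 0 ms", call. = FALSE)
  if (tes[1] >= tr) stop("first echo time must precede TR", call. = FALSE)
  structure(list(tr = tr, fa = fa, tes = tes, label = as.character(label)[1]),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol>%s TR %.3g ms, FA %.3g deg, TEs %s ms\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$tr, x$fa, paste(format(x$tes), collapse = "/")))
  invisible(x)
}

#' Tissue relaxation parameters
#'
#' @param t1 longitudinal relaxation time in ms, > 0
#' @param t2star effective transverse relaxation time in ms, > 0
#' @param s0 signal at TE = 0 in arbitrary units, >= 0
#' @return an object of class `tissue_params`; fields may be vectors or arrays
#'   of a common shape for vectorized evaluation
#' @export
tissue_params <- function(t1, t2star, s0 = 1) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("`t1` must be > 0 ms", call. = FALSE)
  if (any(t2star <= 0, na.rm = TRUE)) stop("`t2star` must be > 0 ms", call. = FALSE)
  if (any(s0 < 0, na.rm = TRUE)) stop("`s0` must be >= 0", call. = FALSE)
  structure(list(t1 = t1, t2star = t2star, s0 = s0), class = "tissue_params")
}

deg2rad <- function(x) x * pi / 180

#' Steady-state spoiled gradient echo signal
#'
#' The ideally spoiled SPGR steady-state magnitude:
#' \deqn{S = S_0 \sin\alpha \frac{1 - e^{-TR/T_1}}{1 - e^{-TR/T_1}\cos\alpha}
#'       \, e^{-TE/T_2^*}.}
#' All arguments are vectorized; arrays broadcast elementwise.
#'
#' @param tissue a [tissue_params()] (or bare list with `t1`, `t2star`, `s0`)
#' @param tr repetition time, ms
#' @param fa flip angle, degrees
#' @param te echo time, ms
#' @return signal in the units of `s0`; bounded by `s0`
#' @export
spgr_signal <- function(tissue, tr, fa, te) {
  e1 <- exp(-tr / tissue$t1)
  a <- deg2rad(fa)
  tissue$s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te / tissue$t2star)
}

#' In-phase echo times for a water-fat chemical shift
#'
#' Echo times at which water and fat magnetization align: multiples of the
#' beat period `1 / (f0 * shift)` where `f0` is the scanner frequency in MHz
#' and `shift` the chemical shift in ppm (the product is the offset in Hz).
#' Results are reported in ms rounded to 0.01 ms, the precision at which
#' protocols quote echo times.
#'
#' @param f0 operating frequency, MHz (123.256 at the 3 T system the default
#'   protocols target)
#' @param shift water-fat chemical shift, ppm (default 3.3)
#' @param n number of in-phase echoes to return
#' @return numeric vector of echo times in ms
#' @examples
#' inphase_echo_times(123.256, 3.3, 2) # 2.46, 4.92
#' @export
inphase_echo_times <- function(f0, shift = 3.3, n = 2) {
  if (f0 <= 0 || shift <= 0 || n < 1) stop("f0, shift must be > 0 and n >= 1", call. = FALSE)
  round(seq_len(n) * 1000 / (f0 * shift), 2)
}

#' Ernst angle
#'
#' Flip angle maximizing the SPGR steady-state signal at a given TR/T1:
#' `acos(exp(-tr/t1))`, in degrees.
#'
#' @param tr repetition time, ms
#' @param t1 longitudinal relaxation time, ms
#' @return angle in degrees (not rounded; round to integer degrees for
#'   protocol reporting)
#' @examples
#' round(ernst_angle(9.24, 500)) # 11
#' @export
ernst_angle <- function(tr, t1) {
  if (any(tr <= 0) || any(t1 <= 0)) stop("tr and t1 must be > 0", call. = FALSE)
  acos(exp(-tr / t1)) * 180 / pi
}

#' Predicted S1/S2 ratio of two SPGR acquisitions
#'
#' Closed-form ratio of the steady-state signals of two scans whose compared
#' echoes share one echo time, so T2* decay and S0 cancel:
#' \deqn{\frac{S_1}{S_2} = \frac{\sin\alpha_1 (1 - e^{-TR_1/T_1})
#'   (1 - e^{-TR_2/T_1}\cos\alpha_2)}{\sin\alpha_2 (1 - e^{-TR_2/T_1})
#'   (1 - e^{-TR_1/T_1}\cos\alpha_1)}.}
#' A common transmit scale `b1_scale` multiplies both nominal flip angles
#' (one transmit chain drives both scans).
#'
#' @param t1 T1 in ms (vectorized)
#' @param p1,p2 [acquisition_protocol()] objects; their first echo times must
#'   be equal (else the ratio would not cancel T2*)
#' @param b1_scale relative transmit scale; scaled angles must stay in
#'   (0, 180) degrees
#' @return the dimensionless ratio S1/S2
#' @export
signal_ratio <- function(t1, p1, p2, b1_scale = 1) {
  if (any(t1 <= 0)) stop("`t1` must be > 0 ms", call. = FALSE)
  if (abs(p1$tes[1] - p2$tes[1]) > 1e-9)
    stop("compared echoes must share one TE (got ", p1$tes[1], " vs ", p2$tes[1],
         " ms): T2* would not cancel", call. = FALSE)
  if (any(b1_scale <= 0) || any(b1_scale * max(p1$fa, p2$fa) >= 180))
    stop("`b1_scale` must keep both effective angles in (0, 180) degrees", call. = FALSE)
  a1 <- deg2rad(b1_scale * p1$fa)
  a2 <- deg2rad(b1_scale * p2$fa)
  e1 <- exp(-p1$tr / t1)
  e2 <- exp(-p2$tr / t1)
  (sin(a1) * (1 - e1) * (1 - e2 * cos(a2))) /
    (sin(a2) * (1 - e2) * (1 - e1 * cos(a1)))
}

#' Read / write acquisition protocols
#'
#' Protocols are stored in a plain YAML file, one scan per block with keys
#' `tr`, `fa`, `tes`, `label`. The shipped default file encodes the two-scan
#' knee protocol the package targets: Measurement 1 (TE 0.03 ms, TR 4.92 ms,
#' FA 3 deg) and Measurement 2 (TEs 0.03/2.46/4.92 ms, TR 9.24 ms, FA 11 deg).
#'
#' @param path a YAML protocol file
#' @return a named list of [acquisition_protocol()] objects
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(b, nm) {
    acquisition_protocol(tr = b$tr, fa = b$fa, tes = unlist(b$tes),
                         label = if (is.null(b$label)) nm else b$label)
  })
}

#' @rdname read_protocols
#' @param protocols named list of `acquisition_protocol` objects
#' @export
write_protocols <- function(protocols, path) {
  yaml::write_yaml(purrr::map(protocols, function(p)
    list(label = p$label, tr = p$tr, fa = p$fa, tes = as.list(p$tes))), path)
  invisible(path)
}

#' @rdname read_protocols
#' @export
default_protocols <- function() {
  read_protocols(system.file("extdata", "default_protocols.yaml",
                             package = "utemap", mustWork = TRUE))
}
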