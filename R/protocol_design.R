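#' T2* sensitivity window of a dual-echo pair
#'
#' For the dual-echo estimator the observable decay between the two echoes is
#' `S3/S2 = exp(-(te3 - te2)/T2*)`. A pair discriminates a T2* well when the
#' later echo has decayed noticeably (by at least `decay_min`, default 25%)
#' yet still retains signal above the noise-sensitive floor (more than
#' `decay_floor`, default 5%, of S2). The corresponding window is
#' `t2star_low = (te3 - te2)/log(1/decay_floor)` to
#' `t2star_high = (te3 - te2)/log(1/(1 - decay_min))`; both bounds scale
#' linearly with the echo spacing.
#'
#' @param te2,te3 echo times in ms, `te3 > te2` (vectorized over `te3`)
#' @param decay_floor minimum retained fraction of S2 (default 0.05)
#' @param decay_min minimum decayed fraction (default 0.25); requires
#'   `0 < decay_floor < 1 - decay_min < 1`
#' @return a tibble with one row per `te3`: `te2`, `te3`, `t2star_low`,
#'   `t2star_high`, `decay_floor`, `decay_min`
#' @examples
#' te3_sensitivity_window(0.03, c(2.46, 4.92))
#' @export
te3_sensitivity_window <- function(te2, te3, decay_floor = 0.05,
                                   decay_min = 0.25) {
  if (!(decay_floor > 0 && decay_floor < 1 - decay_min && decay_min < 1 &&
        decay_min > 0))
    stop("need 0 < decay_floor < 1 - decay_min < 1", call. = FALSE)
  if (any(te3 <= te2)) stop("need te3 > te2", call. = FALSE)
  dte <- te3 - te2
  tibble::tibble(te2 = te2, te3 = te3,
                 t2star_low = dte / log(1 / decay_floor),
                 t2star_high = dte / log(1 / (1 - decay_min)),
                 decay_floor = decay_floor, decay_min = decay_min)
}

#' Low-flip-angle selection for the T1-weighting scan
#'
#' Evaluates candidate flip angles for the low-weighting scan (S1) against
#' the fixed higher-flip scan (S2) over a T1 grid, at the shared ultrashort
#' echo. Each candidate receives two inadmissibility flags:
#' * `too_weak` — the T1 weighting of S1 (its range over the grid) falls
#'   below the noise level, taken as `noise_level * max(S2)`: the ratio would
#'   carry no usable T1 information;
#' * `degenerate` — S1 is indistinguishable from S2 within noise
#'   (`|S1 - S2| < noise_level * S2`) across the whole grid: the ratio is 1
#'   within noise everywhere and carries no T1 information. (A single
#'   crossing of the two curves is not degenerate — the monotone ratio still
#'   discriminates there.)
#' Candidates failing both flags are `admissible`. Admissibility is reported,
#' not auto-selected.
#'
#' @param p1_template protocol supplying TR and TE of the candidate scan
#' @param p2 the fixed higher-flip protocol
#' @param fa1_candidates candidate angles, degrees, each in (0, `p2$fa`)
#' @param t1_grid T1 grid in ms
#' @param noise_level noise as a fraction of the S2 signal (default 0.02)
#' @return a tibble with one row per candidate: `fa1`, `weighting_range`,
#'   `too_weak`, `degenerate`, `admissible`, and a `curve` list-column of
#'   tibbles `(t1, s1, s2, ratio)`
#' @export
fa1_tradeoff <- function(p1_template, p2, fa1_candidates = 1:6,
                         t1_grid = 1:4000, noise_level = 0.02) {
  if (any(fa1_candidates <= 0) || any(fa1_candidates >= p2$fa))
    stop("candidates must lie in (0, fa2)", call. = FALSE)
  te <- p1_template$tes[1]
  if (abs(te - p2$tes[1]) > 1e-9)
    stop("template and p2 must share the compared echo time", call. = FALSE)
  s2 <- spgr_signal(list(t1 = t1_grid, t2star = Inf, s0 = 1),
                    tr = p2$tr, fa = p2$fa, te = 0)
  noise_ref <- noise_level * max(s2)
  purrr::map_dfr(fa1_candidates, function(fa1) {
    s1 <- spgr_signal(list(t1 = t1_grid, t2star = Inf, s0 = 1),
                      tr = p1_template$tr, fa = fa1, te = 0)
    wr <- max(s1) - min(s1)
    too_weak <- noise_level > 0 && wr < noise_ref
    degenerate <- noise_level > 0 && all(abs(s1 - s2) < noise_level * s2)
    if (noise_level == 0) {
      too_weak <- wr == 0
      degenerate <- all(s1 == s2)
    }
    tibble::tibble(fa1 = fa1, weighting_range = wr, too_weak = too_weak,
                   degenerate = degenerate,
                   admissible = !too_weak && !degenerate,
                   curve = list(tibble::tibble(t1 = t1_grid, s1 = s1, s2 = s2,
                                               ratio = s1 / s2)))
  })
}
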