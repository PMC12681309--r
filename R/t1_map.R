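#' Build a T1 lookup table
#'
#' Tabulates the predicted S1/S2 ratio ([signal_ratio()]) over a discrete T1
#' grid (default 1-4000 ms in 1 ms steps) for a given relative transmit scale.
#' The curve must be strictly monotone in T1 — the build refuses protocol
#' pairs for which it is not, because the inversion would be ambiguous. The
#' monotonicity direction is auto-detected and stored.
#'
#' @param p1,p2 [acquisition_protocol()] objects; compared echoes must share
#'   one TE
#' @param b1_scale relative transmit scale multiplying both flip angles
#' @param t1_grid T1 grid in ms, strictly ascending
#' @return an object of class `relaxometry_lut` with fields `t1_grid`,
#'   `ratios`, `b1_scale`, `p1`, `p2`, `increasing`
#' @export
build_lut <- function(p1, p2, b1_scale = 1, t1_grid = 1:4000) {
  t1_grid <- as.numeric(t1_grid)
  if (any(diff(t1_grid) <= 0)) stop("`t1_grid` must be strictly ascending", call. = FALSE)
  ratios <- signal_ratio(t1_grid, p1, p2, b1_scale = b1_scale)
  d <- diff(ratios)
  if (!(all(d > 0) || all(d < 0)))
    stop(sprintf(
      "S1/S2 ratio is not strictly monotone in T1 for protocols [%s] vs [%s] at b1_scale %.3g",
      p1$label, p2$label, b1_scale), call. = FALSE)
  structure(list(t1_grid = t1_grid, ratios = ratios, b1_scale = b1_scale,
                 p1 = p1, p2 = p2, increasing = d[1] > 0),
            class = "relaxometry_lut")
}

#' @export
print.relaxometry_lut <- function(x, ...) {
  cat(sprintf("<relaxometry_lut> %d entries, T1 %g-%g ms, b1_scale %.3g, ratio %s in T1\n",
              length(x$t1_grid), min(x$t1_grid), max(x$t1_grid), x$b1_scale,
              if (x$increasing) "increasing" else "decreasing"))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.relaxometry_lut <- function(x, ...) {
  tibble::tibble(t1 = x$t1_grid, ratio = x$ratios, b1_scale = x$b1_scale)
}

#' Invert measured ratios through a lookup table
#'
#' Maps each measured S1/S2 ratio to the grid T1 whose predicted ratio is
#' nearest (the discrete-LUT behavior; set `interpolate = TRUE` for linear
#' interpolation between grid points). Ties are broken toward the smaller T1.
#' Ratios beyond the table range clamp to the boundary T1 and are flagged in
#' the `"out_of_range"` attribute; non-finite ratios return `NA`.
#'
#' @param ratio numeric vector of measured S1/S2 ratios
#' @param lut a [build_lut()] table
#' @param interpolate linear interpolation instead of nearest entry
#' @return numeric vector of T1 (ms) with logical attribute `"out_of_range"`
#' @export
lut_invert <- function(ratio, lut, interpolate = FALSE) {
  stopifnot(inherits(lut, "relaxometry_lut"))
  r <- if (lut$increasing) lut$ratios else rev(lut$ratios)
  t1 <- if (lut$increasing) lut$t1_grid else rev(lut$t1_grid)
  n <- length(r)
  out <- rep(NA_real_, length(ratio))
  oor <- rep(FALSE, length(ratio))
  fin <- is.finite(ratio)
  lo <- fin & ratio <= r[1]
  hi <- fin & ratio >= r[n]
  out[lo] <- t1[1]; out[hi] <- t1[n]
  oor[fin & (ratio < r[1] | ratio > r[n])] <- TRUE
  mid <- fin & !lo & !hi
  if (any(mid)) {
    x <- ratio[mid]
    i <- findInterval(x, r)          # r[i] <= x < r[i+1]
    if (interpolate) {
      f <- (x - r[i]) / (r[i + 1] - r[i])
      out[mid] <- t1[i] + f * (t1[i + 1] - t1[i])
    } else {
      d_lo <- x - r[i]
      d_hi <- r[i + 1] - x
      # nearest entry; exact ties and smaller distance to the lower-ratio
      # entry both resolve toward the smaller T1 of the pair
      pick_hi <- d_hi < d_lo
      smaller_t1_is_hi <- t1[i + 1] < t1[i]   # decreasing tables
      tie <- d_hi == d_lo
      pick_hi[tie] <- smaller_t1_is_hi[tie]
      out[mid] <- ifelse(pick_hi, t1[i + 1], t1[i])
    }
  }
  attr(out, "out_of_range") <- oor
  out
}

#' Bank of lookup tables indexed by integer effective flip angle
#'
#' One table per integer effective second-scan flip angle (default 1-180
#' degrees, 1-degree steps). Both scans share one transmit chain, so a single
#' B1+ scale multiplies both nominal angles: the table for key `k` uses
#' `b1_scale = k / fa2_nominal`, scaling FA1 by the same factor rather than
#' rounding it independently. Keys whose ratio curve is not strictly
#' monotone are dropped with a warning (the bank reports its coverage).
#'
#' @param p1,p2 [acquisition_protocol()] objects
#' @param fa_keys integer effective FA2 values to cover, degrees
#' @param t1_grid T1 grid passed to [build_lut()]
#' @return an object of class `lut_bank`: list of tables keyed by
#'   `as.character(fa)` plus the nominal angles
#' @export
build_lut_bank <- function(p1, p2, fa_keys = 1:180, t1_grid = 1:4000) {
  fa_keys <- as.integer(fa_keys)
  stopifnot(all(fa_keys >= 1), all(fa_keys <= 180))
  tables <- list()
  dropped <- integer()
  for (k in fa_keys) {
    b1 <- k / p2$fa
    tab <- tryCatch(build_lut(p1, p2, b1_scale = b1, t1_grid = t1_grid),
                    error = function(e) NULL)
    if (is.null(tab)) dropped <- c(dropped, k) else tables[[as.character(k)]] <- tab
  }
  if (length(dropped))
    warning("dropped non-monotone LUT bank entries at effective FA2 = ",
            paste(dropped, collapse = ", "), " degrees")
  if (!length(tables)) stop("no valid LUT bank entries", call. = FALSE)
  structure(list(tables = tables, fa2_nominal = p2$fa, fa1_nominal = p1$fa,
                 p1 = p1, p2 = p2),
            class = "lut_bank")
}

#' @export
print.lut_bank <- function(x, ...) {
  keys <- as.integer(names(x$tables))
  cat(sprintf("<lut_bank> %d tables, effective FA2 %d-%d deg (nominal %g deg)\n",
              length(keys), min(keys), max(keys), x$fa2_nominal))
  invisible(x)
}

#' LUT-based T1 map with B1+ correction
#'
#' Per valid voxel the effective second-scan flip angle
#' `round(b1 * fa2_nominal)` selects the bank table and the measured S1/S2
#' ratio is inverted through it. Voxels with non-positive S2, invalid inputs,
#' or an effective angle outside the bank's coverage are invalid (the count
#' is reported with a message).
#'
#' @param s1 magnitude volume of the low-flip scan
#' @param s2 magnitude volume of the higher-flip scan at the same TE
#' @param b1 relative transmit-scale volume (1.0 = nominal), same grid
#' @param bank a [build_lut_bank()] object
#' @param interpolate see [lut_invert()]
#' @return a `voxel_volume` of T1 (ms) with attribute `"out_of_range"`
#' @export
map_t1 <- function(s1, s2, b1, bank, interpolate = FALSE) {
  stopifnot(inherits(bank, "lut_bank"))
  stop_if_grid_mismatch(s1, s2, "S1/S2 volumes")
  stop_if_grid_mismatch(s1, b1, "S1/B1 volumes")
  dims <- vol_dim(s1)
  valid <- s1$mask & s2$mask & b1$mask & s2$data > 0 & s1$data >= 0 & b1$data > 0
  key <- round(b1$data * bank$fa2_nominal)
  covered <- array(as.character(key) %in% names(bank$tables), dim = dims)
  n_uncovered <- sum(valid & !covered)
  if (n_uncovered > 0)
    message(n_uncovered, " voxel(s) outside LUT bank coverage marked invalid")
  valid <- valid & covered
  ratio <- s1$data / s2$data
  t1 <- array(NA_real_, dims)
  oor <- array(FALSE, dims)
  for (k in unique(key[valid])) {
    sel <- valid & key == k
    inv <- lut_invert(ratio[sel], bank$tables[[as.character(k)]],
                      interpolate = interpolate)
    t1[sel] <- inv
    oor[sel] <- attr(inv, "out_of_range")
  }
  out <- voxel_volume(t1, s1$spacing, mask = valid)
  attr(out, "out_of_range") <- oor
  out
}

#' Inversion-recovery series
#'
#' @param tis inversion times in ms, ascending, length >= 4 (the fit has
#'   three free parameters)
#' @param signals magnitudes per TI
#' @return an object of class `inversion_series`
#' @export
inversion_series <- function(tis, signals) {
  tis <- as.numeric(tis); signals <- as.numeric(signals)
  if (length(tis) < 4L) stop("need at least 4 inversion times", call. = FALSE)
  if (any(diff(tis) <= 0)) stop("`tis` must be strictly ascending", call. = FALSE)
  if (length(signals) != length(tis)) stop("lengths differ", call. = FALSE)
  structure(list(tis = tis, signals = signals), class = "inversion_series")
}

#' Three-parameter inversion-recovery T1 fit
#'
#' Nonlinear least squares of the magnitude recovery model
#' `|A - B * exp(-TI / T1)|` (magnitude images; polarity is not restored).
#' Levenberg-Marquardt is started from a log-spaced grid of T1 values
#' (default 16 starts over 10-8000 ms) and the converged fit with the lowest
#' residual sum of squares is kept. Degenerate series (no converged start,
#' vanishing recovery amplitude, or T1 pinned at the search bound) are
#' returned with `valid = FALSE` / `flagged = TRUE`.
#'
#' @param series an [inversion_series()]
#' @param n_starts number of multi-start T1 values
#' @param t1_range search range for starts and bounds, ms
#' @return an object of class `ir_fit`: list with `a`, `b`, `t1`, `residual`,
#'   `valid`, `flagged`
#' @export
ir_fit <- function(series, n_starts = 16, t1_range = c(10, 8000)) {
  stopifnot(inherits(series, "inversion_series"))
  df <- data.frame(ti = series$tis, s = series$signals)
  df <- df[is.finite(df$s), ]
  if (nrow(df) < 4L) stop("need at least 4 finite samples", call. = FALSE)
  a0 <- max(df$s)
  starts <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = n_starts))
  best <- NULL
  for (t1s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ abs(a - b * exp(-ti / t1)), data = df,
                        start = list(a = a0, b = 2 * a0, t1 = t1s),
                        lower = c(0, 0, t1_range[1] / 10),
                        upper = c(Inf, Inf, t1_range[2] * 10),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(a = NA_real_, b = NA_real_, t1 = NA_real_,
                          residual = NA_real_, valid = FALSE, flagged = TRUE),
                     class = "ir_fit"))
  cf <- stats::coef(best$fit)
  at_bound <- cf[["t1"]] <= t1_range[1] / 10 * (1 + 1e-6) ||
    cf[["t1"]] >= t1_range[2] * 10 * (1 - 1e-6)
  degenerate <- cf[["b"]] <= 1e-8 * max(a0, 1)
  structure(list(a = cf[["a"]], b = cf[["b"]], t1 = cf[["t1"]],
                 residual = sqrt(best$rss),
                 valid = !(at_bound || degenerate),
                 flagged = at_bound || degenerate),
            class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, ...) {
  cat(sprintf("<ir_fit> A = %.4g, B = %.4g, T1 = %.4g ms%s\n",
              x$a, x$b, x$t1, if (x$valid) "" else " [flagged]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ir_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "t1"), estimate = c(x$a, x$b, x$t1))
}

#' @exportS3Method generics::glance
glance.ir_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, t1 = x$t1, residual = x$residual,
                 valid = x$valid, flagged = x$flagged)
}
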