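#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_raster geom_rect labs scale_fill_viridis_c coord_fixed theme_minimal
NULL

#' Plot a lookup-table ratio curve
#'
#' @param object a [build_lut()] table
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.relaxometry_lut <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$t1, y = .data$ratio)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "T1 [ms]", y = "S1/S2 ratio",
         title = sprintf("LUT ratio curve (b1 scale %.2f)", object$b1_scale)) +
    theme_minimal()
}

#' Bland-Altman plot of an agreement report
#'
#' Differences (reference - test) against the reference value, with the mean
#' difference and the 1.96 SD limits of agreement.
#'
#' @param object an [bland_altman()] report
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  u <- if (object$percent) "difference [%]" else "difference"
  ggplot(object$pairs, aes(x = .data$reference, y = .data$difference)) +
    geom_hline(yintercept = object$mean_diff, color = "black") +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dotted") +
    geom_point(color = "#d95f02") +
    labs(x = "reference value", y = paste("reference - test", u)) +
    theme_minimal()
}

#' Plot one slice of a volume
#'
#' @param object a `voxel_volume`
#' @param slice z index (default middle slice)
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.voxel_volume <- function(object, slice = NULL, ...) {
  d <- vol_dim(object)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- vol_data(object)[, , slice]
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(sl))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90") +
    coord_fixed(ratio = object$spacing[2] / object$spacing[1]) +
    labs(title = sprintf("slice %d/%d", slice, d[3])) +
    theme_minimal()
}

#' Plot T2* sensitivity windows over echo-ratio curves
#'
#' Shows `S3/S2 = exp(-(te3 - te2)/T2*)` against T2* for each echo pair, with
#' the admissible window shaded.
#'
#' @param windows a [te3_sensitivity_window()] tibble
#' @param t2star_range T2* range plotted, ms
#' @return a ggplot
#' @export
plot_sensitivity_windows <- function(windows, t2star_range = c(0.2, 40)) {
  t2 <- exp(seq(log(t2star_range[1]), log(t2star_range[2]), length.out = 300))
  curves <- purrr::pmap_dfr(windows, function(te2, te3, ...) {
    tibble::tibble(pair = sprintf("TE %.2f/%.2f ms", te2, te3),
                   t2star = t2, ratio = exp(-(te3 - te2) / t2))
  })
  bands <- dplyr::mutate(windows, pair = sprintf("TE %.2f/%.2f ms", te2, te3))
  ggplot(curves, aes(x = .data$t2star, y = .data$ratio, color = .data$pair)) +
    geom_rect(data = bands,
              aes(xmin = .data$t2star_low, xmax = .data$t2star_high,
                  fill = .data$pair),
              ymin = -Inf, ymax = Inf, alpha = 0.12, inherit.aes = FALSE) +
    geom_line() +
    ggplot2::scale_x_log10() +
    labs(x = "T2* [ms]", y = "S3/S2", color = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot low-flip-angle ratio curves
#'
#' S1/S2 against T1 for each candidate angle, admissible candidates in solid
#' lines.
#'
#' @param tradeoff a [fa1_tradeoff()] tibble
#' @return a ggplot
#' @export
plot_fa1_tradeoff <- function(tradeoff) {
  df <- tradeoff |>
    dplyr::mutate(fa = factor(.data$fa1)) |>
    tidyr_unnest_curve()
  ggplot(df, aes(x = .data$t1, y = .data$ratio, color = .data$fa,
                 linetype = .data$admissible)) +
    geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed")) +
    labs(x = "T1 [ms]", y = "S1/S2", color = "FA1 [deg]") +
    theme_minimal()
}

# minimal unnest of the curve list-column (avoids a tidyr dependency)
tidyr_unnest_curve <- function(df) {
  purrr::pmap_dfr(list(df$fa, df$admissible, df$curve),
                  function(fa, admissible, curve)
                    dplyr::mutate(curve, fa = fa, admissible = admissible))
}
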