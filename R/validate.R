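#' Cylindrical tube VOIs from a truth set
#'
#' Builds per-tube volumes of interest: the voxelized tube cross-section is
#' eroded in-plane by `margin_voxels` (disc-shaped structuring element,
#' keeping the VOI away from the tube wall), the `margin_voxels` outermost
#' slices at each end are dropped, and the remaining interior slices are
#' split into `segments` axial segments (two per tube by default, giving two
#' VOIs per tube as the unit of agreement analysis). Tubes emptied by the
#' erosion are skipped with a warning and listed in the `"skipped"`
#' attribute.
#'
#' @param truth a [render_truth()] volume set (uses its `label` member)
#' @param margin_voxels in-plane erosion margin, voxels, >= 0 (default 3)
#' @param segments axial segments per tube (default 2)
#' @param min_voxels VOIs below this size are flagged non-reportable (the
#'   floor used for in-vivo style reporting is 100; phantom default 1)
#' @return a tibble with columns `tube` (label index), `label`, `segment`,
#'   `n_voxels`, `reportable`, and a list-column `voxels` of linear voxel
#'   indices
#' @export
tube_vois <- function(truth, margin_voxels = 3, segments = 2, min_voxels = 1) {
  stopifnot(margin_voxels >= 0, segments >= 1)
  lab <- truth$label$data
  d <- dim(lab)
  nz <- d[3]
  z_keep <- seq_len(nz)
  if (margin_voxels > 0 && nz > 2 * margin_voxels)
    z_keep <- (margin_voxels + 1):(nz - margin_voxels)
  seg_of <- ceiling(seq_along(z_keep) / (length(z_keep) / segments))
  out <- list()
  skipped <- character()
  for (k in sort(unique(lab[lab > 0]))) {
    m2 <- lab[, , z_keep[1]] == k
    if (margin_voxels > 0) {
      brush <- EBImage::makeBrush(2 * margin_voxels + 1, shape = "disc")
      m2 <- EBImage::erode(matrix(as.numeric(m2), d[1], d[2]), brush) > 0.5
    }
    if (!any(m2)) {
      skipped <- c(skipped, as.character(k))
      warning("erosion emptied tube ", k, "; skipped")
      next
    }
    idx2 <- which(m2)
    for (s in seq_len(segments)) {
      zs <- z_keep[seg_of == s]
      vox <- as.vector(outer(idx2, (zs - 1) * d[1] * d[2], `+`))
      out[[length(out) + 1]] <- tibble::tibble(
        tube = k, segment = s,
        label = sprintf("tube%02d_seg%d", k, s),
        n_voxels = length(vox), reportable = length(vox) >= min_voxels,
        voxels = list(vox))
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "skipped") <- skipped
  res
}

#' VOI statistics over a parameter map
#'
#' Mean, SD, coefficient of variation and valid-voxel count over each VOI,
#' computed on valid voxels only.
#'
#' @param map a `voxel_volume` parameter map
#' @param vois a [tube_vois()] tibble (or any tibble with `label` and a
#'   `voxels` list-column of linear indices)
#' @return a tibble with one row per VOI: `label`, `tube`, `segment`, `mean`,
#'   `sd`, `cv`, `n_valid`
#' @export
voi_stats <- function(map, vois) {
  vals <- vol_data(map)
  purrr::pmap_dfr(list(vois$label, vois$voxels,
                       vois$tube %||% NA, vois$segment %||% NA),
    function(label, vox, tube, segment) {
      v <- vals[vox]
      v <- v[!is.na(v)]
      if (!length(v))
        stop("VOI '", label, "' contains no valid voxels", call. = FALSE)
      m <- mean(v)
      s <- if (length(v) > 1) stats::sd(v) else 0
      tibble::tibble(label = label, tube = tube, segment = segment,
                     mean = m, sd = s, cv = if (m != 0) s / m else NA_real_,
                     n_valid = length(v))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bland-Altman agreement analysis
#'
#' Differences are computed as `reference - test` (the direction used when a
#' reference method is compared against a mapping method), as percentages of
#' the reference by default (`100 * (reference - test) / reference`).
#' Limits of agreement are exactly `mean(diff) +/- 1.96 * sd(diff)`. Pairs
#' with a zero reference are excluded with a warning in percent mode.
#'
#' @param pairs a data frame whose first two columns are the reference and
#'   test values (columns named `reference` / `test` are used when present)
#' @param percent report percent differences (default TRUE)
#' @return an object of class `agreement_report`: list with `pairs` (tibble
#'   with a `difference` column), `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `percent`
#' @examples
#' bland_altman(data.frame(reference = c(10, 10), test = c(9, 11)),
#'              percent = FALSE)
#' @export
bland_altman <- function(pairs, percent = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  if (all(c("reference", "test") %in% names(pairs))) {
    pairs <- dplyr::select(pairs, dplyr::all_of(c("reference", "test")),
                           dplyr::everything())
  } else {
    names(pairs)[1:2] <- c("reference", "test")
  }
  if (nrow(pairs) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (percent && any(pairs$reference == 0)) {
    warning(sum(pairs$reference == 0), " pair(s) with zero reference excluded")
    pairs <- dplyr::filter(pairs, .data$reference != 0)
    if (nrow(pairs) < 2) stop("fewer than 2 usable pairs remain", call. = FALSE)
  }
  d <- pairs$reference - pairs$test
  if (percent) d <- 100 * d / pairs$reference
  pairs$difference <- d
  m <- mean(d); s <- stats::sd(d)
  structure(list(pairs = pairs, mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 percent = percent),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("<agreement_report> n = %d pairs\n  mean difference %.3g%s +/- %.3g%s (SD)\n  limits of agreement [%.3g, %.3g]%s\n",
              nrow(x$pairs), x$mean_diff, u, x$sd_diff, u,
              x$loa_low, x$loa_high, u))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 n = nrow(x$pairs), percent = x$percent)
}

#' Per-tube agreement table between a map and reference values
#'
#' Convenience wrapper: VOI statistics of `map` paired with per-tube
#' reference values, fed to [bland_altman()].
#'
#' @param map a parameter map volume
#' @param vois a [tube_vois()] tibble
#' @param reference named or ordered numeric vector of reference values per
#'   tube index
#' @param percent see [bland_altman()]
#' @return an `agreement_report`; its `pairs` tibble carries the VOI labels
#' @export
map_agreement <- function(map, vois, reference, percent = TRUE) {
  st <- voi_stats(map, vois)
  ref <- reference[st$tube]
  bland_altman(tibble::tibble(reference = as.numeric(ref), test = st$mean,
                              label = st$label),
               percent = percent)
}
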