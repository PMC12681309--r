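# World coordinate of voxel centers along one axis, center-aligned frames:
# two volumes of the same physical field of view share the coordinate origin
# at the volume center. Returns mm offsets from the center.
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Resample a volume onto a target grid
#'
#' Trilinear interpolation of a (typically low-resolution B1+) volume onto
#' the grid of `target`. Both volumes are assumed aligned in a shared,
#' center-aligned frame (same physical field-of-view center) — independent
#' coregistration is out of scope. Target voxels falling outside the source
#' extent take the nearest inside value. Along a degenerate (single-sample)
#' source axis nearest-neighbor is used with a warning. Invalid source voxels
#' propagate: any interpolation touching one yields an invalid target voxel.
#'
#' @param lowres source `voxel_volume`
#' @param target `voxel_volume` defining the output grid
#' @return a `voxel_volume` on `target`'s grid
#' @export
resample_to_grid <- function(lowres, target) {
  src <- vol_data(lowres)
  ds <- dim(src); dt <- vol_dim(target)
  # fractional source indices of each target voxel center, per axis
  fidx <- vector("list", 3)
  for (ax in 1:3) {
    if (ds[ax] == 1L) {
      warning("degenerate source axis ", ax, ": nearest-neighbor fallback")
      fidx[[ax]] <- rep(1, dt[ax])
    } else {
      w <- axis_coords(dt[ax], target$spacing[ax])
      f <- w / lowres$spacing[ax] + (ds[ax] + 1) / 2
      fidx[[ax]] <- pmin(pmax(f, 1), ds[ax])  # clamp: nearest inside value
    }
  }
  i0 <- lapply(1:3, function(ax) pmin(floor(fidx[[ax]]), ds[ax] - (ds[ax] > 1)))
  fr <- lapply(1:3, function(ax) fidx[[ax]] - i0[[ax]])
  gx <- rep(seq_len(dt[1]), times = dt[2] * dt[3])
  gy <- rep(rep(seq_len(dt[2]), each = dt[1]), times = dt[3])
  gz <- rep(seq_len(dt[3]), each = dt[1] * dt[2])
  out <- numeric(prod(dt))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- pmin(i0[[1]] + cx, ds[1])[gx]
    iy <- pmin(i0[[2]] + cy, ds[2])[gy]
    iz <- pmin(i0[[3]] + cz, ds[3])[gz]
    wgt <- (if (cx) fr[[1]][gx] else 1 - fr[[1]][gx]) *
           (if (cy) fr[[2]][gy] else 1 - fr[[2]][gy]) *
           (if (cz) fr[[3]][gz] else 1 - fr[[3]][gz])
    out <- out + wgt * src[cbind(ix, iy, iz)]
  }
  voxel_volume(array(out, dt), target$spacing)
}

# exponent table of the 3D monomial basis with total degree <= degree
monomial_exponents <- function(degree) {
  ex <- expand.grid(i = 0:degree, j = 0:degree, k = 0:degree)
  ex <- ex[rowSums(ex) <= degree, , drop = FALSE]
  ex[order(rowSums(ex), ex$i, ex$j, ex$k), , drop = FALSE]
}

monomial_design <- function(x, y, z, exponents) {
  n <- length(x)
  m <- matrix(1, n, nrow(exponents))
  for (c in seq_len(nrow(exponents)))
    m[, c] <- x^exponents$i[c] * y^exponents$j[c] * z^exponents$k[c]
  m
}

#' Fit a smooth polynomial field to a volume
#'
#' Least-squares fit of a 3D polynomial (total degree <= `degree`, monomial
#' basis on coordinates normalized to roughly \[-1, 1\] for conditioning) to
#' the valid voxels of `vol`. Used to smooth low-SNR B1+ maps before flip
#' angle correction. When the valid-voxel count is below the coefficient
#' count (or the design is rank deficient) the degree is reduced with a
#' warning. Evaluating the fitted field is a projection: fitting the
#' evaluated field again returns the same coefficients.
#'
#' @param vol a `voxel_volume`
#' @param degree polynomial total degree (default 3)
#' @return an object of class `polynomial_field` with fields `degree`,
#'   `coefficients`, `exponents`, `scale_mm` (per-axis normalization
#'   half-extents)
#' @export
fit_smooth_field <- function(vol, degree = 3) {
  stopifnot(degree >= 0)
  dims <- vol_dim(vol)
  half <- pmax((dims - 1) / 2 * vol$spacing, vol$spacing / 2)
  idx <- which(vol$mask)
  if (!length(idx)) stop("no valid voxels to fit", call. = FALSE)
  sub <- arrayInd(idx, dims)
  x <- axis_coords(dims[1], vol$spacing[1])[sub[, 1]] / half[1]
  y <- axis_coords(dims[2], vol$spacing[2])[sub[, 2]] / half[2]
  z <- axis_coords(dims[3], vol$spacing[3])[sub[, 3]] / half[3]
  v <- vol$data[idx]
  deg <- degree
  repeat {
    ex <- monomial_exponents(deg)
    if (nrow(ex) <= length(idx)) {
      dm <- monomial_design(x, y, z, ex)
      qrd <- qr(dm)
      if (qrd$rank == ncol(dm)) {
        coef <- qr.coef(qrd, v)
        break
      }
    }
    if (deg == 0) stop("cannot fit even a constant field", call. = FALSE)
    deg <- deg - 1
    warning("rank-deficient or under-determined design; degree reduced to ", deg)
  }
  structure(list(degree = deg, coefficients = as.numeric(coef), exponents = ex,
                 scale_mm = half),
            class = "polynomial_field")
}

#' @export
print.polynomial_field <- function(x, ...) {
  cat(sprintf("<polynomial_field> degree %d, %d coefficients\n",
              x$degree, length(x$coefficients)))
  invisible(x)
}

#' Evaluate a polynomial field on a grid
#'
#' @param field a [fit_smooth_field()] result (or [polynomial_field()] spec)
#' @param target a `voxel_volume` defining the grid (all voxels evaluated)
#' @return a `voxel_volume` of field values
#' @export
evaluate_field <- function(field, target) {
  dims <- vol_dim(target)
  half <- if (!is.null(field$scale_mm)) field$scale_mm
          else pmax((dims - 1) / 2 * target$spacing, target$spacing / 2)
  x <- axis_coords(dims[1], target$spacing[1]) / half[1]
  y <- axis_coords(dims[2], target$spacing[2]) / half[2]
  z <- axis_coords(dims[3], target$spacing[3]) / half[3]
  gx <- rep(x, times = dims[2] * dims[3])
  gy <- rep(rep(y, each = dims[1]), times = dims[3])
  gz <- rep(z, each = dims[1] * dims[2])
  vals <- monomial_design(gx, gy, gz, field$exponents) %*% field$coefficients
  voxel_volume(array(as.numeric(vals), dims), target$spacing)
}

#' Construct a polynomial field from explicit coefficients
#'
#' Convenience constructor for simulation (e.g. a smooth B1+ inhomogeneity
#' field). Coefficients are ordered as in [fit_smooth_field()]: ascending
#' total degree, then lexicographic in the (x, y, z) exponents; their count
#' must equal `choose(degree + 3, 3)`.
#'
#' @param degree total degree
#' @param coefficients numeric vector of length `choose(degree + 3, 3)`
#' @param scale_mm optional per-axis normalization half-extents (mm); when
#'   `NULL` the evaluation grid's own half-extents are used
#' @return a `polynomial_field`
#' @export
polynomial_field <- function(degree, coefficients, scale_mm = NULL) {
  ex <- monomial_exponents(degree)
  if (length(coefficients) != nrow(ex))
    stop("need ", nrow(ex), " coefficients for degree ", degree, call. = FALSE)
  structure(list(degree = degree, coefficients = as.numeric(coefficients),
                 exponents = ex, scale_mm = scale_mm),
            class = "polynomial_field")
}

#' Polynomially smooth a volume
#'
#' [fit_smooth_field()] followed by [evaluate_field()] on the same grid,
#' restricted to the input's validity mask.
#'
#' @inheritParams fit_smooth_field
#' @return a smoothed `voxel_volume`
#' @export
smooth_field <- function(vol, degree = 3) {
  sm <- evaluate_field(fit_smooth_field(vol, degree = degree), vol)
  apply_mask(sm, vol$mask)
}

# shift a 3D array by integer offsets, padding with NA
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    src[[ax]] <- if (o >= 0) seq_len(d[ax] - o) else seq(1 - o, d[ax])
    dst[[ax]] <- if (o >= 0) seq(1 + o, d[ax]) else seq_len(d[ax] + o)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# separable box mean over (2r+1) windows ignoring NA
box_mean3 <- function(a, r = c(1, 1, 1)) {
  vals <- a
  vals[is.na(vals)] <- 0
  cnt <- array(as.numeric(!is.na(a)), dim(a))
  run1 <- function(m, ax, rr) {
    if (rr == 0) return(m)
    out <- array(0, dim(m))
    for (o in -rr:rr) {
      off <- c(0, 0, 0); off[ax] <- o
      s <- shift_array(m, off)
      s[is.na(s)] <- 0
      out <- out + s
    }
    out
  }
  for (ax in 1:3) {
    vals <- run1(vals, ax, r[ax])
    cnt <- run1(cnt, ax, r[ax])
  }
  out <- vals / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Estimate the magnitude noise level of a volume
#'
#' If the volume has invalid (background-masked) voxels their magnitudes are
#' treated as Rayleigh-distributed pure noise and the Gaussian channel SD is
#' `mean(background) / sqrt(pi/2)`. Otherwise a high-frequency fallback is
#' used: the median absolute first difference along x divided by
#' `sqrt(2) * qnorm(3/4)`.
#'
#' @param vol a `voxel_volume`
#' @return estimated channel noise SD
#' @export
estimate_noise_sd <- function(vol) {
  bg <- vol$data[!vol$mask & is.finite(vol$data)]
  if (length(bg) >= 50 && mean(bg) > 0) return(mean(bg) / sqrt(pi / 2))
  dx <- diff(vol$data[vol$mask])
  stats::median(abs(dx)) / (sqrt(2) * stats::qnorm(0.75))
}

#' Nonlocal means denoising
#'
#' Simplified patchwise nonlocal means: each valid voxel is replaced by a
#' weighted mean of the voxels inside a search window, with weights
#' `exp(-max(d2 - 2*sigma^2, 0) / h^2)` where `d2` is the mean squared patch
#' difference, `sigma` the noise level estimated with [estimate_noise_sd()]
#' (from the background when available), and `h = strength * sigma` the
#' filter bandwidth. `strength = 0` returns the input unchanged. Invalid
#' voxels stay invalid and do not contribute.
#'
#' @param vol a `voxel_volume` of magnitudes
#' @param strength bandwidth multiplier, >= 0 (0 = identity; ~1 is a typical
#'   setting)
#' @param patch_radius half-size of the comparison patch per axis
#' @param search_radius half-size of the search window per axis
#' @return a denoised `voxel_volume`
#' @export
denoise <- function(vol, strength = 1, patch_radius = c(1, 1, 1),
                    search_radius = c(2, 2, 1)) {
  if (length(strength) != 1L || strength < 0) stop("`strength` must be >= 0", call. = FALSE)
  if (strength == 0) return(vol)
  patch_radius <- rep(patch_radius, length.out = 3)
  search_radius <- rep(search_radius, length.out = 3)
  sigma <- estimate_noise_sd(vol)
  if (!is.finite(sigma) || sigma <= 0) return(vol)
  h2 <- (strength * sigma)^2
  a <- vol_data(vol)
  num <- a
  num[is.na(num)] <- 0
  den <- array(as.numeric(vol$mask), dim(a))  # self weight 1
  num <- num * den
  offs <- expand.grid(x = -search_radius[1]:search_radius[1],
                      y = -search_radius[2]:search_radius[2],
                      z = -search_radius[3]:search_radius[3])
  offs <- offs[!(offs$x == 0 & offs$y == 0 & offs$z == 0), ]
  for (i in seq_len(nrow(offs))) {
    off <- c(offs$x[i], offs$y[i], offs$z[i])
    sh <- shift_array(a, off)
    d2 <- box_mean3((a - sh)^2, patch_radius)
    w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h2)
    w[is.na(w) | is.na(sh)] <- 0
    shz <- sh; shz[is.na(shz)] <- 0
    num <- num + w * shz
    den <- den + w
  }
  out <- num / pmax(den, .Machine$double.eps)
  out[!vol$mask] <- NA_real_
  voxel_volume(out, vol$spacing, mask = vol$mask)
}

#' Subtraction image
#'
#' Voxelwise `S2 - S3`, highlighting fast-relaxing structures (short-T2*
#' tissue loses more signal between the ultrashort and the moderate echo).
#' Negative values are retained; a voxel invalid in either input is invalid.
#'
#' @param s2,s3 magnitude volumes on one grid
#' @return a `voxel_volume`
#' @export
subtraction_image <- function(s2, s3) {
  stop_if_grid_mismatch(s2, s3, "subtraction inputs")
  voxel_volume(s2$data - s3$data, s2$spacing, mask = s2$mask & s3$mask)
}

#' Rigid-shift alignment check
#'
#' Coarse guard against misaligned inputs (full affine coregistration is out
#' of scope): searches integer voxel shifts up to `max_shift` for the maximum
#' normalized cross-correlation and warns when the peak is off-center.
#'
#' @param a,b volumes on one grid
#' @param max_shift maximum |shift| per axis, voxels
#' @return the best integer shift (length 3), invisibly
#' @export
check_alignment <- function(a, b, max_shift = 2) {
  stop_if_grid_mismatch(a, b, "alignment inputs")
  av <- vol_data(a); bv <- vol_data(b)
  best <- c(0, 0, 0); best_cc <- -Inf
  for (dz in -max_shift:max_shift) for (dy in -max_shift:max_shift)
    for (dx in -max_shift:max_shift) {
      sb <- shift_array(bv, c(dx, dy, dz))
      ok <- !is.na(av) & !is.na(sb)
      if (sum(ok) < 10) next
      cc <- suppressWarnings(stats::cor(av[ok], sb[ok]))
      if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- c(dx, dy, dz) }
    }
  if (any(abs(best) > 0))
    warning("cross-correlation peak at shift (", paste(best, collapse = ", "),
            ") voxels: inputs appear misaligned by more than 0.5 voxel")
  invisible(best)
}
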