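#' Construct a voxel volume
#'
#' A `voxel_volume` is the package's core image container: a 3D scalar grid
#' with per-axis voxel spacing (mm) and an optional per-voxel validity mask.
#' Volumes hold magnitude signals (arbitrary units) or parameter maps
#' (T1 / T2* in ms, flip-angle scale factors, ...). Invalid voxels carry `NA`
#' in `data` when extracted with [vol_data()] and are excluded from every
#' statistic computed by the package. On disk (NIfTI) the invalid sentinel
#' is `NaN`.
#'
#' @param data numeric 3D array (a matrix is promoted to a single-slice
#'   volume). Non-finite entries are marked invalid in the mask.
#' @param spacing numeric length-3, voxel size per axis in mm; strictly
#'   positive.
#' @param mask logical array of the same dimension, `TRUE` = valid, or `NULL`
#'   (all finite voxels valid).
#' @return an object of class `voxel_volume` with fields `data`, `spacing`,
#'   `mask`.
#' @examples
#' v <- voxel_volume(array(1, dim = c(4, 4, 2)), spacing = c(0.8, 0.8, 0.8))
#' vol_dim(v)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), mask = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimension(s)",
         call. = FALSE)
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  if (is.null(mask)) {
    mask <- is.finite(data)
  } else {
    if (!identical(dim(mask), dim(data)))
      stop("mask dimensions must match data", call. = FALSE)
    mask <- mask & is.finite(data)
  }
  dim(mask) <- dim(data)
  structure(list(data = data, spacing = spacing, mask = mask),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %s mm, %d/%d valid voxels\n",
              d[1], d[2], d[3], paste(format(x$spacing, digits = 3), collapse = " x "),
              sum(x$mask), length(x$mask)))
  v <- vol_values(x)
  if (length(v))
    cat(sprintf("  range of valid values: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' @rdname voxel_volume
#' @param x a `voxel_volume`
#' @export
vol_dim <- function(x) dim(x$data)

#' Extract volume data with invalid voxels as NA
#' @param x a `voxel_volume`
#' @return a numeric 3D array with `NA` at invalid voxels
#' @export
vol_data <- function(x) {
  out <- x$data
  out[!x$mask] <- NA_real_
  out
}

#' Valid voxel values of a volume
#' @param x a `voxel_volume`
#' @return numeric vector of values at valid voxels
#' @export
vol_values <- function(x) x$data[x$mask]

#' Restrict a volume to a mask
#'
#' Combines the volume's own validity mask with `mask` (logical AND).
#'
#' @param x a `voxel_volume`
#' @param mask a logical array or a logical-valued `voxel_volume` (as returned
#'   by [background_mask()]) on the same grid
#' @return a `voxel_volume`
#' @export
apply_mask <- function(x, mask) {
  m <- if (inherits(mask, "voxel_volume")) x_mask_array(mask) else mask
  if (!identical(dim(m), dim(x$data)))
    stop("mask dimensions must match the volume grid", call. = FALSE)
  voxel_volume(x$data, x$spacing, mask = x$mask & m)
}

# logical array from a volume holding a boolean mask
x_mask_array <- function(x) {
  m <- x$data > 0.5 & x$mask
  dim(m) <- dim(x$data)
  m
}

#' Do two volumes share a grid?
#' @param a,b `voxel_volume` objects
#' @param tol relative tolerance on spacing
#' @return logical
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(a$spacing, b$spacing))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " must share one grid (dimensions and spacing)", call. = FALSE)
  invisible(TRUE)
}

#' Named set of volumes on one grid
#'
#' Plumbing container for the images of one analysis (e.g. `S1`, the echoes of
#' the dual-echo scan, `B1`, truth maps). All members must share dimensions
#' and spacing.
#'
#' @param ... named `voxel_volume` objects, or a single named list of them
#' @return an object of class `volume_set` (a named list)
#' @export
volume_set <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && !inherits(vols[[1]], "voxel_volume")) vols <- vols[[1]]
  if (!length(vols)) stop("empty volume set", call. = FALSE)
  if (is.null(names(vols)) || any(names(vols) == ""))
    stop("all members must be named", call. = FALSE)
  ok <- vapply(vols, inherits, logical(1), "voxel_volume")
  if (!all(ok)) stop("all members must be voxel_volume objects", call. = FALSE)
  ref <- vols[[1]]
  for (nm in names(vols)) stop_if_grid_mismatch(ref, vols[[nm]],
                                                paste0("volume_set member '", nm, "'"))
  structure(vols, class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- vol_dim(x[[1]])
  cat(sprintf("<volume_set> %d volume(s) on a %d x %d x %d grid: %s\n",
              length(x), d[1], d[2], d[3], paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Reads a single-image NIfTI file (`.nii` / `.nii.gz`). A 4D file whose last
#' dimension is 1 is squeezed to 3D. Non-finite voxels (the on-disk invalid
#' sentinel is `NaN`) are marked invalid in the mask. World orientation
#' metadata is not interpreted: all volumes of one analysis are assumed to
#' share a grid.
#'
#' @param path path to a NIfTI file
#' @return a [voxel_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img_arr <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img_arr <- array(as.numeric(img), dim = d)
  } else {
    stop(sprintf("expected a 3D image, got %d dimensions (%s) in %s",
                 length(d), paste(d, collapse = "x"), path), call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
  voxel_volume(img_arr, spacing = abs(spacing))
}

#' Write a volume as NIfTI
#'
#' Invalid voxels are written as `NaN`; data is stored as float32, so a read
#' round trip preserves values to single precision and dimensions exactly.
#'
#' @param vol a `voxel_volume`
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  arr <- vol_data(vol)
  arr[is.na(arr)] <- NaN
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Background mask from a relative signal threshold
#'
#' Marks voxels whose signal falls below `rel_threshold` times the robust
#' maximum (99th percentile of valid voxels) as background. The robust
#' maximum, rather than the absolute maximum, resists isolated hot voxels.
#' The operation is idempotent: masking an already background-masked volume
#' leaves the mask unchanged.
#'
#' @param vol a `voxel_volume` of magnitudes
#' @param rel_threshold fraction of the robust maximum, in (0, 1)
#' @return a `voxel_volume` holding the boolean mask (1 = foreground); pass it
#'   to [apply_mask()]
#' @export
background_mask <- function(vol, rel_threshold = 0.1) {
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1L ||
      rel_threshold <= 0 || rel_threshold >= 1)
    stop("`rel_threshold` must be a single value in (0, 1)", call. = FALSE)
  vals <- vol_values(vol)
  robust_max <- if (length(vals)) stats::quantile(vals, 0.99, names = FALSE) else 0
  if (robust_max <= 0) {
    warning("volume has no positive signal; background mask is empty")
    keep <- array(FALSE, dim = vol_dim(vol))
  } else {
    keep <- vol$mask & vol$data >= rel_threshold * robust_max
    dim(keep) <- vol_dim(vol)
  }
  voxel_volume(array(as.numeric(keep), dim = vol_dim(vol)), vol$spacing)
}
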