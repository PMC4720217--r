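#' Grayscale micro-CT volume
#'
#' A 3-D scalar intensity grid with an isotropic voxel size. The axis
#' convention throughout the package is `(slice, row, col)` = `(z, y, x)`:
#' the first array dimension indexes axial slices.
#'
#' @param data 3-D numeric array `(slice, row, col)`; all intensities finite.
#' @param voxel_size_um Positive isotropic voxel edge length in micrometres.
#' @param source Provenance string (file path, generator call, ...).
#' @return An object of class `gray_volume`: a list with elements `data`,
#'   `voxel_size_um` and `source`.
#' @examples
#' g <- gray_volume(array(runif(8 * 8 * 8), c(8, 8, 8)), voxel_size_um = 4.3)
#' dim(g$data)
#' @export
gray_volume <- function(data, voxel_size_um, source = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (slice, row, col)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite (no NA/NaN/Inf)")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 source = as.character(source)),
            class = "gray_volume")
}

#' Binary bone-occupancy volume
#'
#' The sampled bone volume after thresholding: a 3-D logical occupancy grid
#' plus the isotropic voxel size.
#'
#' @param mask 3-D logical array `(slice, row, col)`; `TRUE` = bone.
#' @param voxel_size_um Positive isotropic voxel edge length in micrometres.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(mask, voxel_size_um) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array (slice, row, col)")
  if (any(dim(mask) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.logical(mask)) {
    if (!is.numeric(mask)) stop("`mask` must be logical (or 0/1 numeric)")
    mask <- array(mask != 0, dim(mask))
  }
  if (anyNA(mask)) stop("`mask` must not contain NA")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(list(mask = mask, voxel_size_um = as.numeric(voxel_size_um)),
            class = "voxel_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d (slice, row, col), voxel %.4g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (nzchar(x$source)) cat("  source:", x$source)
  cat("\n")
  invisible(x)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<voxel_volume> %d x %d x %d (slice, row, col), voxel %.4g um, %d foreground voxels\n",
              d[1], d[2], d[3], x$voxel_size_um, sum(x$mask)))
  invisible(x)
}

stopifnot_voxel_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "voxel_volume"))
    stop(sprintf("`%s` must be a voxel_volume", arg))
  invisible(x)
}

stopifnot_gray_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "gray_volume"))
    stop(sprintf("`%s` must be a gray_volume", arg))
  invisible(x)
}
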