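#' Binarise a grayscale volume
#'
#' Applies the user-supplied binary threshold that separates bone from
#' background. Under the default bone-is-brighter polarity a voxel is bone
#' when its intensity is `>= value`. The threshold is a user choice (typical
#' micro-CT practice); no automatic threshold selection is performed.
#'
#' @param gray A [gray_volume()].
#' @param value Threshold in the volume's intensity units. A value outside
#'   the volume's intensity range yields an all-true or all-false mask with a
#'   warning.
#' @param bone_brighter If `FALSE`, the polarity is inverted (bone darker
#'   than background).
#' @return A [voxel_volume()] on the same grid.
#' @export
threshold_volume <- function(gray, value, bone_brighter = TRUE) {
  stopifnot_gray_volume(gray)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("`value` must be a single finite number")
  rng <- range(gray$data)
  if (value < rng[1] || value > rng[2])
    warning(sprintf("threshold %.4g outside the intensity range [%.4g, %.4g]",
                    value, rng[1], rng[2]))
  mask <- if (bone_brighter) gray$data >= value else gray$data <= value
  voxel_volume(array(mask, dim(gray$data)), gray$voxel_size_um)
}

#' Keep one connected component of a binary volume
#'
#' Isolates the bone of interest: disconnected fragments (e.g. a floating
#' patella) are removed. Foreground connectivity is 26 (face, edge and corner
#' neighbours). With no seed the largest component by voxel count is kept; a
#' seed `(slice, row, col)` selects the component containing that voxel.
#'
#' @param vol A [voxel_volume()].
#' @param seed Optional integer vector `(slice, row, col)`, 1-based, on a
#'   foreground voxel.
#' @return A [voxel_volume()] containing a single 26-connected component.
#' @export
select_component <- function(vol, seed = NULL) {
  stopifnot_voxel_volume(vol)
  if (!any(vol$mask)) stop("empty foreground: nothing to select")
  lab <- label_volume(vol$mask, connectivity = 26L)
  if (is.null(seed)) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 3L) stop("`seed` must be (slice, row, col)")
    d <- dim(vol$mask)
    if (any(seed < 1L) || any(seed > d)) stop("seed outside the volume grid")
    keep <- lab[seed[1], seed[2], seed[3]]
    if (keep == 0L) stop("seed lies on a background voxel")
  }
  voxel_volume(array(lab == keep, dim(vol$mask)), vol$voxel_size_um)
}

# 3-D connected-component labels (integer array, 0 = background)
label_volume <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  lab <- cpp_label(as.logical(mask), dim(mask), as.integer(connectivity))
  array(lab, dim(mask))
}

#' Border-reachable background (the exterior)
#'
#' Flood-fills the background from the six faces of the grid using
#' 6-connectivity (the complementary pair to 26-connected foreground) and
#' returns the reachable background voxels. Enclosed cavities are excluded.
#' This is the reachability test used to decide whether a surface hole is
#' open or filled.
#'
#' @param mask 3-D logical array (or [voxel_volume()]); `TRUE` = foreground.
#' @return Logical array of the same shape; `TRUE` = exterior background.
#' @export
exterior_background <- function(mask) {
  if (inherits(mask, "voxel_volume")) mask <- mask$mask
  bg <- !mask
  lab <- label_volume(bg, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  array(lab %in% border, d)
}
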