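#' Render a clipped orthographic face image
#'
#' The 2-D comparison workflow images a bone from three sides, each time
#' with the volume clipped in half so lesions in the near wall show through
#' to the background. This function reproduces that geometry digitally: the
#' half of the volume nearest the camera is kept and projected
#' orthographically along the viewing axis onto a binary silhouette.
#'
#' Face labels follow the tibial naming convention and map to fixed viewing
#' directions on the `(slice, row, col)` grid: `"concave"` views along
#' `-x` (camera at low col), `"fibular"` along `+y` (camera at high row) and
#' `"flat"` along `+x` (camera at high col).
#'
#' @param vol A [voxel_volume()].
#' @param face One of `"concave"`, `"fibular"`, `"flat"`.
#' @param clip_frac Position of the clip plane along the viewing axis as a
#'   fraction of the grid (default `0.5`: bone clipped in half).
#' @return A `face_image`: list with `pixels` (binary matrix, 1 = bone),
#'   `pixel_size_um` and `face`.
#' @export
render_face <- function(vol, face = c("concave", "fibular", "flat"),
                        clip_frac = 0.5) {
  stopifnot_voxel_volume(vol)
  face <- match.arg(face)
  if (clip_frac <= 0 || clip_frac >= 1) stop("`clip_frac` must be in (0, 1)")
  # viewing axis and camera side on the (z, y, x) grid
  view <- switch(face,
                 concave = list(axis = 3L, from_high = FALSE),
                 fibular = list(axis = 2L, from_high = TRUE),
                 flat    = list(axis = 3L, from_high = TRUE))
  m <- vol$mask
  d <- dim(m)
  n <- d[view$axis]
  cut <- as.integer(round(n * clip_frac))
  keep <- if (view$from_high) {
    if (cut >= n) integer(0) else (cut + 1L):n
  } else {
    seq_len(min(cut, n))
  }
  if (length(keep) == 0L) stop("clip plane leaves an empty half")
  half <- switch(view$axis,
                 m[keep, , , drop = FALSE],
                 m[, keep, , drop = FALSE],
                 m[, , keep, drop = FALSE])
  if (!any(half)) stop("clipped half-volume contains no bone")
  sil <- apply(half, setdiff(1:3, view$axis), any)
  structure(list(pixels = sil * 1, pixel_size_um = vol$voxel_size_um,
                 face = face),
            class = "face_image")
}

#' Construct a face image directly
#'
#' @param pixels Binary 2-D matrix (1 = bone silhouette).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param face Face label.
#' @return A `face_image`.
#' @export
face_image <- function(pixels, pixel_size_um,
                       face = c("concave", "fibular", "flat")) {
  face <- match.arg(face)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  structure(list(pixels = (pixels != 0) * 1, pixel_size_um = pixel_size_um,
                 face = face),
            class = "face_image")
}

#' 2-D lesion percentage of a face image
#'
#' Operationalises the 2-D method's "red regions": lesions are the interior
#' background regions of the binarised silhouette (background not connected
#' to the image border), i.e. the places where a hole in the near wall lets
#' the background show through. Returns the total lesion area as a percent
#' of the bone area, with the silhouette (bone plus holes) as denominator so
#' the measure is bounded by 100.
#'
#' @param face A `face_image`.
#' @return Percent in `[0, 100]`.
#' @export
measure_2d <- function(face) {
  stopifnot(inherits(face, "face_image"))
  px <- face$pixels != 0
  if (!any(px)) stop("face image contains no bone pixels")
  d <- dim(px)
  # embed as a 1-slice volume; 6-connectivity acts as 4-connectivity in 2-D
  bg <- array(!px, c(1L, d[1], d[2]))
  lab <- label_volume(bg, connectivity = 6L)
  border <- unique(c(lab[1, 1, ], lab[1, d[1], ], lab[1, , 1], lab[1, , d[2]]))
  border <- border[border > 0L]
  interior <- lab > 0L & !(lab %in% border)
  lesion_px <- sum(interior)
  100 * lesion_px / (sum(px) + lesion_px)
}

#' @export
print.face_image <- function(x, ...) {
  cat(sprintf("<face_image> %s face, %d x %d px, pixel %.4g um, %d bone px\n",
              x$face, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels != 0)))
  invisible(x)
}
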