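#' Reconstruction parameters
#'
#' Parameters of the two-stage surface reconstruction. `d_max_um` is the
#' user-specified maximum lesion diameter: the outward expansion radius is
#' `r = floor(d_max_um / (2 * voxel_size_um))` voxels and holes up to this
#' diameter are bridged. `window_um` is the side of the cubic local windows
#' (tiled with 50% overlap) over which the contraction depth is optimised;
#' it defaults to the maximum lesion diameter.
#'
#' @param d_max_um Maximum lesion diameter in micrometres (> 0).
#' @param window_um Local-window side in micrometres; default `d_max_um`.
#' @param depth_step_vox Contraction-depth search step in voxels (>= 1).
#' @param connectivity Component connectivity for lesion labeling, 6 or 26.
#' @param min_lesion_vox Minimum component size (voxels) for a reported
#'   lesion; suppresses single-voxel threshold noise.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(d_max_um, window_um = d_max_um, depth_step_vox = 1L,
                         connectivity = 26L, min_lesion_vox = 8L) {
  if (!is.numeric(d_max_um) || length(d_max_um) != 1L || d_max_um <= 0)
    stop("`d_max_um` must be a single positive number")
  if (!is.numeric(window_um) || length(window_um) != 1L || window_um <= 0)
    stop("`window_um` must be a single positive number")
  depth_step_vox <- as.integer(depth_step_vox)
  if (is.na(depth_step_vox) || depth_step_vox < 1L)
    stop("`depth_step_vox` must be a positive integer")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26")
  min_lesion_vox <- as.integer(min_lesion_vox)
  if (is.na(min_lesion_vox) || min_lesion_vox < 0L)
    stop("`min_lesion_vox` must be a non-negative integer")
  structure(list(d_max_um = as.numeric(d_max_um),
                 window_um = as.numeric(window_um),
                 depth_step_vox = depth_step_vox,
                 connectivity = connectivity,
                 min_lesion_vox = min_lesion_vox),
            class = "recon_params")
}

# expansion radius in voxels; conservative floor so that nothing wider than
# d_max is ever bridged
radius_vox <- function(d_max_um, voxel_size_um) {
  r <- floor(d_max_um / (2 * voxel_size_um))
  if (r < 1)
    stop(sprintf(paste0("resolution error: d_max_um = %.4g spans < 2 voxels ",
                        "at voxel size %.4g um"), d_max_um, voxel_size_um))
  if (d_max_um / voxel_size_um < 4)
    warning("maximum lesion diameter spans < 4 voxels; detection below the ",
            "4:1 size-to-resolution ratio is unreliable")
  as.integer(r)
}

pad_mask <- function(mask, p) {
  d <- dim(mask)
  out <- array(FALSE, d + 2L * p)
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])] <- mask
  out
}

crop_mask <- function(mask, p, d) {
  mask[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])]
}

# Euclidean dilation: distance-to-foreground <= r
dilate_mask <- function(mask, r) {
  dt2 <- cpp_edt_sq(mask, dim(mask))
  array(dt2 <= r * r, dim(mask))
}

#' Outward volumetric expansion
#'
#' First reconstruction stage: the bone surface is diffused outwards by
#' `d_max_um / 2`, realised as the Euclidean distance-transform level set
#' (all voxels within radius `r` of the bone). Any surface hole or pit of
#' diameter up to `d_max_um` is bridged on the expanded outer surface.
#' The dilation is clipped at the grid bounds; [reconstruct()] pads
#' internally so no clipping occurs there.
#'
#' @param vol A [voxel_volume()], ideally a single connected component
#'   (see [select_component()]).
#' @param params A [recon_params()].
#' @return The expanded [voxel_volume()] (a voxel-wise superset of `vol`).
#' @export
expand_volume <- function(vol, params) {
  stopifnot_voxel_volume(vol)
  r <- radius_vox(params$d_max_um, vol$voxel_size_um)
  voxel_volume(dilate_mask(vol$mask, r), vol$voxel_size_um)
}

#' Locally optimised inward contraction
#'
#' Second reconstruction stage. The expanded volume is contracted from its
#' surface by a variable depth: the family of contractions
#' `C_d = {v : distance-to-background(v) > d}` is evaluated for integer
#' depths `d = 0..r` within cubic windows (side `window_um`, 50% overlap)
#' tiled over the expanded surface, and each window keeps the depth that
#' maximises the overlap ratio `rho(d) = |C_d intersect original| / |C_d|`
#' (ties broken toward the smaller depth, i.e. less contraction). Window
#' depths are blended by trilinear interpolation into a smooth per-voxel
#' depth field. Windows in which the shell is too thin for any overlap
#' (`rho = 0` throughout) fall back to full contraction `d = r`.
#'
#' @param expanded Expanded [voxel_volume()] (superset of `original`).
#' @param original The original [voxel_volume()].
#' @param params A [recon_params()].
#' @return A list with `contracted` (a [voxel_volume()], subset of
#'   `expanded`) and `depth` (a `depth_field`: per-window chosen depths and
#'   achieved overlap ratios on the window-center grid).
#' @export
contract_adaptive <- function(expanded, original, params) {
  stopifnot_voxel_volume(expanded)
  stopifnot_voxel_volume(original)
  if (!identical(dim(expanded$mask), dim(original$mask)))
    stop("`expanded` and `original` must share one grid")
  if (any(original$mask & !expanded$mask))
    stop("contract violation: `expanded` is not a superset of `original`")
  r <- radius_vox(params$d_max_um, original$voxel_size_um)
  d <- dim(original$mask)
  res <- contract_core(pad_mask(expanded$mask, 1L), pad_mask(original$mask, 1L),
                       original$voxel_size_um, params, r)
  res$depth$centers <- lapply(res$depth$centers, function(x) x - 1L)
  list(contracted = voxel_volume(crop_mask(res$contracted, 1L, d),
                                 original$voxel_size_um),
       depth = res$depth)
}

# core of the adaptive contraction, on a grid already padded with background
contract_core <- function(exp_mask, orig_mask, voxel_size_um, params, r) {
  d <- dim(exp_mask)
  dt2 <- cpp_edt_sq(!exp_mask, d)            # squared distance to background
  # depth level: largest integer depth d >= 1 with d^2 < dt2 (-1 outside)
  lev <- integer(length(exp_mask))
  lev[!exp_mask] <- -1L
  ie <- which(exp_mask)
  lev[ie] <- as.integer(floor(sqrt(pmax(dt2[ie], 1) - 1) + 1e-9))

  wv <- max(2L, as.integer(round(params$window_um / voxel_size_um)))
  if (params$window_um < voxel_size_um)
    stop("parameter error: window_um is smaller than one voxel")
  half <- max(1L, wv %/% 2L)
  sp <- half                                  # 50% window overlap
  bb <- apply(arrayInd(ie, d), 2, range)
  centers <- lapply(1:3, function(a) {
    x <- seq.int(bb[1, a], bb[2, a], by = sp)
    if (x[length(x)] < bb[2, a]) x <- c(x, bb[2, a])
    as.integer(x)
  })
  gdim <- lengths(centers)
  cg <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]],
                              KEEP.OUT.ATTRS = FALSE))
  cnt <- cpp_window_counts(lev, as.logical(orig_mask), d,
                           cg[, 1] - 1L, cg[, 2] - 1L, cg[, 3] - 1L,
                           half, r)
  dcand <- unique(c(seq.int(0L, r, by = params$depth_step_vox), r))
  tot <- cnt$tot[, dcand + 1L, drop = FALSE]
  org <- cnt$orig[, dcand + 1L, drop = FALSE]
  rho <- ifelse(tot > 0L, org / pmax(tot, 1L), -Inf)
  best <- apply(rho, 1, max)
  # smallest candidate depth achieving the maximum (ties -> less contraction)
  pick <- max.col(rho >= best - 1e-12, ties.method = "first")
  dstar <- as.numeric(dcand[pick])
  degenerate <- is.finite(best) & best <= 0
  dstar[degenerate] <- r                      # thin shell: full contraction
  surface <- cnt$n_surface > 0L
  dstar[!surface] <- NA_real_
  gd <- array(dstar, gdim)
  gr <- array(ifelse(is.finite(best), pmax(best, 0), 0), gdim)
  gr[!array(surface, gdim)] <- NA_real_
  if (all(is.na(gd))) stop("expanded volume has no surface windows")
  gd <- fill_na_grid(gd)

  # interpolate depths for the shallow shell; deeper voxels (level >= r,
  # i.e. dt2 > r^2 >= depth^2) are kept regardless
  contracted <- exp_mask
  shallow <- ie[lev[ie] < r]
  if (length(shallow)) {
    co <- arrayInd(shallow, d)
    dep <- cpp_trilinear(gd, gdim,
                         origin = vapply(centers, function(x) as.numeric(x[1]), 0),
                         spacing = rep(as.numeric(sp), 3),
                         as.numeric(co[, 1]), as.numeric(co[, 2]),
                         as.numeric(co[, 3]))
    contracted[shallow] <- dt2[shallow] > dep * dep
  }
  n_deg <- sum(degenerate & surface)
  if (n_deg > 0 && isTRUE(getOption("cortlesion.verbose")))
    message(n_deg, " window(s) had zero overlap at every depth; ",
            "using full contraction there")
  field <- structure(list(depth_vox = gd, overlap = gr, centers = centers,
                          spacing_vox = sp, window_vox = wv, r_vox = r,
                          n_degenerate = n_deg),
                     class = "depth_field")
  list(contracted = contracted, depth = field)
}

# fill NA cells of a small grid by iterative 6-neighbour averaging
fill_na_grid <- function(g) {
  while (anyNA(g)) {
    d <- dim(g)
    acc <- array(0, d); n <- array(0, d)
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
    for (s in shifts) {
      sh <- shift_array(g, s)
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      n <- n + ok
    }
    fill <- is.na(g) & n > 0
    if (!any(fill)) stop("cannot fill depth grid")  # unreachable: grid is connected
    g[fill] <- acc[fill] / n[fill]
  }
  g
}

# shift an array by an integer offset, padding with NA
shift_array <- function(a, s) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax])
      dst[[ax]] <- src[[ax]] + s[ax]
    } else {
      src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]
      dst[[ax]] <- seq_len(d[ax] + s[ax])
    }
    if (d[ax] - abs(s[ax]) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Reconstruct the lesion-free bone surface
#'
#' Full two-stage reconstruction: outward expansion by `d_max_um / 2`
#' ([expand_volume()]), locally optimised inward contraction
#' ([contract_adaptive()]), and union with the original volume. The result
#' is a voxel-wise superset of the input whose outer surface carries no
#' holes or pits of diameter up to `d_max_um`; the difference against the
#' original volume is the lesion fill (see [detect_lesions()]). The grid is
#' padded internally so the expansion is never clipped; the returned volume
#' is on the input grid. The procedure is fully deterministic.
#'
#' @param original A single-component [voxel_volume()].
#' @param params A [recon_params()].
#' @return A list with `volume` (the reconstructed [voxel_volume()]) and
#'   `depth` (the `depth_field` from the contraction stage).
#' @export
reconstruct <- function(original, params) {
  stopifnot_voxel_volume(original)
  r <- radius_vox(params$d_max_um, original$voxel_size_um)
  p <- r + 2L
  d <- dim(original$mask)
  m <- pad_mask(original$mask, p)
  expv <- dilate_mask(m, r)
  res <- contract_core(expv, m, original$voxel_size_um, params, r)
  recon <- crop_mask(res$contracted | m, p, d)
  res$depth$centers <- lapply(res$depth$centers, function(x) x - p)
  list(volume = voxel_volume(recon, original$voxel_size_um),
       depth = res$depth)
}

#' Global morphological closing
#'
#' Euclidean closing with a ball of radius `d_max_um / 2`: dilation followed
#' by erosion with the same radius. This is the non-adaptive limit of
#' [reconstruct()] (the two agree wherever every local window selects full
#' contraction, e.g. on flat or convex surfaces) and serves as an
#' independent reference in validation. Standard closing properties hold:
#' the result is a superset of the input (extensive), idempotent, and
#' increasing.
#'
#' @param vol A [voxel_volume()].
#' @param d_max_um Ball diameter in micrometres.
#' @return The closed [voxel_volume()] on the input grid.
#' @export
morph_close <- function(vol, d_max_um) {
  stopifnot_voxel_volume(vol)
  r <- radius_vox(d_max_um, vol$voxel_size_um)
  p <- r + 2L
  d <- dim(vol$mask)
  m <- pad_mask(vol$mask, p)
  dil <- dilate_mask(m, r)
  dt2 <- cpp_edt_sq(!dil, dim(dil))
  closed <- array(dt2 > r * r, dim(dil)) & dil
  voxel_volume(crop_mask(closed, p, d), vol$voxel_size_um)
}

#' @export
print.depth_field <- function(x, ...) {
  cat(sprintf("<depth_field> %d x %d x %d windows, side %d vox, spacing %d vox, r = %d vox\n",
              dim(x$depth_vox)[1], dim(x$depth_vox)[2], dim(x$depth_vox)[3],
              x$window_vox, x$spacing_vox, x$r_vox))
  cat(sprintf("  depths [%g, %g], %d degenerate window(s)\n",
              min(x$depth_vox), max(x$depth_vox), x$n_degenerate))
  invisible(x)
}
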