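# logical shift with FALSE padding: out[v] = a[v - s]
shift_mask <- function(a, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] - abs(s[ax]) <= 0) return(out)
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax]); dst[[ax]] <- src[[ax]] + s[ax]
    } else {
      src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]; dst[[ax]] <- seq_len(d[ax] + s[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

face_dirs <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

# per-direction indicator of an exposed face: fg voxel whose neighbour in
# direction s is exterior background
exposed_by_dir <- function(fg, ext) {
  lapply(face_dirs, function(s) fg & shift_mask(ext, -s))
}

#' Bone surface area of a binary volume
#'
#' Counts foreground voxel faces adjacent to border-reachable background
#' (enclosed cavities such as the medullary canal are not part of the
#' surface) and converts to micrometres squared. Raw face counting
#' overestimates a smooth surface by 3/2 in expectation over orientations,
#' so the default applies the standard 2/3 correction; `corrected = FALSE`
#' returns the raw face-count area.
#'
#' @param vol A [voxel_volume()] with non-empty mask.
#' @param corrected Apply the 2/3 isotropy correction (default `TRUE`).
#' @return Surface area in square micrometres. The raw face count is
#'   attached as attribute `"n_faces"`.
#' @export
surface_area <- function(vol, corrected = TRUE) {
  stopifnot_voxel_volume(vol)
  if (!any(vol$mask)) stop("empty mask has no surface")
  fg <- pad_mask(vol$mask, 1L)
  ext <- exterior_background(fg)
  nf <- sum(vapply(face_dirs, function(s) sum(fg & shift_mask(ext, -s)), 0))
  area <- nf * vol$voxel_size_um^2 * (if (corrected) 2 / 3 else 1)
  attr(area, "n_faces") <- nf
  area
}

#' Detect and measure osteolytic lesions
#'
#' Subtracts the original bone volume from its reconstruction, labels the
#' difference into connected components, drops components smaller than
#' `min_lesion_vox`, and measures each surviving lesion. The per-lesion
#' `cap_area_um2` is the en-face area of the lesion opening: the largest
#' connected patch of difference voxels exposed on the reconstructed outer
#' surface, projected along the patch's dominant face normal (exact for flat
#' openings, and equal to the mouth disc for bowl-shaped caps). The raw
#' exposed-face area is reported alongside as `exposed_faces_um2`.
#' An osteolytic lesion is a breach of the outer cortical surface, so
#' difference components with no exposed face on the reconstructed outer
#' surface (filled enclosed cavities, endosteal discretisation residue) are
#' not lesions and are dropped. The total lesion area is expressed as a percent
#' of the reconstructed (lesion-free) bone surface area, so the denominator
#' does not shrink as disease grows.
#'
#' @param original Original [voxel_volume()].
#' @param reconstructed Reconstructed [voxel_volume()] from [reconstruct()];
#'   must be a voxel-wise superset of `original` on the same grid.
#' @param params The [recon_params()] used for the reconstruction.
#' @return A `lesion_report`: list with `lesions` (data frame sorted by
#'   `cap_area_um2` descending: `id`, `fill_vox`, `cap_area_um2`,
#'   `exposed_faces_um2`, `centroid_z_um`/`_y_um`/`_x_um`, `included`),
#'   `bone_surface_area_um2` (corrected) and `bone_surface_area_raw_um2`,
#'   `total_lesion_area_um2`, `lesion_percent`, `labels` (integer array of
#'   lesion ids), `voxel_size_um` and `params`.
#' @export
detect_lesions <- function(original, reconstructed, params) {
  stopifnot_voxel_volume(original)
  stopifnot_voxel_volume(reconstructed)
  if (!identical(dim(original$mask), dim(reconstructed$mask)))
    stop("`original` and `reconstructed` must share one grid")
  if (original$voxel_size_um != reconstructed$voxel_size_um)
    stop("voxel sizes differ")
  if (any(original$mask & !reconstructed$mask))
    stop("contract violation: `reconstructed` is not a superset of `original`")
  s <- original$voxel_size_um
  d <- dim(original$mask)

  diff <- reconstructed$mask & !original$mask
  lab <- label_volume(diff, params$connectivity)
  n_raw <- max(lab)
  sa <- surface_area(reconstructed, corrected = TRUE)
  sa_raw <- as.numeric(attr(sa, "n_faces")) * s^2

  if (n_raw == 0L) {
    return(new_lesion_report(empty_lesion_df(), as.numeric(sa), sa_raw,
                             array(0L, d), s, params))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n_raw)
  keep_ids <- which(sizes >= max(1L, params$min_lesion_vox))
  if (length(keep_ids) == 0L) {
    return(new_lesion_report(empty_lesion_df(), as.numeric(sa), sa_raw,
                             array(0L, d), s, params))
  }

  # exposed faces of difference voxels on the reconstructed outer surface
  extp <- crop_mask(exterior_background(pad_mask(reconstructed$mask, 1L)), 1L, d)
  dirs <- exposed_by_dir(diff, extp)
  exposed_any <- Reduce(`|`, dirs)
  patch_lab <- label_volume(exposed_any, 26L)

  vox_idx <- which(lab > 0L & array(lab %in% keep_ids, d))
  vox_lab <- lab[vox_idx]
  co <- arrayInd(vox_idx, d)
  by_lesion <- split(seq_along(vox_idx), vox_lab)

  rows <- lapply(names(by_lesion), function(id_chr) {
    ii <- by_lesion[[id_chr]]
    vi <- vox_idx[ii]
    cc <- co[ii, , drop = FALSE]
    dircnt <- vapply(dirs, function(a) sum(a[vi]), 0)
    n_exposed <- sum(dircnt)
    if (n_exposed == 0) return(NULL)      # no surface breach: not a lesion
    cap <- 0
    if (n_exposed > 0) {
      pl <- patch_lab[vi]
      onsurf <- pl > 0L
      patches <- split(which(onsurf), pl[onsurf])
      # patch size = exposed faces it carries
      psize <- vapply(patches, function(jj) {
        sum(vapply(dirs, function(a) sum(a[vi[jj]]), 0))
      }, 0)
      big <- patches[[which.max(psize)]]
      pdir <- vapply(dirs, function(a) sum(a[vi[big]]), 0)
      net <- c(abs(pdir[1] - pdir[2]), abs(pdir[3] - pdir[4]),
               abs(pdir[5] - pdir[6]))
      axis <- which.max(net)                  # ties -> lowest axis (z)
      other <- setdiff(1:3, axis)
      cells <- unique(cc[big, other, drop = FALSE] %*% c(1, max(d) + 1))
      cap <- length(cells) * s^2
    }
    data.frame(id = as.integer(id_chr),
               fill_vox = length(vi),
               cap_area_um2 = cap,
               exposed_faces_um2 = n_exposed * s^2,
               centroid_z_um = mean(cc[, 1]) * s,
               centroid_y_um = mean(cc[, 2]) * s,
               centroid_x_um = mean(cc[, 3]) * s,
               included = TRUE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(new_lesion_report(empty_lesion_df(), as.numeric(sa), sa_raw,
                             array(0L, d), s, params))
  }
  df <- do.call(rbind, rows)
  ord <- order(-df$cap_area_um2, -df$fill_vox, df$id)
  df <- df[ord, , drop = FALSE]
  # relabel: report ids are size ranks (1 = largest cap)
  remap <- integer(n_raw)
  remap[df$id] <- seq_len(nrow(df))
  lab_new <- array(0L, d)
  kept <- remap[vox_lab] > 0L
  lab_new[vox_idx[kept]] <- remap[vox_lab[kept]]
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  new_lesion_report(df, as.numeric(sa), sa_raw, lab_new, s, params)
}

empty_lesion_df <- function() {
  data.frame(id = integer(), fill_vox = integer(), cap_area_um2 = numeric(),
             exposed_faces_um2 = numeric(), centroid_z_um = numeric(),
             centroid_y_um = numeric(), centroid_x_um = numeric(),
             included = logical())
}

new_lesion_report <- function(df, sa, sa_raw, labels, voxel_size_um, params) {
  rep <- structure(list(lesions = df,
                        bone_surface_area_um2 = sa,
                        bone_surface_area_raw_um2 = sa_raw,
                        total_lesion_area_um2 = 0,
                        lesion_percent = 0,
                        labels = labels,
                        voxel_size_um = voxel_size_um,
                        params = unclass(params)),
                   class = "lesion_report")
  recompute_totals(rep)
}

recompute_totals <- function(report) {
  inc <- report$lesions$included
  report$total_lesion_area_um2 <- sum(report$lesions$cap_area_um2[inc])
  report$lesion_percent <-
    100 * report$total_lesion_area_um2 / report$bone_surface_area_um2
  report
}

#' De-select lesions from a report
#'
#' Flags lesions (e.g. naturally occurring blood-vessel canals) as excluded
#' and recomputes the totals over included lesions only. Records are
#' retained, not deleted, so the exclusion is auditable and reversible.
#' Natural-hole removal is a manual expert decision; nothing is excluded
#' automatically.
#'
#' @param report A `lesion_report`.
#' @param ids Integer lesion ids to exclude.
#' @param restore If `TRUE`, first re-include every lesion (so
#'   `deselect(report, integer(0), restore = TRUE)` restores the original
#'   totals).
#' @return The updated `lesion_report`.
#' @export
deselect <- function(report, ids, restore = FALSE) {
  stopifnot(inherits(report, "lesion_report"))
  ids <- as.integer(ids)
  if (restore) report$lesions$included <- TRUE
  if (length(ids)) {
    unknown <- setdiff(ids, report$lesions$id)
    if (length(unknown))
      stop("unknown lesion id(s): ", paste(unknown, collapse = ", "))
    report$lesions$included[report$lesions$id %in% ids] <- FALSE
  }
  recompute_totals(report)
}

#' Identify the lesion at (or near) a voxel coordinate
#'
#' The scriptable analogue of interactive 3-D picking: returns the id of the
#' lesion whose component contains the point; if the point is background,
#' the nearest lesion within `d_max_um / 2` is returned (ties broken toward
#' the lower id), else `NA`.
#'
#' @param report A `lesion_report` (carries the label grid).
#' @param point Integer `(slice, row, col)`, 1-based.
#' @return A lesion id, or `NA_integer_` if no lesion is within reach.
#' @export
pick_lesion <- function(report, point) {
  stopifnot(inherits(report, "lesion_report"))
  point <- as.integer(point)
  d <- dim(report$labels)
  if (length(point) != 3L || any(point < 1L) || any(point > d))
    stop("point outside the volume grid")
  hit <- report$labels[point[1], point[2], point[3]]
  if (hit > 0L) return(as.integer(hit))
  idx <- which(report$labels > 0L)
  if (length(idx) == 0L) return(NA_integer_)
  co <- arrayInd(idx, d)
  d2 <- (co[, 1] - point[1])^2 + (co[, 2] - point[2])^2 + (co[, 3] - point[3])^2
  rmax <- report$params$d_max_um / (2 * report$voxel_size_um)
  ok <- d2 <= rmax^2
  if (!any(ok)) return(NA_integer_)
  cand <- report$labels[idx[ok]]
  dmin <- tapply(d2[ok], cand, min)
  best <- as.integer(names(dmin)[dmin == min(dmin)])
  min(best)                                    # tie -> lower id
}

#' @export
print.lesion_report <- function(x, ...) {
  n <- nrow(x$lesions)
  cat(sprintf("<lesion_report> %d lesion(s), %d included\n",
              n, sum(x$lesions$included)))
  cat(sprintf("  bone surface area: %.5g um^2 (raw faces %.5g um^2)\n",
              x$bone_surface_area_um2, x$bone_surface_area_raw_um2))
  cat(sprintf("  total lesion area: %.5g um^2 (%.3g%% of bone surface)\n",
              x$total_lesion_area_um2, x$lesion_percent))
  if (n > 0) {
    cat("  largest lesions (by cap area):\n")
    print(utils::head(x$lesions[, c("id", "fill_vox", "cap_area_um2",
                                    "included")], 5), row.names = FALSE)
  }
  invisible(x)
}
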