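#' Specify a synthetic cortical-bone phantom
#'
#' Phantoms emulate the cortical shell of a long bone at micro-CT
#' resolution: a thick-walled shaft with an enclosed medullary canal,
#' through-holes of known diameter punched through the wall (the "lesions"),
#' an optional narrow vessel canal, and additive Gaussian grayscale noise.
#' Every geometric quantity is in voxels, so the analytic ground truth is
#' exact on the grid; micrometre outputs scale with `voxel_size_um`.
#'
#' Shapes: `"capped_shaft"` is a closed cylinder with a capsule-shaped canal
#' (hemispherical canal ends, so the interior has no concavity sharper than
#' the canal radius); `"hollow_cylinder"` is the same tube with open ends;
#' `"slab"` is a flat plate with axial through-holes; `"triangular_prism"`
#' is a solid convex prism (no holes), useful as a lesion-free control.
#'
#' @param shape One of `"capped_shaft"`, `"hollow_cylinder"`, `"slab"`,
#'   `"triangular_prism"`.
#' @param outer_radius_vox Outer shaft radius (shaft shapes).
#' @param length_vox Shaft length / slab extent along z.
#' @param wall_vox Wall thickness in voxels (>= 2).
#' @param slab_size_vox For `"slab"`: `c(thickness, height, width)` voxels.
#' @param apex_angle_deg For `"triangular_prism"`: apex angle.
#' @param holes Data frame with columns `z`, `dir` (`"+x"`, `"-x"`, `"+y"`,
#'   `"-y"` for shafts, `"z"` for slabs; for slabs also columns `y`, `x`)
#'   and `diameter_vox`.
#' @param vessel Optional list `list(z, dir, diameter_vox)` describing a
#'   narrow natural canal (recorded in the truth table as a vessel).
#' @param noise_sd Gaussian noise standard deviation in intensity units.
#' @param bone_level,background_level Intensities of bone and background.
#' @param margin_vox Background margin around the object.
#' @param voxel_size_um Isotropic voxel size (default the scanner resolution
#'   4.3 um).
#' @param seed Integer; fixes all randomness of the generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("capped_shaft", "hollow_cylinder", "slab",
                                   "triangular_prism"),
                         outer_radius_vox = 44, length_vox = 140,
                         wall_vox = 28, slab_size_vox = c(28, 80, 80),
                         apex_angle_deg = 60,
                         holes = NULL, vessel = NULL,
                         noise_sd = 0, bone_level = 0.8,
                         background_level = 0.1, margin_vox = 4,
                         voxel_size_um = 4.3, seed = 1L) {
  shape <- match.arg(shape)
  if (wall_vox < 2) stop("wall thickness must be >= 2 voxels")
  if (shape %in% c("capped_shaft", "hollow_cylinder")) {
    if (wall_vox >= outer_radius_vox)
      stop("wall thickness must be smaller than the outer radius")
    if (shape == "capped_shaft" &&
        length_vox < 2 * (wall_vox + (outer_radius_vox - wall_vox)))
      stop("shaft too short for the capsule canal")
  }
  if (!is.null(holes)) {
    holes <- as.data.frame(holes)
    if (!all(c("dir", "diameter_vox") %in% names(holes)))
      stop("`holes` needs columns dir and diameter_vox")
    min_dim <- switch(shape,
                      capped_shaft = ,
                      hollow_cylinder = min(2 * outer_radius_vox, length_vox),
                      slab = min(slab_size_vox[2:3]),
                      triangular_prism = stop("prism phantoms carry no holes"))
    if (any(holes$diameter_vox >= min_dim))
      stop("hole diameter must be smaller than the smallest outer dimension")
    if (any(holes$diameter_vox < 1)) stop("hole diameter must be >= 1 voxel")
  }
  structure(list(shape = shape, outer_radius_vox = outer_radius_vox,
                 length_vox = length_vox, wall_vox = wall_vox,
                 slab_size_vox = slab_size_vox,
                 apex_angle_deg = apex_angle_deg,
                 holes = holes, vessel = vessel, noise_sd = noise_sd,
                 bone_level = bone_level, background_level = background_level,
                 margin_vox = as.integer(margin_vox),
                 voxel_size_um = voxel_size_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Builds the binary geometry of the spec, punches holes and vessel, applies
#' intensities and seeded Gaussian noise, and fills the truth table with the
#' analytic expectations (per-hole mouth area on the voxel lattice, and the
#' closed-form lesion-free surface area). Given the same spec (including
#' seed), the output is bit-identical.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `gray` (a [gray_volume()]), `mask`
#'   (ground-truth bone occupancy before noise), `threshold` (midpoint
#'   intensity separating bone from background), and `truth` (list with
#'   `holes` data frame incl. `expected_cap_area_um2`, a `vessel` flag
#'   column, and `true_surface_area_um2`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$voxel_size_um
  mg <- spec$margin_vox
  geom <- build_geometry(spec)
  mask <- geom$mask

  holes <- spec$holes
  if (!is.null(spec$vessel)) {
    if (!spec$shape %in% c("capped_shaft", "hollow_cylinder"))
      stop("vessel canals are only supported on shaft phantoms")
    v <- spec$vessel
    vrow <- data.frame(z = v$z, dir = v$dir, diameter_vox = v$diameter_vox)
    holes <- if (is.null(holes)) vrow else
      rbind(holes[, c("z", "dir", "diameter_vox")], vrow)
    vessel_flag <- c(rep(FALSE, nrow(holes) - 1L), TRUE)
  } else {
    vessel_flag <- if (is.null(holes)) logical(0) else rep(FALSE, nrow(holes))
  }

  truth_rows <- list()
  if (!is.null(holes) && nrow(holes) > 0) {
    for (i in seq_len(nrow(holes))) {
      h <- holes[i, ]
      punched <- punch_hole(mask, geom, h, spec)
      mask <- punched$mask
      truth_rows[[i]] <- data.frame(
        z = punched$center[1], y = punched$center[2], x = punched$center[3],
        dir = as.character(h$dir), diameter_vox = h$diameter_vox,
        expected_cap_area_um2 = punched$mouth_cells * s^2,
        vessel = vessel_flag[i])
    }
  }
  truth_holes <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(z = numeric(), y = numeric(), x = numeric(), dir = character(),
               diameter_vox = numeric(), expected_cap_area_um2 = numeric(),
               vessel = logical())

  gray_data <- array(spec$background_level, dim(mask))
  gray_data[mask] <- spec$bone_level
  if (spec$noise_sd > 0) {
    gray_data <- gray_data + with_phantom_seed(spec$seed,
      stats::rnorm(length(gray_data), 0, spec$noise_sd))
  }
  gray <- gray_volume(array(gray_data, dim(mask)), s,
                      source = sprintf("phantom:%s seed=%d", spec$shape,
                                       spec$seed))
  structure(list(gray = gray, mask = mask,
                 threshold = (spec$bone_level + spec$background_level) / 2,
                 truth = list(holes = truth_holes,
                              true_surface_area_um2 = geom$surface_area * s^2,
                              notch = geom$notch),
                 spec = spec),
            class = "phantom")
}

with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# binary geometry (no holes); returns mask, analytic lesion-free surface
# area (voxel^2 units) and center bookkeeping
build_geometry <- function(spec) {
  mg <- spec$margin_vox
  if (spec$shape %in% c("capped_shaft", "hollow_cylinder")) {
    Ro <- spec$outer_radius_vox
    Rc <- Ro - spec$wall_vox
    L <- spec$length_vox
    nyx <- as.integer(2 * (Ro + mg))
    nz <- as.integer(L + 2 * mg)
    cy <- cx <- (nyx + 1) / 2
    z0 <- mg + 1L; z1 <- mg + L
    r2 <- outer(((1:nyx) - cy)^2, ((1:nyx) - cx)^2, "+")
    disc_out <- r2 <= Ro^2
    mask <- array(FALSE, c(nz, nyx, nyx))
    if (spec$shape == "capped_shaft") {
      za0 <- z0 + spec$wall_vox + Rc
      za1 <- z1 - spec$wall_vox - Rc
      for (z in z0:z1) {
        dz <- max(0, za0 - z, z - za1)
        canal <- r2 <= Rc^2 - dz^2
        mask[z, , ] <- disc_out & !canal
      }
      sa <- 2 * pi * Ro * L + 2 * pi * Ro^2       # outer surface only
    } else {
      canal <- r2 <= Rc^2
      for (z in z0:z1) mask[z, , ] <- disc_out & !canal
      sa <- 2 * pi * Ro * L + 2 * pi * (Ro^2 - Rc^2) + 2 * pi * Rc * L
    }
    return(list(mask = mask, surface_area = sa,
                center = c(cy = cy, cx = cx, z0 = z0, z1 = z1, Ro = Ro,
                           Rc = Rc),
                notch = NULL))
  }
  if (spec$shape == "slab") {
    t <- spec$slab_size_vox[1]; h <- spec$slab_size_vox[2]
    w <- spec$slab_size_vox[3]
    nz <- as.integer(t + 2 * mg); ny <- as.integer(h + 2 * mg)
    nx <- as.integer(w + 2 * mg)
    mask <- array(FALSE, c(nz, ny, nx))
    mask[(mg + 1):(mg + t), (mg + 1):(mg + h), (mg + 1):(mg + w)] <- TRUE
    sa <- 2 * (t * h + h * w + w * t)
    return(list(mask = mask, surface_area = sa,
                center = c(z0 = mg + 1, z1 = mg + t), notch = NULL))
  }
  # triangular_prism: solid convex prism, apex up (+z), ridge along y
  half <- spec$apex_angle_deg / 2 * pi / 180
  hgt <- spec$slab_size_vox[1]; len <- spec$slab_size_vox[2]
  nz <- as.integer(hgt + 2 * mg)
  base_half <- ceiling(hgt * tan(half))
  nx <- as.integer(2 * base_half + 2 * mg + 2)
  ny <- as.integer(len + 2 * mg)
  cx <- (nx + 1) / 2
  ztop <- mg + hgt
  mask <- array(FALSE, c(nz, ny, nx))
  for (z in (mg + 1):ztop) {
    hw <- (ztop - z) * tan(half)
    cols <- which(abs((1:nx) - cx) <= hw)
    if (length(cols)) mask[z, (mg + 1):(mg + len), cols] <- TRUE
  }
  base <- 2 * hgt * tan(half)
  side <- hgt / cos(half)
  tri_area <- base * hgt / 2
  sa <- len * (base + 2 * side) + 2 * tri_area
  list(mask = mask, surface_area = sa, center = c(cx = cx, ztop = ztop),
       notch = NULL)
}

# punch one hole; returns updated mask, realised center, and the discrete
# mouth-cell count (the analytic cap-area oracle on the voxel lattice)
punch_hole <- function(mask, geom, h, spec) {
  d <- dim(mask)
  a <- h$diameter_vox / 2
  if (h$dir == "z") {
    hy <- h$y; hx <- h$x
    r2 <- outer(((1:d[2]) - hy)^2, ((1:d[3]) - hx)^2, "+")
    m2 <- r2 < a^2
    if (!any(m2)) stop("hole spec error: hole smaller than one voxel")
    zr <- geom$center["z0"]:geom$center["z1"]
    sub <- mask[zr, , , drop = FALSE]
    for (z in seq_along(zr)) sub[z, , ][m2] <- FALSE
    mask[zr, , ] <- sub
    return(list(mask = mask, center = c(mean(zr), hy, hx),
                mouth_cells = sum(m2)))
  }
  cy <- geom$center["cy"]; cx <- geom$center["cx"]
  hz <- h$z
  if (hz - a < geom$center["z0"] || hz + a > geom$center["z1"])
    stop("hole spec error: hole extends beyond the shaft wall")
  axis_y <- h$dir %in% c("+y", "-y")
  perp_c <- if (axis_y) cx else cy
  perp_n <- if (axis_y) d[3] else d[2]
  m2 <- outer(((1:d[1]) - hz)^2, ((1:perp_n) - perp_c)^2, "+") < a^2
  if (!any(m2)) stop("hole spec error: hole smaller than one voxel")
  pos <- substr(h$dir, 1, 1) == "+"
  along_n <- if (axis_y) d[2] else d[3]
  along_c <- if (axis_y) cy else cx
  along_keep <- if (pos) which((1:along_n) >= along_c) else
    which((1:along_n) <= along_c)
  idx <- which(m2, arr.ind = TRUE)             # (z, perp) cells to remove
  for (k in seq_len(nrow(idx))) {
    z <- idx[k, 1]; p <- idx[k, 2]
    if (axis_y) mask[z, along_keep, p] <- FALSE
    else mask[z, p, along_keep] <- FALSE
  }
  Ro <- geom$center["Ro"]
  center <- if (axis_y)                        # approximate mouth location
    c(hz, if (pos) cy + Ro else cy - Ro, cx)
  else c(hz, cy, if (pos) cx + Ro else cx - Ro)
  list(mask = mask, center = unname(center), mouth_cells = sum(m2))
}

#' Acute-angle wedge phantom (known-failure fixture)
#'
#' The reconstruction treats re-entrant creases sharper than the maximum
#' lesion diameter as lesions — a documented limitation for complex
#' structures with very acute angles. For `angle_deg < 90` this generator
#' carves a V-notch of that apex angle into a slab and then regularises the
#' surface with a morphological closing of radius `apex_round_vox` (the
#' voxel-scale smoothing that complex datasets receive before analysis):
#' this rounds the apex and removes sub-voxel staircase concavities, so the
#' phantom is by construction free of concavities below the rounding scale
#' and reconstructions with `d_max` up to twice the rounding report nothing,
#' while a `d_max` spanning the crease opening fills the groove and reports
#' spurious lesions. For `angle_deg >= 90` it returns a solid convex
#' triangular prism with that apex angle, on which the reconstruction is
#' the identity and no lesions exist.
#'
#' @param angle_deg Crease (or prism apex) angle in degrees.
#' @param depth_vox Notch depth in voxels (`angle_deg < 90`).
#' @param apex_round_vox Apex rounding radius in voxels.
#' @param slab_size_vox `c(thickness, height, width)` of the host slab.
#' @param noise_sd,seed,voxel_size_um As in [phantom_spec()].
#' @return A `phantom` (see [make_phantom()]); its truth table contains no
#'   holes, and `truth$notch` is the carved notch mask (`NULL` for the
#'   convex prism) for localising spurious lesions.
#' @export
make_acute_angle_phantom <- function(angle_deg = 20, depth_vox = 24,
                                     apex_round_vox = 3,
                                     slab_size_vox = c(40, 60, 90),
                                     noise_sd = 0, seed = 1L,
                                     voxel_size_um = 4.3) {
  if (angle_deg >= 90) {
    spec <- phantom_spec("triangular_prism", apex_angle_deg = angle_deg,
                         slab_size_vox = c(slab_size_vox[1], slab_size_vox[2]),
                         noise_sd = noise_sd, seed = seed,
                         voxel_size_um = voxel_size_um)
    return(make_phantom(spec))
  }
  spec <- phantom_spec("slab", slab_size_vox = slab_size_vox,
                       noise_sd = noise_sd, seed = seed,
                       voxel_size_um = voxel_size_um)
  ph <- make_phantom(spec)
  mask <- ph$mask
  d <- dim(mask)
  mg <- spec$margin_vox
  t <- slab_size_vox[1]
  ztop <- mg + t
  zapex <- ztop - depth_vox
  if (zapex <= mg) stop("notch deeper than the slab")
  cx <- (d[3] + 1) / 2
  half <- angle_deg / 2 * pi / 180
  notch <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    if (z >= zapex && z <= ztop) {
      hw <- (z - zapex) * tan(half)
      cols <- which(abs((1:d[3]) - cx) < hw)
      if (length(cols)) notch[z, (mg + 1):(d[2] - mg), cols] <- TRUE
    }
  }
  carved <- mask & !notch
  # surface regularisation: closing at the rounding radius removes every
  # concavity below that scale (incl. wall staircases) and rounds the apex
  carved <- morph_close(voxel_volume(carved, voxel_size_um),
                        2 * apex_round_vox * voxel_size_um)$mask
  notch <- notch & !carved
  gray_data <- array(spec$background_level, d)
  gray_data[carved] <- spec$bone_level
  if (noise_sd > 0)
    gray_data <- gray_data + with_phantom_seed(seed,
      stats::rnorm(length(gray_data), 0, noise_sd))
  ph$gray <- gray_volume(array(gray_data, d), voxel_size_um,
                         source = sprintf("phantom:notched_wedge seed=%d", seed))
  ph$mask <- carved
  ph$truth$notch <- notch
  ph
}

#' Specifications for the standard validation battery
#'
#' A seeded battery of hollow-shell (capped shaft) phantoms used throughout
#' validation: wall 28 voxels, canal radius 16 voxels, 2-4 through-holes per
#' phantom with diameters drawn from 8-24 voxels on distinct walls, and
#' Gaussian noise up to 10% of the bone-background contrast. These are the
#' standard conditions for recovery testing with a maximum lesion diameter
#' of 24 voxels.
#'
#' @param n Number of phantoms.
#' @param seed Battery seed; phantom `i` uses `seed * 1000 + i`.
#' @param voxel_size_um Voxel size passed through to the specs.
#' @return A list of [phantom_spec()] objects.
#' @export
phantom_battery_specs <- function(n = 20, seed = 1L, voxel_size_um = 4.3) {
  contrast <- 0.8 - 0.1
  with_phantom_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      dirs <- sample(c("+x", "-x", "+y", "-y"), k)
      stations <- sample(c(62, 70, 78, 86), k)
      dia <- sample(seq(8, 24, by = 2), k, replace = TRUE)
      phantom_spec("capped_shaft", outer_radius_vox = 44, length_vox = 140,
                   wall_vox = 28,
                   holes = data.frame(z = stations, dir = dirs,
                                      diameter_vox = dia),
                   noise_sd = stats::runif(1, 0, 0.10) * contrast,
                   voxel_size_um = voxel_size_um,
                   seed = seed * 1000L + i)
    })
  })
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$gray$data)
  cat(sprintf("<phantom> %s, %d x %d x %d, %d bone voxels, %d hole(s)\n",
              x$spec$shape, d[1], d[2], d[3], sum(x$mask),
              nrow(x$truth$holes)))
  invisible(x)
}
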