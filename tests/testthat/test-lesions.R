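test_that("surface area matches closed forms", {
  s <- 2
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  v1 <- voxel_volume(single, s)
  expect_equal(as.numeric(surface_area(v1)), 6 * s^2 * 2 / 3)   # = 4 s^2
  expect_equal(as.numeric(surface_area(v1, corrected = FALSE)), 6 * s^2)

  cub <- array(FALSE, c(10, 12, 14)); cub[3:6, 3:9, 3:10] <- TRUE  # 4 x 7 x 8
  v2 <- voxel_volume(cub, s)
  expect_equal(as.numeric(surface_area(v2)),
               2 * (4 * 7 + 7 * 8 + 8 * 4) * s^2 * 2 / 3)

  # digitised ball of radius 20: corrected area within 10% of 4 pi r^2
  m <- array(FALSE, c(45, 45, 45)); m[23, 23, 23] <- TRUE
  ball <- voxel_volume(brute_dilate(m, 20L), 1)
  expect_lt(abs(as.numeric(surface_area(ball)) - 4 * pi * 400) / (4 * pi * 400),
            0.1)
  expect_error(surface_area(voxel_volume(array(FALSE, c(2, 2, 2)), 1)), "empty")
})

test_that("an enclosed cavity is not part of the surface", {
  shell <- array(TRUE, c(12, 12, 12))
  shell[4:9, 4:9, 4:9] <- FALSE               # enclosed cavity
  v <- voxel_volume(shell, 1)
  expect_equal(as.numeric(surface_area(v, corrected = FALSE)),
               6 * 12 * 12)                   # outer faces only
})

test_that("identical volumes give zero lesions and zero percent", {
  blob <- random_blob(c(16, 16, 16), k = 3, seed = 4)
  v <- voxel_volume(blob, 1)
  rep <- detect_lesions(v, v, recon_params(8))
  expect_identical(nrow(rep$lesions), 0L)
  expect_identical(rep$lesion_percent, 0)
  expect_error(detect_lesions(expand_volume(v, recon_params(8)), v,
                              recon_params(8)), "superset")
})

test_that("slab holes are found, ordered by size, with analytic cap areas", {
  s <- 4.3
  # wall must exceed both cap dips (2 * (r - sqrt(r^2 - a^2)) = 10.7 at
  # a = 10, r = 12) for the larger hole to seal
  sw <- slab_with_holes(thickness = 16, side = 72, margin = 14,
                        holes = data.frame(y = c(20, 52), x = c(20, 52),
                                           dia = c(10, 20)))
  v <- voxel_volume(sw$mask, s)
  pr <- recon_params(24 * s)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  expect_identical(nrow(rep$lesions), 2L)
  # sorted: the 20-voxel hole first
  expect_false(is.unsorted(rev(rep$lesions$cap_area_um2)))
  ana <- pi * c(10, 5)^2 * s^2
  expect_true(all(abs(rep$lesions$cap_area_um2 - ana) / ana < 0.2))
  expect_true(all(rep$lesions$fill_vox > 0))
})

test_that("a vessel canal below min_lesion_vox is not reported", {
  sp <- phantom_spec("capped_shaft", outer_radius_vox = 22, length_vox = 72,
                     wall_vox = 6,
                     holes = data.frame(z = 30, dir = "+x", diameter_vox = 10),
                     vessel = list(z = 44, dir = "-y", diameter_vox = 2),
                     seed = 3)
  ph <- make_phantom(sp)
  v <- select_component(threshold_volume(ph$gray, ph$threshold))
  # the 2-voxel vessel fills ~2 x 6 voxels; a size floor above that hides it
  pr <- recon_params(12 * sp$voxel_size_um, min_lesion_vox = 40)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  expect_identical(nrow(rep$lesions), 1L)
  expect_true(ph$truth$holes$vessel[2])
  # with the size floor removed, the vessel appears too
  pr0 <- recon_params(12 * sp$voxel_size_um, min_lesion_vox = 0)
  rep0 <- detect_lesions(v, reconstruct(v, pr0)$volume, pr0)
  expect_gte(nrow(rep0$lesions), 2L)
})

test_that("deselection recomputes totals, keeps records, and restores", {
  sw <- slab_with_holes(thickness = 8, side = 64, margin = 12,
                        holes = data.frame(y = c(16, 32, 48), x = c(16, 40, 16),
                                           dia = c(6, 10, 14)))
  v <- voxel_volume(sw$mask, 1)
  pr <- recon_params(18)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  expect_identical(nrow(rep$lesions), 3L)
  a <- rep$lesions$cap_area_um2

  smallest <- rep$lesions$id[3]
  d1 <- deselect(rep, smallest)
  expect_identical(nrow(d1$lesions), 3L)            # record retained
  expect_equal(d1$total_lesion_area_um2, sum(a[1:2]))
  expect_equal(d1$lesion_percent,
               100 * sum(a[1:2]) / rep$bone_surface_area_um2)

  all_off <- deselect(rep, rep$lesions$id)
  expect_identical(all_off$total_lesion_area_um2, 0)
  expect_identical(all_off$lesion_percent, 0)

  restored <- deselect(all_off, integer(0), restore = TRUE)
  expect_identical(restored$total_lesion_area_um2, rep$total_lesion_area_um2)
  expect_error(deselect(rep, 99L), "unknown")
})

test_that("picking returns the lesion at or near a point", {
  sw <- slab_with_holes(thickness = 8, side = 64, margin = 12,
                        holes = data.frame(y = c(16, 48), x = c(16, 48),
                                           dia = c(8, 14)))
  v <- voxel_volume(sw$mask, 1)
  pr <- recon_params(18)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  zmid <- sw$zr[4]
  inside_big <- c(zmid, sw$margin + 48, sw$margin + 48)
  expect_identical(pick_lesion(rep, inside_big), 1L)
  inside_small <- c(zmid, sw$margin + 16, sw$margin + 16)
  expect_identical(pick_lesion(rep, inside_small), 2L)
  # nearby background within d_max/2 resolves to the nearest lesion
  expect_identical(pick_lesion(rep, c(zmid, sw$margin + 16, sw$margin + 22)), 2L)
  # far background: not found
  expect_identical(pick_lesion(rep, c(1, 1, 1)), NA_integer_)
  expect_error(pick_lesion(rep, c(0, 1, 1)), "outside")
})

test_that("min_lesion_vox = 0 reports every exposed difference component", {
  sw <- slab_with_holes(thickness = 6, side = 40, margin = 10,
                        holes = data.frame(y = c(12, 28), x = c(12, 28),
                                           dia = c(4, 6)))
  v <- voxel_volume(sw$mask, 1)
  pr <- recon_params(10, min_lesion_vox = 0)
  rec <- reconstruct(v, pr)
  rep <- detect_lesions(v, rec$volume, pr)
  dif <- rec$volume$mask & !v$mask
  lab <- cortlesion:::label_volume(dif, 26L)
  expect_identical(nrow(rep$lesions), max(lab))
})

test_that("lesion counts and areas are invariant under translation and rotation", {
  sw <- slab_with_holes(thickness = 8, side = 48, margin = 14,
                        holes = data.frame(y = c(14, 34), x = c(20, 30),
                                           dia = c(8, 12)))
  v <- voxel_volume(sw$mask, 1)
  pr <- recon_params(16)
  base <- detect_lesions(v, reconstruct(v, pr)$volume, pr)

  shifted <- cortlesion:::shift_mask(sw$mask, c(2, -3, 4))
  vs <- voxel_volume(shifted, 1)
  rs <- detect_lesions(vs, reconstruct(vs, pr)$volume, pr)
  expect_identical(rs$lesions$cap_area_um2, base$lesions$cap_area_um2)
  expect_identical(rs$lesions$fill_vox, base$lesions$fill_vox)

  rot <- rot90_z(sw$mask)
  vr <- voxel_volume(rot, 1)
  rr <- detect_lesions(vr, reconstruct(vr, pr)$volume, pr)
  expect_identical(sort(rr$lesions$cap_area_um2),
                   sort(base$lesions$cap_area_um2))
  expect_identical(sort(rr$lesions$fill_vox), sort(base$lesions$fill_vox))
  expect_equal(rr$lesion_percent, base$lesion_percent, tolerance = 1e-12)
})
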