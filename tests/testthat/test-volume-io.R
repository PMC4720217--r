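test_that("slice-stack reading preserves shape, order and voxel size", {
  td <- withr::local_tempdir()
  # three slices with distinct constant intensities, named to exercise the
  # natural sort (slice2 must come before slice10); PNG slices are 8-bit
  vals <- c(10, 20, 30) / 255
  names <- c("slice1.png", "slice2.png", "slice10.png")
  for (i in 1:3)
    png::writePNG(matrix(vals[i], 16, 12), file.path(td, names[i]))
  g <- read_stack(td, voxel_size_um = 4.3)
  expect_s3_class(g, "gray_volume")
  expect_identical(dim(g$data), c(3L, 16L, 12L))
  expect_equal(g$voxel_size_um, 4.3)
  expect_equal(g$data[, 1, 1], vals, tolerance = 1e-7)
})

test_that("single-slice stacks are valid and inconsistent stacks error", {
  td <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(td, "only.png"))
  g <- read_stack(td, 1)
  expect_identical(dim(g$data), c(1L, 8L, 8L))

  png::writePNG(matrix(0.5, 4, 4), file.path(td, "other.png"))
  expect_error(read_stack(td, 1), "inconsistent")
  expect_error(read_stack(file.path(td, "missing_dir"), 1), "does not exist")
})

test_that("write_stack / read_stack round-trips 16-bit data exactly", {
  td <- withr::local_tempdir()
  set.seed(42)
  raw <- array(round(runif(5 * 10 * 8) * 65535) / 65535, c(5, 10, 8))
  g <- gray_volume(raw, 2.5)
  write_stack(g, file.path(td, "s"), format = "tiff")
  g2 <- read_stack(file.path(td, "s"), 2.5)
  expect_equal(g2$data, g$data, tolerance = 0)
})

test_that("multipage TIFF and NIfTI volumes load", {
  td <- withr::local_tempdir()
  set.seed(7)
  raw <- array(round(runif(4 * 6 * 5) * 65535) / 65535, c(4, 6, 5))
  pages <- lapply(1:4, function(i) matrix(raw[i, , ], 6, 5))
  f <- file.path(td, "vol.tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 16L)
  g <- read_stack(f, 1)
  expect_equal(g$data, raw, tolerance = 0)

  fn <- file.path(td, "vol.nii")
  RNifti::writeNifti(RNifti::asNifti(aperm(raw, c(3, 2, 1))), fn)
  gn <- read_stack(fn, 1)
  expect_equal(gn$data, raw, tolerance = 1e-6)
})

test_that("label volumes round-trip exactly and overflow errors", {
  td <- withr::local_tempdir()
  lab <- array(0L, c(3, 5, 4))
  lab[1, 1:2, 1] <- 1L; lab[3, 4:5, 2:3] <- 2L
  f <- file.path(td, "lab.tif")
  write_labels(lab, f)
  expect_identical(read_labels(f), lab)

  zero <- array(0L, c(2, 3, 3))
  write_labels(zero, f)
  expect_identical(read_labels(f), zero)

  lab[1, 1, 1] <- 70000L
  expect_error(write_labels(lab, f), "16-bit")
})

test_that("reports round-trip with full precision and sorted rows", {
  sw <- slab_with_holes(holes = data.frame(y = c(14, 34), x = c(14, 34),
                                           dia = c(8, 14)))
  v <- voxel_volume(sw$mask, 4.3)
  pr <- recon_params(16 * 4.3)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  expect_gt(nrow(rep$lesions), 1)
  expect_false(is.unsorted(rev(rep$lesions$cap_area_um2)))

  td <- withr::local_tempdir()
  write_report(rep, file.path(td, "r"))
  back <- read_report(file.path(td, "r"))
  expect_identical(back$lesions$cap_area_um2, rep$lesions$cap_area_um2)
  expect_identical(back$lesions$id, rep$lesions$id)
  expect_identical(back$total_lesion_area_um2, rep$total_lesion_area_um2)
  expect_identical(back$lesion_percent, rep$lesion_percent)
  # CSV rows are sorted descending by cap area
  csv <- utils::read.csv(file.path(td, "r.csv"), comment.char = "#")
  expect_false(is.unsorted(rev(csv$cap_area_um2)))
})

test_that("an empty report writes a header-only table with zero totals", {
  sw <- slab_with_holes(holes = data.frame(y = 24, x = 24, dia = 0)[0, ])
  v <- voxel_volume(sw$mask, 1)
  pr <- recon_params(12)
  rep <- detect_lesions(v, v, pr)   # reconstructed = original: nothing
  expect_identical(nrow(rep$lesions), 0L)
  expect_identical(rep$total_lesion_area_um2, 0)
  expect_identical(rep$lesion_percent, 0)
  td <- withr::local_tempdir()
  write_report(rep, file.path(td, "empty"))
  back <- read_report(file.path(td, "empty"))
  expect_identical(nrow(back$lesions), 0L)
  expect_identical(back$total_lesion_area_um2, 0)
})

test_that("report totals equal the sum over included lesions to 1e-9", {
  sw <- slab_with_holes(holes = data.frame(y = c(12, 24, 36), x = c(12, 30, 14),
                                           dia = c(6, 10, 12)))
  v <- voxel_volume(sw$mask, 4.3)
  pr <- recon_params(16 * 4.3)
  rep <- detect_lesions(v, reconstruct(v, pr)$volume, pr)
  expect_equal(rep$total_lesion_area_um2,
               sum(rep$lesions$cap_area_um2[rep$lesions$included]),
               tolerance = 1e-9)
})
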