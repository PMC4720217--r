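#' Read a micro-CT slice stack or single-file volume
#'
#' Accepts either a directory of equally-sized 2-D grayscale images (PNG or
#' TIFF; one image per axial slice, ordered by natural filename sort so that
#' `slice2 < slice10`) or a single file: a multipage TIFF or a NIfTI volume.
#' Intensities are returned exactly as the decoder produces them (PNG/TIFF
#' readers scale integer samples to `[0, 1]`).
#'
#' @param path Directory of slice images, or a single `.tif`/`.tiff`,
#'   `.nii`/`.nii.gz` file.
#' @param voxel_size_um Isotropic voxel size in micrometres (anisotropic
#'   voxels are not supported).
#' @return A [gray_volume()] with `data` of shape `(n_slices, H, W)`.
#' @export
read_stack <- function(path, voxel_size_um) {
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no slice images (.png/.tif) found in ", path)
    files <- files[natural_order(basename(files))]
    slices <- lapply(files, read_slice_image)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent slice dimensions across the stack")
    vol <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) vol[i, , ] <- slices[[i]]
    return(gray_volume(vol, voxel_size_um, source = path))
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.array(pages) && !is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, collapse_channels)
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent page dimensions in multipage TIFF")
    vol <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
    for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
    return(gray_volume(vol, voxel_size_um, source = path))
  }
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L) stop("NIfTI volume must be 3-D")
    # NIfTI stores (x, y, z); permute to (slice, row, col) = (z, y, x)
    vol <- aperm(a, c(3, 2, 1))
    return(gray_volume(vol, voxel_size_um, source = path))
  }
  stop("unsupported volume format: ", path,
       " (expected slice directory, multipage TIFF, or NIfTI)")
}

read_slice_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
                png = png::readPNG(f),
                tif = ,
                tiff = tiff::readTIFF(f),
                stop("unsupported slice format: ", f))
  collapse_channels(img)
}

collapse_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale from channel 1
  img
}

# natural ("version number") sort order: file2 < file10
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m),
                               function(v) sprintf("%020.0f", as.numeric(v)))
    s
  }, character(1))
  order(keys, method = "radix")
}

#' Write a grayscale volume as a slice stack
#'
#' One grayscale image per axial slice: 16-bit TIFF or 8-bit PNG.
#' Intensities are clipped to `[0, 1]` and quantised to the sample depth,
#' matching what [read_stack()] returns; data already on the 16-bit lattice
#' round-trips exactly through the TIFF format.
#'
#' @param gray A [gray_volume()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @param prefix Filename prefix; slices are numbered with leading zeros.
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(gray, dir, format = c("tiff", "png"), prefix = "slice") {
  stopifnot_gray_volume(gray)
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(gray$data)
  depth <- if (format == "tiff") 65535 else 255
  q <- round(pmin(pmax(gray$data, 0), 1) * depth) / depth
  ext <- if (format == "tiff") "tif" else "png"
  files <- file.path(dir, sprintf("%s%0*d.%s", prefix, nchar(d[1]) + 1L,
                                  seq_len(d[1]), ext))
  for (i in seq_len(d[1])) {
    m <- matrix(q[i, , ], d[2], d[3])
    if (format == "tiff") tiff::writeTIFF(m, files[i], bits.per.sample = 16L)
    else png::writePNG(m, files[i])
  }
  invisible(files)
}

#' Write / read a label volume as multipage TIFF
#'
#' Integer labels (0 = background) are stored losslessly in a 16-bit
#' multipage TIFF, one page per axial slice.
#'
#' @param labels 3-D integer array `(slice, row, col)`, values in
#'   `0..65535`.
#' @param path Output `.tif` path.
#' @return `write_labels()`: invisibly `path`. `read_labels()`: the integer
#'   label array.
#' @export
write_labels <- function(labels, path) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D integer array")
  if (anyNA(labels) || any(labels < 0)) stop("labels must be non-negative integers")
  mx <- max(labels)
  if (mx > 65535) stop("label ", mx, " exceeds the 16-bit representable range (65535)")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1]), function(i)
    matrix(labels[i, , ] / 65535, d[2], d[3]))
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write labels to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  lab <- array(0L, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) lab[i, , ] <- as.integer(pages[[i]])
  lab
}
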