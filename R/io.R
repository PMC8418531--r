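# Minimal uncompressed little-endian single-strip float32 TIFF writer.
# The CRAN tiff package reads float TIFFs but only writes integer samples
# scaled from [0,1]; ratio maps need true float storage.
.write_float_tiff <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  data <- as.numeric(t(m))          # TIFF scanline (row-major) order
  nbytes <- 4L * length(data)
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + nbytes, con, size = 4, endian = "little")   # IFD offset
  writeBin(data, con, size = 4, endian = "little")          # float32 samples
  writeBin(10L, con, size = 2, endian = "little")           # entry count
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: value in low 2 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  entry(256, 4, 1, ncol(m))    # ImageWidth
  entry(257, 4, 1, nrow(m))    # ImageLength
  entry(258, 3, 1, 32)         # BitsPerSample
  entry(259, 3, 1, 1)          # Compression: none
  entry(262, 3, 1, 1)          # Photometric: BlackIsZero
  entry(273, 4, 1, 8)          # StripOffsets
  entry(277, 3, 1, 1)          # SamplesPerPixel
  entry(278, 4, 1, nrow(m))    # RowsPerStrip
  entry(279, 4, 1, nbytes)     # StripByteCounts
  entry(339, 3, 1, 3)          # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")            # no next IFD
  invisible(path)
}

#' Read a single-channel image from TIFF
#'
#' The plane is converted to a double matrix with raw count values (no
#' 0..1 rescaling). Multi-page stacks require a `page` index; RGB images
#' are rejected.
#'
#' @param path TIFF file (uint8 / uint16 / float32).
#' @param page 1-based page index for stacks.
#' @return numeric matrix with attribute `source_bits`.
#' @export
read_channel <- function(path, page = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  # as.is = TRUE returns raw integer counts; float samples are read as-is
  # but readTIFF refuses as.is for them, so fall back
  pages <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                    error = function(e) {
                      if (grepl("floating point", conditionMessage(e)))
                        tiff::readTIFF(path, all = TRUE)
                      else stop(e)
                    })
  if (length(pages) > 1 && is.null(page))
    stop("multi-page TIFF with ", length(pages),
         " pages: pass a page index")
  img <- pages[[if (is.null(page)) 1L else page]]
  if (length(dim(img)) == 3L)
    stop("RGB/multi-sample input not supported: expected a single-channel plane")
  bits <- attr(img, "bits.per.sample")
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  attr(img, "source_bits") <- bits
  img
}

#' Write a single-channel image to TIFF
#'
#' `float32` stores values exactly; `uint16` rounds and clips to
#' [0, 65535], so algebraic exactness then holds only to half a count.
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  .check_image(image)
  if (dtype == "float32") {
    .write_float_tiff(image, path)
  } else {
    x <- round(image)
    if (any(x < 0 | x > 65535))
      warning("values clipped to [0, 65535] for uint16 export")
    if (any(abs(image - x) > 0))
      warning("values rounded for uint16 export: exactness holds only to +/- 0.5 counts")
    x <- pmin(pmax(x, 0), 65535)
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Read a binary mask from TIFF or PNG
#'
#' Any nonzero pixel is foreground.
#'
#' @param path single-plane TIFF or PNG.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(img != 0, nrow(img), ncol(img))
}

#' Write a binary mask as an 8-bit TIFF (255 = foreground)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- .as_mask(mask)
  tiff::writeTIFF((mask * 255) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Export a region set
#'
#' Multi-page 8-bit TIFF (mask, interior, bg_ring) plus a text sidecar
#' with the bg_box coordinates and depths.
#'
#' @param regions a `region_set`.
#' @param path output TIFF path; the sidecar is `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  pages <- lapply(list(regions$mask, regions$interior, regions$bg_ring),
                  function(m) (m * 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  side <- c(sprintf("depth_in\t%g", regions$depth_in),
            sprintf("depth_out\t%g", regions$depth_out),
            if (!is.null(regions$bg_box))
              sprintf("bg_box\t%s", paste(regions$bg_box, collapse = "\t")))
  writeLines(side, paste0(path, ".txt"))
  invisible(path)
}

#' Subtract the camera dark current
#'
#' @param image,dark numeric matrices of equal shape.
#' @return corrected matrix (negative values permitted; float pipeline).
#' @export
dark_current_correct <- function(image, dark) {
  .check_image(image); .check_image(dark, "dark")
  if (!all(dim(image) == dim(dark))) stop("image and dark frame differ in shape")
  image - dark
}

#' Flat-field shading correction
#'
#' The reference (an image of a uniform dye solution) is normalized to
#' mean intensity 1 and the image is divided by it pixelwise.
#'
#' @param image numeric matrix (already dark-corrected).
#' @param reference strictly positive numeric matrix.
#' @return corrected matrix.
#' @export
shading_correct <- function(image, reference) {
  .check_image(image); .check_image(reference, "reference")
  if (!all(dim(image) == dim(reference))) stop("image and reference differ in shape")
  if (any(reference <= 0)) stop("shading reference must be strictly positive")
  image / (reference / mean(reference))
}

#' Write a synthetic scene to disk
#'
#' Writes `img1.tif`, `img2.tif` (float32), `mask_true.tif`, and
#' `truth.json` (all generative parameters and the seed).
#'
#' @param scene an `ncf_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "ncf_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_channel(scene$img1, file.path(dir, "img1.tif"))
  write_channel(scene$img2, file.path(dir, "img2.tif"))
  write_mask(scene$truth$mask_true, file.path(dir, "mask_true.tif"))
  sp <- scene$spec
  truth <- list(shape = sp$shape,
                cells = sp$cells, ramp_width = sp$ramp_width,
                s2_plateau = sp$s2_plateau, a0 = sp$a0,
                B1 = sp$B1, B2 = sp$B2,
                noise_sigma1 = sp$noise_sigma1, noise_sigma2 = sp$noise_sigma2,
                seed = sp$seed,
                true_ncf = scene$truth$true_ncf)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
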