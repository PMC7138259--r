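# PNG/TIFF reading and writing. Images are held in memory as H x W x 3
# numeric arrays in [0, 1]; masks as integer 0/1 matrices.

#' Read an 8-bit image as an H x W x 3 array in \[0, 1\]
#'
#' PNG and TIFF are supported (by extension). Grayscale input is replicated
#' to three channels; an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return numeric `H x W x 3` array with values in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- read_raw_image(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 1L) {
    img <- array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] >= 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

read_raw_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: .", ext, " (use PNG or TIFF)")
}

#' Write an image array or matrix to PNG/TIFF
#'
#' @param img numeric matrix or `H x W x 3` array in \[0, 1\].
#' @param path output path; format chosen by extension.
#' @param bits bits per sample for TIFF output (8 or 16); PNG is 8-bit.
#' @export
write_image <- function(img, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  img <- clip01(img)
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a single-channel mask file and binarize it
#'
#' Any nonzero pixel becomes foreground, which tolerates both 0/1 and 0/255
#' mask dialects. Multi-channel mask files use their first channel.
#'
#' @param path mask file path (PNG or TIFF).
#' @return integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- read_raw_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  as_mask(m)
}

#' @rdname read_mask
#' @param mask integer/logical matrix; nonzero means foreground.
#' @export
write_mask <- function(mask, path) {
  write_image(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
}

# Conventional mask file name: <image_stem>.<short_label>.png
mask_filename <- function(image_stem, label) paste0(image_stem, ".", label, ".png")
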