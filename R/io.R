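#' Read a grayscale TIFF image as a numeric matrix
#'
#' Images are held in memory as plain numeric matrices scaled to `[0, 1]`
#' (rows = image rows). Masks written by this package are 8-bit `{0, 255}`
#' TIFFs; [read_mask()] maps them back to `{0, 1}`.
#'
#' @param path Path to a single-page grayscale TIFF.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L] # drop extra channels
  img
}

#' @rdname read_image
#' @return For `read_mask`, an integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- matrix(as.integer(img > 0.5), nrow(img), ncol(img))
  m
}

#' Write a grayscale image or a binary mask as an 8-bit TIFF
#'
#' @param img Numeric matrix in `[0, 1]` (values are clipped and quantized
#'   to 8-bit) or, for `write_mask`, a 0/1 matrix written as `{0, 255}`.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(img, path) {
  check_binary_mask(img)
  tiff::writeTIFF(img * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a raw/mask image pair with the standard naming convention
#'
#' Writes `<stem>.tif` (8-bit raw) and `<stem>_mask.tif` (8-bit 0/255 mask).
#'
#' @param pair An `image_pair` as returned by [generate_image()].
#' @param dir Output directory (created if missing).
#' @param stem File stem.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_image_pair <- function(pair, dir, stem) {
  stopifnot(inherits(pair, "image_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw_path <- file.path(dir, paste0(stem, ".tif"))
  mask_path <- file.path(dir, paste0(stem, "_mask.tif"))
  write_image(pair$raw, raw_path)
  write_mask(pair$mask, mask_path)
  invisible(c(raw = raw_path, mask = mask_path))
}
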