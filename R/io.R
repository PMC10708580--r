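# Image and mask I/O.  Canonical on-disk format: 8-bit grayscale PNG.
# Images map to [0,1] by v/255; masks are stored as {0,255} and binarized
# at 128 on read.  All writes are atomic (write-temp-then-rename).

atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Load a grayscale image
#'
#' Reads a PNG and maps 8-bit values to `[0, 1]`.  RGB(A) input is
#' converted to grayscale (channel mean) with a warning; 16-bit input is
#' accepted and rescaled.
#'
#' @param path PNG file path.
#' @return A matrix with values in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read PNG '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    warning("multi-channel image ", path, " converted to grayscale")
    img <- apply(img[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Save a grayscale image as 8-bit PNG
#'
#' Values are clipped to `[0, 1]` and quantized to 8 bits; reading the file
#' back reproduces the quantized image exactly.
#'
#' @param img Matrix with values in `[0, 1]`.
#' @param path Output path.
#' @export
save_image <- function(img, path) {
  q <- round(clamp01(img) * 255) / 255
  atomic_write(path, function(p) png::writePNG(q, p))
}

#' Load a binary artifact mask
#'
#' Reads a PNG and binarizes at the 8-bit threshold 128: stored values
#' below 128 become 0 (known pixels), values of 128 and above become 1
#' (repair region).
#'
#' @param path PNG file path.
#' @return A binary matrix with values in `{0, 1}`.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  (round(img * 255) >= 128) * 1
}

#' Save a binary mask as 8-bit PNG
#'
#' @param mask Binary matrix (1 = repair region); stored as `{0, 255}`.
#' @param path Output path.
#' @export
save_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  save_image(mask, path)
}
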