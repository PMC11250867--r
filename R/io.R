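#' Read and write 8-bit RGB images
#'
#' Thin wrappers over the png (and, when installed, tiff) readers that
#' convert to/from the package's `height x width x 3` array convention
#' with values in `[0, 255]`.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_rgb_image()` returns the RGB array; `write_rgb_image()`
#'   returns `path` invisibly.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  array(round(raw * 255), dim = dim(raw))
}

#' @rdname read_rgb_image
#' @param image RGB array in `[0, 255]`.
#' @export
write_rgb_image <- function(image, path) {
  assert_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image / 255, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
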