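#' Three-channel 8-bit color image container
#'
#' A `fundus_image` holds the red, green and blue channels of a retina
#' photograph as numeric matrices of identical shape with values in
#' \[0, 255\] (row = image row, column = image column, origin top-left).
#'
#' @param red,green,blue Numeric matrices of identical dimensions with finite
#'   values in \[0, 255\].
#' @return An object of class `fundus_image` with elements `red`, `green`,
#'   `blue`, `height`, `width`.
#' @export
fundus_image <- function(red, green, blue) {
  if (!is.matrix(red) || !is.matrix(green) || !is.matrix(blue))
    stop("channels must be matrices")
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stop("all three channels must share one shape")
  for (ch in list(red, green, blue)) {
    if (!all(is.finite(ch))) stop("channel values must be finite")
    if (min(ch) < 0 || max(ch) > 255) stop("channel values must lie in [0, 255]")
  }
  structure(
    list(red = red, green = green, blue = blue,
         height = nrow(red), width = ncol(red)),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image %d x %d, channel means R=%.1f G=%.1f B=%.1f>\n",
              x$height, x$width, mean(x$red), mean(x$green), mean(x$blue)))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) c(x$height, x$width)

channel_mean_image <- function(image) {
  (image$red + image$green + image$blue) / 3
}

#' Read a color fundus image from disk
#'
#' Decodes PNG, TIFF or JPEG into an 8-bit RGB [fundus_image()]. An alpha
#' channel, if present, is dropped. Greyscale (single-channel) inputs are
#' rejected: the pipeline needs all three color channels.
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG, TIFF and JPEG are supported)")
  )
  if (length(dim(arr)) == 2L || (length(dim(arr)) == 3L && dim(arr)[3] < 3L))
    stop("greyscale image rejected: ", path, " (an RGB fundus image is required)")
  fundus_image(
    red   = round(arr[, , 1] * 255),
    green = round(arr[, , 2] * 255),
    blue  = round(arr[, , 3] * 255)
  )
}

#' Write a color image to disk
#'
#' Writes PNG (default) or TIFF, preserving the input dimensions.
#'
#' @param image A [fundus_image()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  arr <- array(0, dim = c(image$height, image$width, 3L))
  arr[, , 1] <- image$red / 255
  arr[, , 2] <- image$green / 255
  arr[, , 3] <- image$blue / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path),
    stop("unsupported output format '", ext, "' (PNG and TIFF are supported)")
  )
  invisible(path)
}

#' Write a real-valued surface as a 16-bit greyscale TIFF
#'
#' Used to dump intermediate surfaces (background brightness, adjusted
#' channels) losslessly for inspection. Values are mapped from \[0, 255\] to
#' the 16-bit range by the factor 257, so 8-bit-integral surfaces round-trip
#' exactly.
#'
#' @param surface Numeric matrix with values in \[0, 255\].
#' @param path Output `.tif(f)` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(is.matrix(surface), all(is.finite(surface)))
  v <- pmin(pmax(surface, 0), 255) / 255
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit surface dump back into a matrix
#'
#' @param path Path written by [write_surface()].
#' @return Numeric matrix with values in \[0, 255\].
#' @export
read_surface <- function(path) {
  tiff::readTIFF(path) * 255
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
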