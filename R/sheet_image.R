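#' Sheet image container
#'
#' One fluorescence channel of one paper layer: a 2D raster of non-negative
#' intensities plus the physical pixel size and identifying metadata.
#'
#' Pixel coordinates throughout the package are 0-based, with `x` the column
#' index and `y` the row index, origin at the top-left pixel. The raster is
#' stored as a base matrix indexed `pixels[y + 1, x + 1]`. All geometry is
#' held in micrometres and converted to pixels only at the raster boundary.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_um physical size of one pixel in micrometres (> 0).
#' @param channel channel label, e.g. `"GFP"`, `"mTomato"`, `"calcein"`, `"PI"`.
#' @param layer_id layer label, e.g. `"L1"`.
#' @return An object of class `sheet_image`.
#' @export
sheet_image <- function(pixels, pixel_um, channel = "GFP", layer_id = "L1") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L || pixel_um <= 0)
    stop("`pixel_um` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_um = as.numeric(pixel_um),
         channel = as.character(channel), layer_id = as.character(layer_id)),
    class = "sheet_image")
}

#' @export
print.sheet_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sheet_image> %s / %s: %d x %d px @ %g um/px, range [%g, %g]\n",
              x$layer_id, x$channel, d[2], d[1], x$pixel_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.sheet_image <- function(x) dim(x$pixels)

#' Read a grayscale scan image from TIFF
#'
#' Loads a single-channel TIFF recorded by a fluorescence gel scanner (or any
#' equivalent flat grayscale image) losslessly. Integer sample values are
#' preserved exactly for 8- and 16-bit input.
#'
#' @param path path to a grayscale TIFF file.
#' @param pixel_um physical pixel size in micrometres.
#' @param channel,layer_id metadata labels attached to the image.
#' @return A [sheet_image].
#' @export
read_sheet <- function(path, pixel_um, channel = "GFP", layer_id = "L1") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE, info = FALSE)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) {
      raw <- raw[, , 1L]
    } else {
      stop("format error: '", path, "' has ", dim(raw)[3],
           " samples per pixel; expected a single grayscale channel")
    }
  }
  storage.mode(raw) <- "double"
  sheet_image(raw, pixel_um, channel, layer_id)
}

#' Write a sheet image as a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and clamped to the 16-bit range
#' `[0, 65535]`. Images whose intensities are already 16-bit integers
#' round-trip losslessly through [read_sheet()].
#'
#' @param image a [sheet_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sheet <- function(image, path) {
  stopifnot(inherits(image, "sheet_image"))
  px <- round(image$pixels)
  px[px < 0] <- 0
  px[px > 65535] <- 65535
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
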