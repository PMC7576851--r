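#' Single-channel intensity image with physical pixel size
#'
#' The elementary raster object of the pipeline: one stained channel of one
#' imaged region, stored as a numeric matrix in native intensity units
#' (camera grey levels are never rescaled to 0-1, so gates defined in
#' intensity units transfer across cases), together with the pixel size in
#' micrometres and a channel label ("iba1", "moi", "nuclei", "abeta", ...).
#'
#' Pixel coordinates are 0-based `(row, col)` throughout the package;
#' physical distances are always in micrometres.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_size_um Positive pixel size in micrometres per pixel.
#' @param channel_label Character channel name.
#' @return A `channel_image` object.
#' @export
channel_image <- function(pixels, pixel_size_um, channel_label = "channel") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_histoflow("pixels must be a non-empty 2D numeric matrix")
  }
  if (anyNA(pixels) || min(pixels) < 0) {
    stop_histoflow("pixel intensities must be nonnegative and non-missing")
  }
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    stop_histoflow("pixel_size_um must be a positive number")
  }
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      channel_label = as.character(channel_label)
    ),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> '%s': %d x %d px, %.4g um/px, intensity range [%.4g, %.4g]\n",
    x$channel_label, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Binary mask over an image with physical pixel size
#'
#' @param pixels Logical matrix (TRUE = foreground).
#' @param pixel_size_um Positive pixel size in micrometres per pixel.
#' @param source_label Label naming the staining the mask was derived from.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size_um, source_label = "mask") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_histoflow("mask pixels must be a non-empty 2D matrix")
  }
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels) || anyNA(pixels)) {
    stop_histoflow("mask pixels must be logical (or 0/1) with no missing values")
  }
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    stop_histoflow("pixel_size_um must be a positive number")
  }
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      source_label = as.character(source_label)
    ),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> '%s': %d x %d px, %.4g um/px, %d foreground px (%.2f%%)\n",
    x$source_label, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    sum(x$pixels), 100 * mean(x$pixels)
  ))
  invisible(x)
}

#' Physical foreground area of a mask in square micrometres
#' @param mask A `binary_mask`.
#' @return Area in um^2.
#' @export
mask_area_um2 <- function(mask) {
  sum(mask$pixels) * mask$pixel_size_um^2
}
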