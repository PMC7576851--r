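#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in histoflow route their randomness through this
#' helper so that a seed recorded in a run manifest reproduces the run exactly
#' without clobbering the user's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

stop_histoflow <- function(...) {
  stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_same_geometry <- function(a, b, what_a = "first input", what_b = "second input") {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stop_histoflow(
      sprintf(
        "%s (%d x %d) and %s (%d x %d) have different shapes",
        what_a, nrow(a$pixels), ncol(a$pixels),
        what_b, nrow(b$pixels), ncol(b$pixels)
      )
    )
  }
  if (abs(a$pixel_size_um - b$pixel_size_um) > 1e-12) {
    stop_histoflow(
      sprintf(
        "%s (%g um/px) and %s (%g um/px) have different pixel sizes",
        what_a, a$pixel_size_um, what_b, b$pixel_size_um
      )
    )
  }
  invisible(TRUE)
}

#' Rasterise a disk structuring element
#'
#' The brush contains every pixel whose centre lies within `radius_px` of the
#' central pixel (Euclidean distance, inclusive). Using an explicit raster
#' rather than a pre-smoothed brush keeps morphological dilation consistent
#' with the Euclidean distance transform up to one rasterisation step.
#'
#' @param radius_px Nonnegative integer radius in pixels.
#' @return A (2r+1) x (2r+1) 0/1 matrix.
#' @export
disk_brush <- function(radius_px) {
  radius_px <- as.integer(round(radius_px))
  if (radius_px < 0L) stop_histoflow("disk radius must be nonnegative")
  off <- seq.int(-radius_px, radius_px)
  b <- outer(off, off, function(a, b) (a * a + b * b) <= radius_px^2)
  storage.mode(b) <- "double"
  b
}
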