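#' Tissue-wide integrated intensity of a marker within the master mask
#'
#' Sums the marker intensity over master-mask pixels and normalises by the
#' tissue area of the region of interest, yielding a quantity proportional to
#' the marker concentration in the tissue. The normaliser defaults to the
#' full image area; pass `tissue_area_um2` (e.g. from a user-drawn grey-matter
#' ROI) to restrict it. Background is not subtracted before measurement.
#'
#' @param image Marker [channel_image()].
#' @param master Master [binary_mask()].
#' @param tissue_area_um2 Normalising tissue area in um^2 (default: full
#'   image area).
#' @return Integrated intensity per um^2.
#' @export
tissue_integrated_intensity <- function(image, master, tissue_area_um2 = NULL) {
  stopifnot(inherits(image, "channel_image"), inherits(master, "binary_mask"))
  assert_same_geometry(image, master, "image", "master mask")
  if (is.null(tissue_area_um2)) {
    tissue_area_um2 <- length(image$pixels) * image$pixel_size_um^2
  }
  if (!is_scalar_number(tissue_area_um2) || tissue_area_um2 <= 0) {
    stop_histoflow("tissue_area_um2 must be a positive number")
  }
  sum(image$pixels[master$pixels]) / tissue_area_um2
}

#' Per-cell mean intensity of a channel
#'
#' Arithmetic mean of the channel's pixel values over each labelled cell.
#' The per-cell mean is the single-cell analogue of protein concentration
#' per cell and is the coordinate used for gating.
#'
#' @param cells A `labeled_cells` object.
#' @param image A [channel_image()] of the same geometry.
#' @return Numeric vector of means, one per cell (in `cell_id` order).
#' @export
per_cell_mean_intensity <- function(cells, image) {
  stopifnot(inherits(cells, "labeled_cells"), inherits(image, "channel_image"))
  if (!identical(dim(cells$labels), dim(image$pixels))) {
    stop_histoflow("labels and image have different shapes")
  }
  k <- n_cells(cells)
  if (k == 0L) return(numeric(0))
  idx <- cells$labels > 0L
  sums <- rep(0, k)
  tt <- tapply(image$pixels[idx], cells$labels[idx], sum)
  sums[as.integer(names(tt))] <- as.numeric(tt)
  sums / cells$table$area_px
}

#' Build the per-cell measurement table for one imaged region
#'
#' Combines the labelled master-mask cells with per-channel mean intensities
#' into the tabular form the gating and spatial stages consume
#' (`mean_<channel>` columns, 0-based centroids, physical areas).
#'
#' @param cells A `labeled_cells` object.
#' @param images Named list of [channel_image()]s to measure.
#' @param case_id Case identifier carried into the table.
#' @return A cell-table data.frame.
#' @export
measure_cells <- function(cells, images, case_id = "case") {
  stopifnot(inherits(cells, "labeled_cells"))
  if (!length(images) || is.null(names(images)) || any(names(images) == "")) {
    stop_histoflow("images must be a non-empty named list of channel images")
  }
  tbl <- cbind(data.frame(case_id = rep(case_id, n_cells(cells)),
                          stringsAsFactors = FALSE),
               cells$table)
  for (nm in names(images)) {
    tbl[[paste0("mean_", nm)]] <- per_cell_mean_intensity(cells, images[[nm]])
  }
  tbl
}
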