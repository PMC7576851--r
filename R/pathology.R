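#' Pathology load as percentage area
#'
#' Percentage of the region-of-interest tissue area covered by the
#' amyloid-beta or tau staining mask (generated with
#' [adaptive_threshold()]).
#'
#' @param mask Pathology [binary_mask()].
#' @param roi_area_um2 ROI tissue area in um^2 (default: full image area);
#'   must be at least the mask's foreground area.
#' @return Percent in `[0, 100]`.
#' @export
pathology_load <- function(mask, roi_area_um2 = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- mask_area_um2(mask)
  if (is.null(roi_area_um2)) {
    roi_area_um2 <- length(mask$pixels) * mask$pixel_size_um^2
  }
  if (!is_scalar_number(roi_area_um2) || roi_area_um2 <= 0) {
    stop_histoflow("roi_area_um2 must be a positive number")
  }
  if (roi_area_um2 < fg) {
    stop_histoflow(sprintf(
      "ROI area (%g um^2) is smaller than the mask foreground (%g um^2)",
      roi_area_um2, fg
    ))
  }
  100 * fg / roi_area_um2
}

#' Mean pathology load across sections of a case
#'
#' @param loads_per_section Non-empty numeric vector of per-section percent
#'   loads.
#' @return Arithmetic mean percent load.
#' @export
mean_load <- function(loads_per_section) {
  if (!length(loads_per_section) || !is.numeric(loads_per_section)) {
    stop_histoflow("loads_per_section must be a non-empty numeric vector")
  }
  mean(loads_per_section)
}
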