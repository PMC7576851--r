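#' Flag cells on or touching an amyloid plaque
#'
#' A cell is "on plaque" iff at least one of its pixels overlaps the plaque
#' mask foreground (strict greater-than-zero overlap: a single shared pixel
#' counts).
#'
#' @param cells A `labeled_cells` object.
#' @param plaque_mask Plaque [binary_mask()] of identical geometry.
#' @return Logical vector, one flag per cell in `cell_id` order.
#' @export
assign_plaque_status <- function(cells, plaque_mask) {
  stopifnot(inherits(cells, "labeled_cells"), inherits(plaque_mask, "binary_mask"))
  if (!identical(dim(cells$labels), dim(plaque_mask$pixels))) {
    stop_histoflow("cell labels and plaque mask have different shapes")
  }
  if (abs(cells$pixel_size_um - plaque_mask$pixel_size_um) > 1e-12) {
    stop_histoflow("cell labels and plaque mask have different pixel sizes")
  }
  k <- n_cells(cells)
  flags <- logical(k)
  on <- unique(cells$labels[cells$labels > 0L & plaque_mask$pixels])
  flags[on] <- TRUE
  flags
}

#' Classify cells into plaque-distance bins by incremental dilation
#'
#' The plaque mask is dilated with disks of radius `k * step_um` (k = 1 ..
#' `max_um / step_um`), each dilation applied to the original mask so
#' rasterisation error does not accumulate. A cell not on a plaque takes bin
#' `k * step_um` for the smallest k at which it overlaps the dilated mask
#' (half-open intervals: a cell exactly on a dilation boundary takes the
#' smaller bin); on-plaque cells are bin 0; cells overlapping no dilation
#' are non-plaque. Bins are grouped as `plaque` (0), `plaque-adjacent`
#' (5..50 um by default) and `non-plaque` (beyond `max_um`).
#'
#' @param cells A `labeled_cells` object.
#' @param plaque_mask Plaque [binary_mask()].
#' @param step_um Dilation increment in um (must divide `max_um`).
#' @param max_um Distance at which dilation is discontinued.
#' @return data.frame with `cell_id`, `plaque_bin_um` (0, step, ..., max, or
#'   NA for non-plaque) and `plaque_group`.
#' @export
distance_bins <- function(cells, plaque_mask, step_um = 5, max_um = 50) {
  stopifnot(inherits(cells, "labeled_cells"), inherits(plaque_mask, "binary_mask"))
  if (step_um <= 0 || max_um <= 0 || step_um > max_um) {
    stop_histoflow("need 0 < step_um <= max_um")
  }
  nsteps <- max_um / step_um
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop_histoflow(sprintf("step_um (%g) must divide max_um (%g) exactly", step_um, max_um))
  }
  nsteps <- as.integer(round(nsteps))
  k <- n_cells(cells)
  bin <- rep(NA_real_, k)
  on <- assign_plaque_status(cells, plaque_mask)
  bin[on] <- 0
  ps <- cells$pixel_size_um
  if (any(plaque_mask$pixels)) {
    pm <- plaque_mask$pixels * 1
    for (s in seq_len(nsteps)) {
      unassigned <- which(is.na(bin))
      if (!length(unassigned)) break
      r_px <- round(s * step_um / ps)
      dil <- EBImage::dilate(pm, disk_brush(r_px)) > 0
      hit <- unique(cells$labels[cells$labels > 0L & dil])
      newly <- intersect(hit, unassigned)
      bin[newly] <- s * step_um
    }
  }
  group <- ifelse(is.na(bin), "non-plaque",
                  ifelse(bin == 0, "plaque", "plaque-adjacent"))
  data.frame(cell_id = cells$table$cell_id, plaque_bin_um = bin,
             plaque_group = group, stringsAsFactors = FALSE)
}

#' Summarise cell abundance by plaque-proximity group
#'
#' Per-group (and optionally per-5-um-interval) counts and proportions of
#' total cells; optionally restricted to a gated subpopulation (e.g. the
#' Iba1-low cells) while keeping the full population as denominator, i.e.
#' "percentage of total cells at each spatial location".
#'
#' @param assignments Output of [distance_bins()].
#' @param subset Optional logical vector selecting the subpopulation to
#'   count (same length/order as `assignments`).
#' @param by_bin Also return per-interval proportions.
#' @return List with `groups` (count/proportion per spatial group) and,
#'   when `by_bin = TRUE`, `bins` (per 5-um interval).
#' @export
group_and_summarise <- function(assignments, subset = NULL, by_bin = FALSE) {
  total <- nrow(assignments)
  if (total == 0L) {
    return(list(groups = data.frame(group = character(0), n = integer(0),
                                    proportion = numeric(0))))
  }
  if (is.null(subset)) subset <- rep(TRUE, total)
  if (length(subset) != total) {
    stop_histoflow("subset must match the assignment table length")
  }
  lev <- c("plaque", "plaque-adjacent", "non-plaque")
  counted <- assignments$plaque_group[subset]
  groups <- data.frame(
    group = lev,
    n = vapply(lev, function(g) sum(counted == g), integer(1)),
    proportion = vapply(lev, function(g) sum(counted == g), integer(1)) / total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(groups = groups)
  if (by_bin) {
    bins <- sort(unique(assignments$plaque_bin_um[!is.na(assignments$plaque_bin_um)]))
    bl <- assignments$plaque_bin_um[subset]
    out$bins <- data.frame(
      bin_um = c(bins, NA),
      n = c(vapply(bins, function(b) sum(bl == b, na.rm = TRUE), integer(1)),
            sum(is.na(bl))),
      row.names = NULL
    )
    out$bins$proportion <- out$bins$n / total
  }
  out
}
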