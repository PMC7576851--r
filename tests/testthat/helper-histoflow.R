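# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

# A small, fast three-population field configuration.
small_case_config <- function(seed = 42, n_cells = 60, noise_sd = 2,
                              n_plaques = 3, image_size_px = c(256L, 256L),
                              cell_radius_um = c(2, 4), ...) {
  simulation_config(
    image_size_px = image_size_px, n_cells = n_cells, noise_sd = noise_sd,
    cell_radius_um = cell_radius_um,
    n_plaques = n_plaques, plaque_radius_um = c(8, 15), seed = seed, ...
  )
}

# Quadrant gates at the true decision boundaries of the default populations
# (geometric means of the low/high log-normal location parameters).
default_truth_gates <- function(xmax = 4000, ymax = 4000) {
  boundary_gates("iba1", "moi", sqrt(30 * 120), sqrt(25 * 110),
                 c(0, xmax), c(0, ymax))
}

# Map default population names to the quadrant gate names.
default_pop_to_gate <- c(
  iba1low_moihigh = "lowx_highy",
  iba1high_moihigh = "highx_highy",
  iba1high_moilow = "highx_lowy"
)

# Segment a synthetic case with the standard window/offset and measure it.
segment_and_measure <- function(case, channels = c("iba1", "moi"),
                                window_px = 63L, offset = 5,
                                min_area_um2 = 5) {
  masks <- lapply(channels, function(ch) {
    adaptive_threshold(case$images[[ch]], window_px, offset)
  })
  cells <- label_cells(master_mask(masks), min_area_um2)
  list(cells = cells,
       table = measure_cells(cells, case$images[channels], "sim"))
}

# Match measured cells to ground-truth cells by nearest centroid.
match_to_truth <- function(table, truth_cells) {
  d2 <- outer(table$centroid_row, truth_cells$centroid_row, `-`)^2 +
    outer(table$centroid_col, truth_cells$centroid_col, `-`)^2
  apply(d2, 1, which.min)
}

# A binary mask with disks painted at the given 1-based centres.
disk_mask <- function(dim_px, centers, radii_px, pixel_size_um = 0.5,
                      label = "disks") {
  m <- matrix(0, dim_px[1], dim_px[2])
  for (i in seq_len(nrow(centers))) {
    m <- histoflow:::paint_disk(m, centers[i, 1], centers[i, 2], radii_px[i], 1)
  }
  binary_mask(m > 0, pixel_size_um, label)
}
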