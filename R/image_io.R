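#' Read a single-channel TIFF as a channel_image
#'
#' Integer (8- or 16-bit) TIFFs are read in native grey levels without any
#' rescaling: an 8-bit file whose brightest pixel is 255 yields a raster whose
#' maximum is 255.0. The pixel size always comes from the `pixel_size_um`
#' argument; TIFF resolution metadata, when present and conflicting, triggers
#' a warning but the argument wins (microscope export pipelines routinely
#' write wrong or unit-less resolution tags).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param channel_label Channel name to attach.
#' @param page For multi-page TIFFs, 1-based page index to read.
#' @return A [channel_image()].
#' @export
read_channel <- function(path, pixel_size_um, channel_label = "channel", page = NULL) {
  if (!file.exists(path)) stop_histoflow(sprintf("cannot read image: no such file '%s'", path))
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE)
  if (length(pages) > 1L && is.null(page)) {
    stop_histoflow(sprintf(
      "'%s' is a multi-page TIFF with %d pages; select one with page = 1..%d",
      path, length(pages), length(pages)
    ))
  }
  if (is.null(page)) page <- 1L
  if (page < 1L || page > length(pages)) {
    stop_histoflow(sprintf("page %d out of range (file has %d pages)", page, length(pages)))
  }
  px <- pages[[page]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) {
      px <- px[, , 1L]
    } else {
      stop_histoflow(sprintf(
        "'%s' has %d samples per pixel; write one channel per file (channels 1..%d available)",
        path, dim(px)[3], dim(px)[3]
      ))
    }
  }
  info <- attr(px, "info")
  if (!is.null(info) && !is.null(info$x.resolution) && !is.null(info$res.unit)) {
    meta_um <- switch(as.character(info$res.unit),
      "inch" = 25400 / info$x.resolution,
      "cm"   = 10000 / info$x.resolution,
      NULL
    )
    if (!is.null(meta_um) && is.finite(meta_um) &&
        abs(meta_um - pixel_size_um) / pixel_size_um > 0.01) {
      warning(sprintf(
        "TIFF metadata implies %.4g um/px but argument says %.4g um/px; using the argument",
        meta_um, pixel_size_um
      ), call. = FALSE)
    }
  }
  px <- matrix(as.numeric(px), nrow = nrow(px), ncol = ncol(px))
  channel_image(px, pixel_size_um, channel_label)
}

#' Write a channel_image as a single-channel integer TIFF
#'
#' Intensities are stored as unsigned integers at the requested bit depth,
#' matching camera-native grey levels. Values must be whole numbers within
#' the representable range; the pipeline (and the synthetic generator)
#' quantise intensities to integers, as microscope cameras do.
#'
#' @param image A [channel_image()].
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @export
write_channel <- function(image, path, bits_per_sample = 16L) {
  stopifnot(inherits(image, "channel_image"))
  if (!bits_per_sample %in% c(8L, 16L)) {
    stop_histoflow("bits_per_sample must be 8 or 16")
  }
  maxv <- 2^bits_per_sample - 1
  px <- image$pixels
  if (max(abs(px - round(px))) > 1e-9) {
    stop_histoflow("intensities must be whole numbers for integer TIFF storage")
  }
  if (max(px) > maxv) {
    stop_histoflow(sprintf("intensity %g exceeds %d-bit range [0, %g]", max(px), bits_per_sample, maxv))
  }
  tiff::writeTIFF(round(px) / maxv, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

# Required cell-table columns; per-channel intensity columns ("mean_<channel>")
# come in addition and are detected by prefix.
cell_table_required_cols <- function() {
  c("case_id", "cell_id", "area_px", "area_um2", "centroid_row", "centroid_col")
}

#' Write / read a per-cell measurement table as CSV
#'
#' One row per cell. Required columns: case_id, cell_id, area_px, area_um2,
#' centroid_row, centroid_col; per-channel mean intensities are stored in
#' `mean_<channel>` columns, gate assignments in `gate`, plaque-proximity
#' results in `plaque_bin_um` / `plaque_group`. Numeric values round-trip to
#' better than 1e-9 relative.
#'
#' @param cells A cell-table data.frame.
#' @param path CSV path.
#' @export
write_cell_table <- function(cells, path) {
  missing <- setdiff(cell_table_required_cols(), names(cells))
  if (length(missing)) {
    stop_histoflow(sprintf("cell table is missing columns: %s", paste(missing, collapse = ", ")))
  }
  utils::write.csv(format_df_full_precision(cells), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_df_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' @rdname write_cell_table
#' @return `read_cell_table` returns the cell-table data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_histoflow(sprintf("no such cell table: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cell_table_required_cols(), names(df))
  if (length(missing)) {
    stop_histoflow(sprintf("cell table '%s' is missing columns: %s",
                           path, paste(missing, collapse = ", ")))
  }
  df
}

#' Write / read polygon gates as JSON
#'
#' Gates are first-class artifacts: a JSON array of objects
#' `{name, x_channel, y_channel, vertices: [[x, y], ...]}` in intensity units.
#'
#' @param gates A `gate_set` (or list of `gate` objects).
#' @param path JSON path.
#' @export
write_gates <- function(gates, path) {
  if (inherits(gates, "gate")) gates <- gate_set(gates)
  out <- lapply(gates, function(g) {
    list(
      name = g$name, x_channel = g$x_channel, y_channel = g$y_channel,
      vertices = unname(apply(g$vertices, 1, function(v) c(v[1], v[2]), simplify = FALSE))
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @return `read_gates` returns a [gate_set()].
#' @export
read_gates <- function(path) {
  if (!file.exists(path)) stop_histoflow(sprintf("no such gate file: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  gl <- lapply(raw, function(g) {
    v <- do.call(rbind, lapply(g$vertices, function(p) as.numeric(unlist(p))))
    gate(g$name, g$x_channel, g$y_channel, v)
  })
  do.call(gate_set, gl)
}

#' Read a pipeline/simulation configuration from YAML
#' @param path YAML path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_histoflow(sprintf("no such config file: '%s'", path))
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
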