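#' Adaptive (local-mean) threshold of a stained channel
#'
#' A pixel is foreground iff its intensity exceeds the Gaussian-weighted mean
#' of its `window_px` x `window_px` neighbourhood by more than `offset`.
#' The Gaussian weight (sigma = window/6, renormalised over the window)
#' emphasises the immediate surround; boundaries are handled by replication.
#' On a constant image no pixel exceeds its own local mean, so the mask is
#' empty for any nonnegative offset.
#'
#' @param image A [channel_image()].
#' @param window_px Odd window width >= 3, in pixels.
#' @param offset Intensity offset above the local mean required for
#'   foreground, in grey levels.
#' @return A [binary_mask()] with the same geometry as `image`.
#' @export
adaptive_threshold <- function(image, window_px = 31L, offset = 0) {
  stopifnot(inherits(image, "channel_image"))
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L) {
    stop_histoflow("window_px must be an odd integer >= 3")
  }
  if (window_px > min(dim(image$pixels))) {
    stop_histoflow(sprintf(
      "window (%d px) exceeds image dimension (%d x %d)",
      window_px, nrow(image$pixels), ncol(image$pixels)
    ))
  }
  k <- gaussian_window_kernel(window_px)
  local_mean <- EBImage::filter2(image$pixels, k, boundary = "replicate")
  binary_mask(image$pixels > local_mean + offset, image$pixel_size_um,
              paste0(image$channel_label, "_mask"))
}

gaussian_window_kernel <- function(window_px, sigma = window_px / 6) {
  off <- seq.int(-(window_px %/% 2L), window_px %/% 2L)
  g <- exp(-off^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Combine staining masks into the master mask
#'
#' The master mask is the pixelwise union of the per-channel binary masks;
#' its connected components are the cells of the single-cell analysis. The
#' operation is variadic so double (Iba1 + marker) and triple
#' (Iba1 + L-Ferritin + marker) labels are handled uniformly.
#'
#' @param ... Two or more [binary_mask()]s of identical geometry.
#' @return A [binary_mask()] labelled `"master"`.
#' @export
master_mask <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !inherits(masks[[1]], "binary_mask")) {
    masks <- masks[[1]]
  }
  if (!length(masks)) stop_histoflow("master_mask needs at least one mask")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  out <- masks[[1]]$pixels
  for (m in masks[-1]) {
    assert_same_geometry(masks[[1]], m, "first mask", sprintf("mask '%s'", m$source_label))
    out <- out | m$pixels
  }
  binary_mask(out, masks[[1]]$pixel_size_um, "master")
}

#' Label the objects of a mask as cells
#'
#' Connected components of the master mask (8-connected by default, so cells
#' whose thin processes touch diagonally stay one object) are labelled
#' 1..K; components smaller than `min_area_um2` are treated as debris and
#' removed, and the survivors are relabelled consecutively in raster-scan
#' order. Cells touching the image border are retained unless
#' `drop_border = TRUE`.
#'
#' @param mask A [binary_mask()] (typically the master mask).
#' @param min_area_um2 Minimum physical object area kept, in um^2.
#' @param connectivity 8 (default) or 4.
#' @param drop_border Drop components touching the image border.
#' @return A `labeled_cells` object: the label raster plus a per-cell table
#'   of pixel area, physical area and 0-based centroid.
#' @export
label_cells <- function(mask, min_area_um2 = 20, connectivity = 8L, drop_border = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4L, 8L)) stop_histoflow("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(mask$pixels * 1)  # 4-connected labelling
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (connectivity == 8L && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  nlab <- max(lab)
  if (nlab > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = nlab)
    keep <- areas * mask$pixel_size_um^2 >= min_area_um2
    if (drop_border) {
      border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      keep[border_labs[border_labs > 0L]] <- FALSE
    }
    remap <- integer(nlab)
    remap[keep] <- seq_len(sum(keep))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  build_labeled_cells(lab, mask$pixel_size_um)
}

# merge 4-connected labels that touch diagonally (union-find over label pairs)
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left neighbours
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

build_labeled_cells <- function(lab, pixel_size_um) {
  nlab <- max(lab)
  if (nlab > 0L) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab)       # 0-based row
    cols <- (idx - 1L) %/% nrow(lab)      # 0-based col
    area_px <- tabulate(l, nbins = nlab)
    tbl <- data.frame(
      cell_id = seq_len(nlab),
      area_px = area_px,
      area_um2 = area_px * pixel_size_um^2,
      centroid_row = as.numeric(tapply(rows, l, mean)),
      centroid_col = as.numeric(tapply(cols, l, mean))
    )
  } else {
    tbl <- data.frame(
      cell_id = integer(0), area_px = integer(0), area_um2 = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    )
  }
  structure(
    list(labels = lab, pixel_size_um = pixel_size_um, table = tbl),
    class = "labeled_cells"
  )
}

#' @export
print.labeled_cells <- function(x, ...) {
  cat(sprintf(
    "<labeled_cells> %d cells over %d x %d px (%.4g um/px)\n",
    n_cells(x), nrow(x$labels), ncol(x$labels), x$pixel_size_um
  ))
  invisible(x)
}

#' Number of labelled cells
#' @param cells A `labeled_cells` object.
#' @export
n_cells <- function(cells) nrow(cells$table)
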