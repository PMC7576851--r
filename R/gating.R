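#' A named polygon gate in 2D intensity space
#'
#' A gate is a simple closed polygon in the plane spanned by two per-cell
#' mean-intensity axes (e.g. Iba1 on x, a marker of interest on y), exactly
#' as drawn on a FACS-style scatter plot. Gates are plain data (JSON on
#' disk, see [write_gates()]), so the subjective drawing step is separated
#' from the deterministic assignment machinery.
#'
#' @param name Gate (population) name.
#' @param x_channel,y_channel Channel names of the two intensity axes.
#' @param vertices Numeric n x 2 matrix of (x, y) vertices, n >= 3, forming
#'   a simple (non-self-intersecting) closed polygon; an explicitly repeated
#'   closing vertex is tolerated and dropped.
#' @return A `gate` object.
#' @export
gate <- function(name, x_channel, y_channel, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || !is.numeric(vertices)) {
    stop_histoflow("vertices must be an n x 2 numeric matrix")
  }
  n <- nrow(vertices)
  if (n >= 4L && all(vertices[1, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop_histoflow("a gate polygon needs at least 3 vertices")
  if (anyNA(vertices)) stop_histoflow("gate vertices must be finite")
  if (!polygon_is_simple(vertices[, 1], vertices[, 2])) {
    stop_histoflow(sprintf("gate '%s' polygon is self-intersecting", name))
  }
  structure(
    list(name = as.character(name), x_channel = as.character(x_channel),
         y_channel = as.character(y_channel), vertices = unname(vertices)),
    class = "gate"
  )
}

#' Axis-aligned rectangular gate
#'
#' Convenience constructor for rectangular gates (quadrant-style gating and
#' simulation tests with known decision boundaries).
#'
#' @inheritParams gate
#' @param xlim,ylim Length-2 numeric ranges.
#' @export
rect_gate <- function(name, x_channel, y_channel, xlim, ylim) {
  gate(name, x_channel, y_channel,
       cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
             c(ylim[1], ylim[1], ylim[2], ylim[2])))
}

#' A set of mutually non-overlapping gates
#'
#' @param ... `gate` objects (or a single list of them).
#' @return A `gate_set` (list of gates) whose interiors are verified
#'   pairwise disjoint when they share axes, so cell assignment is unique
#'   and order-independent.
#' @export
gate_set <- function(...) {
  gates <- list(...)
  if (length(gates) == 1L && is.list(gates[[1]]) && !inherits(gates[[1]], "gate")) {
    gates <- gates[[1]]
  }
  if (!length(gates)) stop_histoflow("gate_set needs at least one gate")
  for (g in gates) stopifnot(inherits(g, "gate"))
  nms <- vapply(gates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_histoflow("gate names must be unique")
  for (i in seq_along(gates)) {
    for (j in seq_len(i - 1L)) {
      gi <- gates[[i]]; gj <- gates[[j]]
      if (gi$x_channel == gj$x_channel && gi$y_channel == gj$y_channel &&
          polygons_overlap(gi$vertices, gj$vertices)) {
        stop_histoflow(sprintf("gates '%s' and '%s' overlap", gj$name, gi$name))
      }
    }
  }
  names(gates) <- nms
  structure(gates, class = "gate_set")
}

# ---- polygon geometry -------------------------------------------------------

# Even-odd point-in-polygon, vectorised over points; points on the boundary
# count as inside (a cell on a drawn gate line belongs to that gate).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  scale <- max(abs(c(vx, vy, 1)))
  eps <- 1e-9 * scale
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on_seg <- abs(cross) <= eps * max(seg_len, 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    # even-odd ray crossing (ray towards +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | on_edge
}

seg_orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  eps <- 1e-12 * max(abs(c(ax, ay, bx, by, cx, cy, 1)))^2
  ifelse(abs(v) <= eps, 0, sign(v))
}

segments_intersect <- function(p1, p2, q1, q2, proper_only = FALSE) {
  o1 <- seg_orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  o2 <- seg_orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  o3 <- seg_orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  o4 <- seg_orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) return(TRUE)
  if (proper_only) return(FALSE)
  on_seg <- function(a, b, c) {
    seg_orient(a[1], a[2], b[1], b[2], c[1], c[2]) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, q1) || on_seg(p1, p2, q2) || on_seg(q1, q2, p1) || on_seg(q1, q2, p2)
}

polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  v <- cbind(vx, vy)
  for (i in seq_len(n)) {
    i2 <- i %% n + 1L
    for (j in seq_len(n)) {
      j2 <- j %% n + 1L
      if (j == i || j == i2 || j2 == i) next
      if (j < i) next  # each unordered pair once
      if (segments_intersect(v[i, ], v[i2, ], v[j, ], v[j2, ])) return(FALSE)
    }
  }
  TRUE
}

polygons_overlap <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    i2 <- i %% na + 1L
    for (j in seq_len(nb)) {
      j2 <- j %% nb + 1L
      if (segments_intersect(a[i, ], a[i2, ], b[j, ], b[j2, ])) return(TRUE)
    }
  }
  any(point_in_polygon(a[, 1], a[, 2], b[, 1], b[, 2])) ||
    any(point_in_polygon(b[, 1], b[, 2], a[, 1], a[, 2]))
}

# ---- assignment and summaries ----------------------------------------------

gate_axis_columns <- function(cells, g) {
  xs <- paste0("mean_", g$x_channel)
  ys <- paste0("mean_", g$y_channel)
  missing <- setdiff(c(xs, ys), names(cells))
  if (length(missing)) {
    stop_histoflow(sprintf(
      "gate '%s' needs channel column(s) %s not present in the cell table",
      g$name, paste(missing, collapse = ", ")
    ))
  }
  list(x = cells[[xs]], y = cells[[ys]])
}

#' Assign cells to populations by polygon gating
#'
#' Each cell is tested against every gate in its (x, y) mean-intensity
#' coordinates using the even-odd rule, with points on a gate boundary
#' counted inside. A cell contained in more than one gate is an error naming
#' both gates (gate sets are meant to be disjoint); cells in no gate are
#' `"ungated"`.
#'
#' @param cells Cell-table data.frame with `mean_<channel>` columns.
#' @param gates A [gate_set()] (a single [gate()] is promoted).
#' @return `cells` with a `gate` character column added.
#' @export
apply_gates <- function(cells, gates) {
  if (inherits(gates, "gate")) gates <- gate_set(gates)
  stopifnot(inherits(gates, "gate_set"))
  n <- nrow(cells)
  member <- matrix(FALSE, n, length(gates),
                   dimnames = list(NULL, names(gates)))
  for (k in seq_along(gates)) {
    g <- gates[[k]]
    ax <- gate_axis_columns(cells, g)
    member[, k] <- point_in_polygon(ax$x, ax$y, g$vertices[, 1], g$vertices[, 2])
  }
  multi <- which(rowSums(member) > 1L)
  if (length(multi)) {
    hit <- names(gates)[member[multi[1], ]]
    stop_histoflow(sprintf(
      "cell %s falls inside overlapping gates '%s' and '%s'",
      cells$cell_id[multi[1]], hit[1], hit[2]
    ))
  }
  assign <- rep("ungated", n)
  for (k in seq_along(gates)) assign[member[, k]] <- names(gates)[k]
  cells$gate <- assign
  cells
}

#' Population abundances and mean population intensities
#'
#' For each gate (plus the ungated remainder) reports the cell count, the
#' proportion of all cells in the table, and the mean population intensity
#' per channel. The proportion denominator is the full gated universe, i.e.
#' every cell of the master mask, so proportions plus the ungated remainder
#' sum to 1. The default population-intensity statistic is the arithmetic
#' mean of member-cell intensities; `stat = "density_mode"` instead reports
#' the peak of a 2D kernel density of the members, an alternative reading of
#' "centre of the population" on a contour plot.
#'
#' @param assigned Cell table with a `gate` column (see [apply_gates()]).
#' @param stat `"mean"` or `"density_mode"`.
#' @param include_ungated Include the ungated remainder row.
#' @return data.frame with columns `population`, `n`, `proportion` and
#'   `mean_<channel>` for every channel column present.
#' @export
population_proportions <- function(assigned, stat = c("mean", "density_mode"),
                                   include_ungated = TRUE) {
  stat <- match.arg(stat)
  if (!"gate" %in% names(assigned)) stop_histoflow("run apply_gates() first")
  total <- nrow(assigned)
  chan_cols <- grep("^mean_", names(assigned), value = TRUE)
  pops <- setdiff(unique(assigned$gate), "ungated")
  if (include_ungated) pops <- c(pops, "ungated")
  if (total == 0L) {
    out <- data.frame(population = character(0), n = integer(0), proportion = numeric(0))
    for (cc in chan_cols) out[[cc]] <- numeric(0)
    return(out)
  }
  rows <- lapply(pops, function(p) {
    sel <- assigned$gate == p
    row <- data.frame(population = p, n = sum(sel), proportion = sum(sel) / total,
                      stringsAsFactors = FALSE)
    for (cc in chan_cols) {
      row[[cc]] <- if (!any(sel)) NA_real_ else mean(assigned[[cc]][sel])
    }
    row
  })
  out <- do.call(rbind, rows)
  if (stat == "density_mode") {
    for (p in setdiff(pops, "ungated")) {
      sel <- assigned$gate == p
      if (sum(sel) >= 5L && length(chan_cols) >= 2L) {
        for (cc in chan_cols) {
          out[[cc]][out$population == p] <- density_mode_1d(assigned[[cc]][sel])
        }
      }
    }
  }
  out
}

density_mode_1d <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Pool per-case cell tables for joint gating
#'
#' Concatenates cell tables from several cases (requiring identical channel
#' sets) while preserving the case of origin, so gates drawn on the pooled
#' scatter can be transferred back and evaluated per case.
#'
#' @param tables List of cell-table data.frames.
#' @return One pooled cell table.
#' @export
pool_cases <- function(tables) {
  if (!length(tables)) stop_histoflow("no tables to pool")
  chans <- lapply(tables, function(t) sort(grep("^mean_", names(t), value = TRUE)))
  for (i in seq_along(chans)) {
    if (!identical(chans[[i]], chans[[1]])) {
      stop_histoflow(sprintf(
        "table %d has channels {%s} but table 1 has {%s}",
        i, paste(chans[[i]], collapse = ","), paste(chans[[1]], collapse = ",")
      ))
    }
  }
  common <- Reduce(intersect, lapply(tables, names))
  do.call(rbind, lapply(tables, function(t) t[common]))
}

#' Hierarchical (two-stage) gating
#'
#' First restricts to the cells inside `stage1_gate` (e.g. the Iba1-low
#' population on Iba1 vs L-Ferritin axes), then applies `stage2_gates`
#' (e.g. L-Ferritin vs marker populations) within that subset. Stage-2
#' proportions are reported as fractions of the stage-1 cells.
#'
#' @param cells Cell table.
#' @param stage1_gate A [gate()].
#' @param stage2_gates A [gate_set()].
#' @return List with `stage1_n`, the stage-2 `cells` table (with `gate`
#'   column) and the stage-2 `summary` (proportions of stage-1 cells).
#' @export
hierarchical_gate <- function(cells, stage1_gate, stage2_gates) {
  stopifnot(inherits(stage1_gate, "gate"))
  s1 <- apply_gates(cells, gate_set(stage1_gate))
  inside <- s1$gate == stage1_gate$name
  sub <- cells[inside, , drop = FALSE]
  if (!nrow(sub)) {
    return(list(stage1_n = 0L, cells = sub,
                summary = population_proportions(transform(sub, gate = character(0)))))
  }
  s2 <- apply_gates(sub, stage2_gates)
  list(stage1_n = nrow(sub), cells = s2, summary = population_proportions(s2))
}

#' Net change between two groups' 2D intensity distributions
#'
#' Histograms both groups' (x, y) mean intensities over identical bins,
#' normalises each histogram to unit mass, and returns the signed difference
#' (group2 minus group1) -- the heat-map of normalised change between, e.g.,
#' normal and AD pooled scatters. The output sums to zero by construction.
#' Values falling outside `axis_ranges` are clipped into the edge bins so no
#' mass is lost.
#'
#' @param cells_group1,cells_group2 Non-empty cell tables.
#' @param x_channel,y_channel Channel names of the two axes.
#' @param bins Integer pair: number of bins in x and y.
#' @param axis_ranges List with `x` and `y` length-2 ranges (default: the
#'   combined data range).
#' @return `bins[1]` x `bins[2]` matrix (x by y) with attributes
#'   `x_breaks`, `y_breaks`.
#' @export
net_change_heatmap <- function(cells_group1, cells_group2, x_channel, y_channel,
                               bins = c(64L, 64L), axis_ranges = NULL) {
  if (!nrow(cells_group1) || !nrow(cells_group2)) {
    stop_histoflow("both groups must contain at least one cell")
  }
  xs <- paste0("mean_", x_channel); ys <- paste0("mean_", y_channel)
  for (tb in list(cells_group1, cells_group2)) {
    if (!all(c(xs, ys) %in% names(tb))) {
      stop_histoflow(sprintf("cell tables need columns %s and %s", xs, ys))
    }
  }
  if (is.null(axis_ranges)) {
    axis_ranges <- list(
      x = range(c(cells_group1[[xs]], cells_group2[[xs]])),
      y = range(c(cells_group1[[ys]], cells_group2[[ys]]))
    )
  }
  bx <- seq(axis_ranges$x[1], axis_ranges$x[2], length.out = bins[1] + 1L)
  by <- seq(axis_ranges$y[1], axis_ranges$y[2], length.out = bins[2] + 1L)
  h <- function(tb) {
    ix <- pmin(pmax(findInterval(tb[[xs]], bx, rightmost.closed = TRUE), 1L), bins[1])
    iy <- pmin(pmax(findInterval(tb[[ys]], by, rightmost.closed = TRUE), 1L), bins[2])
    m <- matrix(tabulate((iy - 1L) * bins[1] + ix, nbins = bins[1] * bins[2]),
                bins[1], bins[2])
    m / sum(m)
  }
  out <- h(cells_group2) - h(cells_group1)
  attr(out, "x_breaks") <- bx
  attr(out, "y_breaks") <- by
  out
}

#' Starter rectangular gates from pooled-density quantiles
#'
#' Derives the three canonical quadrant gates (low-x/high-y, high-x/high-y,
#' high-x/low-y) from per-axis quantile splits of a pooled cell table --- a
#' reproducible stand-in for freehand gate drawing, useful for tests and as
#' an initial gate file for manual refinement.
#'
#' @param pooled Pooled cell table.
#' @param x_channel,y_channel Channel names.
#' @param x_split,y_split Quantile (in 0..1) at which each axis is split.
#' @param pad Fractional padding added beyond the data range.
#' @return A [gate_set()] of three rectangular gates.
#' @export
quantile_gates <- function(pooled, x_channel, y_channel,
                           x_split = 0.5, y_split = 0.5, pad = 0.05) {
  xs <- pooled[[paste0("mean_", x_channel)]]
  ys <- pooled[[paste0("mean_", y_channel)]]
  bx <- stats::quantile(xs, x_split, names = FALSE)
  by <- stats::quantile(ys, y_split, names = FALSE)
  rx <- range(xs); ry <- range(ys)
  gx <- diff(rx) * pad; gy <- diff(ry) * pad
  eps <- 1e-6 * max(abs(c(rx, ry, 1)))
  boundary_gates(x_channel, y_channel, bx, by,
                 xlim = c(rx[1] - gx, rx[2] + gx),
                 ylim = c(ry[1] - gy, ry[2] + gy), eps = eps)
}

#' Three quadrant gates at explicit decision boundaries
#'
#' @param x_channel,y_channel Channel names.
#' @param x_boundary,y_boundary Decision boundaries in intensity units.
#' @param xlim,ylim Outer extents of the gates.
#' @param eps Gap inserted between adjacent gates so their edges do not
#'   touch (touching edges would make boundary points members of two gates).
#' @return A [gate_set()] named `lowx_highy`, `highx_highy`, `highx_lowy`.
#' @export
boundary_gates <- function(x_channel, y_channel, x_boundary, y_boundary,
                           xlim, ylim, eps = NULL) {
  if (is.null(eps)) eps <- 1e-6 * max(abs(c(xlim, ylim, 1)))
  gate_set(
    rect_gate("lowx_highy", x_channel, y_channel,
              c(xlim[1], x_boundary - eps), c(y_boundary + eps, ylim[2])),
    rect_gate("highx_highy", x_channel, y_channel,
              c(x_boundary + eps, xlim[2]), c(y_boundary + eps, ylim[2])),
    rect_gate("highx_lowy", x_channel, y_channel,
              c(x_boundary + eps, xlim[2]), c(ylim[1], y_boundary - eps))
  )
}
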