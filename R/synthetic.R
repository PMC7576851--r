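#' Define a simulated cell population
#'
#' Each population is a mixture component of the simulated field. Per-channel
#' intensities are drawn log-normally (`meanlog`/`sdlog`), reflecting the
#' right-skewed single-cell intensity clouds seen in stained myeloid
#' populations; channels are named freely (e.g. `iba1`, `moi`, `lferritin`).
#'
#' @param name Population name.
#' @param fraction Mixture fraction in `[0, 1]`.
#' @param ... One `c(meanlog, sdlog)` pair per marker channel, named.
#' @return A `sim_population` list.
#' @export
sim_population <- function(name, fraction, ...) {
  ch <- list(...)
  if (!length(ch) || is.null(names(ch)) || any(names(ch) == "")) {
    stop_histoflow("each population needs named per-channel c(meanlog, sdlog) pairs")
  }
  for (nm in names(ch)) {
    if (length(ch[[nm]]) != 2L || !is.numeric(ch[[nm]]) || ch[[nm]][2] < 0) {
      stop_histoflow(sprintf("channel '%s': expected c(meanlog, sdlog) with sdlog >= 0", nm))
    }
  }
  structure(list(name = name, fraction = fraction, channels = ch),
            class = "sim_population")
}

default_populations <- function() {
  list(
    sim_population("iba1low_moihigh", 0.20,
                   iba1 = c(log(30), 0.20), moi = c(log(110), 0.20)),
    sim_population("iba1high_moihigh", 0.40,
                   iba1 = c(log(120), 0.20), moi = c(log(110), 0.20)),
    sim_population("iba1high_moilow", 0.40,
                   iba1 = c(log(120), 0.20), moi = c(log(25), 0.20))
  )
}

#' Configuration for the synthetic grey-matter field generator
#'
#' Defaults emulate a 20x field of cortical grey matter at 0.5 um/px with
#' three myeloid populations (Iba1-low/marker-high, Iba1-high/marker-high,
#' Iba1-high/marker-low), disk-shaped amyloid plaques and a nuclei channel.
#' Intensities are in camera grey levels and are quantised to integers by
#' default, as a camera digitiser would.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param pixel_size_um Pixel size, um/px.
#' @param n_cells Number of cells to place.
#' @param populations List of [sim_population()]; fractions must sum to 1.
#' @param cell_radius_um Range (min, max) of cell radii in um.
#' @param n_plaques Number of amyloid plaques.
#' @param plaque_radius_um Range of plaque radii in um.
#' @param background_level Uniform background grey level.
#' @param noise_sd SD of additive Gaussian noise (truncated at 0).
#' @param seed Integer seed; the same config is bit-reproducible.
#' @param nuclei_radius_um Radius of the rendered nucleus disk.
#' @param nuclei_level Grey level of nucleus disks.
#' @param plaque_level Grey level of plaque disks.
#' @param quantize Round all rendered values to integer grey levels.
#' @param blur_sigma_px Optional Gaussian blur applied to marker channels
#'   (0 = hard-edged disks, keeping mean-intensity ground truth exact).
#' @param min_separation_px Minimum extra gap between cell rims, in px.
#' @param max_place_tries Placement attempts per cell before failing.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(image_size_px = c(512L, 512L),
                              pixel_size_um = 0.5,
                              n_cells = 200L,
                              populations = default_populations(),
                              cell_radius_um = c(3, 6),
                              n_plaques = 5L,
                              plaque_radius_um = c(10, 25),
                              background_level = 10,
                              noise_sd = 2,
                              seed = 1L,
                              nuclei_radius_um = 1.5,
                              nuclei_level = 200,
                              plaque_level = 150,
                              quantize = TRUE,
                              blur_sigma_px = 0,
                              min_separation_px = 3,
                              max_place_tries = 200L) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 8L)) {
    stop_histoflow("image_size_px must be two integers >= 8")
  }
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_histoflow(sprintf("population fractions must sum to 1 (got %.12g)", sum(fr)))
  }
  if (any(fr < 0)) stop_histoflow("population fractions must be nonnegative")
  chans <- names(populations[[1]]$channels)
  for (p in populations) {
    if (!identical(names(p$channels), chans)) {
      stop_histoflow("all populations must define the same channel set, in the same order")
    }
  }
  if (any(cell_radius_um <= 0) || any(plaque_radius_um <= 0) || nuclei_radius_um <= 0) {
    stop_histoflow("all radii must be strictly positive")
  }
  if (diff(range(cell_radius_um)) < 0) stop_histoflow("cell_radius_um must be c(min, max)")
  max_r_px <- max(cell_radius_um) / pixel_size_um
  if (n_cells > 0 && any(image_size_px < 2 * (max_r_px + 2))) {
    stop_histoflow("image too small to hold a single cell of the configured radius")
  }
  if (background_level < 0 || noise_sd < 0) {
    stop_histoflow("background_level and noise_sd must be nonnegative")
  }
  structure(
    list(
      image_size_px = image_size_px, pixel_size_um = pixel_size_um,
      n_cells = as.integer(n_cells), populations = populations,
      marker_channels = chans,
      cell_radius_um = sort(as.numeric(cell_radius_um)),
      n_plaques = as.integer(n_plaques),
      plaque_radius_um = sort(as.numeric(plaque_radius_um)),
      background_level = background_level, noise_sd = noise_sd,
      seed = as.integer(seed),
      nuclei_radius_um = nuclei_radius_um, nuclei_level = nuclei_level,
      plaque_level = plaque_level, quantize = isTRUE(quantize),
      blur_sigma_px = blur_sigma_px,
      min_separation_px = min_separation_px,
      max_place_tries = as.integer(max_place_tries)
    ),
    class = "simulation_config"
  )
}

# paint value into mat over the disk (continuous centre, 1-based), in place
paint_disk <- function(mat, cr, cc, r_px, value) {
  i0 <- max(1L, floor(cr - r_px)); i1 <- min(nrow(mat), ceiling(cr + r_px))
  j0 <- max(1L, floor(cc - r_px)); j1 <- min(ncol(mat), ceiling(cc + r_px))
  if (i0 > i1 || j0 > j1) return(mat)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cr)^2, (jj - cc)^2, `+`)
  sub <- mat[ii, jj, drop = FALSE]
  sub[d2 <= r_px^2] <- value
  mat[ii, jj] <- sub
  mat
}

#' Generate one ground-truthed synthetic case
#'
#' Renders non-overlapping disk cells with per-population log-normal
#' intensities on a uniform background, one small bright nucleus disk per
#' cell, and disk-shaped amyloid plaques, then adds truncated Gaussian noise
#' and (by default) quantises to integer grey levels. Identical configs
#' (including seed) produce bit-identical images.
#'
#' @param config A [simulation_config()].
#' @return A list with `images` (named list of [channel_image()]: the marker
#'   channels plus `nuclei` and `abeta`), `truth` (cells and plaques
#'   data.frames; centroids 0-based `(row, col)`), and `config`.
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_case_impl(config))
}

generate_case_impl <- function(config) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  ps <- config$pixel_size_um
  n <- config$n_cells
  pops <- config$populations
  pop_names <- vapply(pops, `[[`, character(1), "name")
  fr <- vapply(pops, `[[`, numeric(1), "fraction")
  chans <- config$marker_channels

  # 1. population labels
  labels <- if (n > 0) sample(pop_names, n, replace = TRUE, prob = fr) else character(0)
  # 2. radii
  r_um <- if (n > 0) stats::runif(n, config$cell_radius_um[1], config$cell_radius_um[2]) else numeric(0)
  r_px <- r_um / ps
  # 3. placement: bounded rejection sampling, no touching cells
  cr <- numeric(n); cc <- numeric(n)
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(config$max_place_tries)) {
      yi <- stats::runif(1, r_px[i] + 1, nr - r_px[i])
      xi <- stats::runif(1, r_px[i] + 1, nc - r_px[i])
      if (placed == 0L ||
          all((cr[seq_len(placed)] - yi)^2 + (cc[seq_len(placed)] - xi)^2 >
              (r_px[seq_len(placed)] + r_px[i] + config$min_separation_px)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop_histoflow(sprintf(
        "could not place cell %d of %d after %d tries (placed %d); reduce n_cells or cell radius",
        i, n, config$max_place_tries, placed
      ))
    }
    cr[i] <- yi; cc[i] <- xi; placed <- placed + 1L
  }
  # 4. per-channel intensities (channel-major order)
  q <- function(x) if (config$quantize) round(x) else x
  intens <- matrix(0, nrow = n, ncol = length(chans), dimnames = list(NULL, chans))
  pop_idx <- match(labels, pop_names)
  for (k in seq_along(chans)) {
    ml <- vapply(pops, function(p) p$channels[[chans[k]]][1], numeric(1))[pop_idx]
    sl <- vapply(pops, function(p) p$channels[[chans[k]]][2], numeric(1))[pop_idx]
    if (n > 0) intens[, k] <- q(stats::rlnorm(n, ml, sl))
  }
  # 5. plaques
  np <- config$n_plaques
  pr_um <- if (np > 0) stats::runif(np, config$plaque_radius_um[1], config$plaque_radius_um[2]) else numeric(0)
  pr_px <- pr_um / ps
  pcr <- numeric(np); pcc <- numeric(np)
  for (i in seq_len(np)) {
    pcr[i] <- stats::runif(1, pr_px[i] + 1, nr - pr_px[i])
    pcc[i] <- stats::runif(1, pr_px[i] + 1, nc - pr_px[i])
  }

  base <- matrix(q(config$background_level), nr, nc)
  imgs <- list()
  for (k in seq_along(chans)) {
    m <- base
    for (i in seq_len(n)) m <- paint_disk(m, cr[i], cc[i], r_px[i], intens[i, k])
    imgs[[chans[k]]] <- m
  }
  nuc <- base
  nrad <- config$nuclei_radius_um / ps
  for (i in seq_len(n)) nuc <- paint_disk(nuc, cr[i], cc[i], nrad, q(config$nuclei_level))
  imgs[["nuclei"]] <- nuc
  ab <- base
  for (i in seq_len(np)) ab <- paint_disk(ab, pcr[i], pcc[i], pr_px[i], q(config$plaque_level))
  imgs[["abeta"]] <- ab

  # optional blur, then 6. noise (fixed channel order), truncation, quantise
  for (nm in names(imgs)) {
    m <- imgs[[nm]]
    if (config$blur_sigma_px > 0 && nm %in% chans) {
      m <- EBImage::gblur(m, sigma = config$blur_sigma_px)
    }
    if (config$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow(m), ncol(m))
    }
    m <- pmax(m, 0)
    imgs[[nm]] <- q(m)
  }
  images <- lapply(names(imgs), function(nm) channel_image(imgs[[nm]], ps, nm))
  names(images) <- names(imgs)

  truth_cells <- data.frame(
    cell = seq_len(n),
    centroid_row = cr - 1, centroid_col = cc - 1,  # 0-based
    radius_um = r_um, population = labels,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(chans)) truth_cells[[paste0("true_", chans[k])]] <- intens[, k]
  truth_plaques <- data.frame(
    plaque = seq_len(np),
    centroid_row = pcr - 1, centroid_col = pcc - 1,
    radius_um = pr_um
  )
  list(
    images = images,
    truth = list(cells = truth_cells, plaques = truth_plaques, affine = NULL),
    config = config
  )
}

#' Generate a fixed/moving nuclei image pair under a known affine
#'
#' The fixed image is the nuclei channel of a synthetic case; the moving image
#' is that image resampled under the given affine transform (bilinear,
#' background fill), emulating the second staining round of a sequential
#' protocol. The matrix recorded in the ground truth maps moving (row, col)
#' pixel coordinates to fixed coordinates, i.e. it is the transform a
#' registration should recover.
#'
#' @param config A [simulation_config()].
#' @param affine A 2x3 matrix or [affine_transform()] mapping moving to fixed
#'   coordinates.
#' @return List with `fixed`, `moving` ([channel_image()]s) and `truth`
#'   (cells table plus the applied `affine`).
#' @export
generate_registration_pair <- function(config, affine) {
  t <- as_affine_transform(affine)
  case <- generate_case(config)
  fixed <- case$images$nuclei
  # moving(p) = fixed(T(p)): pull back through the moving->fixed map
  moving <- warp_image(fixed, t, fill = case$config$background_level)
  moving$channel_label <- "nuclei_moving"
  truth <- case$truth
  truth$affine <- t
  list(fixed = fixed, moving = moving, truth = truth, config = config)
}

#' Write a synthetic case to disk
#'
#' Channel images go to `<channel>.tif` (16-bit), ground truth to
#' `truth_cells.csv` and `truth.json`, the configuration to `config.yaml`.
#'
#' @param case Result of [generate_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(case$images)) {
    write_channel(case$images[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  utils::write.csv(format_df_full_precision(case$truth$cells),
                   file.path(dir, "truth_cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      plaques = case$truth$plaques,
      affine = if (is.null(case$truth$affine)) NULL else unclass(case$truth$affine),
      pixel_size_um = case$config$pixel_size_um
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  cfg <- unclass(case$config)
  cfg$populations <- lapply(cfg$populations, unclass)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
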