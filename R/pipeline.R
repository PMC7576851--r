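#' Run one pipeline stage on a case directory
#'
#' File-based orchestration of the analysis stages, designed so a whole run
#' is reproducible from its YAML configuration and seed alone. Each stage
#' reads its inputs from `input_dir` (a case directory as produced by
#' [write_case()] and/or earlier stages), writes its artifacts to `out_dir`,
#' and drops a machine-readable `manifest_<stage>.json` recording inputs,
#' parameters, seed and package version.
#'
#' Stages: `simulate` (synthetic case to TIFFs + ground truth), `segment`
#' (adaptive thresholds, master mask, cell labels), `quantify` (per-cell
#' mean intensities to `cells.csv`), `gate` (polygon gating + population
#' summary), `spatial` (plaque-proximity bins), `register` (nuclei-landmark
#' affine + channel transfer), `pathology` (percent-area loads), `stats`
#' (screened two-group comparison of a measurement CSV).
#'
#' @param stage Stage name (see above).
#' @param config Named list (or path to a YAML file) with one section per
#'   stage; `pixel_size_um` at the top level.
#' @param input_dir Directory with the stage's inputs.
#' @param out_dir Output directory (created; defaults to `input_dir`).
#' @param seed Integer seed overriding `config$seed` for stochastic stages.
#' @param overrides Named list merged over the stage's config section.
#' @return Named list of artifact paths, invisibly.
#' @export
run_stage <- function(stage, config = list(), input_dir = NULL, out_dir = NULL,
                      seed = NULL, overrides = list()) {
  stages <- c("simulate", "segment", "quantify", "gate", "spatial",
              "register", "pathology", "stats")
  if (!stage %in% stages) {
    stop_histoflow(sprintf("unknown stage '%s' (expected one of: %s)",
                           stage, paste(stages, collapse = ", ")))
  }
  if (is.character(config)) config <- read_config(config)
  section <- config[[stage]]
  if (is.null(section)) section <- list()
  known <- stage_known_keys(stage)
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop_histoflow(sprintf("invalid config key(s) for stage '%s': %s",
                           stage, paste(bad, collapse = ", ")))
  }
  section[names(overrides)] <- overrides
  bad <- setdiff(names(section), known)
  if (length(bad)) {
    stop_histoflow(sprintf("invalid config key(s) for stage '%s': %s",
                           stage, paste(bad, collapse = ", ")))
  }
  if (is.null(out_dir)) out_dir <- input_dir
  if (is.null(out_dir)) stop_histoflow("out_dir (or input_dir) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps <- config$pixel_size_um %||% 0.5
  t0 <- Sys.time()
  log_line <- function(...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(...)))
  }
  outputs <- switch(stage,
    simulate  = stage_simulate(section, out_dir, seed, log_line),
    segment   = stage_segment(section, input_dir, out_dir, ps, log_line),
    quantify  = stage_quantify(section, input_dir, out_dir, ps, log_line),
    gate      = stage_gate(section, input_dir, out_dir, log_line),
    spatial   = stage_spatial(section, input_dir, out_dir, ps, log_line),
    register  = stage_register(section, input_dir, out_dir, ps, seed, log_line),
    pathology = stage_pathology(section, input_dir, out_dir, ps, log_line),
    stats     = stage_stats(section, input_dir, out_dir, log_line)
  )
  manifest <- list(
    stage = stage,
    package = "histoflow",
    version = as.character(utils::packageVersion("histoflow")),
    seed = seed,
    pixel_size_um = ps,
    parameters = section,
    input_dir = input_dir,
    outputs = outputs,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(outputs, manifest = mpath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_known_keys <- function(stage) {
  switch(stage,
    simulate  = c(names(formals(simulation_config))),
    segment   = c("channels", "window_px", "offset", "min_area_um2",
                  "connectivity", "drop_border"),
    quantify  = c("channels", "case_id"),
    gate      = c("gates", "cells", "stat"),
    spatial   = c("step_um", "max_um", "plaque_channel", "plaque_window_px",
                  "plaque_offset", "cells"),
    register  = c("fixed", "moving", "apply_to", "rolling_radius_px",
                  "median_radius_px", "ratio", "ransac_tol_px", "model"),
    pathology = c("channels", "window_px", "offset", "roi_area_um2"),
    stats     = c("measurements", "value_column", "group_column", "alpha")
  )
}

require_input <- function(input_dir, name) {
  if (is.null(input_dir)) stop_histoflow("this stage needs input_dir")
  p <- file.path(input_dir, name)
  if (!file.exists(p)) stop_histoflow(sprintf("missing input: %s", p))
  p
}

stage_simulate <- function(s, out_dir, seed, log_line) {
  if (!is.null(seed)) s$seed <- as.integer(seed)
  if (!is.null(s$populations) && !inherits(s$populations[[1]], "sim_population")) {
    s$populations <- lapply(s$populations, function(p) {
      do.call(sim_population, c(list(name = p$name, fraction = p$fraction),
                                lapply(p$channels, as.numeric)))
    })
  }
  cfg <- do.call(simulation_config, s)
  case <- generate_case(cfg)
  write_case(case, out_dir)
  log_line("wrote %d channels, %d cells, %d plaques", length(case$images),
           nrow(case$truth$cells), nrow(case$truth$plaques))
  stats::setNames(
    as.list(file.path(out_dir, c(paste0(names(case$images), ".tif"),
                                 "truth_cells.csv", "truth.json", "config.yaml"))),
    c(names(case$images), "truth_cells", "truth", "config")
  )
}

stage_segment <- function(s, input_dir, out_dir, ps, log_line) {
  chans <- s$channels %||% c("iba1", "moi")
  masks <- lapply(chans, function(ch) {
    img <- read_channel(require_input(input_dir, paste0(ch, ".tif")), ps, ch)
    adaptive_threshold(img, s$window_px %||% 31L, s$offset %||% 5)
  })
  master <- master_mask(masks)
  cells <- label_cells(master, s$min_area_um2 %||% 20,
                       s$connectivity %||% 8L, isTRUE(s$drop_border))
  log_line("master mask %d px -> %d cells", sum(master$pixels), n_cells(cells))
  mp <- file.path(out_dir, "master_mask.tif")
  write_channel(channel_image(master$pixels * 1, ps, "master"), mp, 8L)
  lp <- file.path(out_dir, "labels.tif")
  write_channel(channel_image(cells$labels * 1, ps, "labels"), lp, 16L)
  list(master_mask = mp, labels = lp)
}

read_labels <- function(input_dir, ps) {
  li <- read_channel(require_input(input_dir, "labels.tif"), ps, "labels")
  lab <- matrix(as.integer(round(li$pixels)), nrow(li$pixels), ncol(li$pixels))
  build_labeled_cells(lab, ps)
}

stage_quantify <- function(s, input_dir, out_dir, ps, log_line) {
  cells <- read_labels(input_dir, ps)
  chans <- s$channels %||% c("iba1", "moi")
  imgs <- lapply(chans, function(ch) {
    read_channel(require_input(input_dir, paste0(ch, ".tif")), ps, ch)
  })
  names(imgs) <- chans
  tbl <- measure_cells(cells, imgs, s$case_id %||% basename(input_dir))
  cp <- file.path(out_dir, "cells.csv")
  write_cell_table(tbl, cp)
  log_line("measured %d cells x %d channels", nrow(tbl), length(chans))
  list(cells = cp)
}

stage_gate <- function(s, input_dir, out_dir, log_line) {
  cells <- read_cell_table(require_input(input_dir, s$cells %||% "cells.csv"))
  gates <- read_gates(require_input(input_dir, s$gates %||% "gates.json"))
  assigned <- apply_gates(cells, gates)
  summary <- population_proportions(assigned, stat = s$stat %||% "mean")
  ap <- file.path(out_dir, "cells_gated.csv")
  write_cell_table(assigned, ap)
  sp <- file.path(out_dir, "population_summary.csv")
  utils::write.csv(format_df_full_precision(summary), sp, row.names = FALSE)
  log_line("gated %d cells into %d populations", nrow(assigned), length(gates))
  list(cells_gated = ap, population_summary = sp)
}

stage_spatial <- function(s, input_dir, out_dir, ps, log_line) {
  cells <- read_labels(input_dir, ps)
  pc <- s$plaque_channel %||% "abeta"
  ab <- read_channel(require_input(input_dir, paste0(pc, ".tif")), ps, pc)
  pm <- adaptive_threshold(ab, s$plaque_window_px %||% 63L, s$plaque_offset %||% 5)
  bins <- distance_bins(cells, pm, s$step_um %||% 5, s$max_um %||% 50)
  tblp <- file.path(input_dir, s$cells %||% "cells.csv")
  outputs <- list()
  if (file.exists(tblp)) {
    tbl <- read_cell_table(tblp)
    tbl$plaque_bin_um <- bins$plaque_bin_um[match(tbl$cell_id, bins$cell_id)]
    tbl$plaque_group <- bins$plaque_group[match(tbl$cell_id, bins$cell_id)]
    cp <- file.path(out_dir, "cells_spatial.csv")
    write_cell_table(tbl, cp)
    outputs$cells_spatial <- cp
  }
  summ <- group_and_summarise(bins, by_bin = TRUE)
  gp <- file.path(out_dir, "spatial_summary.csv")
  utils::write.csv(format_df_full_precision(summ$groups), gp, row.names = FALSE)
  log_line("plaque %.1f%%, adjacent %.1f%%, non-plaque %.1f%%",
           100 * summ$groups$proportion[1], 100 * summ$groups$proportion[2],
           100 * summ$groups$proportion[3])
  c(outputs, list(spatial_summary = gp))
}

stage_register <- function(s, input_dir, out_dir, ps, seed, log_line) {
  fx <- read_channel(require_input(input_dir, s$fixed %||% "nuclei.tif"), ps, "nuclei")
  mv <- read_channel(require_input(input_dir, s$moving %||% "nuclei_moving.tif"),
                     ps, "nuclei_moving")
  rr <- s$rolling_radius_px %||% 50L
  mr <- s$median_radius_px %||% 5L
  fx_p <- preprocess_nuclei(fx, rr, mr)
  mv_p <- preprocess_nuclei(mv, rr, mr)
  t <- estimate_affine(fx_p, mv_p, seed = seed %||% 1L,
                       ratio = s$ratio %||% 0.75,
                       ransac_tol_px = s$ransac_tol_px %||% 3,
                       model = s$model %||% "affine")
  log_line("affine from %d inliers, rms %.3f px", attr(t, "n_inliers"), attr(t, "rms_px"))
  tp <- file.path(out_dir, "transform.json")
  jsonlite::write_json(
    list(matrix = unclass(t), n_inliers = attr(t, "n_inliers"),
         n_matches = attr(t, "n_matches"), rms_px = attr(t, "rms_px")),
    tp, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  outputs <- list(transform = tp)
  for (ch in s$apply_to %||% character(0)) {
    img <- read_channel(require_input(input_dir, paste0(ch, ".tif")), ps, ch)
    reg <- apply_transform(t, img)
    reg$pixels <- round(reg$pixels)
    op <- file.path(out_dir, paste0(ch, "_registered.tif"))
    write_channel(reg, op)
    outputs[[paste0(ch, "_registered")]] <- op
  }
  outputs
}

stage_pathology <- function(s, input_dir, out_dir, ps, log_line) {
  chans <- s$channels %||% c("abeta", "tau")
  rows <- lapply(chans, function(ch) {
    img <- read_channel(require_input(input_dir, paste0(ch, ".tif")), ps, ch)
    m <- adaptive_threshold(img, s$window_px %||% 63L, s$offset %||% 5)
    data.frame(channel = ch,
               load_percent = pathology_load(m, s$roi_area_um2 %||% NULL))
  })
  df <- do.call(rbind, rows)
  lp <- file.path(out_dir, "pathology_load.csv")
  utils::write.csv(format_df_full_precision(df), lp, row.names = FALSE)
  log_line("%s", paste(sprintf("%s %.2f%%", df$channel, df$load_percent), collapse = ", "))
  list(pathology_load = lp)
}

stage_stats <- function(s, input_dir, out_dir, log_line) {
  mp <- require_input(input_dir, s$measurements %||% "measurements.csv")
  df <- utils::read.csv(mp, stringsAsFactors = FALSE)
  vc <- s$value_column %||% "value"
  gc <- s$group_column %||% "group"
  if (!all(c(vc, gc) %in% names(df))) {
    stop_histoflow(sprintf("measurements need columns '%s' and '%s'", vc, gc))
  }
  gl <- unique(df[[gc]])
  if (length(gl) != 2L) stop_histoflow("stats stage compares exactly two groups")
  rep <- choose_and_compare(df[[vc]][df[[gc]] == gl[1]],
                            df[[vc]][df[[gc]] == gl[2]],
                            alpha = s$alpha %||% 0.05)
  log_line("%s branch, p = %.4g", rep$branch, rep$p_value)
  rp <- file.path(out_dir, "test_report.json")
  jsonlite::write_json(
    list(test = rep$test, branch = rep$branch, statistic = rep$statistic,
         p_value = rep$p_value, significant = rep$significant,
         screening = as.list(rep$screening), groups = gl,
         summary = rep$summary),
    rp, auto_unbox = TRUE, digits = NA
  )
  list(test_report = rp)
}
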