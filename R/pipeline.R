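# Pipeline orchestration: run simulator-backed (or file-backed) datasets
# through the analysis stages, summarize per-condition metrics, apply the
# configured group comparisons, and write tidy CSV/JSON outputs with a
# provenance log. All randomness is derived from the single config seed, so
# a re-run with the same config is numerically identical.

#' Run the full quantification pipeline from a config
#'
#' The config (YAML file or equivalent list) declares datasets, one per
#' experimental condition and stage, each executed for `n_replicates`
#' replicates with seeds derived deterministically from the base seed.
#' Supported stages: `motility` (baseline simulation, mean motility
#' index), `velocity` (chemotaxis simulation, auto-tracked per-cell
#' velocity), `coverage` (engulfment simulation, percent coverage at the
#' final time point), `morphology` (field simulation, cell count, mean
#' endpoints and branch length), `intensity` (staining simulation, percent
#' in processes), `qpcr` (Cq table from CSV, fold change per group).
#'
#' Config keys: `seed`; `datasets`, a list of entries with `stage`,
#' `condition`, `n_replicates` and stage-specific `params`;
#' `comparisons`, optional entries with `stage`, `metric`, `design`,
#' `groups`, `posthoc`. An empty dataset list is a valid no-op.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir output directory; created if missing. `NULL` disables
#'   file output.
#' @return (invisibly) a list with `results` (tidy data frame: `stage`,
#'   `condition`, `replicate`, `metric`, `value`), `summary` (group
#'   mean +/- SEM per stage x condition x metric), `comparisons`, and
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  datasets <- cfg$datasets %||% list()
  rows <- list()
  k <- 0L
  for (ds in datasets) {
    stage <- ds$stage %||% stop("dataset entry without 'stage'")
    condition <- ds$condition %||% "all"
    n_rep <- as.integer(ds$n_replicates %||% 1L)
    params <- ds$params %||% list()
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      metrics <- run_stage(stage, params, derive_seed(seed, k))
      for (m in names(metrics)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stage, condition = condition, replicate = r,
          metric = m, value = metrics[[m]])
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), condition = character(0),
               replicate = integer(0), metric = character(0),
               value = numeric(0))
  summary_df <- summarize_results(results)
  comparisons <- run_comparisons(cfg$comparisons %||% list(), results)
  provenance <- list(seed = seed,
                     n_datasets = length(datasets),
                     package_version = as.character(utils::packageVersion("microgliaQuant")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."))
  out <- list(results = results, summary = summary_df,
              comparisons = comparisons, provenance = provenance)
  if (!is.null(out_dir)) write_report(out, out_dir)
  invisible(out)
}

stage_cfg <- function(params, defaults) {
  geom <- utils::modifyList(defaults, params[names(params) %in%
    c("image_shape", "pixel_size", "frame_interval", "n_frames",
      "noise_sigma", "background_level")])
  geom
}

run_stage <- function(stage, params, seed) {
  switch(stage,
    motility = {
      g <- stage_cfg(params, list(image_shape = c(256L, 256L), pixel_size = 284 / 1024,
                                  frame_interval = 20, n_frames = 16L,
                                  noise_sigma = 3, background_level = 20))
      cfg <- sim_config(image_shape = unlist(g$image_shape), pixel_size = g$pixel_size,
                        frame_interval = g$frame_interval, n_frames = g$n_frames,
                        seed = seed, noise_sigma = g$noise_sigma,
                        background_level = g$background_level)
      sim <- simulate_baseline_timelapse(cfg, turnover_rate = params$turnover_rate %||% 0.1)
      res <- timelapse_motility(sim$stack)
      list(mean_index = res$mean_index)
    },
    velocity = {
      g <- stage_cfg(params, list(image_shape = c(256L, 256L), pixel_size = 284 / 1024,
                                  frame_interval = 20, n_frames = 16L,
                                  noise_sigma = 3, background_level = 20))
      cfg <- sim_config(image_shape = unlist(g$image_shape), pixel_size = g$pixel_size,
                        frame_interval = g$frame_interval, n_frames = g$n_frames,
                        seed = seed, noise_sigma = g$noise_sigma,
                        background_level = g$background_level)
      sim <- simulate_chemotaxis(cfg, tip_velocity = params$tip_velocity %||% 1.5,
                                 n_processes = params$n_processes %||% 3L,
                                 jitter_sd_px = params$jitter_sd_px %||% 0)
      tracks <- auto_track_tips(sim$stack, sim$truth$pipette_xy,
                                n_tips = params$n_processes %||% 3L)
      v <- vapply(tracks, function(tr) {
        track_velocity(tr, cfg$pixel_size, cfg$frame_interval)$velocity_um_min
      }, numeric(1))
      list(per_cell_velocity = aggregate_cell(v)$per_cell_velocity)
    },
    coverage = {
      g <- stage_cfg(params, list(image_shape = c(256L, 256L), pixel_size = 284 / 2048,
                                  frame_interval = 900, n_frames = 9L,
                                  noise_sigma = 3, background_level = 20))
      cfg <- sim_config(image_shape = unlist(g$image_shape), pixel_size = g$pixel_size,
                        frame_interval = g$frame_interval, n_frames = g$n_frames,
                        seed = seed, noise_sigma = g$noise_sigma,
                        background_level = g$background_level)
      sched <- params$schedule %||% list(c(0, 0), c(45, 51), c(120, 70))
      sched <- do.call(rbind, lapply(sched, function(s) data.frame(minute = s[[1]], percent = s[[2]])))
      sim <- simulate_abeta_engulfment(cfg, schedule = sched)
      ts <- coverage_timeseries(sim$stack)
      pts <- ts$points
      list(percent_coverage_final = pts$percent_coverage[nrow(pts)])
    },
    morphology = {
      g <- stage_cfg(params, list(image_shape = c(1024L, 1024L), pixel_size = 284 / 1024,
                                  frame_interval = 20, n_frames = 1L,
                                  noise_sigma = 3, background_level = 20))
      cfg <- sim_config(image_shape = unlist(g$image_shape), pixel_size = g$pixel_size,
                        frame_interval = g$frame_interval, n_frames = g$n_frames,
                        seed = seed, noise_sigma = g$noise_sigma,
                        background_level = g$background_level)
      sim <- simulate_field(cfg, n_cells = params$n_cells %||% 8L)
      fc <- count_cells(sim$stack, field_depth_um = sim$truth$field_depth_um)
      fm <- field_morphology(sim$stack)
      list(n_cells = fc$n_cells,
           density_per_mm3 = fc$density_per_mm3,
           mean_endpoints = mean(fm$cells$endpoints),
           mean_branch_length_um = mean(fm$cells$branch_length_um))
    },
    intensity = {
      g <- stage_cfg(params, list(image_shape = c(512L, 512L), pixel_size = 284 / 1024,
                                  frame_interval = 20, n_frames = 1L,
                                  noise_sigma = 0, background_level = 0))
      cfg <- sim_config(image_shape = unlist(g$image_shape), pixel_size = g$pixel_size,
                        frame_interval = g$frame_interval, n_frames = g$n_frames,
                        seed = seed, noise_sigma = g$noise_sigma,
                        background_level = g$background_level)
      sim <- simulate_intensity_image(cfg, soma_fraction = params$soma_fraction %||% 0.25)
      part <- intensity_partition(sim$stack, sim$soma_masks)
      list(percent_in_processes = part$percent_in_processes,
           total_intensity = part$total_intensity)
    },
    qpcr = {
      file <- params$file %||% stop("qpcr stage needs params$file (Cq CSV)")
      tab <- utils::read.csv(file)
      fc <- ddct_fold_change(tab, reference_group = params$reference_group %||% "E3",
                             reference_gene = params$reference_gene %||% "GAPDH")
      vals <- fc$groups$fold_change
      names(vals) <- paste0("fold_change_", fc$groups$gene, "_", fc$groups$group)
      as.list(vals)
    },
    stop("unknown stage: ", stage))
}

summarize_results <- function(results) {
  if (nrow(results) == 0L) {
    return(data.frame(stage = character(0), condition = character(0),
                      metric = character(0), n = integer(0),
                      mean = numeric(0), sem = numeric(0)))
  }
  parts <- split(results, list(results$stage, results$condition, results$metric),
                 drop = TRUE)
  out <- lapply(parts, function(d) {
    data.frame(stage = d$stage[1], condition = d$condition[1],
               metric = d$metric[1], n = nrow(d), mean = mean(d$value),
               sem = if (nrow(d) > 1) sem(d$value) else NA_real_)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$stage, df$metric, df$condition), ]
}

run_comparisons <- function(specs, results) {
  lapply(specs, function(sp) {
    sub <- results[results$stage == sp$stage & results$metric == sp$metric &
                     results$condition %in% unlist(sp$groups), ]
    values <- split(sub$value, sub$condition)
    values <- values[unlist(sp$groups)]
    cmp <- compare_groups(values, design = sp$design %||% "t_test_two_tailed",
                          posthoc = sp$posthoc %||% "none")
    list(stage = sp$stage, metric = sp$metric, groups = unlist(sp$groups),
         result = cmp)
  })
}

write_report <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$results, file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(out$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  report <- list(summary = out$summary,
                 comparisons = lapply(out$comparisons, function(cm) {
                   list(stage = cm$stage, metric = cm$metric,
                        groups = cm$groups,
                        statistic = cm$result$statistic,
                        df = cm$result$df, p_value = cm$result$p_value)
                 }),
                 provenance = out$provenance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(paste("seed:", out$provenance$seed),
               paste("datasets:", out$provenance$n_datasets),
               paste("package:", out$provenance$package_version),
               paste("R:", out$provenance$r_version)),
             file.path(out_dir, "provenance.log"))
  invisible(out_dir)
}
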