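#' Configuration for the synthetic time-lapse generator
#'
#' Defaults mirror the motility acquisition geometry of the study this
#' package models: 1024 x 1024 px fields imaged every 20 s, with the pixel
#' pitch derived from a 284 um field width (284/1024 = 0.277 um/px). The
#' amyloid-beta presets use 2048 x 2048 px at 15-min intervals (see
#' [simulate_abeta_engulfment()]). Intensities are arbitrary units on an
#' 8-bit-like 0-255 scale with additive Gaussian noise.
#'
#' @param image_shape pixels, `c(height, width)`.
#' @param pixel_size um/px, positive.
#' @param frame_interval s between frames, positive.
#' @param n_frames number of time points (single-frame modes ignore this).
#' @param seed integer; the one seed governing all stochastic draws of a
#'   simulation. Identical config + seed gives bit-identical output; the
#'   global RNG state is left untouched.
#' @param noise_sigma s.d. of additive Gaussian intensity noise (a.u.).
#' @param background_level background intensity (a.u.).
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(image_shape = c(1024L, 1024L), pixel_size = 284 / 1024,
                       frame_interval = 20, n_frames = 61L, seed = 1L,
                       noise_sigma = 3, background_level = 20) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), noise_sigma = noise_sigma,
                 background_level = background_level),
            class = "SimConfig")
}

# Render one frame: background + per-level masks + Gaussian noise, quantized
# to the 0-255 integer grid.
render_frame <- function(cfg, masks, levels, background = cfg$background_level) {
  img <- matrix(background, cfg$image_shape[1], cfg$image_shape[2])
  for (i in seq_along(masks)) img[masks[[i]]] <- levels[[i]]
  if (cfg$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sigma),
                        nrow(img), ncol(img))
  }
  quantize8(img)
}

# A ramified cell: soma disk plus straight branches radiating from the soma
# centre at well-separated angles. Returns the mask, the per-branch pixel
# chains, tip positions, and chamfer lengths (px).
make_ramified_cell <- function(shape, center_xy, soma_radius = 3,
                               n_branches = 5, branch_length_px = c(40, 70),
                               brush = 0L, angle_jitter = 0.25) {
  spacing <- 2 * pi / n_branches
  angles <- (seq_len(n_branches) - 1) * spacing + stats::runif(1, 0, 2 * pi) +
    stats::runif(n_branches, -angle_jitter, angle_jitter) * spacing
  lens <- stats::runif(n_branches, branch_length_px[1], branch_length_px[2])
  mask <- rasterize_disk(shape, center_xy, soma_radius)
  chains <- vector("list", n_branches)
  tips <- matrix(0, n_branches, 2)
  chamfer_px <- numeric(n_branches)
  for (b in seq_len(n_branches)) {
    tip <- center_xy + lens[b] * c(cos(angles[b]), sin(angles[b]))
    tip <- clamp(tip, 2, rev(shape) - 1)
    chain <- polyline_chain(rbind(center_xy, tip))
    chains[[b]] <- chain
    tips[b, ] <- chain[nrow(chain), ]
    chamfer_px[b] <- chamfer_chain_length(chain)
    mask <- mask | stamp_chain(shape, chain, brush = brush)
  }
  list(mask = mask, chains = chains, tips = tips, chamfer_px = chamfer_px,
       center = center_xy, soma_radius = soma_radius)
}

new_ground_truth <- function(...) structure(list(...), class = "GroundTruth")

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a baseline surveillance time-lapse with exact pixel turnover
#'
#' Builds one ramified cell and, per frame pair, flips approximately
#' `turnover_rate * A` of its `A` foreground pixels: half additions on the
#' outer margin (process growth), half removals from the boundary
#' (retraction). The exact extend/retract/stable counts of every pair are
#' recorded as ground truth, so the downstream motility pipeline can be
#' validated pixel-for-pixel at zero noise.
#'
#' @param cfg a [sim_config()].
#' @param turnover_rate proportion of cell pixels changed per frame pair,
#'   in `[0, 1)`.
#' @param foreground_level cell intensity (a.u.).
#' @return a list with `stack` (a `TYX` [image_stack()]) and `truth`
#'   (`GroundTruth` with `per_pair_change_counts`, a data frame of
#'   `extend`, `retract`, `stable`).
#' @export
simulate_baseline_timelapse <- function(cfg, turnover_rate,
                                        foreground_level = 150) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (turnover_rate < 0 || turnover_rate >= 1) {
    stop("turnover_rate must be in [0, 1)")
  }
  shape <- cfg$image_shape
  withr::with_seed(cfg$seed, {
    cell <- make_ramified_cell(shape, center_xy = rev(shape) / 2,
                               soma_radius = max(3, round(min(shape) / 40)),
                               n_branches = 5,
                               branch_length_px = c(0.15, 0.3) * min(shape),
                               brush = 1L)
    mask <- cell$mask
    nt <- cfg$n_frames
    frames <- array(0, c(nt, shape[1], shape[2]))
    counts <- data.frame(extend = integer(nt - 1), retract = integer(nt - 1),
                         stable = integer(nt - 1))
    frames[1, , ] <- render_frame(cfg, list(mask), foreground_level)
    for (t in seq_len(nt - 1)) {
      a <- sum(mask)
      n_target <- round(turnover_rate * a / 2)
      add_pool <- which(outer_ring8(mask))
      rem_pool <- which(inner_boundary8(mask))
      n_add <- min(n_target, length(add_pool))
      n_rem <- min(n_target, length(rem_pool))
      add <- add_pool[sample.int(length(add_pool), n_add)]
      rem <- rem_pool[sample.int(length(rem_pool), n_rem)]
      mask[rem] <- FALSE
      mask[add] <- TRUE
      counts$extend[t] <- as.integer(n_add)
      counts$retract[t] <- as.integer(n_rem)
      counts$stable[t] <- as.integer(a - n_rem)
      frames[t + 1, , ] <- render_frame(cfg, list(mask), foreground_level)
    }
  })
  stack <- image_stack(frames, axes = "TYX", pixel_size = cfg$pixel_size,
                       frame_interval = cfg$frame_interval)
  truth <- new_ground_truth(per_pair_change_counts = counts,
                            turnover_rate = turnover_rate,
                            initial_area_px = sum(cell$mask))
  list(stack = stack, truth = truth)
}

#' Simulate directed process chemotaxis toward a pipette
#'
#' `n_processes` tips advance toward `pipette_xy` at a programmed speed
#' (um/min, converted to px/frame through the pixel size and frame
#' interval), with optional isotropic positional jitter. A tip that comes
#' within the capture radius of the pipette stops advancing (arrival). The
#' exact continuous tip tracks are recorded as ground truth.
#'
#' @param cfg a [sim_config()].
#' @param tip_velocity programmed speed, um/min (>= 0).
#' @param pipette_xy pipette position `c(x, y)` px; default field centre.
#' @param n_processes number of tips (>= 1).
#' @param jitter_sd_px s.d. of per-frame Gaussian jitter on each axis (px).
#' @param capture_radius_um arrival radius around the pipette (um).
#' @param start_distance_px range of starting distances from the pipette.
#' @param tip_radius_px rendered tip blob radius.
#' @param foreground_level tip intensity (a.u.).
#' @return list with `stack` (`TYX` [image_stack()]) and `truth`
#'   (`GroundTruth` with `tip_tracks`, `arrival_frame`,
#'   `programmed_tip_velocity`, `step_px`).
#' @export
simulate_chemotaxis <- function(cfg, tip_velocity, pipette_xy = NULL,
                                n_processes = 3L, jitter_sd_px = 0,
                                capture_radius_um = 2,
                                start_distance_px = NULL, tip_radius_px = 2,
                                foreground_level = 150) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (n_processes < 1) stop("n_processes must be >= 1")
  if (tip_velocity < 0) stop("tip_velocity must be >= 0")
  shape <- cfg$image_shape
  pipette_xy <- pipette_xy %||% (rev(shape) / 2)
  if (pipette_xy[1] < 1 || pipette_xy[1] > shape[2] ||
      pipette_xy[2] < 1 || pipette_xy[2] > shape[1]) {
    stop("pipette must be inside the field")
  }
  step_px <- tip_velocity * (cfg$frame_interval / 60) / cfg$pixel_size
  capture_px <- capture_radius_um / cfg$pixel_size
  start_distance_px <- start_distance_px %||%
    (c(0.25, 0.4) * min(shape))
  nt <- cfg$n_frames
  withr::with_seed(cfg$seed, {
    ang <- stats::runif(1, 0, 2 * pi) +
      (seq_len(n_processes) - 1) * 2 * pi / n_processes
    r0 <- stats::runif(n_processes, start_distance_px[1], start_distance_px[2])
    pos <- cbind(x = pipette_xy[1] + r0 * cos(ang),
                 y = pipette_xy[2] + r0 * sin(ang))
    pos[, 1] <- clamp(pos[, 1], 1 + tip_radius_px, shape[2] - tip_radius_px)
    pos[, 2] <- clamp(pos[, 2], 1 + tip_radius_px, shape[1] - tip_radius_px)
    arrived <- rep(FALSE, n_processes)
    arrival_frame <- rep(NA_integer_, n_processes)
    track_x <- matrix(0, nt, n_processes)
    track_y <- matrix(0, nt, n_processes)
    frames <- array(0, c(nt, shape[1], shape[2]))
    for (t in seq_len(nt)) {
      if (t > 1L) {
        for (p in seq_len(n_processes)) {
          if (arrived[p]) next
          delta <- pipette_xy - pos[p, ]
          dist <- sqrt(sum(delta^2))
          adv <- if (dist > 0) min(step_px, dist) * delta / dist else c(0, 0)
          jit <- if (jitter_sd_px > 0) stats::rnorm(2, 0, jitter_sd_px) else c(0, 0)
          pos[p, ] <- pos[p, ] + adv + jit
          if (sqrt(sum((pipette_xy - pos[p, ])^2)) <= capture_px) {
            arrived[p] <- TRUE
            arrival_frame[p] <- t
          }
        }
      }
      track_x[t, ] <- pos[, 1]
      track_y[t, ] <- pos[, 2]
      # rasterize at the continuous centre so blob centroids track the true
      # subpixel position without systematic step-length bias
      tip_masks <- lapply(seq_len(n_processes), function(p) {
        rasterize_disk(shape, pos[p, ], tip_radius_px)
      })
      merged <- Reduce(`|`, tip_masks)
      frames[t, , ] <- render_frame(cfg, list(merged), foreground_level)
    }
  })
  tracks <- lapply(seq_len(n_processes), function(p) {
    process_track(data.frame(frame = seq_len(nt), x = track_x[, p],
                             y = track_y[, p]),
                  cell_id = "sim_cell", pipette_xy = pipette_xy)
  })
  stack <- image_stack(frames, axes = "TYX", pixel_size = cfg$pixel_size,
                       frame_interval = cfg$frame_interval)
  truth <- new_ground_truth(tip_tracks = tracks,
                            arrival_frame = arrival_frame,
                            programmed_tip_velocity = tip_velocity,
                            step_px = step_px, pipette_xy = pipette_xy)
  list(stack = stack, truth = truth)
}

#' Simulate progressive microglial coverage of an amyloid-beta deposit
#'
#' Channel 2 holds a fixed circular deposit; channel 1 holds microglial
#' pixels that overlap exactly the scheduled percentage of the deposit at
#' each rendered time point (linear interpolation between schedule knots).
#' Coverage grows contiguously from an approach side, with a process stalk
#' rendered outside the deposit. Default geometry follows the engulfment
#' acquisitions: 9 time points, 0-120 min by 15.
#'
#' @param cfg a [sim_config()]; for this mode the frame interval is in
#'   seconds as usual (default preset: 900 s = 15 min).
#' @param schedule data frame (or 2-column matrix) of `minute`, `percent`
#'   knots; minutes ascending, percents in `[0, 100]`.
#' @param deposit_radius_px radius of the deposit disk.
#' @param microglia_level,abeta_level channel intensities (a.u.).
#' @return list with `stack` (`TCYX` [image_stack()], channels
#'   `microglia`, `abeta`) and `truth` (`GroundTruth` with the input
#'   schedule and the exactly-rendered per-frame percents).
#' @export
simulate_abeta_engulfment <- function(cfg = sim_config(image_shape = c(2048L, 2048L),
                                                       pixel_size = 284 / 2048,
                                                       frame_interval = 900,
                                                       n_frames = 9L),
                                      schedule,
                                      deposit_radius_px = NULL,
                                      microglia_level = 150, abeta_level = 150) {
  stopifnot(inherits(cfg, "SimConfig"))
  schedule <- as.data.frame(schedule)
  if (nrow(schedule) == 0L || ncol(schedule) < 2L) {
    stop("schedule must not be empty")
  }
  names(schedule)[1:2] <- c("minute", "percent")
  if (any(schedule$percent < 0 | schedule$percent > 100)) {
    stop("schedule percents must be in [0, 100]")
  }
  if (is.unsorted(schedule$minute, strictly = FALSE)) {
    stop("schedule minutes must be sorted ascending")
  }
  shape <- cfg$image_shape
  deposit_radius_px <- deposit_radius_px %||% round(min(shape) / 8)
  center <- rev(shape) / 2
  disk <- rasterize_disk(shape, center, deposit_radius_px)
  disk_idx <- which(disk)
  a <- length(disk_idx)
  # order deposit pixels by distance from the approach point on the left edge
  # of the disk, so coverage grows contiguously like an advancing lamellipodium
  approach <- center - c(deposit_radius_px, 0)
  ys <- ((disk_idx - 1L) %% shape[1]) + 1L
  xs <- ((disk_idx - 1L) %/% shape[1]) + 1L
  ord <- order((xs - approach[1])^2 + (ys - approach[2])^2)
  disk_idx <- disk_idx[ord]
  minutes <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval / 60
  p_t <- if (nrow(schedule) == 1L) rep(schedule$percent, length(minutes)) else
    stats::approx(schedule$minute, schedule$percent, xout = minutes, rule = 2)$y
  k_t <- round(p_t / 100 * a)
  stalk <- stamp_chain(shape, polyline_chain(rbind(c(1, center[2]), approach)),
                       brush = 1L)
  stalk <- stalk & !disk
  nt <- cfg$n_frames
  frames <- array(0, c(nt, 2L, shape[1], shape[2]))
  withr::with_seed(cfg$seed, {
    for (t in seq_len(nt)) {
      mg <- matrix(FALSE, shape[1], shape[2])
      if (k_t[t] > 0) mg[disk_idx[seq_len(k_t[t])]] <- TRUE
      mg <- mg | stalk
      frames[t, 1, , ] <- render_frame(cfg, list(mg), microglia_level)
      frames[t, 2, , ] <- render_frame(cfg, list(disk), abeta_level)
    }
  })
  stack <- image_stack(frames, axes = "TCYX", pixel_size = cfg$pixel_size,
                       frame_interval = cfg$frame_interval,
                       channel_names = c("microglia", "abeta"))
  truth <- new_ground_truth(
    coverage_schedule = schedule,
    rendered = data.frame(minute = minutes, percent = 100 * k_t / a),
    deposit_area_px = a)
  list(stack = stack, truth = truth)
}

#' Simulate a single calibrated field of ramified cells
#'
#' Places `n_cells` non-overlapping ramified cells (bright soma, dimmer
#' 1-px-wide branches radiating from the soma centre) in one field and
#' records, per cell, the planted endpoint count (number of branch tips)
#' and the chamfer length of the rendered branch chains in micrometres,
#' which is what the skeleton-based morphometry measures.
#'
#' @param cfg a [sim_config()]; default field preset is 1024 x 1024 px at
#'   284/1024 um/px (a 284 x 284 um field).
#' @param n_cells number of cells to plant (>= 0).
#' @param soma_radius_px,n_branches,branch_length_um cell geometry;
#'   `n_branches` and `branch_length_um` may be length-2 ranges.
#' @param soma_level,process_level intensities (a.u.).
#' @param field_depth_um imaged depth used for the density denominator.
#' @param max_retries placement retries before giving up.
#' @return list with `stack` (single-frame `YX` [image_stack()]) and
#'   `truth` (`GroundTruth` with `planted_cell_count`, `soma_centers`,
#'   `planted_endpoint_counts`, `planted_branch_lengths_um`,
#'   `field_depth_um`).
#' @export
simulate_field <- function(cfg = sim_config(n_frames = 1L), n_cells,
                           soma_radius_px = 3, n_branches = c(4L, 6L),
                           branch_length_um = c(15, 25),
                           soma_level = 220, process_level = 120,
                           field_depth_um = 20, max_retries = 2000L,
                           min_separation_px = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), n_cells >= 0)
  shape <- cfg$image_shape
  max_len_px <- max(branch_length_um) / cfg$pixel_size
  margin <- max_len_px + soma_radius_px + 2
  # default keeps whole arbors disjoint so each cell is one component
  min_sep <- min_separation_px %||% (2 * max_len_px + 6)
  withr::with_seed(cfg$seed, {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("could not place ", n_cells, " cells with separation ",
             round(min_sep), " px in a ", shape[1], "x", shape[2], " field")
      }
      cand <- c(stats::runif(1, margin, shape[2] - margin),
                stats::runif(1, margin, shape[1] - margin))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 > min_sep^2)) {
        centers <- rbind(centers, cand)
      }
    }
    soma_mask <- matrix(FALSE, shape[1], shape[2])
    proc_mask <- matrix(FALSE, shape[1], shape[2])
    endpoints <- integer(n_cells)
    lengths_um <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      nb <- if (length(n_branches) > 1) sample(seq(n_branches[1], n_branches[2]), 1) else n_branches
      cell <- make_ramified_cell(shape, centers[i, ], soma_radius = soma_radius_px,
                                 n_branches = nb,
                                 branch_length_px = branch_length_um / cfg$pixel_size,
                                 brush = 0L)
      soma_mask <- soma_mask | rasterize_disk(shape, centers[i, ], soma_radius_px)
      proc_mask <- proc_mask | cell$mask
      endpoints[i] <- nb
      lengths_um[i] <- sum(cell$chamfer_px) * cfg$pixel_size
    }
    img <- render_frame(cfg, list(proc_mask & !soma_mask, soma_mask),
                        c(process_level, soma_level))
  })
  stack <- image_stack(img, axes = "YX", pixel_size = cfg$pixel_size)
  truth <- new_ground_truth(
    planted_cell_count = n_cells,
    soma_centers = if (n_cells > 0) data.frame(x = centers[, 1], y = centers[, 2])
                   else data.frame(x = numeric(0), y = numeric(0)),
    planted_endpoint_counts = endpoints,
    planted_branch_lengths_um = lengths_um,
    field_depth_um = field_depth_um)
  list(stack = stack, truth = truth)
}

#' Simulate a receptor-staining image with a programmed soma/process split
#'
#' Renders ramified cells whose soma and process intensities are chosen so
#' that the union of the soma masks contains exactly `soma_fraction` of the
#' total integrated signal (up to 8-bit quantization). Background is zero
#' in this mode so the partition refers to the signal alone.
#'
#' @param cfg a [sim_config()].
#' @param soma_fraction proportion of total intensity inside the somas,
#'   in `[0, 1]`.
#' @param n_cells,soma_radius_px,n_branches,branch_length_um geometry.
#' @return list with `stack` (single-frame `YX` [image_stack()]),
#'   `soma_masks` (list of [roi_mask()], one per cell) and `truth`
#'   (`GroundTruth` with programmed and achieved soma fractions).
#' @export
simulate_intensity_image <- function(cfg = sim_config(n_frames = 1L,
                                                      background_level = 0),
                                     soma_fraction, n_cells = 4L,
                                     soma_radius_px = 6, n_branches = 5L,
                                     branch_length_um = c(15, 25)) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (soma_fraction < 0 || soma_fraction > 1) {
    stop("soma_fraction must be in [0, 1]")
  }
  shape <- cfg$image_shape
  cfg_geom <- cfg
  cfg_geom$noise_sigma <- 0
  cfg_geom$background_level <- 0
  field <- simulate_field(cfg_geom, n_cells = n_cells,
                          soma_radius_px = soma_radius_px,
                          n_branches = n_branches,
                          branch_length_um = branch_length_um,
                          soma_level = 255, process_level = 128,
                          min_separation_px = 4 * soma_radius_px + 4)
  img0 <- field$stack$data
  soma_masks <- lapply(seq_len(max(n_cells, 0L)), function(i) {
    ctr <- as.numeric(field$truth$soma_centers[i, ])
    roi_mask(rasterize_disk(shape, ctr, soma_radius_px + 0.5),
             label = paste0("soma_", i))
  })
  soma_union <- if (n_cells > 0) Reduce(`|`, lapply(soma_masks, `[[`, "mask"))
                else matrix(FALSE, shape[1], shape[2])
  proc_region <- (img0 > 0) & !soma_union
  a_soma <- sum(soma_union); a_proc <- sum(proc_region)
  if (soma_fraction >= 1) {
    vs <- 100; vp <- 0
  } else if (soma_fraction <= 0 || a_soma == 0) {
    vs <- 0; vp <- 100
  } else {
    # intensity ratio soma/process that realizes the programmed split; derive
    # the smaller of the two levels so 8-bit rounding error stays small
    rho <- soma_fraction / (1 - soma_fraction) * a_proc / a_soma
    if (rho <= 2.5) { vp <- 100; vs <- round(100 * rho) }
    else { vs <- 250; vp <- round(250 / rho) }
  }
  img <- matrix(0, shape[1], shape[2])
  img[proc_region] <- vp
  img[soma_union] <- vs
  if (cfg$noise_sigma > 0) {
    img <- withr::with_seed(derive_seed(cfg$seed, 1L), {
      img + matrix(stats::rnorm(length(img), 0, cfg$noise_sigma),
                   nrow(img), ncol(img))
    })
  }
  img <- quantize8(img)
  achieved <- if (vs * a_soma + vp * a_proc > 0) {
    vs * a_soma / (vs * a_soma + vp * a_proc)
  } else NA_real_
  stack <- image_stack(img, axes = "YX", pixel_size = cfg$pixel_size)
  truth <- new_ground_truth(intensity_soma_fraction = soma_fraction,
                            achieved_soma_fraction = achieved)
  list(stack = stack, soma_masks = soma_masks, truth = truth)
}
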