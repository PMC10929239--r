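# The generators must be deterministic under a fixed seed, honour their
# programmed parameters exactly, and record ground truth that the analysis
# modules can recover.

test_that("identical config and seed give bit-identical stacks; seeds differ", {
  cfg <- small_cfg(seed = 1, n_frames = 4, noise_sigma = 2)
  a <- simulate_baseline_timelapse(cfg, 0.1)
  b <- simulate_baseline_timelapse(cfg, 0.1)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$per_pair_change_counts, b$truth$per_pair_change_counts)
  cfg2 <- small_cfg(seed = 2, n_frames = 4, noise_sigma = 2)
  c <- simulate_baseline_timelapse(cfg2, 0.1)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("simulation leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_baseline_timelapse(small_cfg(seed = 9, n_frames = 3), 0.1))
  expect_identical(.Random.seed, before)
})

test_that("zero turnover freezes the lapse and records all-zero changes", {
  cfg <- small_cfg(seed = 3, n_frames = 5)
  sim <- simulate_baseline_timelapse(cfg, 0)
  for (t in 2:5) expect_identical(sim$stack$data[t, , ], sim$stack$data[1, , ])
  expect_true(all(sim$truth$per_pair_change_counts$extend == 0))
  expect_true(all(sim$truth$per_pair_change_counts$retract == 0))
})

test_that("turnover rate outside [0, 1) is rejected", {
  cfg <- small_cfg()
  expect_error(simulate_baseline_timelapse(cfg, 1), "turnover_rate")
  expect_error(simulate_baseline_timelapse(cfg, -0.1), "turnover_rate")
})

test_that("recorded change counts obey the conservation identities", {
  cfg <- small_cfg(seed = 5, n_frames = 6)
  sim <- simulate_baseline_timelapse(cfg, 0.12)
  bin <- binarize(sim$stack, "fixed", value = 80)
  cc <- sim$truth$per_pair_change_counts
  for (t in seq_len(nrow(cc))) {
    area_t <- sum(bin$masks[t, , ])
    area_t1 <- sum(bin$masks[t + 1, , ])
    expect_identical(cc$extend[t] + cc$stable[t], area_t1)
    expect_identical(cc$retract[t] + cc$stable[t], area_t)
  }
})

test_that("programmed chemotaxis step follows the calibration arithmetic", {
  cfg <- sim_config(image_shape = c(256, 256), pixel_size = 0.277,
                    frame_interval = 20, n_frames = 10, seed = 1,
                    noise_sigma = 0)
  sim <- simulate_chemotaxis(cfg, tip_velocity = 1.5)
  expect_equal(sim$truth$step_px, 1.5 * (20 / 60) / 0.277, tolerance = 1e-12)
  pts <- sim$truth$tip_tracks[[1]]$points
  steps <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  expect_equal(steps, rep(sim$truth$step_px, length(steps)), tolerance = 1e-9)
  # doubling the pixel pitch halves the programmed px/frame step
  cfg2 <- sim_config(image_shape = c(256, 256), pixel_size = 0.554,
                     frame_interval = 20, n_frames = 10, seed = 1,
                     noise_sigma = 0)
  sim2 <- simulate_chemotaxis(cfg2, tip_velocity = 1.5)
  expect_equal(sim2$truth$step_px, sim$truth$step_px / 2, tolerance = 1e-12)
})

test_that("zero-velocity tips are stationary and arrival follows distance/velocity", {
  cfg <- sim_config(image_shape = c(300, 300), pixel_size = 0.277,
                    frame_interval = 20, n_frames = 70, seed = 2,
                    noise_sigma = 0)
  sim0 <- simulate_chemotaxis(cfg, tip_velocity = 0)
  for (tr in sim0$truth$tip_tracks) {
    expect_equal(stats::sd(tr$points$x), 0)
    expect_equal(stats::sd(tr$points$y), 0)
  }
  # a tip starting 30 um out at 1.5 um/min crosses the 2-um capture radius
  # after (30 - 2) / (1.5 / 3) = 56 frames of 20 s
  d_px <- 30 / 0.277
  sim <- simulate_chemotaxis(cfg, tip_velocity = 1.5, n_processes = 1L,
                             start_distance_px = c(d_px, d_px))
  expected_frame <- 1 + ceiling((30 - 2) / (1.5 * 20 / 60))
  expect_equal(sim$truth$arrival_frame[1], expected_frame, tolerance = 1)
  # after arrival the tip stops advancing
  pts <- sim$truth$tip_tracks[[1]]$points
  post <- pts[pts$frame >= sim$truth$arrival_frame[1], ]
  expect_lt(max(stats::sd(post$x), stats::sd(post$y)), 1e-9)
})

test_that("chemotaxis rejects invalid parameters", {
  cfg <- small_cfg()
  expect_error(simulate_chemotaxis(cfg, 1.5, n_processes = 0), "n_processes")
  expect_error(simulate_chemotaxis(cfg, -1), "tip_velocity")
  expect_error(simulate_chemotaxis(cfg, 1.5, pipette_xy = c(-5, 10)), "pipette")
})

test_that("engulfment schedules render the programmed coverage", {
  cfg <- sim_config(image_shape = c(128, 128), pixel_size = 284 / 2048,
                    frame_interval = 900, n_frames = 5, seed = 4,
                    noise_sigma = 0)
  expect_error(simulate_abeta_engulfment(cfg, data.frame()), "empty")
  expect_error(simulate_abeta_engulfment(cfg,
    data.frame(minute = c(0, 30), percent = c(0, 120))), "percent")
  expect_error(simulate_abeta_engulfment(cfg,
    data.frame(minute = c(30, 0), percent = c(0, 50))), "sorted")
  zero <- simulate_abeta_engulfment(cfg, data.frame(minute = 0, percent = 0))
  expect_true(all(zero$truth$rendered$percent == 0))
  full <- simulate_abeta_engulfment(cfg, data.frame(minute = 0, percent = 100))
  expect_equal(full$truth$rendered$percent[1], 100)
  mid <- simulate_abeta_engulfment(cfg,
    data.frame(minute = c(0, 60), percent = c(0, 60)))
  expect_equal(mid$truth$rendered$percent,
               c(0, 15, 30, 45, 60), tolerance = 0.5)
})

test_that("field simulator plants the requested number of separated cells", {
  cfg <- sim_config(image_shape = c(1024, 1024), pixel_size = 284 / 1024,
                    n_frames = 1, seed = 6)
  sim <- simulate_field(cfg, n_cells = 6)
  expect_equal(sim$truth$planted_cell_count, 6)
  ctr <- sim$truth$soma_centers
  d <- as.matrix(stats::dist(cbind(ctr$x, ctr$y)))
  diag(d) <- Inf
  expect_gt(min(d), 2 * 3)  # separation far exceeds twice the soma radius
  empty <- simulate_field(cfg, n_cells = 0)
  expect_equal(empty$truth$planted_cell_count, 0)
  # an over-packed small field fails after bounded retries
  tiny <- sim_config(image_shape = c(200, 200), pixel_size = 284 / 1024,
                     n_frames = 1, seed = 6)
  expect_error(simulate_field(tiny, n_cells = 10, max_retries = 50),
               "could not place")
})

test_that("a planted 4-branch cell records 4 endpoints and the polyline length", {
  cfg <- sim_config(image_shape = c(256, 256), pixel_size = 0.25,
                    n_frames = 1, seed = 8, noise_sigma = 0)
  sim <- simulate_field(cfg, n_cells = 1, n_branches = 4L,
                        branch_length_um = c(10, 10))
  expect_equal(sim$truth$planted_endpoint_counts, 4)
  # four 10-um branches: chamfer length of the rendered chains is within a
  # few percent of the 40-um geometric total
  expect_equal(sim$truth$planted_branch_lengths_um[1], 40, tolerance = 0.09)
})

test_that("intensity images honour the programmed soma fraction", {
  cfg <- sim_config(image_shape = c(256, 256), pixel_size = 284 / 1024,
                    n_frames = 1, seed = 2, noise_sigma = 0,
                    background_level = 0)
  expect_error(simulate_intensity_image(cfg, 1.2), "soma_fraction")
  s0 <- simulate_intensity_image(cfg, 0)
  expect_equal(intensity_partition(s0$stack, s0$soma_masks)$percent_in_processes, 100)
  s1 <- simulate_intensity_image(cfg, 1)
  expect_equal(intensity_partition(s1$stack, s1$soma_masks)$percent_in_processes, 0)
  s <- simulate_intensity_image(cfg, 0.4)
  expect_equal(s$truth$achieved_soma_fraction, 0.4, tolerance = 0.005)
})
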