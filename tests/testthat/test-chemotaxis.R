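# Track velocities, arrival truncation, per-cell aggregation and the
# automated tip tracker.

test_that("velocity is total path over elapsed time with unit conversion", {
  tr <- process_track(data.frame(frame = 1:10, x = 1:10, y = rep(5, 10)))
  v <- track_velocity(tr, pixel_size = 0.5, frame_interval = 20)
  expect_equal(v$path_um, 9 * 0.5)
  expect_equal(v$elapsed_min, 3)
  expect_equal(v$velocity_um_min, 1.5)
  still <- process_track(data.frame(frame = 1:5, x = rep(3, 5), y = rep(3, 5)))
  expect_equal(track_velocity(still, 0.5, 20)$velocity_um_min, 0)
})

test_that("arrival truncation keeps only pre-arrival points", {
  # 90 frames at 1 px/frame toward a pipette reached (within 2 um) at frame 30
  x <- seq(100, 100 - 89)
  pip <- c(x[30] - 2, 50)  # 2 px from the frame-30 position; pixel_size 1
  tr <- process_track(data.frame(frame = 1:90, x = x, y = rep(50, 90)),
                      pipette_xy = pip)
  v <- track_velocity(tr, pixel_size = 1, frame_interval = 60, capture_radius = 2)
  expect_equal(v$truncated_at_frame, 30)
  expect_equal(v$n_points_used, 30)
  expect_equal(v$path_um, 29)
  expect_equal(v$elapsed_min, 29)
  expect_equal(v$velocity_um_min, 1)
  # truncation never increases elapsed time
  v_full <- track_velocity(process_track(tr$points), 1, 60)
  expect_lte(v$elapsed_min, v_full$elapsed_min)
  # a track starting inside the capture radius has no usable pair
  tr0 <- process_track(data.frame(frame = 1:5, x = pip[1] + 0:4, y = rep(50, 5)),
                       pipette_xy = pip)
  v0 <- track_velocity(tr0, 1, 60)
  expect_true(is.na(v0$velocity_um_min))
  expect_equal(v0$n_points_used, 1)
})

test_that("velocity is invariant to rigid translation and frame relabeling", {
  withr::with_seed(41, {
    pts <- data.frame(frame = 1:12,
                      x = cumsum(stats::rnorm(12)) + 50,
                      y = cumsum(stats::rnorm(12)) + 50)
  })
  v0 <- track_velocity(process_track(pts), 0.3, 20)$velocity_um_min
  shifted <- transform(pts, x = x + 17.3, y = y - 8.1)
  expect_equal(track_velocity(process_track(shifted), 0.3, 20)$velocity_um_min, v0)
  relabeled <- transform(pts, frame = frame + 100L)
  expect_equal(track_velocity(process_track(relabeled), 0.3, 20)$velocity_um_min, v0)
})

test_that("path-length velocity is at least displacement velocity", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      pts <- data.frame(frame = 1:15,
                        x = cumsum(stats::rnorm(15)) + 100,
                        y = cumsum(stats::rnorm(15)) + 100)
      v <- track_velocity(process_track(pts), 0.277, 20)
      disp <- sqrt((pts$x[15] - pts$x[1])^2 + (pts$y[15] - pts$y[1])^2) * 0.277
      expect_gte(v$velocity_um_min + 1e-12, disp / v$elapsed_min)
    }
  })
})

test_that("per-cell aggregation averages defined velocities and logs exclusions", {
  r <- aggregate_cell(c(1.0, 1.2, 1.4))
  expect_equal(r$per_cell_velocity, 1.2)
  expect_equal(aggregate_cell(0.8)$per_cell_velocity, 0.8)
  r2 <- aggregate_cell(c(1.0, NA, 1.4))
  expect_equal(r2$per_cell_velocity, 1.2)
  expect_equal(r2$n_defined, 2)
  expect_equal(r2$n_excluded, 1)
  expect_warning(r3 <- aggregate_cell(c(NA_real_, NA_real_)), "no defined")
  expect_true(r3$excluded)
})

test_that("auto-tracking recovers programmed velocities and their ratio", {
  cfg <- sim_config(image_shape = c(256, 256), pixel_size = 0.277,
                    frame_interval = 20, n_frames = 21, seed = 17,
                    noise_sigma = 0)
  run_v <- function(vel) {
    sim <- simulate_chemotaxis(cfg, vel, n_processes = 3)
    tracks <- auto_track_tips(sim$stack, sim$truth$pipette_xy, 3)
    mean(vapply(tracks, function(tr) {
      track_velocity(tr, cfg$pixel_size, cfg$frame_interval)$velocity_um_min
    }, numeric(1)))
  }
  v08 <- run_v(0.8); v16 <- run_v(1.6)
  expect_equal(v08, 0.8, tolerance = 0.05)
  expect_equal(v16 / v08, 2.0, tolerance = 0.05)
  # a static stack yields zero velocities
  sim0 <- simulate_chemotaxis(cfg, 0, n_processes = 3)
  t0 <- auto_track_tips(sim0$stack, sim0$truth$pipette_xy, 3)
  for (tr in t0) {
    expect_equal(track_velocity(tr, cfg$pixel_size, cfg$frame_interval)$velocity_um_min, 0)
  }
})

test_that("truth tracks reproduce the programmed velocity to under 1%", {
  cfg <- sim_config(image_shape = c(256, 256), pixel_size = 0.277,
                    frame_interval = 20, n_frames = 21, seed = 19,
                    noise_sigma = 0)
  sim <- simulate_chemotaxis(cfg, 1.5, n_processes = 4)
  for (tr in sim$truth$tip_tracks) {
    v <- track_velocity(tr, cfg$pixel_size, cfg$frame_interval,
                        capture_radius = 0)
    expect_equal(v$velocity_um_min, 1.5, tolerance = 0.01)
  }
})

test_that("track CSVs round-trip through the reader", {
  df <- data.frame(track_id = rep(c("t1", "t2"), each = 3),
                   cell_id = "c1", frame = rep(1:3, 2),
                   x_px = c(1, 2, 3, 10, 11, 12), y_px = rep(5, 6))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  tracks <- read_tracks(f, pipette_xy = c(50, 50))
  expect_length(tracks, 2)
  expect_equal(tracks[["t1"]]$points$x, c(1, 2, 3))
  expect_equal(tracks[["t2"]]$pipette_xy, c(50, 50))
  expect_error(read_tracks(f <- {
    g <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), g, row.names = FALSE)
    g
  }), "columns")
})
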