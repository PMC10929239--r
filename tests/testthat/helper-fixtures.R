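# Shared fixture builders and independent oracles for the test suite.

# Logical mask from (row, col) coordinate pairs.
mask_from_coords <- function(shape, coords) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (length(coords)) m[do.call(rbind, coords)] <- TRUE
  m
}

# Brute-force per-pixel change classifier: the independent oracle for
# classify_pixel_changes, written as an explicit double loop.
brute_force_changes <- function(mask_t, mask_t1) {
  extend <- 0L; retract <- 0L; stable <- 0L
  for (i in seq_len(nrow(mask_t))) {
    for (j in seq_len(ncol(mask_t))) {
      a <- mask_t[i, j]; b <- mask_t1[i, j]
      if (a && b) stable <- stable + 1L
      else if (!a && b) extend <- extend + 1L
      else if (a && !b) retract <- retract + 1L
    }
  }
  list(extend = extend, retract = retract, stable = stable)
}

# Exact subpixel image translation via the Fourier shift theorem; used to
# construct ground-truth-shifted frames for registration tests.
fourier_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ky <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
  kx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  ph <- exp(-2i * pi * (outer(ky, rep(1, nc)) * dy / nr +
                        outer(rep(1, nr), kx) * dx / nc))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Small simulation geometry used throughout the suite (keeps runtimes low
# while preserving the calibration of the full-size acquisitions).
small_cfg <- function(seed = 1L, n_frames = 8L, shape = c(128L, 128L),
                      noise_sigma = 0, pixel_size = 284 / 1024,
                      frame_interval = 20, background_level = 20) {
  sim_config(image_shape = shape, pixel_size = pixel_size,
             frame_interval = frame_interval, n_frames = n_frames,
             seed = seed, noise_sigma = noise_sigma,
             background_level = background_level)
}

# Match recovered cells to planted truth by nearest soma centre.
match_cells_to_truth <- function(cells, soma_centers) {
  vapply(seq_len(nrow(soma_centers)), function(i) {
    which.min((cells$x - soma_centers$x[i])^2 + (cells$y - soma_centers$y[i])^2)
  }, integer(1))
}
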