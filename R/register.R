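# Translation registration by phase correlation.
#
# The cross-power spectrum of two frames that differ by a pure translation is
# a complex exponential whose inverse transform is a delta at the (negative)
# displacement. The integer peak is refined to subpixel precision by
# evaluating the inverse DFT on an upsampled grid around the peak with a
# direct matrix-multiply kernel, so no large zero-padded FFT is needed.

# Wrapped DFT frequency indices: 0, 1, ..., -2, -1 (centred on zero).
wrapped_freqs <- function(n) {
  v <- 0:(n - 1)
  v[v >= ceiling(n / 2)] <- v[v >= ceiling(n / 2)] - n
  v
}

wrap_index <- function(i, n) if (i >= ceiling(n / 2)) i - n else i

#' Estimate the translation between two frames by phase correlation
#'
#' Returns the shift `(dy, dx)` that, applied to `moving` (rows down by
#' `dy`, columns right by `dx`), best aligns it with `reference`.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param upsample subpixel refinement factor; 1 disables refinement, 10
#'   gives 0.1 px resolution.
#' @return numeric vector `c(dy, dx)` in pixels (possibly fractional).
#' @export
phase_correlate <- function(reference, moving, upsample = 10) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    warning("degenerate (constant) frame; returning zero shift")
    return(c(dy = 0, dx = 0))
  }
  nr <- nrow(reference); nc <- ncol(reference)
  R <- stats::fft(reference) * Conj(stats::fft(moving))
  R <- R / pmax(Mod(R), 1e-12)
  corr <- Re(stats::fft(R, inverse = TRUE))
  p <- which.max(corr)
  row0 <- (p - 1) %% nr
  col0 <- (p - 1) %/% nr
  d0 <- c(wrap_index(row0, nr), wrap_index(col0, nc))
  if (upsample <= 1) return(c(dy = d0[1], dx = d0[2]))

  # evaluate sum_k R_k exp(2*pi*i*k*u/N) on a fine grid u = d0 +/- 1 px
  fy <- wrapped_freqs(nr); fx <- wrapped_freqs(nc)
  uy <- d0[1] + seq(-1, 1, by = 1 / upsample)
  ux <- d0[2] + seq(-1, 1, by = 1 / upsample)
  kern_y <- exp((2i * pi / nr) * outer(uy, fy))        # |uy| x nr
  kern_x <- exp((2i * pi / nc) * outer(fx, ux))        # nc x |ux|
  cc <- Re(kern_y %*% R %*% kern_x)
  q <- which.max(cc)
  iy <- (q - 1) %% length(uy) + 1
  ix <- (q - 1) %/% length(uy) + 1
  c(dy = uy[iy], dx = ux[ix])
}

#' Stabilize a time-lapse by translation registration
#'
#' Aligns every frame to a reference frame with phase correlation and
#' applies the (nearest-integer) correcting shift. Pixels shifted in from
#' outside the field are filled with the stack's modal background
#' intensity, which avoids spurious "extension" pixels at the borders after
#' binarization.
#'
#' @param stack an [image_stack()] with `T >= 2` (axes `TYX`).
#' @param reference index of the reference frame (default 1).
#' @param upsample subpixel refinement factor passed to [phase_correlate()];
#'   the applied correction is rounded to whole pixels, the returned
#'   `shifts` table keeps the subpixel estimates.
#' @param mode `"progressive"` (default) estimates the shift of each frame
#'   against its predecessor and accumulates from the reference -- robust
#'   when the scene itself remodels between distant frames;
#'   `"fixed"` estimates every frame directly against the reference.
#' @return a list with `stack` (the registered [image_stack()]) and
#'   `shifts`, a data frame of `frame`, `dy`, `dx` (cumulative correction
#'   relative to the reference frame).
#' @export
register_translation <- function(stack, reference = 1L, upsample = 10,
                                 mode = c("progressive", "fixed")) {
  mode <- match.arg(mode)
  if (stack$axes != "TYX") stop("register_translation expects a TYX stack")
  nt <- n_frames(stack)
  if (nt < 2L) stop("registration needs at least 2 frames")
  frames <- lapply(seq_len(nt), function(t) get_frame(stack, t = t))
  fill <- modal_intensity(frames[[reference]])
  shifts <- matrix(0, nt, 2)
  if (mode == "fixed") {
    for (t in seq_len(nt)) {
      if (t == reference) next
      shifts[t, ] <- phase_correlate(frames[[reference]], frames[[t]],
                                     upsample = upsample)
    }
  } else {
    step <- matrix(0, nt, 2)
    for (t in 2:nt) {
      step[t, ] <- phase_correlate(frames[[t - 1L]], frames[[t]],
                                   upsample = upsample)
    }
    cum <- apply(step, 2, cumsum)
    # cumulative correction relative to the chosen reference frame
    shifts <- sweep(cum, 2, cum[reference, ])
  }
  out <- stack$data
  for (t in seq_len(nt)) {
    s <- round(shifts[t, ])
    if (any(s != 0)) out[t, , ] <- mat_shift(frames[[t]], s[1], s[2], fill = fill)
  }
  list(stack = set_data(stack, out),
       shifts = data.frame(frame = seq_len(nt), dy = shifts[, 1], dx = shifts[, 2]))
}
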