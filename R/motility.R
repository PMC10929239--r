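# Surveillance motility: binarize the time-lapse, classify per-pair pixel
# changes into extending / retracting / stable, and average the motility
# index (extend + retract) / stable over the lapse.

otsu_threshold <- function(m) {
  255 * EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1), levels = 256L)
}

#' Binarize a single-channel time-lapse
#'
#' Foreground is every pixel strictly above the threshold. The default
#' method computes one Otsu threshold on the temporal mean image and
#' applies it to all frames: a single fixed threshold avoids the
#' frame-to-frame flicker that per-frame thresholds introduce, which would
#' inflate the motility index.
#'
#' @param stack a single-channel [image_stack()] (`TYX` or `YX`).
#' @param method `"otsu_global"` (Otsu on the temporal mean, default),
#'   `"otsu_per_frame"`, or `"fixed"`.
#' @param value threshold for `method = "fixed"` (a.u.).
#' @return an object of class `BinaryTimelapse`: list with `masks`
#'   (`T x Y x X` logical array), `method`, `thresholds` (one per frame).
#' @export
binarize <- function(stack, method = c("otsu_global", "otsu_per_frame", "fixed"),
                     value = NULL) {
  method <- match.arg(method)
  if (n_channels(stack) != 1L) stop("binarize expects a single-channel stack")
  if (!stack$axes %in% c("TYX", "YX")) {
    stop("binarize expects a TYX (or YX) stack; project z first")
  }
  nt <- n_frames(stack)
  d <- dim(stack$data)
  ny <- d[length(d) - 1L]; nx <- d[length(d)]
  frames <- lapply(seq_len(nt), function(t) get_frame(stack, t = t))
  thresholds <- switch(method,
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold value")
      rep(value, nt)
    },
    otsu_global = {
      mean_img <- Reduce(`+`, frames) / nt
      rep(otsu_threshold(mean_img), nt)
    },
    otsu_per_frame = vapply(frames, otsu_threshold, numeric(1)))
  masks <- array(FALSE, c(nt, ny, nx))
  for (t in seq_len(nt)) masks[t, , ] <- frames[[t]] > thresholds[t]
  if (!any(masks)) warning("all frames have empty foreground")
  structure(list(masks = masks, method = method, thresholds = thresholds),
            class = "BinaryTimelapse")
}

#' Classify pixel changes between two binary frames
#'
#' Color-merge semantics of consecutive binarized frames: green pixels are
#' extensions (present only at t+1), red pixels retractions (present only
#' at t), yellow pixels stable structure (present in both).
#'
#' @param mask_t,mask_t1 logical matrices of identical shape.
#' @return an object of class `ChangeCounts`: list with integer `extend`,
#'   `retract`, `stable`.
#' @export
classify_pixel_changes <- function(mask_t, mask_t1) {
  if (!identical(dim(mask_t), dim(mask_t1))) {
    stop("mask shapes differ: ", paste(dim(mask_t), collapse = "x"), " vs ",
         paste(dim(mask_t1), collapse = "x"))
  }
  structure(list(extend = sum(mask_t1 & !mask_t),
                 retract = sum(mask_t & !mask_t1),
                 stable = sum(mask_t & mask_t1)),
            class = "ChangeCounts")
}

#' Motility index of one frame pair
#'
#' The index is (extending + retracting pixels) / stable pixels. With no
#' stable pixels the ratio is undefined; the pair is marked `NA` and
#' excluded from time-lapse averaging rather than propagating infinity.
#'
#' @param counts a [classify_pixel_changes()] result (or any list with
#'   `extend`, `retract`, `stable`).
#' @return a single numeric value, `NA` when `stable == 0`.
#' @export
motility_index <- function(counts) {
  if (counts$stable == 0) return(NA_real_)
  (counts$extend + counts$retract) / counts$stable
}

#' Motility index of a whole time-lapse
#'
#' Full surveillance pipeline: z-max projection (when a `Z` axis is
#' present), translation registration, ROI masking, binarization, per-pair
#' change classification, and the arithmetic mean of the defined per-pair
#' indices. A 20-min lapse at 20-s intervals (61 frames) yields 60 pairs.
#'
#' @param stack a single-channel [image_stack()] with `T >= 2`.
#' @param roi optional [roi_mask()] selecting one microglia.
#' @param method,value threshold settings, see [binarize()].
#' @param register run [register_translation()] first (default TRUE).
#' @param reference reference frame for registration.
#' @return an object of class `MotilityResult`: list with `per_pair_index`,
#'   `mean_index`, `n_pairs` (defined pairs), `excluded_pairs`, `counts`
#'   (per-pair data frame), `thresholds`, and `valid` (FALSE when every
#'   pair was undefined).
#' @export
timelapse_motility <- function(stack, roi = NULL,
                               method = c("otsu_global", "otsu_per_frame", "fixed"),
                               value = NULL, register = TRUE, reference = 1L) {
  method <- match.arg(method)
  if (grepl("Z", stack$axes)) stack <- max_project_z(stack)
  nt <- n_frames(stack)
  if (nt < 2L) stop("timelapse_motility needs at least 2 frames")
  if (register) stack <- register_translation(stack, reference = reference)$stack
  if (!is.null(roi)) stack <- apply_roi(stack, roi)
  bin <- binarize(stack, method = method, value = value)
  n_pairs_total <- nt - 1L
  counts <- data.frame(extend = integer(n_pairs_total),
                       retract = integer(n_pairs_total),
                       stable = integer(n_pairs_total))
  idx <- numeric(n_pairs_total)
  for (t in seq_len(n_pairs_total)) {
    cc <- classify_pixel_changes(bin$masks[t, , ], bin$masks[t + 1L, , ])
    counts[t, ] <- unclass(cc)[c("extend", "retract", "stable")]
    idx[t] <- motility_index(cc)
  }
  defined <- !is.na(idx)
  structure(list(per_pair_index = idx,
                 mean_index = if (any(defined)) mean(idx[defined]) else NA_real_,
                 n_pairs = sum(defined),
                 excluded_pairs = sum(!defined),
                 counts = counts,
                 thresholds = bin$thresholds,
                 valid = any(defined)),
            class = "MotilityResult")
}

#' @export
print.MotilityResult <- function(x, ...) {
  cat("MotilityResult: mean index ", signif(x$mean_index, 4), " over ",
      x$n_pairs, " pairs (", x$excluded_pairs, " excluded)\n", sep = "")
  invisible(x)
}
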