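# Two-channel percent coverage of an amyloid-beta deposit by microglial
# processes: yellow = overlap, red = deposit only, percent = yellow over
# (yellow + red).

#' Coverage fraction of one frame pair of masks
#'
#' Color-merge semantics of the two binarized channels: yellow pixels are
#' microglia overlapping the deposit, red pixels deposit not yet covered.
#' Percent coverage is `100 * yellow / (yellow + red)`; note that
#' `yellow + red` equals the deposit area.
#'
#' @param microglia_mask,abeta_mask logical matrices of identical shape.
#' @return list with `yellow_px`, `red_px`, `percent_coverage` (`NA` and
#'   `undefined = TRUE` when the deposit mask is empty).
#' @export
coverage_fraction <- function(microglia_mask, abeta_mask) {
  if (!identical(dim(microglia_mask), dim(abeta_mask))) {
    stop("mask shapes differ")
  }
  yellow <- sum(microglia_mask & abeta_mask)
  red <- sum(abeta_mask & !microglia_mask)
  if (yellow + red == 0L) {
    return(list(yellow_px = 0L, red_px = 0L, percent_coverage = NA_real_,
                undefined = TRUE))
  }
  list(yellow_px = yellow, red_px = red,
       percent_coverage = 100 * yellow / (yellow + red), undefined = FALSE)
}

#' Percent-coverage time series of a two-channel time-lapse
#'
#' Per time point: z-max projection per channel (when a `Z` axis is
#' present), independent per-channel binarization (the channels are
#' acquired separately, so no spectral unmixing is attempted), then
#' [coverage_fraction()]. The deposit mask is re-binarized per time point
#' by default (the deposit can diffuse or compact); `freeze_abeta = TRUE`
#' reuses the t = 1 deposit mask throughout, which makes a monotonically
#' growing microglia mask yield a non-decreasing series.
#'
#' @param stack a two-channel [image_stack()] (`TCYX` or `TZCYX`) with
#'   `T >= 2`.
#' @param channels length-2 vector of channel indices
#'   `c(microglia, abeta)`.
#' @param freeze_abeta reuse the first-frame deposit mask (default FALSE).
#' @param thresholds optional fixed thresholds `c(microglia, abeta)`;
#'   `NULL` applies one Otsu per channel computed on its temporal mean.
#' @return an object of class `CoverageTimeSeries`: list with `points`
#'   (data frame `minute`, `yellow_px`, `red_px`, `percent_coverage`) and
#'   `thresholds`.
#' @export
coverage_timeseries <- function(stack, channels = c(1L, 2L),
                                freeze_abeta = FALSE, thresholds = NULL) {
  if (grepl("Z", stack$axes)) stack <- max_project_z(stack)
  stopifnot(stack$axes == "TCYX")
  nt <- n_frames(stack)
  if (nt < 2L) stop("coverage_timeseries needs at least 2 time points")
  mg_frames <- lapply(seq_len(nt), function(t) get_frame(stack, t, channel = channels[1]))
  ab_frames <- lapply(seq_len(nt), function(t) get_frame(stack, t, channel = channels[2]))
  if (is.null(thresholds)) {
    thresholds <- c(otsu_threshold(Reduce(`+`, mg_frames) / nt),
                    otsu_threshold(Reduce(`+`, ab_frames) / nt))
  }
  ab0 <- ab_frames[[1]] > thresholds[2]
  if (!any(ab0)) stop("abeta channel empty at the first time point")
  minutes <- (seq_len(nt) - 1L) * stack$frame_interval / 60
  pts <- data.frame(minute = minutes, yellow_px = integer(nt),
                    red_px = integer(nt), percent_coverage = numeric(nt))
  for (t in seq_len(nt)) {
    mg <- mg_frames[[t]] > thresholds[1]
    ab <- if (freeze_abeta) ab0 else ab_frames[[t]] > thresholds[2]
    cf <- coverage_fraction(mg, ab)
    pts$yellow_px[t] <- cf$yellow_px
    pts$red_px[t] <- cf$red_px
    pts$percent_coverage[t] <- cf$percent_coverage
  }
  structure(list(points = pts, thresholds = thresholds,
                 freeze_abeta = freeze_abeta),
            class = "CoverageTimeSeries")
}

#' @export
print.CoverageTimeSeries <- function(x, ...) {
  cat("CoverageTimeSeries over", nrow(x$points), "time points:\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}
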