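#' Calibrated image stack
#'
#' Container for a fluorescence image stack with physical calibration. The
#' pixel array is stored with its axes named by a compact string such as
#' `"YX"`, `"TYX"`, `"ZYX"`, `"TZYX"` or `"TCYX"` (time, z-plane, channel,
#' row, column). Intensities are arbitrary units on an 8-bit-like 0-255
#' scale; the synthetic generators emit integer grids so that TIFF
#' round-trips are bit-exact.
#'
#' @param data numeric array (or matrix for a single `"YX"` image) whose
#'   dimensions follow `axes`.
#' @param axes character scalar naming the axes in order, a permutation-free
#'   subset of `T`, `Z`, `C`, `Y`, `X` ending in `"YX"`.
#' @param pixel_size pixel pitch in micrometres per pixel; must be positive.
#' @param frame_interval time between consecutive frames in seconds;
#'   required (positive) whenever the stack has more than one time point.
#' @param channel_names optional character vector naming the `C` axis.
#'
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, axes = NULL, pixel_size, frame_interval = NA_real_,
                        channel_names = NULL) {
  if (is.matrix(data) && is.null(axes)) axes <- "YX"
  if (is.null(axes)) stop("`axes` must be given for non-matrix data")
  ax <- strsplit(axes, "")[[1]]
  if (!identical(tail_2(ax), c("Y", "X"))) {
    stop("axes must end in 'YX', got: ", axes)
  }
  if (is.matrix(data)) dim(data) <- c(if (length(ax) > 2) rep(1L, length(ax) - 2L), dim(data))
  if (length(dim(data)) != length(ax)) {
    stop("data has ", length(dim(data)), " dimensions but axes is '", axes, "'")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar (um/px)")
  }
  nt <- axis_len(dim(data), ax, "T")
  if (nt > 1L && (is.na(frame_interval) || frame_interval <= 0)) {
    stop("frame_interval (s) must be positive for stacks with T > 1")
  }
  nc <- axis_len(dim(data), ax, "C")
  if (!is.null(channel_names) && length(channel_names) != nc) {
    stop("channel_names length (", length(channel_names), ") != channel count (", nc, ")")
  }
  structure(
    list(data = data, axes = axes, pixel_size = pixel_size,
         frame_interval = frame_interval,
         channel_names = channel_names %||% if (any(ax == "C")) paste0("ch", seq_len(nc)) else NULL),
    class = "ImageStack")
}

tail_2 <- function(x) x[c(length(x) - 1L, length(x))]

axis_len <- function(dims, ax, name) {
  i <- match(name, ax)
  if (is.na(i)) 1L else dims[i]
}

#' @export
print.ImageStack <- function(x, ...) {
  cat("ImageStack [", x$axes, "] ", paste(dim(x$data), collapse = " x "),
      "  pixel_size=", x$pixel_size, " um/px",
      if (!is.na(x$frame_interval)) paste0("  frame_interval=", x$frame_interval, " s"),
      "\n", sep = "")
  if (!is.null(x$channel_names)) cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of time points of a stack
#' @param stack an [image_stack()].
#' @return integer count (1 if the stack has no `T` axis).
#' @export
n_frames <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  axis_len(dim(stack$data), ax, "T")
}

#' Number of channels of a stack
#' @param stack an [image_stack()].
#' @return integer count (1 if the stack has no `C` axis).
#' @export
n_channels <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  axis_len(dim(stack$data), ax, "C")
}

#' Extract one 2-D frame from a stack
#'
#' @param stack an [image_stack()].
#' @param t time index (ignored when the stack has no `T` axis).
#' @param channel channel index (ignored without a `C` axis).
#' @param z z index (ignored without a `Z` axis).
#' @return a `Y x X` numeric matrix.
#' @export
get_frame <- function(stack, t = 1L, channel = 1L, z = 1L) {
  ax <- strsplit(stack$axes, "")[[1]]
  idx <- lapply(ax, function(a) switch(a, T = t, Z = z, C = channel,
                                       Y = quote(expr = ), X = quote(expr = )))
  do.call(`[`, c(list(stack$data), idx, list(drop = FALSE))) |> drop_to_matrix(dim(stack$data), ax)
}

drop_to_matrix <- function(x, dims, ax) {
  d <- dim(x)
  matrix(x, d[length(d) - 1L], d[length(d)])
}

# Replace the pixel array while keeping calibration (internal).
set_data <- function(stack, data, axes = stack$axes) {
  out <- stack
  out$data <- data
  out$axes <- axes
  out
}

#' Region-of-interest mask
#'
#' A boolean `Y x X` mask selecting the sub-image (typically one microglia)
#' in which a metric is computed.
#'
#' @param mask logical matrix (or numeric, coerced by `> 0`).
#' @param label optional text label.
#' @return an object of class `RoiMask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(mask = mask, label = label), class = "RoiMask")
}

#' @export
print.RoiMask <- function(x, ...) {
  cat("RoiMask '", x$label, "' ", nrow(x$mask), " x ", ncol(x$mask),
      " (", sum(x$mask), " px)\n", sep = "")
  invisible(x)
}
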