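#' Write a calibrated stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are written in `T` (then `Z`, then `C`) order, 8-bit grayscale.
#' Calibration and axis layout that the plain TIFF cannot carry travel in a
#' JSON sidecar named `<stem>.json` next to the image; [read_stack()] reads
#' it back automatically. Intensities must lie on the integer 0-255 grid
#' (the synthetic generators guarantee this), which makes the round-trip
#' bit-exact.
#'
#' @param stack an [image_stack()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  ax <- strsplit(stack$axes, "")[[1]]
  d <- dim(stack$data)
  nt <- axis_len(d, ax, "T"); nz <- axis_len(d, ax, "Z"); nc <- axis_len(d, ax, "C")
  pages <- vector("list", nt * nz * nc)
  k <- 0L
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    k <- k + 1L
    pages[[k]] <- get_frame(stack, t = t, channel = ch, z = z) / 255
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(axes = stack$axes, n_t = nt, n_z = nz, n_c = nc,
               pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Reads a multi-page grayscale TIFF, normalizing axes to
#' `T(,Z)(,C),Y,X`. Calibration comes from the JSON sidecar written by
#' [write_stack()] when present; explicit arguments override it. Missing
#' calibration with no override is an error.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration overrides (um/px, s).
#' @param axes,channel_names layout overrides for TIFFs without a sidecar;
#'   `axes` describes the page order, e.g. `"TYX"` or `"TCYX"`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       axes = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(pixel_size)) stop("no pixel size in metadata and none supplied")
  frame_interval <- frame_interval %||% meta$frame_interval %||% NA_real_
  axes <- axes %||% meta$axes
  n_pages <- length(pages)
  nt <- meta$n_t %||% NULL; nz <- meta$n_z %||% NULL; nc <- meta$n_c %||% NULL
  if (is.null(axes)) {
    axes <- if (n_pages == 1L) "YX" else "TYX"
  }
  ax <- strsplit(axes, "")[[1]]
  nc <- nc %||% if ("C" %in% ax) stop("channel count needed for axes '", axes, "' without sidecar") else 1L
  nz <- nz %||% 1L
  nt <- nt %||% (n_pages / (nz * nc))
  if (nt * nz * nc != n_pages) stop("page count ", n_pages, " does not match layout ", axes)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # grayscale written, first sample
    round(p * 255)
  })
  dims <- c(if ("T" %in% ax) nt, if ("Z" %in% ax) nz, if ("C" %in% ax) nc, ny, nx)
  data <- array(0, dims)
  k <- 0L
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    k <- k + 1L
    idx <- lapply(ax, function(a) switch(a, T = t, Z = z, C = ch,
                                         Y = quote(expr = ), X = quote(expr = )))
    data <- do.call(`[<-`, c(list(data), idx, list(value = mats[[k]])))
  }
  cn <- channel_names %||% (if (!is.null(meta$channel_names) && length(meta$channel_names)) meta$channel_names else NULL)
  image_stack(data, axes = axes, pixel_size = pixel_size,
              frame_interval = frame_interval, channel_names = cn)
}

#' Maximum-intensity projection across z
#'
#' Per-pixel maximum over the `Z` axis, collapsing 3-D volumes to 2-D
#' images; all other axes are preserved.
#'
#' @param stack an [image_stack()] with a `Z` axis.
#' @return an [image_stack()] without the `Z` axis.
#' @export
max_project_z <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  zi <- match("Z", ax)
  if (is.na(zi)) stop("stack has no Z axis")
  keep <- setdiff(seq_along(ax), zi)
  proj <- apply(stack$data, keep, max)
  if (length(keep) == 2L) proj <- matrix(proj, dim(stack$data)[keep[1]], dim(stack$data)[keep[2]])
  image_stack(proj, axes = paste(ax[keep], collapse = ""),
              pixel_size = stack$pixel_size, frame_interval = stack$frame_interval,
              channel_names = stack$channel_names)
}

#' Mask a stack to a region of interest
#'
#' Sets pixels outside the ROI to zero in every frame and channel.
#'
#' @param stack an [image_stack()].
#' @param roi a [roi_mask()] with the same `Y x X` shape as the frames.
#' @return the masked [image_stack()], with the ROI label recorded in
#'   attribute `"roi_label"`.
#' @export
apply_roi <- function(stack, roi) {
  stopifnot(inherits(roi, "RoiMask"))
  d <- dim(stack$data)
  ny <- d[length(d) - 1L]; nx <- d[length(d)]
  if (nrow(roi$mask) != ny || ncol(roi$mask) != nx) {
    stop("ROI shape ", nrow(roi$mask), "x", ncol(roi$mask),
         " does not match frames ", ny, "x", nx)
  }
  nd <- length(d)
  n_planes <- prod(d) / (ny * nx)
  # bring Y, X to the front so every YX plane is a contiguous column-major block
  front <- aperm(stack$data, c(nd - 1L, nd, seq_len(max(nd - 2L, 0L))))
  dim(front) <- c(ny * nx, n_planes)
  front[!as.vector(roi$mask), ] <- 0
  dim(front) <- c(ny, nx, d[seq_len(nd - 2L)])
  out <- aperm(front, c(2L + seq_len(nd - 2L), 1L, 2L))
  res <- set_data(stack, out)
  attr(res, "roi_label") <- roi$label
  res
}
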