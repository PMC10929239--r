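# Directed process velocity toward a point source (ATP- or abeta-containing
# pipette): path-length velocity of tracked tips with arrival truncation,
# per-cell aggregation, and an automated nearest-blob tracker for synthetic
# stacks.

#' Construct a process track
#'
#' An ordered sequence of tip positions for one microglial process,
#' optionally annotated with the pipette target used for arrival
#' truncation. Coordinates are 1-based pixels, `(x = column, y = row)`.
#'
#' @param points data frame with columns `frame` (strictly increasing
#'   integers), `x`, `y` (pixels).
#' @param cell_id label of the parent cell.
#' @param pipette_xy optional pipette position `c(x, y)` px.
#' @return an object of class `ProcessTrack`.
#' @export
process_track <- function(points, cell_id = "cell", pipette_xy = NULL) {
  stopifnot(is.data.frame(points), all(c("frame", "x", "y") %in% names(points)))
  if (nrow(points) < 1L) stop("a track needs at least one point")
  if (is.unsorted(points$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing")
  }
  structure(list(points = points[, c("frame", "x", "y")], cell_id = cell_id,
                 pipette_xy = pipette_xy),
            class = "ProcessTrack")
}

#' @export
print.ProcessTrack <- function(x, ...) {
  cat("ProcessTrack (", x$cell_id, "): ", nrow(x$points), " points, frames ",
      x$points$frame[1], "-", x$points$frame[nrow(x$points)],
      if (!is.null(x$pipette_xy)) paste0(", pipette (",
                                         paste(round(x$pipette_xy, 1), collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Path-length velocity of one tracked process
#'
#' Velocity is the total path length (sum of consecutive Euclidean step
#' lengths, converted to micrometres) divided by the elapsed time in
#' minutes -- the per-step distance semantics of manual tip tracking, not
#' net displacement. When the track carries a pipette position, it is
#' truncated at the first point within `capture_radius` of the pipette
#' (the process has arrived) and elapsed time ends there.
#'
#' @param track a [process_track()].
#' @param pixel_size um/px.
#' @param frame_interval s between consecutive frame indices.
#' @param capture_radius arrival radius in um (default 2).
#' @return list with `velocity_um_min` (`NA` when fewer than 2 usable
#'   points remain), `truncated_at_frame` (`NA` if no arrival),
#'   `path_um`, `elapsed_min`, `n_points_used`.
#' @export
track_velocity <- function(track, pixel_size, frame_interval,
                           capture_radius = 2) {
  stopifnot(inherits(track, "ProcessTrack"), pixel_size > 0, frame_interval > 0)
  pts <- track$points
  truncated_at <- NA_integer_
  if (!is.null(track$pipette_xy)) {
    d_um <- sqrt((pts$x - track$pipette_xy[1])^2 +
                 (pts$y - track$pipette_xy[2])^2) * pixel_size
    hit <- which(d_um <= capture_radius)
    if (length(hit) > 0L) {
      k <- hit[1]
      truncated_at <- pts$frame[k]
      pts <- pts[seq_len(k), , drop = FALSE]
    }
  }
  if (nrow(pts) < 2L) {
    return(list(velocity_um_min = NA_real_, truncated_at_frame = truncated_at,
                path_um = NA_real_, elapsed_min = NA_real_,
                n_points_used = nrow(pts)))
  }
  steps <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  path_um <- sum(steps) * pixel_size
  elapsed_min <- (pts$frame[nrow(pts)] - pts$frame[1]) * frame_interval / 60
  list(velocity_um_min = path_um / elapsed_min,
       truncated_at_frame = truncated_at,
       path_um = path_um, elapsed_min = elapsed_min,
       n_points_used = nrow(pts))
}

#' Aggregate process velocities to one value per cell
#'
#' The per-cell velocity is the arithmetic mean of the defined per-process
#' velocities (3-5 tracked processes per microglia is typical). Undefined
#' velocities are excluded and counted; a cell with no defined velocity is
#' flagged excluded.
#'
#' @param velocities numeric vector of per-process velocities (um/min),
#'   `NA` for undefined.
#' @param cell_id label.
#' @return an object of class `VelocityResult`: list with
#'   `per_process_velocity`, `per_cell_velocity`, `n_defined`,
#'   `n_excluded`, `excluded` (TRUE when no velocity was defined).
#' @export
aggregate_cell <- function(velocities, cell_id = "cell") {
  defined <- !is.na(velocities)
  if (!any(defined)) {
    warning("cell '", cell_id, "' has no defined process velocity; excluded")
  }
  structure(list(cell_id = cell_id,
                 per_process_velocity = velocities,
                 per_cell_velocity = if (any(defined)) mean(velocities[defined]) else NA_real_,
                 n_defined = sum(defined),
                 n_excluded = sum(!defined),
                 excluded = !any(defined)),
            class = "VelocityResult")
}

#' Automatically track tip blobs toward a pipette
#'
#' Automated stand-in for manual tip tracking on synthetic stacks: frames
#' are binarized (one global Otsu threshold unless a fixed value is
#' given), connected foreground blobs are reduced to centroids, the
#' `n_tips` blobs nearest the pipette at the first frame seed the tracks,
#' and each track links to the nearest centroid within `search_radius_px`
#' per subsequent frame. A track with no candidate in range is terminated
#' and flagged lost.
#'
#' @param stack a `TYX` [image_stack()].
#' @param pipette_xy pipette position `c(x, y)` px.
#' @param n_tips number of tracks to seed.
#' @param threshold optional fixed binarization threshold (a.u.).
#' @param search_radius_px per-frame linkage radius (default 10).
#' @return list of [process_track()]; lost tracks carry attribute
#'   `"lost_at_frame"`.
#' @export
auto_track_tips <- function(stack, pipette_xy, n_tips, threshold = NULL,
                            search_radius_px = 10) {
  if (grepl("Z", stack$axes)) stack <- max_project_z(stack)
  stopifnot(stack$axes == "TYX")
  shape <- dim(stack$data)[2:3]
  if (pipette_xy[1] < 1 || pipette_xy[1] > shape[2] ||
      pipette_xy[2] < 1 || pipette_xy[2] > shape[1]) {
    stop("pipette must be inside the field")
  }
  bin <- if (is.null(threshold)) binarize(stack, "otsu_global")
         else binarize(stack, "fixed", value = threshold)
  nt <- n_frames(stack)
  cents <- lapply(seq_len(nt), function(t) {
    component_centroids(label_components8(bin$masks[t, , ]))
  })
  c0 <- cents[[1]]
  if (nrow(c0) < n_tips) {
    stop("only ", nrow(c0), " foreground blobs at t = 1, need ", n_tips)
  }
  d0 <- sqrt((c0[, 1] - pipette_xy[1])^2 + (c0[, 2] - pipette_xy[2])^2)
  seed_idx <- order(d0)[seq_len(n_tips)]
  tracks <- lapply(seed_idx, function(i) {
    list(frame = 1L, x = c0[i, 1], y = c0[i, 2], lost = NA_integer_)
  })
  for (t in 2:nt) {
    ct <- cents[[t]]
    for (p in seq_along(tracks)) {
      tr <- tracks[[p]]
      if (!is.na(tr$lost)) next
      last <- length(tr$frame)
      if (nrow(ct) == 0L) { tracks[[p]]$lost <- t; next }
      d <- sqrt((ct[, 1] - tr$x[last])^2 + (ct[, 2] - tr$y[last])^2)
      j <- which.min(d)
      if (d[j] > search_radius_px) { tracks[[p]]$lost <- t; next }
      tracks[[p]]$frame <- c(tr$frame, t)
      tracks[[p]]$x <- c(tr$x, ct[j, 1])
      tracks[[p]]$y <- c(tr$y, ct[j, 2])
    }
  }
  lapply(seq_along(tracks), function(p) {
    tr <- tracks[[p]]
    out <- process_track(data.frame(frame = tr$frame, x = tr$x, y = tr$y),
                         cell_id = "auto", pipette_xy = pipette_xy)
    if (!is.na(tr$lost)) attr(out, "lost_at_frame") <- tr$lost
    out
  })
}

#' Read process tracks from CSV
#'
#' Expected columns: `track_id`, `cell_id`, `frame`, `x_px`, `y_px`
#' (1-based pixel coordinates, x = column).
#'
#' @param path CSV path.
#' @param pipette_xy optional pipette position attached to every track.
#' @return list of [process_track()], one per `track_id`.
#' @export
read_tracks <- function(path, pipette_xy = NULL) {
  df <- utils::read.csv(path)
  need <- c("track_id", "cell_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("track CSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    process_track(data.frame(frame = d$frame, x = d$x_px, y = d$y_px),
                  cell_id = as.character(d$cell_id[1]), pipette_xy = pipette_xy)
  })
}
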