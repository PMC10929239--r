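# Skeleton-based morphometry: cell counts per calibrated field, and per-cell
# endpoint counts and total branch length measured on the topological
# skeleton of the binarized cell.

# Zhang-Suen thinning of a logical mask to a 1-px-wide 8-connected skeleton,
# fully vectorized over the image.
thin_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # 8-neighbours in the conventional P2..P9 clockwise order starting north
      p2 <- mat_shift(m, 1L, 0L, FALSE);  p3 <- mat_shift(m, 1L, -1L, FALSE)
      p4 <- mat_shift(m, 0L, -1L, FALSE); p5 <- mat_shift(m, -1L, -1L, FALSE)
      p6 <- mat_shift(m, -1L, 0L, FALSE); p7 <- mat_shift(m, -1L, 1L, FALSE)
      p8 <- mat_shift(m, 0L, 1L, FALSE);  p9 <- mat_shift(m, 1L, 1L, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      cond <- cond & if (step == 1) (!(p2 & p4 & p6)) & (!(p4 & p6 & p8))
                     else (!(p2 & p4 & p8)) & (!(p2 & p6 & p8))
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Total skeleton length in pixels: minimum spanning tree of the 8-adjacency
# graph with orthogonal steps weighted 1 and diagonal steps sqrt(2). The MST
# de-duplicates the redundant diagonal adjacencies of corner configurations,
# so a straight n-px line measures n - 1.
skeleton_length_px <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 2L) return(0)
  node <- matrix(0L, nrow(skel), ncol(skel))
  node[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  dirs <- list(list(c(0L, 1L), 1), list(c(1L, 0L), 1),
               list(c(1L, 1L), sqrt(2)), list(c(1L, -1L), sqrt(2)))
  for (d in dirs) {
    shifted <- mat_shift(node, d[[1]][1], d[[1]][2], fill = 0L)
    both <- node > 0L & shifted > 0L
    if (any(both)) {
      from <- c(from, node[both]); to <- c(to, shifted[both])
      w <- c(w, rep(d[[2]], sum(both)))
    }
  }
  if (length(from) == 0L) return(0)
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- w
  sum(igraph::E(igraph::mst(g))$weight)
}

#' Skeletonize one cell mask and measure endpoints and branch length
#'
#' The binary cell (soma included) is reduced to its topological skeleton
#' by Zhang-Suen thinning. Endpoints -- skeleton pixels with exactly one
#' 8-neighbour, the standard skeleton-analysis definition -- count the
#' cell's processes; an isolated skeleton pixel counts as one endpoint.
#' Total branch length sums skeleton adjacency steps (1 px orthogonal,
#' sqrt(2) px diagonal) converted to micrometres.
#'
#' @param cell_mask logical matrix holding one connected cell.
#' @param pixel_size um/px.
#' @return an object of class `SkeletonMetrics`: list with `endpoints`,
#'   `total_branch_length_um`, `skeleton_px`, and the `skeleton` mask.
#' @export
skeletonize_cell <- function(cell_mask, pixel_size) {
  if (!is.matrix(cell_mask)) stop("cell_mask must be a matrix")
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop("empty cell mask")
  stopifnot(pixel_size > 0)
  skel <- thin_mask(cell_mask)
  nb <- neighbor_count8(skel)
  endpoints <- sum(skel & (nb == 1L | nb == 0L))
  structure(list(endpoints = endpoints,
                 total_branch_length_um = skeleton_length_px(skel) * pixel_size,
                 skeleton_px = sum(skel),
                 skeleton = skel),
            class = "SkeletonMetrics")
}

#' @export
print.SkeletonMetrics <- function(x, ...) {
  cat("SkeletonMetrics: ", x$endpoints, " endpoints, ",
      signif(x$total_branch_length_um, 4), " um total branch length (",
      x$skeleton_px, " skeleton px)\n", sep = "")
  invisible(x)
}

#' Count cells in a calibrated field
#'
#' Somas are detected as connected bright components above the threshold
#' and a minimum area; the count is also expressed as a density over the
#' field volume (field area times imaged depth).
#'
#' @param projection a single-frame `YX` [image_stack()] (a z-max
#'   projection) or a stack with a `Z` axis, projected internally.
#' @param min_area minimum component area in px (default 50).
#' @param threshold fixed intensity threshold; `NULL` for Otsu.
#' @param min_mean_intensity minimum mean component intensity; components
#'   dimmer than this are rejected. The default (modal background plus six
#'   robust deviations) guards against Otsu splitting a field that contains
#'   only background noise.
#' @param field_depth_um imaged depth in um for the volume denominator
#'   (default 20).
#' @return an object of class `FieldCount`: list with `n_cells`,
#'   `field_volume_um3`, `density_per_mm3`, `areas_px`.
#' @export
count_cells <- function(projection, min_area = 50L, threshold = NULL,
                        min_mean_intensity = NULL, field_depth_um = 20) {
  if (grepl("Z", projection$axes)) projection <- max_project_z(projection)
  img <- get_frame(projection)
  thr <- threshold %||% otsu_threshold(img)
  min_mean_intensity <- min_mean_intensity %||%
    (modal_intensity(img) + 6 * stats::mad(img))
  lab <- label_components8(img > thr)
  n_lab <- max(lab)
  areas <- if (n_lab > 0L) tabulate(lab[lab > 0L], nbins = n_lab) else integer(0)
  mean_int <- if (n_lab > 0L) {
    as.numeric(tapply(img[lab > 0L],
                      factor(lab[lab > 0L], levels = seq_len(n_lab)), mean))
  } else numeric(0)
  keep <- areas >= min_area & mean_int >= min_mean_intensity
  vol_um3 <- nrow(img) * ncol(img) * projection$pixel_size^2 * field_depth_um
  structure(list(n_cells = sum(keep),
                 field_volume_um3 = vol_um3,
                 density_per_mm3 = sum(keep) / (vol_um3 * 1e-9),
                 areas_px = areas[keep],
                 threshold = thr),
            class = "FieldCount")
}

#' @export
print.FieldCount <- function(x, ...) {
  cat("FieldCount: ", x$n_cells, " cells in ",
      signif(x$field_volume_um3, 4), " um^3 (",
      signif(x$density_per_mm3, 4), " cells/mm^3)\n", sep = "")
  invisible(x)
}

#' Per-cell skeleton morphometry of a whole field
#'
#' Binarize, label 8-connected components, drop components below the
#' minimum area, and skeletonize each remaining component. When
#' `soma_centers` are supplied, components containing more than one soma
#' are split by watershed on the distance transform before measuring.
#'
#' @param projection a single-frame `YX` [image_stack()] (or a `Z` stack,
#'   projected internally).
#' @param min_area minimum component area in px (default 50); smaller
#'   fragments (including isolated pixels) are excluded from cell
#'   statistics.
#' @param threshold fixed intensity threshold; `NULL` for Otsu.
#' @param soma_centers optional data frame of `x`, `y` soma markers used
#'   to split touching cells.
#' @return list with `cells` (data frame: `cell_id`, `x`, `y`, `area_px`,
#'   `endpoints`, `branch_length_um`) and `metrics` (list of
#'   [skeletonize_cell()] results).
#' @export
field_morphology <- function(projection, min_area = 50L, threshold = NULL,
                             soma_centers = NULL) {
  if (grepl("Z", projection$axes)) projection <- max_project_z(projection)
  img <- get_frame(projection)
  thr <- threshold %||% otsu_threshold(img)
  mask <- img > thr
  lab <- label_components8(mask)
  if (!is.null(soma_centers) && nrow(soma_centers) > 1L) {
    lab <- split_touching_cells(mask, lab, soma_centers)
  }
  n_lab <- max(lab)
  areas <- if (n_lab > 0L) tabulate(lab, nbins = n_lab) else integer(0)
  keep <- which(areas >= min_area)
  metrics <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    comp <- lab == keep[i]
    met <- skeletonize_cell(comp, projection$pixel_size)
    met$skeleton <- NULL
    metrics[[i]] <- met
    ys <- row(comp)[comp]; xs <- col(comp)[comp]
    rows[[i]] <- data.frame(cell_id = i, x = mean(xs), y = mean(ys),
                            area_px = areas[keep[i]],
                            endpoints = met$endpoints,
                            branch_length_um = met$total_branch_length_um)
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
               area_px = integer(0), endpoints = integer(0),
               branch_length_um = numeric(0))
  list(cells = cells, metrics = metrics, threshold = thr)
}

# Watershed split of components containing more than one soma marker, on the
# negated distance transform seeded implicitly by the markers' basins.
split_touching_cells <- function(mask, lab, soma_centers) {
  marker_lab <- lab[cbind(round(soma_centers$y), round(soma_centers$x))]
  multi <- unique(marker_lab[duplicated(marker_lab) & marker_lab > 0L])
  if (length(multi) == 0L) return(lab)
  next_label <- max(lab)
  for (l in multi) {
    comp <- lab == l
    dm <- EBImage::distmap(EBImage::Image(comp * 1))
    ws <- EBImage::imageData(EBImage::watershed(dm))
    ws[!comp] <- 0
    for (w in setdiff(unique(as.vector(ws)), 0)) {
      next_label <- next_label + 1L
      lab[ws == w] <- next_label
    }
  }
  # compact labels
  u <- sort(setdiff(unique(as.vector(lab)), 0L))
  relab <- integer(max(u) + 1L)
  relab[u + 1L] <- seq_along(u)
  lab[lab > 0L] <- relab[lab[lab > 0L] + 1L]
  lab
}
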