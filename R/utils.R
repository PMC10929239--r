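# Internal helpers shared across modules. Coordinates are R-native 1-based,
# (row = y, col = x); all micrometre conversions go through pixel_size.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Quantize rendered intensities to the 8-bit-like [0, 255] integer grid so
# TIFF write/read round-trips are bit-exact.
quantize8 <- function(x) round(clamp(x, 0, 255))

# Integer shift of a matrix, filling vacated pixels with `fill`.
mat_shift <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  y_src <- ys - dy
  x_src <- xs - dx
  yk <- y_src >= 1 & y_src <= ny
  xk <- x_src >= 1 & x_src <= nx
  if (any(yk) && any(xk)) {
    out[ys[yk], xs[xk]] <- m[y_src[yk], x_src[xk]]
  }
  out
}

# Number of TRUE 8-neighbours of every pixel.
neighbor_count8 <- function(mask) {
  m <- mask * 1L
  n <- matrix(0L, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    n <- n + mat_shift(m, dy, dx, fill = 0L)
  }
  n
}

# Background pixels 8-adjacent to the mask (one-pixel outer ring).
outer_ring8 <- function(mask) (neighbor_count8(mask) > 0L) & !mask

# Foreground pixels touching background (8-connectivity boundary).
inner_boundary8 <- function(mask) mask & (neighbor_count8(mask) < 8L)

# Modal intensity of a (rounded) image; used as the fill value after shifts.
modal_intensity <- function(m) {
  tab <- table(round(as.vector(m)))
  as.numeric(names(tab)[which.max(tab)])
}

# Logical disk of radius r centred at (x, y) in a ny x nx field.
rasterize_disk <- function(shape, center_xy, radius) {
  ny <- shape[1]; nx <- shape[2]
  cx <- center_xy[1]; cy <- center_xy[2]
  y <- matrix(seq_len(ny), ny, nx)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= radius^2
}

# Ordered Bresenham chain from p0 to p1, each of c(x, y); returns a matrix
# with columns x, y including both endpoints.
bresenham_points <- function(p0, p1) {
  x0 <- round(p0[1]); y0 <- round(p0[2])
  x1 <- round(p1[1]); y1 <- round(p1[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  pts <- matrix(0L, dx + dy + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx)  { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(i), , drop = FALSE]
}

# Pixel chain of a polyline given as a matrix of (x, y) vertices; consecutive
# duplicate pixels at segment joins are removed.
polyline_chain <- function(vertices) {
  n <- nrow(vertices)
  chain <- bresenham_points(vertices[1, ], vertices[min(2L, n), ])
  if (n > 2L) {
    for (k in 2L:(n - 1L)) {
      seg <- bresenham_points(vertices[k, ], vertices[k + 1L, ])
      chain <- rbind(chain, seg[-1L, , drop = FALSE])
    }
  }
  chain[!duplicated(chain), , drop = FALSE]
}

# Chamfer length (1 per orthogonal step, sqrt(2) per diagonal step) of an
# ordered pixel chain, in pixels.
chamfer_chain_length <- function(chain) {
  if (nrow(chain) < 2L) return(0)
  steps <- abs(diff(chain))
  sum(ifelse(steps[, 1] & steps[, 2], sqrt(2), 1))
}

# Stamp a pixel chain into a logical field with a square-ish brush of the
# given radius (0 = single pixel).
stamp_chain <- function(shape, chain, brush = 0L) {
  mask <- matrix(FALSE, shape[1], shape[2])
  off <- -brush:brush
  for (dy in off) for (dx in off) {
    xs <- chain[, 1] + dx
    ys <- chain[, 2] + dy
    keep <- xs >= 1 & xs <= shape[2] & ys >= 1 & ys <= shape[1]
    mask[cbind(ys[keep], xs[keep])] <- TRUE
  }
  mask
}

# 8-connected component labelling of a logical matrix via the pixel adjacency
# graph. Returns an integer matrix of labels (0 = background).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  node <- matrix(0L, nrow(mask), ncol(mask))
  node[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    shifted <- mat_shift(node, d[1], d[2], fill = 0L)
    both <- node > 0L & shifted > 0L
    if (any(both)) edges <- c(edges, rbind(node[both], shifted[both]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Centroids (x, y) of labelled components; rows ordered by label.
component_centroids <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  l <- lab[idx]
  ys <- ((idx - 1L) %% nrow(lab)) + 1L
  xs <- ((idx - 1L) %/% nrow(lab)) + 1L
  cx <- tapply(xs, l, mean)
  cy <- tapply(ys, l, mean)
  cbind(x = as.numeric(cx), y = as.numeric(cy))
}

# Derive a stream of sub-seeds from one base seed (kept well below 2^31).
derive_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2000000011L
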