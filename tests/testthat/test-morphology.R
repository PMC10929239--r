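# Skeleton morphometry: endpoints, branch length, field counts.

test_that("canonical shapes give the textbook endpoint counts and lengths", {
  line <- matrix(FALSE, 20, 20); line[10, 5:15] <- TRUE
  sk <- skeletonize_cell(line, 0.2)
  expect_equal(sk$endpoints, 2)
  expect_equal(sk$total_branch_length_um, 2.0)
  plus <- matrix(FALSE, 21, 21); plus[11, 6:16] <- TRUE; plus[6:16, 11] <- TRUE
  skp <- skeletonize_cell(plus, 1)
  expect_equal(skp$endpoints, 4)
  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  skd <- skeletonize_cell(dot, 1)
  expect_equal(skd$endpoints, 1)
  expect_equal(skd$total_branch_length_um, 0)
  diagonal <- matrix(FALSE, 20, 20); diagonal[cbind(4:15, 4:15)] <- TRUE
  skdg <- skeletonize_cell(diagonal, 1)
  expect_equal(skdg$endpoints, 2)
  expect_equal(skdg$total_branch_length_um, 11 * sqrt(2))
  expect_error(skeletonize_cell(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("metrics are invariant under rotation by 90 degrees and mirroring", {
  withr::with_seed(51, {
    cfg <- sim_config(image_shape = c(200, 200), pixel_size = 0.25,
                      n_frames = 1, seed = 51, noise_sigma = 0)
    sim <- simulate_field(cfg, n_cells = 1, n_branches = 5L,
                          branch_length_um = c(8, 12))
    mask <- get_frame(sim$stack) > 60
  })
  base <- skeletonize_cell(mask, 1)
  rot <- skeletonize_cell(t(mask)[ncol(mask):1, ], 1)          # 90 deg
  mir <- skeletonize_cell(mask[, ncol(mask):1], 1)             # mirror
  expect_equal(rot$endpoints, base$endpoints)
  expect_equal(mir$endpoints, base$endpoints)
  # thinning sub-iterations are directionally asymmetric, so lengths agree
  # to a fraction of a percent rather than exactly
  expect_equal(rot$total_branch_length_um, base$total_branch_length_um,
               tolerance = 0.01)
  expect_equal(mir$total_branch_length_um, base$total_branch_length_um,
               tolerance = 0.01)
})

test_that("digital line length tracks geometric length near axis and diagonal", {
  # the (1, sqrt(2)) chamfer estimator is within 5% of the Euclidean length
  # for orientations near the axes or the diagonal
  for (ang in c(0, 5, 40, 45, 85, 90) * pi / 180) {
    p1 <- c(30, 30)
    p2 <- p1 + 55 * c(cos(ang), sin(ang))
    chain <- microgliaQuant:::polyline_chain(rbind(p1, p2))
    mask <- microgliaQuant:::stamp_chain(c(120, 120), chain, brush = 0L)
    sk <- skeletonize_cell(mask, 1)
    geo <- sqrt(sum((round(p2) - p1)^2))
    expect_lt(abs(sk$total_branch_length_um - geo) / geo, 0.05)
  }
})

test_that("endpoint count equals the leaf count of the skeleton graph", {
  # graph-theoretic oracle: degree-1 vertices of the graph whose vertices are
  # skeleton pixels and whose edges connect 8-adjacent pairs (independent of
  # the convolution-based neighbour counting in the implementation)
  leaf_count <- function(skel) {
    idx <- which(skel)
    node <- matrix(0L, nrow(skel), ncol(skel))
    node[idx] <- seq_along(idx)
    edges <- integer(0)
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      sh <- microgliaQuant:::mat_shift(node, d[1], d[2], 0L)
      both <- node > 0L & sh > 0L
      edges <- c(edges, rbind(node[both], sh[both]))
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    sum(igraph::degree(g) <= 1)
  }
  withr::with_seed(53, {
    for (s in 1:4) {
      cfg <- sim_config(image_shape = c(220, 220), pixel_size = 0.25,
                        n_frames = 1, seed = 53 + s, noise_sigma = 0)
      sim <- simulate_field(cfg, n_cells = 1, n_branches = 5L,
                            branch_length_um = c(8, 13))
      mask <- get_frame(sim$stack) > 60
      sk <- skeletonize_cell(mask, 1)
      expect_equal(sk$endpoints, leaf_count(sk$skeleton))
    }
  })
  # on explicit tree-shaped skeletons the leaves are the planted tips
  plus <- matrix(FALSE, 15, 15); plus[8, 3:13] <- TRUE; plus[3:13, 8] <- TRUE
  expect_equal(skeletonize_cell(plus, 1)$endpoints, leaf_count(plus))
  expect_equal(leaf_count(plus), 4)
})

test_that("cell counts and densities follow the field calibration", {
  cfg <- sim_config(image_shape = c(1024, 1024), pixel_size = 284 / 1024,
                    n_frames = 1, seed = 11)
  sim <- simulate_field(cfg, 12)
  fc <- count_cells(sim$stack, field_depth_um = 20)
  expect_equal(fc$n_cells, 12)
  # 284 x 284 x 20 um = 1.61312e-3 mm^3 -> ~7439 cells/mm^3
  expect_equal(fc$field_volume_um3, 284 * 284 * 20, tolerance = 0.01)
  expect_equal(fc$density_per_mm3, 12 / (fc$field_volume_um3 * 1e-9))
  expect_equal(round(fc$density_per_mm3), 7439, tolerance = 0.01)
  empty <- simulate_field(cfg, 0)
  expect_equal(count_cells(empty$stack)$n_cells, 0)
})

test_that("density scales linearly with the planted cell count", {
  counts <- c(3L, 6L)
  dens <- vapply(counts, function(n) {
    cfg <- sim_config(image_shape = c(1024, 1024), pixel_size = 284 / 1024,
                      n_frames = 1, seed = 23)
    count_cells(simulate_field(cfg, n)$stack)$density_per_mm3
  }, numeric(1))
  expect_equal(dens[2] / dens[1], 2, tolerance = 1e-9)
})

test_that("field morphometry recovers planted endpoints and branch lengths", {
  cfg <- sim_config(image_shape = c(768, 768), pixel_size = 284 / 1024,
                    n_frames = 1, seed = 29)
  sim <- simulate_field(cfg, 5)
  fm <- field_morphology(sim$stack)
  expect_equal(nrow(fm$cells), 5)
  ord <- match_cells_to_truth(fm$cells, sim$truth$soma_centers)
  expect_equal(fm$cells$endpoints[ord], sim$truth$planted_endpoint_counts)
  expect_equal(fm$cells$branch_length_um[ord],
               sim$truth$planted_branch_lengths_um, tolerance = 0.05)
  # one straight-line cell gives a single two-endpoint record
  img <- matrix(0, 64, 64); img[32, 10:50] <- 150
  st <- image_stack(quantize8(img), pixel_size = 0.5)
  fm1 <- field_morphology(st, min_area = 10, threshold = 75)
  expect_equal(nrow(fm1$cells), 1)
  expect_equal(fm1$cells$endpoints, 2)
  # an empty field is a valid empty result
  st0 <- image_stack(matrix(0, 64, 64), pixel_size = 0.5)
  expect_equal(nrow(field_morphology(st0, threshold = 75)$cells), 0)
})
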