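test_that("euclidean matrix is a metric with the expected values", {
  cc <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  d <- euclidean_matrix(cc)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))
  set.seed(1)
  cc2 <- matrix(runif(30), ncol = 3)
  d2 <- euclidean_matrix(cc2)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
  }
})

test_that("density thresholding keeps the top-k edges with nested grids", {
  set.seed(2)
  n <- 5
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- sample(10:100, 10)
  w <- w + t(w)
  conn <- connectome(w, matrix(runif(15), ncol = 3))

  expect_identical(threshold_density(conn, 1)$weights, w)
  half <- threshold_density(conn, 0.5)
  expect_equal(sum(half$weights[upper.tri(half$weights)] > 0), 5)
  # the retained edges are exactly the 5 largest
  kept <- sort(half$weights[upper.tri(half$weights)][half$weights[upper.tri(half$weights)] > 0])
  expect_equal(kept, sort(sort(w[upper.tri(w)], decreasing = TRUE)[1:5]),
               ignore_attr = TRUE)

  # nesting: edges at density 0.2 are a subset of edges at density 0.4
  e2 <- threshold_density(conn, 0.2)$weights > 0
  e4 <- threshold_density(conn, 0.4)$weights > 0
  expect_true(all(e4[e2]))

  expect_error(threshold_density(conn, 0), class = "lagnav_invalid_argument")
  expect_error(threshold_density(conn, 1.2), class = "lagnav_invalid_argument")
})

test_that("cut-off ties break lexicographically and survive rescaling", {
  n <- 4
  w <- matrix(0, n, n)
  w[1, 2] <- w[2, 1] <- 7
  w[1, 3] <- w[3, 1] <- 7
  w[2, 3] <- w[3, 2] <- 7
  w[3, 4] <- w[4, 3] <- 9
  conn <- connectome(w, matrix(seq_len(12), ncol = 3))
  thr <- threshold_density(conn, 2 / 6)  # keep 2 of 4 edges
  expect_equal(thr$weights[3, 4], 9)
  expect_equal(thr$weights[1, 2], 7)  # (1,2) beats (1,3) and (2,3)
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 2)

  # scaling all weights by a positive constant keeps the same edge set
  conn10 <- connectome(w * 10, conn$coords)
  expect_identical(threshold_density(conn10, 2 / 6)$weights > 0,
                   thr$weights > 0)
})

test_that("weight-to-length remapping is positive, monotone, with Inf off-edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 9
  w[2, 3] <- w[3, 2] <- 3
  L <- weight_to_length(w)
  expect_equal(L[1, 2], -log10(9 / 10))
  expect_equal(L[2, 3], -log10(3 / 10))
  expect_true(is.infinite(L[1, 3]))
  expect_equal(diag(L), rep(0, 3), ignore_attr = TRUE)
  expect_lt(L[1, 2], L[2, 3])          # larger weight, shorter length
  expect_true(all(L[w > 0] > 0))

  # printed variant exposed for audit: -log10(W/max + 1), non-positive
  Lp <- weight_to_length(w, form = "printed")
  expect_equal(Lp[1, 2], -log10(9 / 9 + 1))
  expect_true(all(Lp[w > 0] <= 0))

  expect_error(weight_to_length(matrix(0, 2, 2)),
               class = "lagnav_invalid_argument")
})

test_that("shortest paths match closed forms and the exhaustive oracle", {
  # two nodes, one edge
  L2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(shortest_paths(L2), L2, ignore_attr = TRUE)

  # triangle with a shortcut through k
  Lt <- matrix(Inf, 3, 3)
  diag(Lt) <- 0
  Lt[1, 2] <- Lt[2, 1] <- 5
  Lt[1, 3] <- Lt[3, 1] <- 1
  Lt[3, 2] <- Lt[2, 3] <- 1
  expect_equal(shortest_paths(Lt)[1, 2], 2)

  set.seed(33)
  for (rep in 1:50) {
    g <- random_length_graph(sample(4:8, 1), p_edge = runif(1, 0.3, 0.9))
    expect_equal(shortest_paths(g$L), oracle_shortest_paths(g$L),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("navigation matches the step-by-step greedy oracle", {
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    g <- random_length_graph(n, p_edge = runif(1, 0.3, 0.9))
    nav <- navigate(g$L, g$conn$coords)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      ref <- oracle_navigate_pair(g$L, g$conn$coords, i, j)
      expect_equal(nav$lambda_nav[i, j], ref$lambda, tolerance = 1e-12)
      expect_equal(nav$d_nav[i, j], ref$d, tolerance = 1e-12)
      expect_equal(nav$hops_nav[i, j], ref$hops)
    }
  }
})

test_that("navigation succeeds in one hop on complete graphs and fails at dead ends", {
  set.seed(4)
  n <- 6
  w <- matrix(5, n, n); diag(w) <- 0
  coords <- matrix(runif(3 * n, 0, 50), ncol = 3)
  conn <- connectome(w, coords)
  L <- weight_to_length(conn)
  nav <- navigate(L, coords)
  d <- euclidean_matrix(coords)
  off <- row(w) != col(w)
  expect_equal(nav$hops_nav[off], rep(1, sum(off)))
  expect_equal(nav$lambda_nav[off], L[off])
  expect_equal(nav$d_nav[off], d[off])

  # s's only neighbour is a, whose only neighbour is s: s -> a -> s revisits
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 1   # s = 1, a = 2
  w2[3, 4] <- w2[4, 3] <- 1   # target component
  conn2 <- connectome(w2, matrix(c(0, 1, 10, 11, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 3))
  nav2 <- navigate(weight_to_length(conn2), conn2$coords)
  expect_true(is.infinite(nav2$lambda_nav[1, 3]))
  expect_true(is.infinite(nav2$d_nav[1, 3]))

  # isolated node: every walk from it fails
  w3 <- w2; w3[1, 2] <- w3[2, 1] <- 0
  nav3 <- navigate(weight_to_length(connectome(w3, conn2$coords)), conn2$coords)
  expect_true(all(is.infinite(nav3$lambda_nav[1, -1])))
})

test_that("shortest paths lower-bound navigation and D^nav dominates Euclid", {
  set.seed(5)
  for (rep in 1:20) {
    g <- random_length_graph(sample(5:8, 1), p_edge = runif(1, 0.4, 1))
    sp <- shortest_paths(g$L)
    nav <- navigate(g$L, g$conn$coords)
    expect_true(all(sp <= nav$lambda_nav + 1e-9))
    d <- euclidean_matrix(g$conn$coords)
    ok <- is.finite(nav$d_nav) & row(d) != col(d)
    expect_true(all(nav$d_nav[ok] >= d[ok] - 1e-9))
  }
  # equality of the two schemes on a complete graph
  n <- 5
  w <- matrix(3, n, n); diag(w) <- 0
  coords <- matrix(runif(15), ncol = 3)
  L <- weight_to_length(connectome(w, coords))
  expect_equal(shortest_paths(L), navigate(L, coords)$lambda_nav,
               ignore_attr = TRUE)
})

test_that("efficiency implements the mean inverse path length", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  expect_equal(efficiency(m), 1)

  m2 <- matrix(Inf, 3, 3); diag(m2) <- 0
  m2[1, 2] <- m2[2, 1] <- 1
  m2[1, 3] <- m2[3, 1] <- 1
  expect_equal(efficiency(m2), 4 / 6)

  # homogeneity: scaling lengths by c scales efficiency by 1/c
  set.seed(6)
  m3 <- matrix(runif(16, 1, 5), 4, 4); diag(m3) <- 0
  expect_equal(efficiency(m3 * 2), efficiency(m3) / 2)

  # invariance under node relabeling
  perm <- c(3, 1, 4, 2)
  expect_equal(efficiency(m3[perm, perm]), efficiency(m3))

  expect_error(efficiency(matrix(0, 1, 1)), class = "lagnav_invalid_argument")
})

test_that("density AUC integrates the efficiency curve", {
  # a star of 20 nodes has exactly 10% density, so every threshold in the
  # grid retains the whole graph and the efficiency curve is constant
  n <- 20
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 5
  coords <- matrix(runif(3 * n, 0, 10), ncol = 3)
  conn <- connectome(w, coords)
  prof <- comm_profile(conn)
  expect_equal(length(unique(round(prof$per_density$e_nav, 12))), 1)
  expect_equal(prof$auc_e_nav, 0.40 * prof$per_density$e_nav[1])
  expect_equal(prof$auc_e_sp, 0.40 * prof$per_density$e_sp[1])

  # trapezoid rule is exact for a measure linear in density
  dens <- seq(0.10, 0.50, by = 0.05)
  y <- 2 * dens + 1
  expect_equal(lagnav:::trapz(dens, y),
               (2 * 0.5^2 / 2 + 0.5) - (2 * 0.1^2 / 2 + 0.1))

  expect_error(comm_profile(conn, densities = 0.3),
               class = "lagnav_invalid_argument")
})

test_that("lesioned connectomes are no more efficient than intact ones", {
  regions <- gen_parcellation(12, seed = 15)
  conn <- gen_connectome(regions, cohort_config(n_pairs = 12), seed = 15)
  hub <- which.max(rowSums(conn$weights > 0))
  centroid <- conn$coords[hub, ]
  les <- lesion_connectome(conn, centroid, 25)
  grid <- seq(0.10, 0.50, by = 0.10)
  expect_lte(auc_over_densities(les, grid, "e_nav"),
             auc_over_densities(conn, grid, "e_nav"))
  expect_lte(auc_over_densities(les, grid, "e_sp"),
             auc_over_densities(conn, grid, "e_sp"))
})

test_that("region-to-lesion distance uses ipsilesional coordinates and the nearest lesion", {
  regions <- gen_parcellation(6, seed = 16)
  right1 <- regions[regions$hemisphere == "right" & regions$pair_id == 1, ]
  at_region <- as.numeric(right1[c("x", "y", "z")])

  d <- region_to_lesion_distance(regions, at_region, "right")
  expect_equal(d$distance_mm[d$pair_id == 1], 0)

  # two lesions: the nearer one defines the distance
  far <- at_region + c(200, 0, 0)
  d2 <- region_to_lesion_distance(regions, rbind(at_region, far), "right")
  expect_equal(d2$distance_mm, d$distance_mm)

  # contralesional coordinates are never used: mirroring the left hemisphere
  # away leaves right-lesion distances untouched
  moved <- regions
  moved$x[moved$hemisphere == "left"] <- moved$x[moved$hemisphere == "left"] - 500
  d3 <- region_to_lesion_distance(moved, at_region, "right")
  expect_equal(d3$distance_mm, d$distance_mm)

  expect_error(region_to_lesion_distance(regions, NULL, "right"),
               class = "lagnav_invalid_argument")
  expect_error(region_to_lesion_distance(regions, at_region, "up"),
               class = "lagnav_invalid_argument")
})
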