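test_that("mean distance matrix averages per-frame distances", {
  two <- toy_traj(list(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(mean_distance_matrix(two)$values[1, 2], 1.0)
  pair <- toy_traj(list(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                        matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(mean_distance_matrix(pair)$values[1, 2], 1.5)
  set.seed(13)
  frames <- lapply(1:20, function(f) matrix(rnorm(21), 7, 3))
  traj <- toy_traj(frames)
  expect_lt(max(abs(mean_distance_matrix(traj)$values -
                      oracle_mean_dist(traj$coords))), 1e-12)
})

test_that("graph edges honor the distance truncation and correlation gate", {
  d <- toy_dist(matrix(c(0, 1.6, 1.6, 0), 2))
  cm <- xcorr_matrix(matrix(c(1, 0.9, 0.9, 1), 2), "normalized")
  g <- build_graph(d, cm, cutoff = 1.5)
  expect_equal(nrow(g$edges), 0L)
  # same pair inside the cutoff, perfect correlation: weight -ln 1 = 0
  d2 <- toy_dist(matrix(c(0, 1.4, 1.4, 0), 2))
  cm2 <- xcorr_matrix(matrix(c(1, 1, 1, 1), 2), "normalized")
  g2 <- build_graph(d2, cm2, cutoff = 1.5)
  expect_equal(g2$edges$weight, 0)
  # hand-enumerated 4-node toy
  D <- matrix(2, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.5; D[2, 3] <- D[3, 2] <- 1.0
  D[3, 4] <- D[4, 3] <- 1.2; D[1, 3] <- D[3, 1] <- 1.4
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.8; C[2, 3] <- C[3, 2] <- -0.5
  C[3, 4] <- C[4, 3] <- 0.02; C[1, 3] <- C[3, 1] <- 0.6
  g3 <- build_graph(toy_dist(D), xcorr_matrix(C, "normalized"),
                    cutoff = 1.5, min_abs_corr = 0.05)
  # (3,4) fails the correlation gate; all pairs at 2 nm fail the cutoff
  expect_equal(g3$edges[, c("i", "j")],
               data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  expect_equal(g3$edges$weight, -log(c(0.8, 0.6, 0.5)), tolerance = 1e-12)
  expect_error(build_graph(toy_dist(D), cm2), "shape mismatch")
  # neighbor exclusion drops sequence-adjacent pairs
  g4 <- build_graph(toy_dist(D), xcorr_matrix(C, "normalized"),
                    exclude_neighbors = 1L)
  expect_equal(g4$edges[, c("i", "j")], data.frame(i = 1L, j = 3L))
})

test_that("edge count grows with cutoff and shrinks with the correlation gate", {
  set.seed(55)
  s <- make_fixture_structure(20, "helix")
  traj <- sample_trajectory(gnm_model(s), 100, seed = 55)
  dm <- mean_distance_matrix(traj)
  cm <- dccm_matrix(traj, fit = "none")
  n_edges <- function(cutoff, floor)
    nrow(build_graph(dm, cm, cutoff = cutoff, min_abs_corr = floor)$edges)
  expect_true(all(diff(sapply(c(0.5, 1.0, 1.5, 2.0), n_edges, floor = 0.05)) >= 0))
  expect_true(all(diff(sapply(c(0.05, 0.2, 0.5), n_edges, cutoff = 1.5)) <= 0))
})

test_that("the middle node of a path graph dominates the shortest-path map", {
  g <- toy_graph(3, i = c(1, 2), j = c(2, 3), weight = c(1, 1))
  map <- shortest_path_map(g)
  expect_equal(which.max(map$nodes$usage), 2L)
  expect_equal(max(map$nodes$usage_norm), 1)
})

test_that("disconnected dyads are scored independently", {
  g <- toy_graph(4, i = c(1, 3), j = c(2, 4), weight = c(0.5, 0.5))
  map <- shortest_path_map(g)
  expect_equal(map$edges$usage, c(2, 2))  # one traversal per direction
  expect_equal(map$edges$usage_norm, c(1, 1))
  empty <- toy_graph(2, integer(0), integer(0), numeric(0))
  expect_equal(spm_density(shortest_path_map(empty), 0),
               list(n_nodes_retained = 0L, n_edges_retained = 0L))
})

test_that("usages and path weights match exhaustive enumeration on small graphs", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(4:7, 1)
    g <- random_residue_graph(n)
    map <- shortest_path_map(g)
    ref <- oracle_spm(n, g$edges)
    expect_equal(map$nodes$usage, ref$node_usage)
    expect_equal(map$edges$usage, ref$edge_usage)
  }
})

test_that("shortest-path distances agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(202)
  g <- random_residue_graph(7, p = 0.5)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$weight),
    directed = FALSE, vertices = data.frame(name = 1:7))
  ours <- sapply(1:7, function(t) lipdyn:::.dijkstra(
    lapply(1:7, function(u) {
      a <- which(g$edges$i == u); b <- which(g$edges$j == u)
      data.frame(v = c(g$edges$j[a], g$edges$i[b]),
                 w = c(g$edges$weight[a], g$edges$weight[b]), e = c(a, b))
    }), 7, t))
  expect_equal(unname(ours), unname(igraph::distances(ig)), tolerance = 1e-10)
})

test_that("the SPM is deterministic across repeated runs", {
  s <- make_fixture_structure(15, "helix")
  traj <- sample_trajectory(gnm_model(s), 80, seed = 3)
  g <- build_graph(mean_distance_matrix(traj), dccm_matrix(traj, fit = "none"))
  m1 <- shortest_path_map(g); m2 <- shortest_path_map(g)
  expect_identical(m1, m2)
})

test_that("damping correlations prunes the interaction network monotonically", {
  expect_error(spm_density(shortest_path_map(toy_graph(3, 1, 2, 1)), 1.2),
               "usage_floor")
  s <- make_fixture_structure(25, "helix")
  traj <- sample_trajectory(gnm_model(s), 150, seed = 8)
  dm <- mean_distance_matrix(traj)
  cm <- dccm_matrix(traj, fit = "none")
  damped <- cm
  off <- !diag(nrow(damped$values))
  damped$values[off] <- damped$values[off] * 0.5
  g_full <- build_graph(dm, cm)
  g_damp <- build_graph(dm, damped)
  # weaker correlations can only lose edges at the |c| gate, never gain them
  expect_lte(nrow(g_damp$edges), nrow(g_full$edges))
  key <- function(g) paste(g$edges$i, g$edges$j)
  expect_true(all(key(g_damp) %in% key(g_full)))
  # surviving edges carry doubled-distance weights: -ln(c/2) = ln 2 - ln c
  shared <- match(key(g_damp), key(g_full))
  expect_equal(g_damp$edges$weight, g_full$edges$weight[shared] + log(2),
               tolerance = 1e-12)
})
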