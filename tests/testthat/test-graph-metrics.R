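complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

star_graph <- function(leaves) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  A
}

test_that("proportional thresholding keeps round(s * N(N-1)/2) edges", {
  set.seed(1)
  w <- matrix(runif(900), 30); w <- (w + t(w)) / 2; diag(w) <- 0
  g5 <- threshold_by_sparsity(w, 0.05)
  expect_equal(sum(g5$adjacency) / 2, 22)   # round-half-up of 21.75
  g100 <- threshold_by_sparsity(w, 1)
  expect_equal(sum(g100$adjacency) / 2, 435)
  expect_error(threshold_by_sparsity(w, 0), "sparsity")
  expect_error(threshold_by_sparsity(w, 1.2), "sparsity")
})

test_that("thresholded edge sets are nested for tie-free weights", {
  set.seed(2)
  w <- matrix(runif(900), 30); w <- (w + t(w)) / 2; diag(w) <- 0
  a10 <- threshold_by_sparsity(w, 0.10)$adjacency
  a20 <- threshold_by_sparsity(w, 0.20)$adjacency
  expect_true(all(a20[a10 == 1] == 1))
})

test_that("ties at the cutoff break deterministically", {
  w <- matrix(0.5, 6, 6); diag(w) <- 0
  g <- threshold_by_sparsity(w, 0.2)      # 3 of 15 equal-weight edges
  expect_equal(sum(g$adjacency) / 2, 3)
  expect_identical(g$adjacency, threshold_by_sparsity(w, 0.2)$adjacency)
})

test_that("clustering matches hand-worked cases", {
  k5 <- clustering_coef(complete_graph(5))
  expect_equal(k5$C_i, rep(1, 5))
  expect_equal(k5$C, 1)
  expect_equal(clustering_coef(star_graph(5))$C, 0)
  # triangle a-b-c plus pendant d-a
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A[1, 4] <- A[4, 1] <- 1L
  cl <- clustering_coef(A)
  expect_equal(cl$C_i, c(1 / 3, 1, 1, 0))
  expect_equal(cl$C, 7 / 12)
})

test_that("path length and efficiency match hand-worked cases", {
  # path graph a-b-c
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  cp <- characteristic_path_length(A)
  expect_equal(cp$L, 6 / 5)     # harmonic mean of {1,1,2} both directions
  expect_equal(sort(cp$L_ij[upper.tri(cp$L_ij)]), c(1, 1, 2))
  expect_equal(global_efficiency(A), 5 / 6)
  expect_equal(characteristic_path_length(complete_graph(6))$L, 1)
  expect_equal(global_efficiency(complete_graph(6)), 1)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
  # arithmetic variant averages over connected pairs
  expect_equal(characteristic_path_length(A, "arithmetic")$L, 4 / 3)
})

test_that("nodal local efficiency conventions", {
  expect_equal(nodal_local_efficiency(star_graph(5), 1), 0)
  expect_equal(nodal_local_efficiency(complete_graph(4)), rep(1, 4))
  # pendant node (degree 1) -> 0 by convention
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- 1L
  expect_equal(unname(nodal_local_efficiency(A)), c(0, 0, 0))
  expect_error(nodal_local_efficiency(complete_graph(4), 9), "range")
})

test_that("C, L, E_g, NE_loc agree with brute-force oracles", {
  set.seed(42)
  for (r in 1:40) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.7))
    expect_equal(clustering_coef(A)$C_i, oracle_clustering(A)$C_i,
                 tolerance = 1e-12)
    cp <- characteristic_path_length(A)
    expect_equal(cp$L_ij, oracle_dists(A), tolerance = 1e-12)
    expect_equal(cp$L, oracle_L_harmonic(A), tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_geff(A), tolerance = 1e-12)
    expect_equal(unname(nodal_local_efficiency(A)), oracle_neloc(A),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on a batch of random graphs", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (r in 1:10) {
    A <- random_adjacency(10, 0.4)
    g <- igraph::graph_from_adjacency_matrix(A, "undirected")
    ci <- igraph::transitivity(g, "localundirected", isolates = "zero")
    # igraph reports NaN->0 for degree<2 via isolates="zero"
    expect_equal(clustering_coef(A)$C_i, ci, tolerance = 1e-12)
    D <- igraph::distances(g)
    expect_equal(characteristic_path_length(A)$L_ij, D, tolerance = 1e-12,
                 ignore_attr = TRUE)
    eg <- igraph::global_efficiency(g)
    expect_equal(global_efficiency(A), eg, tolerance = 1e-12)
  }
})

test_that("efficiency and clustering stay within [0,1] on random graphs", {
  set.seed(33)
  for (r in 1:25) {
    A <- random_adjacency(sample(3:20, 1), runif(1, 0.05, 0.95))
    m <- network_metrics(binary_graph(A))
    expect_true(all(m$C_i >= 0 & m$C_i <= 1))
    expect_true(m$E_g >= 0 && m$E_g <= 1)
    expect_true(all(m$NE_loc >= 0 & m$NE_loc <= 1))
    if (sum(A) > 0) expect_gte(m$L, 1)
  }
})

test_that("rewired references preserve degrees and are seed-reproducible", {
  set.seed(4)
  A <- random_adjacency(20, 0.3)
  ref1 <- random_reference(A, 5, seed = 99)
  ref2 <- random_reference(A, 5, seed = 99)
  expect_identical(ref1, ref2)
  # degree preservation on a single realization
  set.seed(99)
  rw <- plinet:::cpp_rewire(A, 10L * sum(A) / 2, 10000L)
  expect_gt(rw$swaps, 0)
  expect_equal(rowSums(rw$adjacency), rowSums(A))
  expect_equal(diag(rw$adjacency), rep(0L, 20), ignore_attr = TRUE)
})

test_that("rewiring a ring lattice destroys clustering", {
  A <- ws_adjacency(30, 2, 0)          # C = 0.5 for this lattice
  expect_equal(clustering_coef(A)$C, 0.5)
  ref <- random_reference(A, 10, seed = 1)
  expect_lt(ref$C_random, 0.5)
})

test_that("small-world indices: identity, WS > 1, precondition", {
  A <- ws_adjacency(30, 2, 0)
  self_ref <- list(C_random = clustering_coef(A)$C,
                   L_random = characteristic_path_length(A)$L)
  sw <- small_world_indices(A, self_ref)
  expect_equal(c(sw$gamma, sw$lambda, sw$sigma), c(1, 1, 1))
  set.seed(6)
  Aws <- ws_adjacency(30, 2, 0.1)
  ref <- random_reference(Aws, 20, seed = 2)
  expect_gt(small_world_indices(Aws, ref)$sigma, 1)
  expect_error(small_world_indices(A, list(C_random = 0, L_random = 1)),
               "positive")
})

test_that("sparsity sweep averages per-sparsity metrics over the grid", {
  set.seed(8)
  w <- matrix(runif(900), 30); w <- (w + t(w)) / 2; diag(w) <- 0
  sw <- sparsity_sweep(w, n_realizations = 0)
  expect_equal(nrow(sw$per_sparsity), 8)
  expect_equal(sw$averaged$C, mean(sw$per_sparsity$C))
  expect_equal(sw$averaged$E_g, mean(sw$per_sparsity$E_g))
  # adding edges never lengthens shortest paths
  expect_true(all(diff(sw$per_sparsity$E_g) >= 0))
  expect_error(sparsity_sweep(w, grid = c(0.1, 1.5)), "0, 1")
  # normalized indices appear when references are requested
  sw2 <- sparsity_sweep(w, grid = c(0.2, 0.3), n_realizations = 3, seed = 5)
  expect_true(all(is.finite(sw2$per_sparsity$sigma)))
})
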