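# Brute-force graph oracles, independent of the package implementation.

oracle_dists <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))        # Floyd-Warshall
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  C_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb))
      for (b in seq_along(nb))
        if (a < b && A[nb[a], nb[b]] == 1) e <- e + 1
    C_i[i] <- 2 * e / (k * (k - 1))
  }
  list(C_i = C_i, C = mean(C_i))
}

oracle_geff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_dists(A)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_L_harmonic <- function(A) {
  eg <- oracle_geff(A)
  if (eg > 0) 1 / eg else Inf
}

oracle_neloc <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    out[i] <- oracle_geff(A[nb, nb, drop = FALSE])
  }
  out
}

# Erdos-Renyi-style random adjacency for property tests.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# Watts-Strogatz ring lattice (degree 2*nei) with rewiring prob p.
ws_adjacency <- function(n, nei, p) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (d in seq_len(nei)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  if (p > 0) {
    edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    for (r in seq_len(nrow(edges))) {
      if (stats::runif(1) >= p) next
      i <- edges[r, 1]; j <- edges[r, 2]
      free <- which(A[i, ] == 0)
      free <- setdiff(free, i)
      if (!length(free)) next
      k <- free[sample.int(length(free), 1)]
      A[i, j] <- A[j, i] <- 0L
      A[i, k] <- A[k, i] <- 1L
    }
  }
  A
}

# A small 3-channel montage for connectivity fixtures.
tiny_montage <- function() {
  montage_spec(c("A", "B", "C"),
               c(A = "frontal", B = "central", C = "occipital"),
               c(A = "left", B = "midline", C = "right"))
}

# Build a phase_array directly from a channels x samples phase matrix.
phase_fixture <- function(phase, fs = 250, edge = 0L) {
  structure(list(phase = phase,
                 amplitude = abs(phase) * 0 + 1,
                 fs = fs, band = NULL, condition = NULL,
                 channel_names = rownames(phase),
                 edge_samples = edge),
            class = "phase_array")
}
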