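#' Binary graph from a connectivity matrix
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity the fraction of possible edges retained, if known.
#' @return An object of class `binary_graph`.
#' @seealso [threshold_by_sparsity()]
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  storage.mode(A) <- "integer"
  structure(list(adjacency = A, sparsity = sparsity), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  m <- sum(x$adjacency) / 2
  cat(sprintf("<binary_graph> %d nodes, %d edges", n, m))
  if (!is.null(x$sparsity)) cat(sprintf(" (sparsity %.2f)", x$sparsity))
  cat("\n")
  invisible(x)
}

#' Proportional-threshold binarization
#'
#' Retains the `round(sparsity * N(N-1)/2)` strongest off-diagonal
#' connections as edges (round-half-up). Ties at the cutoff are broken
#' by lexicographic channel-pair order, so for tie-free weights the edge
#' sets are nested across increasing sparsity.
#'
#' @param conn a [pli_matrix()] or plain symmetric weight matrix.
#' @param sparsity fraction of possible edges to keep, in (0, 1\].
#' @return A [binary_graph()].
#' @export
threshold_by_sparsity <- function(conn, sparsity) {
  w <- if (inherits(conn, "pli_matrix")) conn$values else as.matrix(conn)
  if (sparsity <= 0 || sparsity > 1)
    stop("sparsity must lie in (0, 1] (got ", sparsity, ")")
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  m_keep <- floor(sparsity * n * (n - 1) / 2 + 0.5)
  ord <- order(-w[idx], idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(m_keep)], , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = dimnames(w))
  A[keep] <- 1L
  A[keep[, c(2, 1), drop = FALSE]] <- 1L
  binary_graph(A, sparsity)
}

as_adj <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency
  else binary_graph(graph)$adjacency
}

#' Clustering coefficient
#'
#' Per-node clustering `C_i = 2 #_i / (K_i (K_i - 1))`, where `#_i` is
#' the number of edges between the neighbors of `i` and `K_i` its
#' degree; nodes with fewer than 2 neighbors get `C_i = 0`. The graph
#' value `C` is the mean over all nodes.
#'
#' @param graph a [binary_graph()] or adjacency matrix.
#' @return List with `C_i` (vector) and `C` (scalar).
#' @export
clustering_coef <- function(graph) {
  A <- as_adj(graph)
  K <- rowSums(A)
  tri <- diag(A %*% A %*% A)      # 2 x (edges among neighbors)
  C_i <- ifelse(K >= 2, tri / (K * (K - 1)), 0)
  list(C_i = unname(C_i), C = mean(C_i))
}

#' Characteristic path length
#'
#' Shortest-path lengths `L_ij` come from breadth-first search. The
#' default graph value is the harmonic mean
#' `L = N(N-1) / sum(1/L_ij) = 1/E_g`, which stays finite on
#' disconnected graphs (disconnected pairs contribute 0 to the sum) --
#' essential at 5% sparsity where the graph is almost surely
#' disconnected. `method = "arithmetic"` instead averages `L_ij` over
#' connected pairs only.
#'
#' @param graph a [binary_graph()] or adjacency matrix.
#' @param method `"harmonic"` (default) or `"arithmetic"`.
#' @return List with `L` (scalar) and `L_ij` (matrix, `Inf` for
#'   disconnected pairs).
#' @export
characteristic_path_length <- function(graph,
                                       method = c("harmonic", "arithmetic")) {
  method <- match.arg(method)
  A <- as_adj(graph)
  n <- nrow(A)
  if (n < 2) stop("path length needs at least 2 nodes")
  D <- cpp_graph_dist(A)
  off <- D[row(D) != col(D)]
  L <- if (method == "harmonic") {
    eg <- mean(ifelse(is.finite(off), 1 / off, 0))
    if (eg > 0) 1 / eg else Inf
  } else {
    fin <- off[is.finite(off)]
    if (length(fin)) mean(fin) else Inf
  }
  list(L = L, L_ij = D)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length,
#' with disconnected pairs contributing 0; 1 on a complete graph, 0 on
#' an edgeless one.
#'
#' @param graph a [binary_graph()] or adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  A <- as_adj(graph)
  if (nrow(A) < 2) stop("efficiency needs at least 2 nodes")
  cpp_global_efficiency(A)
}

#' Nodal and mean local efficiency
#'
#' `nodal_local_efficiency` is the global efficiency of the subgraph
#' induced on a node's neighbors (0 for nodes with fewer than 2
#' neighbors); it measures the node's capacity for parallel information
#' transfer. [local_efficiency()] is its mean over nodes.
#'
#' @param graph a [binary_graph()] or adjacency matrix.
#' @param node optional node index or channel name; if omitted the full
#'   per-node vector is returned.
#' @return Numeric vector (or scalar if `node` is given).
#' @export
nodal_local_efficiency <- function(graph, node = NULL) {
  A <- as_adj(graph)
  ne <- cpp_local_efficiency(A)
  names(ne) <- rownames(A)
  if (is.null(node)) return(ne)
  if (is.character(node)) {
    if (!node %in% rownames(A)) stop("unknown node '", node, "'")
    return(ne[[node]])
  }
  if (node < 1 || node > length(ne)) stop("node index out of range")
  ne[[node]]
}

#' @rdname nodal_local_efficiency
#' @export
local_efficiency <- function(graph) mean(nodal_local_efficiency(graph))

#' Degree-preserving random reference networks
#'
#' Generates `n_realizations` Maslov-Sneppen rewired versions of the
#' graph (10 x |E| successful double-edge swaps each, preserving every
#' node's degree) and returns the mean clustering coefficient and
#' characteristic path length across realizations -- the null values
#' used to normalize the small-world indices. If the graph admits no
#' valid swap, a density-matched Erdos-Renyi graph is drawn instead,
#' with a warning.
#'
#' @param graph a [binary_graph()] or adjacency matrix (>= 2 edges).
#' @param n_realizations number of rewired references (default 20).
#' @param seed integer seed.
#' @param l_method path-length convention, see
#'   [characteristic_path_length()].
#' @return List with `C_random`, `L_random`, and `realizations` (a
#'   data.frame of per-realization C and L).
#' @export
random_reference <- function(graph, n_realizations = 20, seed,
                             l_method = c("harmonic", "arithmetic")) {
  l_method <- match.arg(l_method)
  A <- as_adj(graph)
  m <- sum(A) / 2
  if (m < 2) stop("need at least 2 edges to build a random reference")
  if (missing(seed)) stop("a seed is required for reproducible references")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  set.seed(seed)
  n <- nrow(A)
  Cr <- Lr <- numeric(n_realizations)
  for (r in seq_len(n_realizations)) {
    rw <- cpp_rewire(A, nswap = 10L * m, max_tries = 1000L * m)
    Ar <- rw$adjacency
    if (rw$swaps == 0L) {
      warning("graph admits no degree-preserving swap; ",
              "falling back to a density-matched Erdos-Renyi reference")
      Ar <- matrix(0L, n, n)
      pairs <- which(upper.tri(Ar))
      on <- sample(pairs, m)
      Ar[on] <- 1L
      Ar <- Ar + t(Ar)
    }
    Cr[r] <- clustering_coef(Ar)$C
    Lr[r] <- characteristic_path_length(Ar, l_method)$L
  }
  list(C_random = mean(Cr), L_random = mean(Lr),
       realizations = data.frame(C = Cr, L = Lr))
}

#' Small-world indices
#'
#' `gamma = C / C_random`, `lambda = L / L_random`,
#' `sigma = gamma / lambda`. A network with `sigma > 1` has the
#' small-world property: more clustered than its degree-matched random
#' null without proportionally longer paths.
#'
#' @param graph a [binary_graph()] or adjacency matrix.
#' @param reference list with `C_random` and `L_random` (see
#'   [random_reference()]).
#' @param l_method path-length convention, see
#'   [characteristic_path_length()].
#' @return List with `gamma`, `lambda`, `sigma` (and the raw `C`, `L`).
#' @export
small_world_indices <- function(graph, reference,
                                l_method = c("harmonic", "arithmetic")) {
  l_method <- match.arg(l_method)
  if (!is.finite(reference$C_random) || reference$C_random <= 0 ||
      !is.finite(reference$L_random) || reference$L_random <= 0)
    stop("reference C_random and L_random must be positive and finite ",
         "(got C_random = ", reference$C_random,
         ", L_random = ", reference$L_random, ")")
  C <- clustering_coef(graph)$C
  L <- characteristic_path_length(graph, l_method)$L
  gamma <- C / reference$C_random
  lambda <- L / reference$L_random
  list(C = C, L = L, gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Small-world metric set at one sparsity
#'
#' @param graph a [binary_graph()].
#' @param reference optional [random_reference()] output; when `NULL`
#'   the normalized indices are `NA`.
#' @param l_method path-length convention.
#' @return List with `C`, `C_i`, `L`, `gamma`, `lambda`, `sigma`,
#'   `E_g`, `E_loc`, `NE_loc`, `K_i`, `sparsity`.
#' @export
network_metrics <- function(graph, reference = NULL,
                            l_method = c("harmonic", "arithmetic")) {
  l_method <- match.arg(l_method)
  cl <- clustering_coef(graph)
  L <- characteristic_path_length(graph, l_method)$L
  ne <- nodal_local_efficiency(graph)
  gamma <- lambda <- sigma <- NA_real_
  if (!is.null(reference)) {
    sw <- small_world_indices(graph, reference, l_method)
    gamma <- sw$gamma; lambda <- sw$lambda; sigma <- sw$sigma
  }
  list(C = cl$C, C_i = cl$C_i, L = L,
       gamma = gamma, lambda = lambda, sigma = sigma,
       E_g = global_efficiency(graph),
       E_loc = mean(ne), NE_loc = ne,
       K_i = rowSums(as_adj(graph)),
       sparsity = graph$sparsity)
}

#' Sparsity sweep with range-averaged metrics
#'
#' Thresholds a connectivity matrix over a sparsity grid (default 5% to
#' 40% in 5% steps), computes the small-world metric set at each point
#' (normalizing against freshly rewired references when
#' `n_realizations > 0`), and averages each metric arithmetically over
#' the grid. The range average is the per-subject summary used in group
#' comparisons; `sigma` is computed per sparsity and then averaged.
#'
#' @param conn a [pli_matrix()] or weight matrix.
#' @param grid sparsity fractions in (0, 1\].
#' @param n_realizations rewired references per sparsity (0 skips the
#'   normalized indices).
#' @param seed integer seed for the references.
#' @param l_method path-length convention.
#' @return List with `per_sparsity` (data.frame, one row per grid
#'   point), `averaged` (named list of range-averaged scalars plus the
#'   element-wise averaged `NE_loc` vector), and `grid`.
#' @export
sparsity_sweep <- function(conn, grid = seq(0.05, 0.40, by = 0.05),
                           n_realizations = 20, seed = 1,
                           l_method = c("harmonic", "arithmetic")) {
  l_method <- match.arg(l_method)
  if (length(grid) == 0 || any(grid <= 0 | grid > 1))
    stop("sparsity grid values must lie in (0, 1]")
  rows <- vector("list", length(grid))
  ne_acc <- NULL
  for (k in seq_along(grid)) {
    g <- threshold_by_sparsity(conn, grid[k])
    ref <- if (n_realizations > 0)
      random_reference(g, n_realizations, seed = seed + k,
                       l_method = l_method)
    else NULL
    m <- network_metrics(g, ref, l_method)
    rows[[k]] <- data.frame(sparsity = grid[k], C = m$C, L = m$L,
                            gamma = m$gamma, lambda = m$lambda,
                            sigma = m$sigma, E_g = m$E_g, E_loc = m$E_loc)
    ne_acc <- if (is.null(ne_acc)) m$NE_loc else ne_acc + m$NE_loc
  }
  per <- do.call(rbind, rows)
  averaged <- as.list(colMeans(per[, -1, drop = FALSE]))
  averaged$NE_loc <- ne_acc / length(grid)
  list(per_sparsity = per, averaged = averaged, grid = grid)
}
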