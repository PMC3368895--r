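# Binary network construction and graph measures. Thresholding keeps the
# strongest Fisher-z values (literally z > T: negative partial correlations
# never become edges unless use_absolute is set); degree-uniform
# thresholding keeps the same edge *count* for every network.

#' Binarize a connectivity matrix at a threshold
#'
#' Edge present iff `z_ij > T` (strictly); the diagonal is zero.
#'
#' @param z_matrix symmetric matrix.
#' @param T threshold.
#' @param use_absolute threshold `|z|` instead of `z`.
#' @return 0/1 adjacency matrix with attribute `threshold`.
#' @export
binarize_at_threshold <- function(z_matrix, T, use_absolute = FALSE) {
  if (max(abs(z_matrix - t(z_matrix))) > 1e-8)
    stop("'z_matrix' must be symmetric", call. = FALSE)
  v <- if (use_absolute) abs(z_matrix) else z_matrix
  A <- (v > T) * 1L
  A <- A * (1 - diag(nrow(A)))
  storage.mode(A) <- "integer"
  attr(A, "threshold") <- T
  A
}

# Upper-triangle edge order, strongest first; ties broken by ascending
# (i, j) lexicographic order. Returns 1-based (i, j) index vectors.
edge_order <- function(z_matrix, use_absolute = FALSE) {
  n <- nrow(z_matrix)
  ut <- which(upper.tri(z_matrix))
  v <- if (use_absolute) abs(z_matrix[ut]) else z_matrix[ut]
  i <- row(z_matrix)[ut]; j <- col(z_matrix)[ut]
  o <- order(-v, i, j)
  list(i = i[o], j = j[o], value = v[o], n = n)
}

#' Threshold to a uniform mean degree
#'
#' Keeps the `E = round(K_target * N / 2)` largest off-diagonal values as
#' edges, so every network in a cohort has the same edge count (and hence
#' the same mean degree up to rounding). Equivalent to [binarize_at_threshold()]
#' with `T` between the E-th and (E+1)-th largest value when these differ;
#' ties are broken by ascending `(i, j)` order.
#'
#' @param z_matrix symmetric matrix.
#' @param K_target desired mean degree, `0 < K_target <= N - 1`.
#' @param use_absolute rank by `|z|`.
#' @return 0/1 adjacency matrix with attributes `K_target` and `K_achieved`.
#' @export
threshold_to_degree <- function(z_matrix, K_target, use_absolute = FALSE) {
  n <- nrow(z_matrix)
  E <- round(K_target * n / 2)
  if (E > n * (n - 1) / 2)
    stop(sprintf("edge count %d exceeds the maximum %d", E, n * (n - 1) / 2),
         call. = FALSE)
  if (E < 1) stop("'K_target' too small: zero edges", call. = FALSE)
  eo <- edge_order(z_matrix, use_absolute)
  A <- matrix(0L, n, n)
  idx <- cbind(eo$i[seq_len(E)], eo$j[seq_len(E)])
  A[idx] <- 1L
  A[idx[, c(2, 1)]] <- 1L
  attr(A, "K_target") <- K_target
  attr(A, "K_achieved") <- 2 * E / n
  A
}

#' Is the network connected?
#'
#' @param network 0/1 adjacency matrix.
#' @return `TRUE` iff every node is reachable from node 1.
#' @export
is_connected_network <- function(network) {
  cpp_connected(check_adjacency(network))
}

#' Degree and cost of a binary network
#'
#' @param network 0/1 adjacency matrix.
#' @return List `K_i` (per-node degrees), `K_net` (mean degree) and
#'   `Cost_net = K_net / (N - 1)` (connection density).
#' @export
degree_and_cost <- function(network) {
  A <- check_adjacency(network)
  k <- rowSums(A)
  list(K_i = k, K_net = mean(k), Cost_net = mean(k) / (nrow(A) - 1))
}

#' Clustering coefficients
#'
#' Per-node fraction of existing edges among each node's neighbours (0 for
#' degree < 2), and the network mean.
#'
#' @param network 0/1 adjacency matrix.
#' @return List `C_i`, `C_net`.
#' @export
clustering_coefficients <- function(network) {
  ci <- cpp_clustering(check_adjacency(network))
  list(C_i = ci, C_net = mean(ci))
}

#' All-pairs shortest path lengths
#'
#' Unweighted breadth-first-search distances; unreachable pairs are `Inf`,
#' the diagonal is 0.
#'
#' @param network 0/1 adjacency matrix.
#' @return N-by-N numeric distance matrix.
#' @export
shortest_paths_matrix <- function(network) {
  cpp_bfs_distances(check_adjacency(network))
}

#' Characteristic path length
#'
#' Nodal means of the shortest path lengths and their network mean;
#' `Inf` propagates when any pair is unreachable.
#'
#' @param distances matrix from [shortest_paths_matrix()].
#' @return List `L_i`, `L_net`.
#' @export
characteristic_path_length <- function(distances) {
  n <- nrow(distances)
  if (n < 2) return(list(L_i = numeric(n), L_net = 0))
  li <- (rowSums(distances)) / (n - 1)     # diagonal contributes 0
  list(L_i = li, L_net = mean(li))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' `1/Inf = 0`; equals 1 only for a complete graph.
#'
#' @param distances matrix from [shortest_paths_matrix()].
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(distances) {
  n <- nrow(distances)
  if (n < 2) return(0)
  inv <- 1 / distances
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours (the node itself removed); nodes with fewer than two
#' neighbours contribute 0. Measures fault tolerance: how well a node's
#' neighbourhood communicates when the node is removed.
#'
#' @param network 0/1 adjacency matrix.
#' @return List `E_local_i`, `E_local_net`.
#' @export
local_efficiency <- function(network) {
  el <- cpp_local_efficiency(check_adjacency(network))
  list(E_local_i = el, E_local_net = mean(el))
}

#' All scalar network measures at once
#'
#' @param network 0/1 adjacency matrix.
#' @return Named list `K_net`, `Cost_net`, `C_net`, `L_net`, `E_global_net`,
#'   `E_local_net`, `connected`.
#' @export
network_metrics <- function(network) {
  A <- check_adjacency(network)
  d <- cpp_bfs_distances(A)
  list(K_net = mean(rowSums(A)),
       Cost_net = mean(rowSums(A)) / (nrow(A) - 1),
       C_net = mean(cpp_clustering(A)),
       L_net = characteristic_path_length(d)$L_net,
       E_global_net = global_efficiency(d),
       E_local_net = mean(cpp_local_efficiency(A)),
       connected = cpp_connected(A))
}

#' Degree-preserving rewiring (Markov-chain null model)
#'
#' Randomizes a network by repeated double-edge swaps, each replacing edges
#' (a,b), (c,d) with (a,d), (c,b) when this creates no self-loop or
#' multi-edge. The degree sequence is preserved exactly. When the input is
#' connected, the null is re-swapped until connected (bounded retries).
#'
#' @param network 0/1 adjacency matrix.
#' @param n_swaps_factor accepted swaps per edge (default 10).
#' @param seed integer seed.
#' @param max_connect_retries bound on connectivity-restoring rounds.
#' @return Rewired 0/1 adjacency matrix.
#' @export
rewire_preserving_degree <- function(network, n_swaps_factor = 10,
                                     seed = NULL, max_connect_retries = 100L) {
  A <- check_adjacency(network)
  with_seed(seed, cpp_rewire(A, n_swaps_factor, TRUE, max_connect_retries))
}

#' Small-worldness against a rewiring null ensemble
#'
#' For each of `n_nulls` degree-preserving rewired null networks, computes
#' `gamma = C_net / C_rand`, `lambda = L_net / L_rand` and
#' `sigma = gamma / lambda`; the ensemble small-worldness is the mean of the
#' per-null sigma values. Theoretical random-graph references
#' `C_rand = K_net / N` and `L_rand = ln N / ln K_net` are reported for
#' diagnostics but not used for sigma.
#'
#' @param network connected 0/1 adjacency matrix.
#' @param n_nulls number of null networks (default 25).
#' @param seed integer seed.
#' @param n_swaps_factor accepted swaps per edge in each null.
#' @return Object of class `sw_nullensemble`: list with `sigma` (ensemble
#'   mean), `sigma_per_null`, `gamma`, `lambda`, `c_net`, `l_net`, `c_rand`,
#'   `l_rand` (per null), `c_rand_theory`, `l_rand_theory`, `n_excluded`.
#' @export
small_worldness <- function(network, n_nulls = 25L, seed = NULL,
                            n_swaps_factor = 10) {
  A <- check_adjacency(network)
  if (!cpp_connected(A))
    stop("network must be connected for small-worldness", call. = FALSE)
  res <- with_seed(seed, cpp_sigma_ensemble(A, n_nulls, n_swaps_factor, 100L))
  sig <- res$sigma
  excl <- sum(is.na(sig))
  if (excl > 0)
    warning(sprintf("%d null(s) with zero clustering excluded from sigma", excl),
            call. = FALSE)
  k_net <- mean(rowSums(A)); n <- nrow(A)
  structure(list(sigma = mean(sig, na.rm = TRUE),
                 sigma_per_null = sig,
                 gamma = res$c_net / res$c_rand,
                 lambda = res$l_net / res$l_rand,
                 c_net = res$c_net, l_net = res$l_net,
                 c_rand = res$c_rand, l_rand = res$l_rand,
                 c_rand_theory = k_net / n,
                 l_rand_theory = log(n) / log(k_net),
                 n_nulls = n_nulls, n_excluded = excl),
            class = "sw_nullensemble")
}

#' @export
print.sw_nullensemble <- function(x, ...) {
  cat(sprintf("Small-worldness over %d rewired nulls: sigma = %.3f (gamma %.3f, lambda %.3f)\n",
              x$n_nulls, x$sigma, mean(x$gamma, na.rm = TRUE),
              mean(x$lambda, na.rm = TRUE)))
  invisible(x)
}
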