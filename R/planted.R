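# Planted ground-truth graphs and the Gaussian graphical model that makes
# them recoverable by *partial* correlation: the graph is written into a
# precision matrix (-coupling on edges), whose inverse is the node covariance.

#' Sample a planted small-world graph
#'
#' Draws a connected Watts-Strogatz graph: a ring lattice where every node is
#' joined to its `target_degree` nearest neighbours, with each edge rewired
#' independently with probability `rewiring_prob`. Higher rewiring lowers the
#' expected clustering coefficient, which is the dial used to plant group and
#' load differences.
#'
#' @param n_nodes number of nodes.
#' @param target_degree even lattice degree (< `n_nodes`).
#' @param rewiring_prob per-edge rewiring probability in \[0, 1\].
#' @param seed integer seed.
#' @param max_retries resampling attempts for a connected draw.
#' @return A symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
sample_planted_graph <- function(n_nodes, target_degree, rewiring_prob,
                                 seed = NULL, max_retries = 50L) {
  stopifnot_scalar_num(n_nodes, "n_nodes", positive = TRUE)
  stopifnot_scalar_num(target_degree, "target_degree", positive = TRUE)
  if (target_degree %% 2 != 0)
    stop("'target_degree' must be even (ring-lattice neighbours)", call. = FALSE)
  if (target_degree >= n_nodes)
    stop("'target_degree' must be smaller than 'n_nodes'", call. = FALSE)
  if (rewiring_prob < 0 || rewiring_prob > 1)
    stop("'rewiring_prob' must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      g <- igraph::sample_smallworld(1, n_nodes, target_degree / 2,
                                     rewiring_prob)
      if (igraph::is_connected(g)) {
        A <- as.matrix(igraph::as_adjacency_matrix(g))
        dimnames(A) <- NULL
        storage.mode(A) <- "integer"
        return(A)
      }
    }
    stop(sprintf("no connected graph in %d draws; lower rewiring_prob or raise target_degree",
                 max_retries), call. = FALSE)
  })
}

#' Node covariance implied by a planted graph
#'
#' Builds the precision matrix `P` with `-coupling` on planted edges, zero on
#' non-edges and diagonal `1 + degree * coupling * margin`, and returns its
#' inverse. Partial correlations computed from the returned covariance are
#' exactly zero on non-edges and positive on edges, so the partial-correlation
#' stage of the pipeline recovers the planted graph in the noiseless,
#' long-series limit.
#'
#' @param graph symmetric 0/1 adjacency matrix.
#' @param coupling_strength positive off-diagonal precision magnitude.
#' @param margin diagonal-dominance margin (> 1 guarantees positive
#'   definiteness via Gershgorin).
#' @param normalize rescale the covariance to unit variances
#'   (`cov2cor`); partial correlations are invariant to this, and it makes
#'   the additive `noise_sd` of the simulator interpretable. Set `FALSE`
#'   for the raw inverse of `P`.
#' @return Covariance matrix (positive definite, symmetric).
#' @export
graph_to_covariance <- function(graph, coupling_strength, margin = 1.05,
                                normalize = TRUE) {
  A <- check_adjacency(graph)
  stopifnot_scalar_num(coupling_strength, "coupling_strength", positive = TRUE)
  stopifnot_scalar_num(margin, "margin", positive = TRUE)
  P <- -coupling_strength * A
  diag(P) <- 1 + rowSums(A) * coupling_strength * margin
  ev_min <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("precision matrix not positive definite (min eigenvalue %.3g); reduce coupling or raise margin",
                 ev_min), call. = FALSE)
  S <- solve(P)
  S <- (S + t(S)) / 2
  if (normalize) S <- stats::cov2cor(S)
  S
}
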