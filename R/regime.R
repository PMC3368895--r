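# Small-world regime search and the metric table. The regime is the degree
# interval over which *every* network (all subjects, all loads) is both
# fully connected and small-world (mean sigma > 1 over the rewiring null
# ensemble); an evenly spaced observation grid inside it feeds the
# statistics stage.

adj_from_order <- function(eo, E) {
  A <- matrix(0L, eo$n, eo$n)
  idx <- cbind(eo$i[seq_len(E)], eo$j[seq_len(E)])
  A[idx] <- 1L
  A[idx[, c(2, 1)]] <- 1L
  A
}

edge_count_for <- function(K, n) as.integer(round(K * n / 2))

# Flat list of per-network edge orders for an sw_connectivity object.
connectivity_edge_orders <- function(conn, use_absolute = FALSE) {
  lapply(seq_len(nrow(conn$meta)), function(r) {
    s <- conn$meta$subject[r]; l <- conn$meta$load[r]
    edge_order(conn$z[[s]][[l]], use_absolute)
  })
}

all_connected_at <- function(orders, K, n) {
  E <- edge_count_for(K, n)
  for (eo in orders) if (!cpp_connected(adj_from_order(eo, E))) return(FALSE)
  TRUE
}

# Mean sigma per network at degree K; early_exit stops at the first network
# with sigma <= 1 (returns NA for the rest). Seeds are derived per
# (network, K) so re-evaluation is deterministic.
sigma_at <- function(orders, K, n, n_nulls, swaps_factor, seed,
                     early_exit = TRUE) {
  E <- edge_count_for(K, n)
  out <- rep(NA_real_, length(orders))
  for (i in seq_along(orders)) {
    A <- adj_from_order(orders[[i]], E)
    if (!cpp_connected(A)) return(out)   # disconnected counts as failure
    res <- with_seed(child_seed(seed, i, round(K * 10)),
                     cpp_sigma_ensemble(A, n_nulls, swaps_factor, 100L))
    out[i] <- mean(res$sigma, na.rm = TRUE)
    if (early_exit && !(out[i] > 1)) return(out)
  }
  out
}

sigma_pass <- function(sig) all(!is.na(sig)) && all(sig > 1)

#' Find the small-world regime and observation grid
#'
#' Searches, on a 0.1-degree lattice, for the maximal degree interval
#' `[K_min, K_max]` over which every network of the cohort (each subject at
#' each load, thresholded to that uniform degree) is fully connected *and*
#' has mean small-worldness sigma > 1 over the rewiring null ensemble. An
#' evenly spaced grid of `grid_size` observation degrees with a fixed
#' increment (the largest multiple of 0.1 fitting the interval) is placed at
#' the lower bound, and every grid point is then verified explicitly; the
#' upper bound shrinks if a grid point fails. The search assumes the
#' feasible set is a single interval (connectivity is monotone in degree;
#' sigma decays toward 1 with density).
#'
#' @param conn an `sw_connectivity` object.
#' @param grid_size number of observation degrees (default 16).
#' @param n_nulls rewired nulls per sigma estimate (default 25).
#' @param seed integer seed for the null ensembles.
#' @param n_swaps_factor accepted swaps per edge when rewiring.
#' @param k_search search bounds for the degree (defaults to
#'   `c(2, N - 1)`).
#' @param resolution degree lattice step (default 0.1).
#' @return Object of class `sw_regime`: list with `k_min`, `k_max`,
#'   `increment`, `grid` (the observation degrees), `sigma` (networks x
#'   grid matrix of verified mean sigmas), `meta` (network metadata),
#'   `n_nulls`, `seed`.
#' @export
find_small_world_regime <- function(conn, grid_size = 16L, n_nulls = 25L,
                                    seed = 1L, n_swaps_factor = 10,
                                    k_search = NULL, resolution = 0.1) {
  n <- conn$n_nodes
  orders <- connectivity_edge_orders(conn)
  if (is.null(k_search)) k_search <- c(2, n - 1)
  ks <- seq(ceiling(k_search[1] / resolution) * resolution,
            floor(k_search[2] / resolution) * resolution, by = resolution)
  ks <- round(ks, 10)

  # 1. connectivity lower bound (monotone: adding edges keeps connectivity)
  lo <- 1L; hi <- length(ks)
  if (!all_connected_at(orders, ks[hi], n))
    stop("networks are not all connected even at the densest searched degree",
         call. = FALSE)
  if (all_connected_at(orders, ks[lo], n)) {
    k_conn <- lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (all_connected_at(orders, ks[mid], n)) hi <- mid else lo <- mid
    }
    k_conn <- hi
  }

  # 2. smallest degree >= k_conn where sigma passes (coarse scan, then refine)
  coarse <- max(1L, as.integer(round(0.5 / resolution)))
  i_lo <- NA_integer_
  i <- k_conn
  while (i <= length(ks)) {
    if (sigma_pass(sigma_at(orders, ks[i], n, n_nulls, n_swaps_factor, seed))) {
      i_lo <- i; break
    }
    i <- i + coarse
  }
  if (is.na(i_lo))
    stop("empty small-world regime: no searched degree has all networks connected with sigma > 1",
         call. = FALSE)
  while (i_lo > k_conn &&
         sigma_pass(sigma_at(orders, ks[i_lo - 1L], n, n_nulls,
                             n_swaps_factor, seed)))
    i_lo <- i_lo - 1L

  # 3. largest degree where sigma passes (bisection above i_lo)
  lo <- i_lo; hi <- length(ks)
  if (sigma_pass(sigma_at(orders, ks[hi], n, n_nulls, n_swaps_factor, seed))) {
    i_hi <- hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (sigma_pass(sigma_at(orders, ks[mid], n, n_nulls, n_swaps_factor,
                              seed)))
        lo <- mid else hi <- mid
    }
    i_hi <- lo
  }

  # 4. place the grid and verify every point, shrinking k_max on failure
  repeat {
    k_min <- ks[i_lo]; k_max <- ks[i_hi]
    inc <- floor((k_max - k_min) / (grid_size - 1) / resolution) * resolution
    if (inc < resolution)
      stop(sprintf("small-world regime [%.1f, %.1f] too narrow for a %d-point grid",
                   k_min, k_max, grid_size), call. = FALSE)
    grid <- round(k_min + (seq_len(grid_size) - 1L) * inc, 10)
    sig <- matrix(NA_real_, length(orders), grid_size)
    failed <- NA_integer_
    for (gidx in seq_along(grid)) {
      s <- sigma_at(orders, grid[gidx], n, n_nulls, n_swaps_factor, seed,
                    early_exit = TRUE)
      sig[, gidx] <- s
      if (!sigma_pass(s)) { failed <- gidx; break }
    }
    if (is.na(failed)) break
    i_hi <- which(ks == grid[failed]) - 1L
    if (i_hi <= i_lo)
      stop("small-world regime collapsed during grid verification", call. = FALSE)
  }
  structure(list(k_min = k_min, k_max = k_max, increment = inc, grid = grid,
                 sigma = sig, meta = conn$meta, n_nulls = n_nulls,
                 seed = seed, n_nodes = n),
            class = "sw_regime")
}

#' @export
print.sw_regime <- function(x, ...) {
  cat(sprintf("Small-world regime: degrees %.1f to %.1f (cost %.3f to %.3f)\n",
              x$k_min, x$k_max, x$k_min / (x$n_nodes - 1),
              x$k_max / (x$n_nodes - 1)))
  cat(sprintf("Observation grid: %d degrees from %.1f to %.1f, increment %.1f\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)], x$increment))
  cat(sprintf("Verified min mean sigma over all networks and grid points: %.3f\n",
              min(x$sigma)))
  invisible(x)
}

#' Network measures at every observation degree
#'
#' Thresholds every subject-by-load connectivity matrix to each observation
#' degree of the grid and computes the four network measures (clustering
#' coefficient `C_net`, characteristic path length `L_net`, local efficiency
#' `E_local`, global efficiency `E_global`), plus each subject-by-load
#' average over the grid (`observation = "avg"`).
#'
#' @param conn an `sw_connectivity` object.
#' @param grid numeric vector of observation degrees, or an `sw_regime`.
#' @return Object of class `sw_metric_table` (a data frame): long-form
#'   records `subject`, `group`, `site`, `load`, `observation` (`"1"` ..
#'   `"16"` or `"avg"`), `degree`, `measure`, `value`.
#' @export
compute_metric_table <- function(conn, grid) {
  if (inherits(grid, "sw_regime")) grid <- grid$grid
  n <- conn$n_nodes
  ec <- vapply(grid, edge_count_for, integer(1), n = n)
  if (is.unsorted(ec)) stop("grid degrees must be increasing", call. = FALSE)
  rows <- vector("list", nrow(conn$meta))
  for (r in seq_len(nrow(conn$meta))) {
    s <- conn$meta$subject[r]; l <- conn$meta$load[r]
    eo <- edge_order(conn$z[[s]][[l]])
    m <- cpp_metrics_nested(n, eo$i - 1L, eo$j - 1L, ec, TRUE)
    if (any(m[, 6] == 0))
      stop(sprintf("disconnected network for %s at %s within the observation grid",
                   s, l), call. = FALSE)
    vals <- rbind(m[, 2], m[, 3], m[, 5], m[, 4])  # C, L, E_local, E_global
    rows[[r]] <- data.frame(
      subject = s, group = conn$meta$group[r], site = conn$meta$site[r],
      load = l,
      observation = rep(c(as.character(seq_along(grid)), "avg"), each = 4),
      degree = rep(c(grid, NA_real_), each = 4),
      measure = rep(MEASURES, length(grid) + 1L),
      value = c(as.numeric(vals), rowMeans(vals)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sw_metric_table", "data.frame")
  attr(out, "grid") <- grid
  out
}
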