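test_that("binarization keeps strictly supra-threshold edges only", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.9
  z[1, 3] <- z[3, 1] <- 0.2
  z[2, 3] <- z[3, 2] <- 0.5
  A <- binarize_at_threshold(z, 0.4)
  expect_equal(A[1, 2], 1L); expect_equal(A[2, 3], 1L); expect_equal(A[1, 3], 0L)
  expect_equal(sum(binarize_at_threshold(z, 1)), 0)         # above max: empty
  expect_equal(binarize_at_threshold(z, -1), complete_graph(3),
               ignore_attr = TRUE)                           # below min: complete
  expect_equal(diag(binarize_at_threshold(z, -1)), rep(0L, 3))
  zneg <- -abs(z)
  expect_equal(sum(binarize_at_threshold(zneg, 0.1)), 0)     # z > T literally
  expect_equal(sum(binarize_at_threshold(zneg, 0.1, use_absolute = TRUE)) > 0,
               TRUE)
})

test_that("degree-uniform thresholding keeps the top-E edges with stable ties", {
  set.seed(1)
  z <- matrix(rnorm(105^2), 105)
  z <- z + t(z); diag(z) <- 0
  A <- threshold_to_degree(z, 19.9)
  expect_equal(sum(A) / 2, 1045)                             # round(19.9*105/2)
  expect_equal(attr(A, "K_achieved"), 19.905, tolerance = 5e-4)
  expect_equal(mean(rowSums(A)), 2 * 1045 / 105)
  # sorting oracle: edge set equals the top-E distinct values
  ut <- which(upper.tri(z))
  topE <- ut[order(-z[ut])][1:1045]
  expect_true(all(A[topE] == 1))
  # complete at K = N - 1
  expect_equal(threshold_to_degree(z, 104), complete_graph(105),
               ignore_attr = TRUE)
  expect_error(threshold_to_degree(z, 200), "exceeds")
  # agrees with plain thresholding between the E-th and (E+1)-th value
  v <- sort(z[ut], decreasing = TRUE)
  Tcut <- (v[1045] + v[1046]) / 2
  expect_equal(unclass(A), unclass(binarize_at_threshold(z, Tcut)),
               ignore_attr = TRUE)
  # deterministic lexicographic tie-break
  zt <- matrix(1, 4, 4); diag(zt) <- 0
  At <- threshold_to_degree(zt, 1)                           # E = 2 of 6 tied
  expect_equal(which(At[upper.tri(At)] == 1), c(1L, 2L))
})

test_that("connectivity detection matches hand-constructed cases", {
  expect_true(is_connected_network(complete_graph(5)))
  iso <- path_graph(4); iso <- rbind(cbind(iso, 0L), 0L)     # isolated node
  expect_false(is_connected_network(iso))
  two <- matrix(0L, 6, 6)                                    # two triangles + bridge
  two[1:3, 1:3] <- complete_graph(3); two[4:6, 4:6] <- complete_graph(3)
  two[3, 4] <- two[4, 3] <- 1L
  expect_true(is_connected_network(two))
})

test_that("degree and cost follow the printed degree-to-cost conversions", {
  set.seed(2)
  z <- matrix(rnorm(105^2), 105); z <- z + t(z); diag(z) <- 0
  dc <- degree_and_cost(threshold_to_degree(z, 19.9))
  expect_equal(round(dc$Cost_net, 3), 0.191)
  dc2 <- degree_and_cost(threshold_to_degree(z, 34.9))
  expect_equal(round(dc2$Cost_net, 3), 0.336)
  expect_equal(degree_and_cost(complete_graph(8))$Cost_net, 1)
  expect_equal(degree_and_cost(path_graph(3))$K_i, c(1, 2, 1))
})

test_that("clustering matches closed forms and the triangle oracle", {
  expect_equal(clustering_coefficients(complete_graph(5))$C_net, 1)
  expect_equal(clustering_coefficients(star_graph(6))$C_net, 0)
  A <- ring_lattice(10, 4)
  expect_equal(clustering_coefficients(A)$C_net, 0.5)        # 3(k-2)/(4(k-1))
  expect_equal(clustering_coefficients(A)$C_i, oracle_clustering(A))
})

test_that("shortest paths, path length and efficiencies match hand computations", {
  P3 <- path_graph(3)
  D <- shortest_paths_matrix(P3)
  expect_equal(D[1, 3], 2)
  expect_equal(characteristic_path_length(D)$L_net, 4 / 3)
  expect_equal(global_efficiency(D), (1 + 1 + 1 / 2) / 3)
  expect_equal(characteristic_path_length(
    shortest_paths_matrix(complete_graph(4)))$L_net, 1)
  expect_equal(global_efficiency(shortest_paths_matrix(complete_graph(4))), 1)
  # disconnection: infinite path length, efficiency unaffected by 1/Inf = 0
  iso <- rbind(cbind(path_graph(3), 0L), 0L)
  Di <- shortest_paths_matrix(iso)
  expect_equal(Di[1, 4], Inf)
  expect_equal(characteristic_path_length(Di)$L_net, Inf)
  expect_equal(global_efficiency(shortest_paths_matrix(matrix(0L, 4, 4))), 0)
  # local efficiency: complete K4 -> 1, star -> 0, pendant case vs oracle
  expect_equal(local_efficiency(complete_graph(4))$E_local_net, 1)
  expect_equal(local_efficiency(star_graph(5))$E_local_net, 0)
  tri_p <- matrix(0L, 4, 4)
  tri_p[1:3, 1:3] <- complete_graph(3); tri_p[3, 4] <- tri_p[4, 3] <- 1L
  expect_equal(local_efficiency(tri_p)$E_local_i, oracle_local_eff(tri_p))
})

test_that("all metrics agree with igraph on random graphs", {
  set.seed(3)
  for (rep in 1:20) {
    A <- random_graph(sample(10:40, 1))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(clustering_coefficients(A)$C_net,
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    D <- shortest_paths_matrix(A)
    Di <- igraph::distances(g)
    expect_equal(D, Di, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(global_efficiency(D), igraph::global_efficiency(g),
                 tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring conserves degrees and edges", {
  set.seed(4)
  for (rep in 1:20) {
    A <- random_graph(sample(8:30, 1), runif(1, 0.2, 0.7))
    W <- rewire_preserving_degree(A, seed = rep)
    expect_equal(rowSums(W), rowSums(A))
    expect_equal(sum(W), sum(A))
    expect_equal(diag(W), rep(0L, nrow(W)))
  }
  # triangle admits no swap: output equals input
  expect_equal(unclass(rewire_preserving_degree(complete_graph(3), seed = 1)),
               unclass(complete_graph(3)), ignore_attr = TRUE)
  # connected input stays connected under enforcement
  A <- ring_lattice(30, 4)
  expect_true(is_connected_network(rewire_preserving_degree(A, seed = 2)))
  expect_identical(rewire_preserving_degree(A, seed = 9),
                   rewire_preserving_degree(A, seed = 9))
})

test_that("small-worldness is 1 for the complete graph and > 1 for a lattice-like graph", {
  sw <- small_worldness(complete_graph(12), n_nulls = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  A <- sample_planted_graph(105, 20, 0.1, seed = 2)
  sw2 <- small_worldness(A, n_nulls = 10, seed = 3)
  expect_gt(sw2$sigma, 1)
  expect_equal(sw2$c_rand_theory, 20 / 105, tolerance = 1e-3)
  expect_equal(sw2$l_rand_theory, log(105) / log(mean(rowSums(A))))
  expect_error(small_worldness(rbind(cbind(path_graph(3), 0L), 0L)),
               "connected")
})

test_that("theoretical random-graph references hold on matched random graphs", {
  # C_rand ~ K/N at the dense end; the L_rand ~ ln N / ln K reference is an
  # asymptotic approximation that is accurate at sparser degrees (at K = 25
  # the true mean distance of an ER graph, ~2 - p, exceeds it by ~20%)
  set.seed(5)
  cs <- vapply(1:20, function(i)
    clustering_coefficients(random_graph(105, 25 / 104))$C_net, numeric(1))
  expect_lt(abs(mean(cs) - 25 / 105) / (25 / 105), 0.2)
  # the approximation under-estimates the true ER mean distance by
  # 10-20% at N = 105 across the relevant degrees; it is reported as a
  # diagnostic only, never used for sigma
  for (K in c(10, 25)) {
    ls <- vapply(1:20, function(i)
      characteristic_path_length(shortest_paths_matrix(
        random_graph(105, K / 104)))$L_net, numeric(1))
    th <- log(105) / log(K)
    expect_lt(abs(mean(ls) - th) / th, 0.25)
    expect_gt(mean(ls), th)
  }
})

test_that("scalar metrics are invariant under node relabeling", {
  set.seed(6)
  A <- random_graph(25, 0.3)
  perm <- sample(25)
  B <- A[perm, perm]
  ma <- network_metrics(A); mb <- network_metrics(B)
  for (f in c("K_net", "Cost_net", "C_net", "L_net", "E_global_net",
              "E_local_net"))
    expect_equal(ma[[f]], mb[[f]], tolerance = 1e-12)
})

test_that("metrics are monotone along nested thresholded edge sets", {
  set.seed(7)
  z <- matrix(rnorm(40^2), 40); z <- z + t(z); diag(z) <- 0
  ks <- c(8, 12, 16, 20, 24)
  m <- t(vapply(ks, function(k) {
    A <- threshold_to_degree(z, k)
    d <- shortest_paths_matrix(A)
    c(C = clustering_coefficients(A)$C_net,
      L = characteristic_path_length(d)$L_net,
      Eg = global_efficiency(d),
      El = local_efficiency(A)$E_local_net)
  }, numeric(4)))
  expect_true(all(diff(m[, "Eg"]) >= 0))
  expect_true(all(diff(m[is.finite(m[, "L"]), "L"]) <= 0))
  # lowering the degree only removes edges
  A1 <- threshold_to_degree(z, 8); A2 <- threshold_to_degree(z, 24)
  expect_true(all(A2[A1 == 1] == 1))
})
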