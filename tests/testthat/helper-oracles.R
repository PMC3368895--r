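# Independent brute-force reference implementations of the graph measures
# and statistics, kept deliberately naive (triangle enumeration,
# Floyd-Warshall, definitional BH step-up, textbook sums of squares). They
# share no code with the package internals.

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] == 1) e <- e + 1
    ci[i] <- e / (k * (k - 1) / 2)
  }
  ci
}

oracle_distances <- function(A) {   # Floyd-Warshall (min-plus relaxation)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    el[i] <- oracle_global_eff(A[nb, nb, drop = FALSE])
  }
  el
}

oracle_lnet <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  if (n < 2) return(0)
  mean(D[row(D) != col(D)])
}

# definitional BH step-up: adjusted p_(k) = min over j >= k of m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m))
    adj[k] <- min(1, min(m * ps[k:m] / (k:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# balanced two-way ANOVA by textbook sums of squares
oracle_anova2 <- function(value, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  a <- nlevels(f1); b <- nlevels(f2)
  nrep <- length(value) / (a * b)
  gm <- mean(value)
  m1 <- tapply(value, f1, mean)
  m2 <- tapply(value, f2, mean)
  m12 <- tapply(value, interaction(f1, f2), mean)
  ss1 <- b * nrep * sum((m1 - gm)^2)
  ss2 <- a * nrep * sum((m2 - gm)^2)
  cellm <- m12[interaction(f1, f2)]
  sse <- sum((value - cellm)^2)
  ss12 <- sum((value - gm)^2) - ss1 - ss2 - sse
  df1 <- a - 1; df2 <- b - 1; df12 <- df1 * df2
  dfe <- a * b * (nrep - 1)
  F1 <- (ss1 / df1) / (sse / dfe)
  F2 <- (ss2 / df2) / (sse / dfe)
  F12 <- (ss12 / df12) / (sse / dfe)
  data.frame(term = c("f1", "f2", "f1:f2"),
             F = c(F1, F2, F12),
             p = c(pf(F1, df1, dfe, lower.tail = FALSE),
                   pf(F2, df2, dfe, lower.tail = FALSE),
                   pf(F12, df12, dfe, lower.tail = FALSE)))
}

# random symmetric 0/1 adjacency with zero diagonal
random_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.1, 0.9)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A + t(A)
}

# all labeled graphs on n nodes (n small), as adjacency matrices
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  up <- which(upper.tri(matrix(0, n, n)))
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0L, n, n)
    A[up] <- bits
    A + t(A)
  })
}
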