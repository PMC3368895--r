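# Shared small fixtures, built once per test run.

# tiny cohort used by several module tests (2 runs would break the default
# design, so keep the standard 3-run schedule but few subjects)
tiny_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(n_per_group = 2, seed = 42)
    coh
  }
})

ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

star_graph <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}
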