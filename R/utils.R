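# Internal helpers: seed management and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# With seed = NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic child seed from a base seed and integer tags, kept inside
# the 32-bit range R accepts. Multiplicative hashing keeps distinct tags
# well separated even for small consecutive bases.
child_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (as.numeric(t) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483563) + 1L
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

check_adjacency <- function(A, name = "adjacency") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (any(A != t(A)))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  if (any(!A %in% c(0, 1)))
    stop(sprintf("'%s' must be binary 0/1", name), call. = FALSE)
  if (any(diag(A) != 0))
    stop(sprintf("'%s' must have a zero diagonal", name), call. = FALSE)
  storage.mode(A) <- "integer"
  A
}
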