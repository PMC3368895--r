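# Partial-correlation connectivity. The partial correlation between two
# nodes is computed jointly against all other nodes via the precision
# (inverse covariance) matrix: r_ij = -P_ij / sqrt(P_ii P_jj). With 105
# nodes and ~132 TRs per load the sample covariance is near-singular, so a
# Ledoit-Wolf analytic shrinkage toward a scaled identity is applied by
# default before inversion.

# Ledoit-Wolf (2004) optimal linear shrinkage of the sample covariance
# toward mu * I. X is samples-by-variables.
ledoit_wolf <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2) / p
  if (d2 <= 0) return(list(S = S, weight = 0, mu = mu))
  # (1/n^2) sum_t || x_t x_t' - S ||_F^2 / p, vectorized
  b2bar <- (sum(crossprod(Xc^2)) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2bar, d2)
  w <- b2 / d2
  list(S = (1 - w) * S + w * mu * diag(p), weight = w, mu = mu)
}

#' Partial-correlation matrix of node time series
#'
#' Estimates the node-by-node partial correlations (each pair conditioned on
#' all remaining nodes) from the (optionally shrinkage-regularized) inverse
#' sample covariance.
#'
#' @param load_series nodes-by-time matrix (one load's concatenated series).
#' @param shrinkage `"auto"` for Ledoit-Wolf analytic shrinkage toward a
#'   scaled identity, or a fixed value in \[0, 1\] (0 = naive estimator,
#'   which requires more time points than nodes).
#' @return Symmetric matrix of partial correlations with zero diagonal and
#'   attributes `shrinkage_weight` and `n_samples`.
#' @export
partial_correlation_matrix <- function(load_series, shrinkage = "auto") {
  if (!is.matrix(load_series) || ncol(load_series) < 2)
    stop("'load_series' must be a nodes-by-time matrix with >= 2 time points",
         call. = FALSE)
  if (any(!is.finite(load_series)))
    stop("'load_series' contains non-finite values", call. = FALSE)
  X <- t(load_series)                       # samples x nodes
  p <- ncol(X)
  if (identical(shrinkage, "auto")) {
    lw <- ledoit_wolf(X)
    S <- lw$S; w <- lw$weight
  } else {
    stopifnot_scalar_num(shrinkage, "shrinkage")
    if (shrinkage < 0 || shrinkage > 1)
      stop("'shrinkage' must be in [0, 1] or \"auto\"", call. = FALSE)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    S0 <- crossprod(Xc) / nrow(X)
    mu <- sum(diag(S0)) / p
    S <- (1 - shrinkage) * S0 + shrinkage * mu * diag(p)
    w <- shrinkage
  }
  P <- tryCatch(solve(S), error = function(e)
    stop("covariance is singular; use shrinkage = \"auto\" or a positive shrinkage value",
         call. = FALSE))
  d <- 1 / sqrt(diag(P))
  R <- -P * tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 0
  attr(R, "shrinkage_weight") <- w
  attr(R, "n_samples") <- nrow(X)
  R
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` elementwise to the off-diagonal entries. Values with
#' `|r| >= 1` are an error unless `clip` is set, in which case they are
#' clipped to `+/-(1 - 1e-7)` first.
#'
#' @param r_matrix symmetric correlation-valued matrix (zero diagonal).
#' @param clip clip out-of-range values instead of erroring (default off).
#' @return Symmetric matrix of Fisher-z values, zero diagonal; attributes of
#'   the input are preserved.
#' @export
fisher_z_transform <- function(r_matrix, clip = FALSE) {
  off <- r_matrix[row(r_matrix) != col(r_matrix)]
  if (any(abs(off) >= 1)) {
    if (!clip)
      stop("|r| >= 1 encountered; set clip = TRUE to clip before transforming",
           call. = FALSE)
    r_matrix[] <- pmin(pmax(r_matrix, -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(r_matrix)
  diag(z) <- 0
  for (a in c("shrinkage_weight", "n_samples"))
    attr(z, a) <- attr(r_matrix, a)
  z
}

#' Validate a connectivity matrix
#'
#' Checks symmetry, finiteness and shape, returning a small report and
#' erroring on violations.
#'
#' @param z matrix of Fisher-z partial correlations.
#' @param tol symmetry tolerance.
#' @return (invisibly) list with `n_nodes`, `max_abs_z`, `symmetry_dev`,
#'   `n_nonfinite`.
#' @export
validate_matrix <- function(z, tol = 1e-8) {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop("connectivity matrix must be square", call. = FALSE)
  bad <- which(!is.finite(z), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite entry at (%d, %d)", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  dev <- max(abs(z - t(z)))
  if (dev > tol)
    stop(sprintf("asymmetry %.3g exceeds tolerance %.3g", dev, tol),
         call. = FALSE)
  invisible(list(n_nodes = nrow(z),
                 max_abs_z = max(abs(z[row(z) != col(z)])),
                 symmetry_dev = dev, n_nonfinite = nrow(bad)))
}

#' Connectivity matrices for a preprocessed cohort
#'
#' One Fisher-z partial-correlation matrix per subject and load.
#'
#' @param loadseries an `sw_loadseries` from [preprocess_cohort()].
#' @param shrinkage see [partial_correlation_matrix()].
#' @return Object of class `sw_connectivity`: list with `z` (list indexed
#'   `[[subject]][[load]]`), `meta` (data frame `subject`, `group`, `site`,
#'   `load`), `n_nodes`, `shrinkage`.
#' @export
connectivity_matrices <- function(loadseries, shrinkage = "auto") {
  subs <- loadseries$subjects
  z <- lapply(subs$subject, function(s) {
    out <- lapply(loadseries$series[[s]], function(x)
      fisher_z_transform(partial_correlation_matrix(x, shrinkage)))
    out
  })
  names(z) <- subs$subject
  meta <- do.call(rbind, lapply(subs$subject, function(s)
    data.frame(subject = s,
               group = subs$group[subs$subject == s],
               site = subs$site[subs$subject == s],
               load = names(z[[s]]), stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  structure(list(z = z, meta = meta, n_nodes = nrow(z[[1]][[1]]),
                 shrinkage = shrinkage),
            class = "sw_connectivity")
}

#' @export
print.sw_connectivity <- function(x, ...) {
  cat(sprintf("Connectivity: %d matrices (%d subjects x %d loads), %d nodes, shrinkage = %s\n",
              nrow(x$meta), length(x$z), length(x$z[[1]]), x$n_nodes,
              as.character(x$shrinkage)))
  invisible(x)
}
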