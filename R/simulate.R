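# Synthetic cohort generator. Emulates the node-level output of the real
# study's upstream pipeline (ICA-defined regions averaged to 105 node time
# series) for a two-group, two-site, three-load block design, with planted
# graph structure per (group, load) cell, reaction times negatively coupled
# to planted clustering, and head-motion traces that differ by group but are
# independent of the network truth.

#' Default synthetic-cohort parameters
#'
#' The defaults define the study conditions the generator emulates: 105
#' nodes, TR 2 s, three 6-minute runs of six blocks each, 35 subjects per
#' group, and a planted connectivity deficit (extra edge rewiring, hence
#' lower clustering and local efficiency) in the patient group at the medium
#' load only. See the package vignette for how the numerical values were
#' chosen.
#'
#' @param n_nodes number of network nodes.
#' @param target_degree planted ring-lattice degree (even).
#' @param rewiring_prob named list `HC`/`SZ` of per-load rewiring
#'   probabilities (`L1`, `L3`, `L5`).
#' @param coupling_strength off-diagonal precision magnitude.
#' @param margin diagonal-dominance margin of the precision matrix.
#' @param noise_sd additive measurement noise (signal has unit variance).
#' @param activation_amplitude task-locked mean amplitude (HRF-convolved
#'   boxcar over encode+probe).
#' @param drift_amplitude amplitude of the slow scanner drift.
#' @param site_noise_factor per-site multiplier on `noise_sd` (two sites).
#' @param rt_mean named list `HC`/`SZ` of mean reaction times (ms) per load.
#' @param rt_noise_sd named list `HC`/`SZ` of residual RT standard deviation (ms).
#' @param rt_clustering_slope RT decrease (ms) per unit planted clustering;
#'   applied around the cell mean, so cell means stay at `rt_mean`.
#' @param accuracy_mean named list `HC`/`SZ` of mean accuracies per load.
#' @param accuracy_sd accuracy noise (values are clamped to \[0.9, 1\]).
#' @param motion_step_sd named list `HC`/`SZ` of random-walk step standard
#'   deviations, `c(translation_mm, rotation_rad)`.
#' @return A named list of class `sw_params`.
#' @export
default_cohort_params <- function(
    n_nodes = 105L,
    target_degree = 4L,
    rewiring_prob = list(HC = c(L1 = 0.02, L3 = 0.02, L5 = 0.02),
                         SZ = c(L1 = 0.02, L3 = 0.12, L5 = 0.02)),
    coupling_strength = 5,
    margin = 1.05,
    noise_sd = 0.10,
    activation_amplitude = 0.15,
    drift_amplitude = 0.1,
    site_noise_factor = c(A = 1, B = 1.05),
    rt_mean = list(HC = c(L1 = 550, L3 = 636, L5 = 691),
                   SZ = c(L1 = 594, L3 = 702, L5 = 764)),
    rt_noise_sd = list(HC = 40, SZ = 50),
    rt_clustering_slope = 1000,
    accuracy_mean = list(HC = c(L1 = 0.992, L3 = 0.984, L5 = 0.973),
                         SZ = c(L1 = 0.967, L3 = 0.955, L5 = 0.954)),
    accuracy_sd = 0.01,
    motion_step_sd = list(HC = c(0.02, 4e-4), SZ = c(0.03, 6e-4))) {
  p <- as.list(environment())
  for (g in GROUPS) {
    if (!all(LOADS %in% names(p$rewiring_prob[[g]])))
      stop("rewiring_prob must have one entry per load for each group",
           call. = FALSE)
  }
  structure(p, class = "sw_params")
}

# Canonical double-gamma hemodynamic response sampled at the TR grid.
hrf_double_gamma <- function(t) {
  a1 <- 6; a2 <- 16; b <- 1; c <- 1 / 6
  h <- (t^(a1 - 1) * exp(-t / b)) / (b^a1 * gamma(a1)) -
    c * (t^(a2 - 1) * exp(-t / b)) / (b^a2 * gamma(a2))
  h[t < 0] <- 0
  h
}

# Task regressor for one run: boxcar over encode+probe spans convolved with
# the canonical HRF, on the TR grid, unit peak.
activation_regressor <- function(schedule, run, n_tr) {
  tr <- attr(schedule, "tr_seconds")
  box <- numeric(n_tr)
  blk <- schedule[schedule$run == run, ]
  for (b in seq_len(nrow(blk))) {
    i0 <- round(blk$encode_onset[b] / tr) + 1L
    i1 <- round((blk$probe_onset[b] + blk$probe_dur[b]) / tr)
    box[i0:min(i1, n_tr)] <- 1
  }
  h <- hrf_double_gamma(seq(0, 30, by = tr))
  reg <- stats::convolve(box, rev(h), type = "open")[seq_len(n_tr)]
  if (max(reg) > 0) reg <- reg / max(reg)
  reg
}

#' Simulate one subject's node time series
#'
#' Within each block's encode+probe span, node samples are drawn from that
#' load's planted covariance; prompt and fixation TRs are unit-variance
#' noise. A task-locked mean (HRF-convolved boxcar scaled by per-node
#' weights) and a slow sinusoidal drift are added, plus white measurement
#' noise. Samples are independent across TRs (no temporal autocorrelation is
#' modelled).
#'
#' @param schedule an [make_design_schedule()] object.
#' @param covariance_by_load named list (`L1`, `L3`, `L5`) of node covariance
#'   matrices, e.g. from [graph_to_covariance()].
#' @param activation_amplitude task-locked mean amplitude (0 disables).
#' @param noise_sd additive white-noise standard deviation.
#' @param drift_amplitude slow-drift amplitude (0 disables).
#' @param seed integer seed.
#' @return A list with one `n_nodes x n_tr` matrix per run.
#' @export
simulate_subject_timecourses <- function(schedule, covariance_by_load,
                                         activation_amplitude = 0,
                                         noise_sd = 0, drift_amplitude = 0,
                                         seed = NULL) {
  if (!all(LOADS %in% names(covariance_by_load)))
    stop("covariance_by_load needs entries L1, L3, L5", call. = FALSE)
  n_nodes <- nrow(covariance_by_load[[1]])
  for (l in LOADS) {
    if (!is.matrix(covariance_by_load[[l]]) ||
        nrow(covariance_by_load[[l]]) != n_nodes ||
        ncol(covariance_by_load[[l]]) != n_nodes)
      stop(sprintf("covariance for %s does not match the node count %d",
                   l, n_nodes), call. = FALSE)
  }
  tr <- attr(schedule, "tr_seconds")
  n_tr <- run_length_tr(schedule)
  chols <- lapply(covariance_by_load, chol)

  with_seed(seed, {
    node_w <- runif(n_nodes, 0.5, 1)
    lapply(sort(unique(schedule$run)), function(r) {
      X <- matrix(rnorm(n_nodes * n_tr), n_nodes, n_tr)  # background/fixation
      blk <- schedule[schedule$run == r, ]
      for (b in seq_len(nrow(blk))) {
        i0 <- round(blk$encode_onset[b] / tr) + 1L
        i1 <- round((blk$probe_onset[b] + blk$probe_dur[b]) / tr)
        span <- i0:i1
        Z <- matrix(rnorm(length(span) * n_nodes), length(span), n_nodes)
        X[, span] <- t(Z %*% chols[[blk$load[b]]])
        if (noise_sd > 0)
          X[, span] <- X[, span] +
            matrix(rnorm(n_nodes * length(span), 0, noise_sd),
                   n_nodes, length(span))
      }
      if (activation_amplitude != 0) {
        reg <- activation_regressor(schedule, r, n_tr)
        X <- X + activation_amplitude * outer(node_w, reg)
      }
      if (drift_amplitude != 0) {
        ph <- runif(n_nodes, 0, 2 * pi)
        tt <- seq_len(n_tr) * tr
        X <- X + drift_amplitude *
          sin(outer(ph, 2 * pi * 0.001 * tt, `+`))
      }
      X
    })
  })
}

#' Simulate behavioural records from the planted truth
#'
#' Mean correct-trial reaction time per subject and load is the group/load
#' cell mean minus `slope * (planted clustering - cell mean clustering)` plus
#' noise, so cell means follow the configured table while within-cell RT is
#' negatively coupled to the planted clustering. Accuracy is high by
#' construction (clamped to \[0.9, 1\]).
#'
#' @param truth data frame with columns `subject`, `group`, `load`,
#'   `clustering` (planted per-subject clustering coefficients).
#' @param params an [default_cohort_params()] object.
#' @param seed integer seed.
#' @return Data frame `subject`, `group`, `load`, `accuracy`, `rt_ms`.
#' @export
simulate_behavior <- function(truth, params = default_cohort_params(),
                              seed = NULL) {
  need <- c("subject", "group", "load", "clustering")
  if (!all(need %in% names(truth)))
    stop("truth needs columns subject, group, load, clustering", call. = FALSE)
  with_seed(seed, {
    out <- truth[, c("subject", "group", "load")]
    out$accuracy <- NA_real_
    out$rt_ms <- NA_real_
    for (g in GROUPS) for (l in LOADS) {
      idx <- which(truth$group == g & truth$load == l)
      if (!length(idx)) next
      cc <- truth$clustering[idx]
      base <- params$rt_mean[[g]][[l]]
      rt <- base - params$rt_clustering_slope * (cc - mean(cc)) +
        rnorm(length(idx), 0, params$rt_noise_sd[[g]])
      acc <- params$accuracy_mean[[g]][[l]] +
        rnorm(length(idx), 0, params$accuracy_sd)
      out$rt_ms[idx] <- pmax(rt, 150)
      out$accuracy[idx] <- pmin(pmax(acc, 0.9), 1)
    }
    out
  })
}

#' Simulate a rigid-body head-motion trace
#'
#' Smooth random walk in the six rigid-body parameters (three translations in
#' mm, three rotations in radians). Step sizes are scaled per group so that
#' group differences in motion summaries exist while remaining independent of
#' the planted network structure.
#'
#' @param n_frames number of frames (TRs).
#' @param step_sd length-2 numeric: translation and rotation step SD.
#' @param seed integer seed.
#' @return `n_frames x 6` matrix with columns tx, ty, tz, rx, ry, rz.
#' @export
simulate_motion <- function(n_frames, step_sd = c(0.02, 4e-4), seed = NULL) {
  with_seed(seed, {
    steps <- cbind(matrix(rnorm(3 * n_frames, 0, step_sd[1]), n_frames, 3),
                   matrix(rnorm(3 * n_frames, 0, step_sd[2]), n_frames, 3))
    m <- apply(steps, 2, cumsum)
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws, per subject and load, a planted Watts-Strogatz graph from the
#' group/load rewiring table, converts it to a node covariance, simulates the
#' block-design node time series for all runs, and attaches behaviour, motion
#' and the ground-truth channel. Every quantity is a pure function of
#' `(params, seed)`.
#'
#' @param n_per_group subjects per group (HC, SZ).
#' @param params an [default_cohort_params()] object.
#' @param seed integer seed.
#' @param schedule optionally, a pre-built [make_design_schedule()]; by
#'   default one 3-run schedule is drawn per subject.
#' @return An object of class `sw_cohort`: list with elements `design`
#'   (per-subject schedules), `subjects` (data frame `subject`, `group`,
#'   `site`), `timecourses` (per subject, list of node-by-time run matrices),
#'   `behavior`, `motion`, `truth` (planted graphs, clustering table and
#'   parameters), and `tr_seconds`.
#' @examples
#' coh <- generate_cohort(n_per_group = 2, seed = 1)
#' coh
#' @export
generate_cohort <- function(n_per_group = 35L,
                            params = default_cohort_params(),
                            seed = 1L, schedule = NULL) {
  if (n_per_group < 2) stop("'n_per_group' must be at least 2", call. = FALSE)
  n <- 2L * n_per_group
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    group = rep(GROUPS, each = n_per_group),
    site = rep_len(names(params$site_noise_factor), n),
    stringsAsFactors = FALSE)

  covs <- vector("list", n)
  graphs <- vector("list", n)
  designs <- vector("list", n)
  tcs <- vector("list", n)
  motions <- vector("list", n)
  truth_rows <- vector("list", n)

  for (s in seq_len(n)) {
    g <- subjects$group[s]
    sch <- if (is.null(schedule))
      make_design_schedule(seed = child_seed(seed, 1L, s)) else schedule
    designs[[s]] <- sch
    gl <- list(); cl <- list()
    for (l in LOADS) {
      A <- sample_planted_graph(params$n_nodes, params$target_degree,
                                params$rewiring_prob[[g]][[l]],
                                seed = child_seed(seed, 2L, s, match(l, LOADS)))
      gl[[l]] <- A
      cl[[l]] <- mean(cpp_clustering(A))
    }
    graphs[[s]] <- gl
    covs[[s]] <- lapply(gl, graph_to_covariance,
                        coupling_strength = params$coupling_strength,
                        margin = params$margin)
    site_f <- params$site_noise_factor[[subjects$site[s]]]
    tcs[[s]] <- simulate_subject_timecourses(
      sch, covs[[s]],
      activation_amplitude = params$activation_amplitude,
      noise_sd = params$noise_sd * site_f,
      drift_amplitude = params$drift_amplitude,
      seed = child_seed(seed, 3L, s))
    motions[[s]] <- lapply(seq_len(max(sch$run)), function(r)
      simulate_motion(run_length_tr(sch), params$motion_step_sd[[g]],
                      seed = child_seed(seed, 4L, s, r)))
    truth_rows[[s]] <- data.frame(
      subject = subjects$subject[s], group = g, load = LOADS,
      clustering = unlist(cl, use.names = FALSE), stringsAsFactors = FALSE)
  }
  truth_tab <- do.call(rbind, truth_rows)
  behavior <- simulate_behavior(truth_tab, params,
                                seed = child_seed(seed, 5L))
  names(designs) <- names(tcs) <- names(motions) <- names(graphs) <-
    subjects$subject
  structure(list(design = designs, subjects = subjects, timecourses = tcs,
                 behavior = behavior, motion = motions,
                 truth = list(graphs = graphs, clustering = truth_tab,
                              params = params, seed = seed),
                 tr_seconds = attr(designs[[1]], "tr_seconds")),
            class = "sw_cohort")
}

#' @export
print.sw_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d nodes, %d run(s)/subject, TR = %g s\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$group)[GROUPS], GROUPS),
                    collapse = " / "),
              nrow(x$timecourses[[1]][[1]]),
              length(x$timecourses[[1]]), x$tr_seconds))
  cat(sprintf("Planted mean clustering by group x load:\n"))
  agg <- stats::aggregate(clustering ~ group + load, x$truth$clustering, mean)
  print(stats::xtabs(clustering ~ group + load, agg))
  invisible(x)
}
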