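# End-to-end pipeline: simulate (or read) -> preprocess -> connectivity ->
# small-world regime + metric table -> statistics, bundled into one report.

#' Default pipeline configuration
#'
#' @param n_per_group subjects per group for the synthetic cohort.
#' @param params generator parameters ([default_cohort_params()]).
#' @param low_factor,high_factor,order band-pass settings.
#' @param shrinkage covariance shrinkage (see
#'   [partial_correlation_matrix()]).
#' @param grid_size observation degrees in the small-world regime.
#' @param n_nulls rewired nulls per sigma estimate.
#' @param grid optional fixed observation grid (skips the regime search).
#' @param alpha significance level; `fdr_alpha` the FDR-corrected level;
#'   `marginal_alpha` the marginal band reported alongside.
#' @return Named list of class `sw_config`.
#' @export
pipeline_config <- function(n_per_group = 35L,
                            params = default_cohort_params(),
                            low_factor = 0.01, high_factor = 0.9, order = 5L,
                            shrinkage = "auto", grid_size = 16L,
                            n_nulls = 25L, grid = NULL, alpha = 0.05,
                            fdr_alpha = 0.05, marginal_alpha = 0.1) {
  structure(as.list(environment()), class = "sw_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, preprocesses it, builds the load-wise
#' partial-correlation networks, finds the small-world regime and the
#' observation grid, computes the metric table, applies site correction and
#' runs the statistical stage: two-way group-by-load ANOVA per measure,
#' per-load group tests (averaged and per observation with FDR), the
#' cross-load HC-L5 vs SZ-L3 contrast, one-tailed load-contrast tests,
#' reaction-time correlations per load, and motion summaries with a group
#' test.
#'
#' @param config an [pipeline_config()] object.
#' @param cohort optional pre-built `sw_cohort` (otherwise one is generated
#'   from `config` and `seed`).
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir optional directory; when given, the metric table (TSV),
#'   regime (JSON) and summary (JSON) are written there.
#' @return Object of class `sw_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         seed = 1L, out_dir = NULL) {
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_per_group, config$params,
                              seed = child_seed(seed, 101L))
  pre <- preprocess_cohort(cohort, config$low_factor, config$high_factor,
                           config$order)
  conn <- connectivity_matrices(pre, config$shrinkage)
  if (is.null(config$grid)) {
    regime <- find_small_world_regime(conn, grid_size = config$grid_size,
                                      n_nulls = config$n_nulls,
                                      seed = child_seed(seed, 102L))
    grid <- regime$grid
  } else {
    regime <- NULL
    grid <- config$grid
  }
  tab <- correct_site_effects(compute_metric_table(conn, grid))

  anova <- do.call(rbind, lapply(MEASURES, function(m) {
    a <- anova_group_by_load(tab, m)
    a$measure <- m
    a
  }))
  group_tests <- list()
  for (l in LOADS) {
    group_tests[[l]] <- lapply(MEASURES, function(m)
      group_tests_per_observation(tab, m, load = l))
    names(group_tests[[l]]) <- MEASURES
  }
  cross <- lapply(MEASURES, function(m)
    group_tests_per_observation(tab, m,
                                comparison = list(a = c("HC", "L5"),
                                                  b = c("SZ", "L3"))))
  names(cross) <- MEASURES
  contrasts <- do.call(rbind, lapply(MEASURES, function(m) {
    rbind(cbind(measure = m, contrast = "L1->L3",
                load_contrast_tests(tab, m, "L1", "L3", "decrease")),
          cbind(measure = m, contrast = "L3->L5",
                load_contrast_tests(tab, m, "L3", "L5", "increase")))
  }))
  behav <- do.call(rbind, lapply(LOADS, function(l)
    do.call(rbind, lapply(MEASURES, function(m)
      cbind(measure = m, load = l,
            behavior_correlations(tab, cohort$behavior, m, l))))))

  motion <- do.call(rbind, lapply(cohort$subjects$subject, function(s)
    cbind(data.frame(subject = s,
                     group = cohort$subjects$group[
                       cohort$subjects$subject == s]),
          as.data.frame(motion_summaries(cohort$motion[[s]])))))
  motion_tests <- do.call(rbind, lapply(
    c("mean_motion", "max_motion", "mean_rotation", "n_movements"),
    function(v) {
      tt <- t.test(motion[[v]][motion$group == "HC"],
                   motion[[v]][motion$group == "SZ"], var.equal = TRUE)
      data.frame(summary = v, t = unname(tt$statistic), p = tt$p.value)
    }))

  avg_sig <- vapply(LOADS, function(l) {
    gt <- group_tests[[l]][["C_net"]]
    gt$p_raw[gt$observation == "avg"]
  }, numeric(1))

  report <- structure(list(
    config = config, seed = seed,
    subjects = cohort$subjects,
    regime = regime, grid = grid,
    metric_table = tab,
    anova = anova,
    group_tests = group_tests,
    cross_load = cross,
    load_contrasts = contrasts,
    behavior_correlations = behav,
    motion = motion, motion_tests = motion_tests,
    flagged_load = LOADS[which.min(avg_sig)]),
    class = "sw_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "metric_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(regime))
      jsonlite::write_json(
        list(k_min = regime$k_min, k_max = regime$k_max,
             increment = regime$increment, grid = regime$grid,
             min_sigma = min(regime$sigma)),
        file.path(out_dir, "regime.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary_list(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# Plain-list summary used for JSON serialization and printing.
summary_list <- function(report) {
  iact <- report$anova[report$anova$term == "group:load", ]
  list(
    n_subjects = nrow(report$subjects),
    grid = report$grid,
    regime = if (!is.null(report$regime))
      list(k_min = report$regime$k_min, k_max = report$regime$k_max,
           min_sigma = min(report$regime$sigma)) else NULL,
    interaction_p = stats::setNames(iact$p, iact$measure),
    avg_group_p_by_load = lapply(stats::setNames(LOADS, LOADS), function(l)
      vapply(MEASURES, function(m) {
        gt <- report$group_tests[[l]][[m]]
        gt$p_raw[gt$observation == "avg"]
      }, numeric(1))),
    flagged_load = report$flagged_load)
}

#' @export
print.sw_report <- function(x, ...) {
  cat("Small-world network analysis report\n")
  cat(sprintf("  %d subjects; observation grid %.1f..%.1f (%d degrees)\n",
              nrow(x$subjects), min(x$grid), max(x$grid), length(x$grid)))
  if (!is.null(x$regime))
    cat(sprintf("  regime degrees %.1f-%.1f, verified min sigma %.3f\n",
                x$regime$k_min, x$regime$k_max, min(x$regime$sigma)))
  iact <- x$anova[x$anova$term == "group:load", ]
  cat("  group x load interaction p-values:\n")
  for (i in seq_len(nrow(iact)))
    cat(sprintf("    %-9s %.4g\n", iact$measure[i], iact$p[i]))
  cat(sprintf("  load with the strongest averaged C_net group difference: %s\n",
              x$flagged_load))
  invisible(x)
}

#' @export
summary.sw_report <- function(object, ...) {
  s <- summary_list(object)
  print(object)
  cat("\n  averaged group-difference p-values by load:\n")
  for (l in LOADS)
    cat(sprintf("    %s: %s\n", l,
                paste(sprintf("%s=%.3g", MEASURES,
                              s$avg_group_p_by_load[[l]]), collapse = " ")))
  invisible(s)
}

#' Plot measures along the observation grid
#'
#' Group means of one measure per observation degree at one load, with one
#' line per group — the per-degree group comparison view.
#'
#' @param x an `sw_report`.
#' @param measure measure name (default `"C_net"`).
#' @param load load label (default `"L3"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sw_report <- function(x, measure = "C_net", load = "L3", ...) {
  tab <- metric_subset(x$metric_table, measure = measure, load = load)
  tab <- tab[tab$observation != "avg", ]
  means <- vapply(GROUPS, function(g)
    vapply(split(tab$value[tab$group == g], tab$degree[tab$group == g]),
           mean, numeric(1)), numeric(length(unique(tab$degree))))
  graphics::matplot(sort(unique(tab$degree)), means, type = "b", pch = 16,
                    lty = 1, col = c("forestgreen", "firebrick"),
                    xlab = "degree K", ylab = measure,
                    main = sprintf("%s at %s", measure, load), ...)
  graphics::legend("topleft", GROUPS, col = c("forestgreen", "firebrick"),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
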