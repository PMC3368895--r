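# Statistical stage: site correction, group x load ANOVA, per-observation
# group tests with Benjamini-Hochberg FDR, one-tailed load-contrast tests,
# behaviour correlations and head-motion summaries.

metric_subset <- function(tab, measure = NULL, load = NULL, observation = NULL) {
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(measure)) keep <- keep & tab$measure %in% measure
  if (!is.null(load)) keep <- keep & tab$load %in% load
  if (!is.null(observation)) keep <- keep & tab$observation %in% observation
  tab[keep, , drop = FALSE]
}

#' Remove site effects from a metric table
#'
#' Within each (measure, load, observation) cell, site means are removed and
#' the grand mean restored — equivalent to regressing the measure on site.
#' With a single site (or any site with fewer than 2 subjects) the table is
#' returned unchanged with a warning.
#'
#' @param tab an `sw_metric_table`.
#' @return Corrected table of the same shape.
#' @export
correct_site_effects <- function(tab) {
  sites <- unique(tab$site)
  if (length(sites) < 2) {
    warning("single site: site correction is the identity", call. = FALSE)
    return(tab)
  }
  if (any(table(unique(tab[, c("subject", "site")])$site) < 2)) {
    warning("a site has fewer than 2 subjects: site correction skipped",
            call. = FALSE)
    return(tab)
  }
  key <- interaction(tab$measure, tab$load, tab$observation, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- tab$value[idx]
    gm <- mean(v)
    sm <- stats::ave(v, tab$site[idx])
    tab$value[idx] <- v - sm + gm
  }
  tab
}

#' Two-way group-by-load ANOVA on a network measure
#'
#' Ordinary two-way ANOVA (`value ~ group * load`) on subject-level values —
#' by default the per-subject averages over the observation grid.
#'
#' @param tab an `sw_metric_table`.
#' @param measure one of `"C_net"`, `"L_net"`, `"E_local"`, `"E_global"`.
#' @param use_averaged use the `"avg"` observation (default); otherwise
#'   supply a specific `observation`.
#' @param observation observation label when `use_averaged = FALSE`.
#' @return Data frame with rows `group`, `load`, `group:load` and columns
#'   `term`, `df`, `F`, `p`.
#' @export
anova_group_by_load <- function(tab, measure, use_averaged = TRUE,
                                observation = NULL) {
  obs <- if (use_averaged) "avg" else observation
  d <- metric_subset(tab, measure = measure, observation = obs)
  if (!nrow(d)) stop("no rows for the requested measure", call. = FALSE)
  if (length(unique(d$group)) < 2 || length(unique(d$load)) < 2)
    stop("need at least 2 levels in group and load", call. = FALSE)
  if (stats::var(d$value) == 0) {
    return(data.frame(term = c("group", "load", "group:load"),
                      df = NA_real_, F = 0, p = 1))
  }
  fit <- stats::aov(value ~ group * load,
                    data = transform(d, group = factor(group),
                                     load = factor(load)))
  s <- summary(fit)[[1]]
  data.frame(term = c("group", "load", "group:load"),
             df = s[1:3, "Df"], F = s[1:3, "F value"], p = s[1:3, "Pr(>F)"])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (wraps `p.adjust(method = "BH")`), with input
#' validation.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Per-observation two-sample group tests with FDR
#'
#' A two-sample t-test at each observation degree of the grid, comparing two
#' (group, load) cells — by default HC vs SZ at the same load; a
#' `comparison` of the form `list(a = c("HC", "L5"), b = c("SZ", "L3"))`
#' supports the cross-load contrast. FDR correction is applied across the
#' observations of the grid.
#'
#' @param tab an `sw_metric_table`.
#' @param measure measure name.
#' @param load load label (used when `comparison` is `NULL`).
#' @param comparison optional list with `a`, `b`, each `c(group, load)`.
#' @param var_equal pooled-variance t-test (default `TRUE`); `FALSE` for
#'   Welch.
#' @param include_average also test the `"avg"` observation (reported with
#'   `observation = "avg"`, not part of the FDR family).
#' @return Data frame `observation`, `degree`, `t`, `p_raw`, `p_fdr`.
#' @export
group_tests_per_observation <- function(tab, measure, load = NULL,
                                        comparison = NULL, var_equal = TRUE,
                                        include_average = TRUE) {
  if (is.null(comparison)) {
    if (is.null(load)) stop("give 'load' or 'comparison'", call. = FALSE)
    comparison <- list(a = c("HC", load), b = c("SZ", load))
  }
  obs_levels <- unique(tab$observation[tab$observation != "avg"])
  obs_levels <- obs_levels[order(as.numeric(obs_levels))]
  one <- function(obs) {
    da <- metric_subset(tab, measure, comparison$a[2], obs)
    da <- da[da$group == comparison$a[1], ]
    db <- metric_subset(tab, measure, comparison$b[2], obs)
    db <- db[db$group == comparison$b[1], ]
    if (!nrow(da) || !nrow(db))
      stop(sprintf("empty cell at observation %s", obs), call. = FALSE)
    tt <- t.test(da$value, db$value, var.equal = var_equal)
    data.frame(observation = obs,
               degree = if (obs == "avg") NA_real_ else da$degree[1],
               t = unname(tt$statistic), p_raw = tt$p.value)
  }
  res <- do.call(rbind, lapply(obs_levels, one))
  res$p_fdr <- fdr_correct(res$p_raw)
  if (include_average) {
    avg <- one("avg")
    avg$p_fdr <- NA_real_
    res <- rbind(res, avg)
  }
  rownames(res) <- NULL
  res
}

#' One-tailed load-contrast tests
#'
#' Per-subject difference of a measure between two loads, tested against
#' zero with a one-tailed one-sample t-test in the stated direction,
#' separately per group.
#'
#' @param tab an `sw_metric_table`.
#' @param measure measure name.
#' @param from_load,to_load load labels; the contrast is `to - from`.
#' @param direction `"increase"` (right-tailed) or `"decrease"`
#'   (left-tailed).
#' @param observation observation label (default `"avg"`).
#' @return Data frame `group`, `mean_diff`, `t`, `df`, `p`.
#' @export
load_contrast_tests <- function(tab, measure, from_load, to_load,
                                direction = c("increase", "decrease"),
                                observation = "avg") {
  direction <- match.arg(direction)
  out <- lapply(GROUPS, function(g) {
    a <- metric_subset(tab, measure, from_load, observation)
    a <- a[a$group == g, ]
    b <- metric_subset(tab, measure, to_load, observation)
    b <- b[b$group == g, ]
    if (!nrow(a) && !nrow(b)) return(NULL)
    miss <- union(setdiff(a$subject, b$subject), setdiff(b$subject, a$subject))
    if (length(miss))
      stop(paste("missing paired values for subject(s):",
                 paste(miss, collapse = ", ")), call. = FALSE)
    d <- b$value[match(a$subject, b$subject)] - a$value
    if (stats::sd(d) == 0) {
      return(data.frame(group = g, mean_diff = mean(d), t = 0,
                        df = length(d) - 1, p = 0.5))
    }
    tt <- t.test(d, alternative = if (direction == "increase") "greater"
                                  else "less")
    data.frame(group = g, mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Correlation of network measures with behaviour
#'
#' Pearson correlation between a per-subject averaged network measure and
#' the mean correct-trial reaction time at one load, pooled over all
#' subjects and within each group.
#'
#' @param tab an `sw_metric_table`.
#' @param behavior data frame `subject`, `group`, `load`, `accuracy`, `rt_ms`.
#' @param measure measure name.
#' @param load load label.
#' @param observation observation label (default `"avg"`).
#' @return Data frame `scope` (`all`, `HC`, `SZ`), `n`, `r`, `p`.
#' @export
behavior_correlations <- function(tab, behavior, measure, load,
                                  observation = "avg") {
  d <- metric_subset(tab, measure, load, observation)
  b <- behavior[behavior$load == load, ]
  m <- merge(d[, c("subject", "group", "value")],
             b[, c("subject", "rt_ms")], by = "subject")
  one <- function(scope, rows) {
    if (stats::var(rows$value) == 0 || stats::var(rows$rt_ms) == 0)
      stop(sprintf("zero variance in '%s' correlation", scope), call. = FALSE)
    ct <- cor.test(rows$value, rows$rt_ms)
    data.frame(scope = scope, n = nrow(rows), r = unname(ct$estimate),
               p = ct$p.value)
  }
  out <- rbind(one("all", m),
               do.call(rbind, lapply(GROUPS, function(g)
                 one(g, m[m$group == g, ]))))
  rownames(out) <- NULL
  out
}

#' Head-motion summaries from a rigid-body trace
#'
#' Mean and maximum frame-to-frame Euclidean translation displacement, mean
#' frame-to-frame rotation magnitude, and the number of movements (frames
#' whose displacement exceeds `movement_threshold`). Means are taken over
#' the `n - 1` frame-to-frame displacements.
#'
#' @param motion_trace frames-by-6 matrix (tx, ty, tz in mm; rx, ry, rz in
#'   radians), or a list of such matrices (runs are concatenated).
#' @param movement_threshold displacement threshold in mm (default 0.1).
#' @return List `mean_motion`, `max_motion`, `mean_rotation`,
#'   `n_movements`.
#' @export
motion_summaries <- function(motion_trace, movement_threshold = 0.1) {
  if (is.list(motion_trace)) motion_trace <- do.call(rbind, motion_trace)
  if (!is.matrix(motion_trace) || ncol(motion_trace) != 6)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  if (nrow(motion_trace) < 2)
    stop("motion trace needs at least 2 frames", call. = FALSE)
  dt <- diff(motion_trace[, 1:3, drop = FALSE])
  dr <- diff(motion_trace[, 4:6, drop = FALSE])
  disp <- sqrt(rowSums(dt^2))
  rot <- sqrt(rowSums(dr^2))
  list(mean_motion = mean(disp), max_motion = max(disp),
       mean_rotation = mean(rot), n_movements = sum(disp > movement_threshold))
}
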