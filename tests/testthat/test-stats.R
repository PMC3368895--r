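# Statistics on hand-built metric tables (no pipeline needed).

make_table <- function(n_per_group = 8, n_obs = 4, sites = c("A", "B"),
                       effect = function(group, load, obs) 0, sd = 0.05,
                       seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(2 * n_per_group))
  grp <- rep(c("HC", "SZ"), each = n_per_group)
  site <- rep_len(sites, 2 * n_per_group)
  grid <- 10 + seq_len(n_obs)
  rows <- expand.grid(subject = subj, load = LOADS,
                      observation = c(as.character(seq_len(n_obs)), "avg"),
                      measure = c("C_net", "E_local"),
                      stringsAsFactors = FALSE)
  rows$group <- grp[match(rows$subject, subj)]
  rows$site <- site[match(rows$subject, subj)]
  rows$degree <- ifelse(rows$observation == "avg", NA,
                        grid[suppressWarnings(as.integer(rows$observation))])
  base <- 0.3 + rnorm(nrow(rows), 0, sd)
  rows$value <- base + mapply(effect, rows$group, rows$load, rows$observation)
  # make avg rows consistent
  for (s in subj) for (l in LOADS) for (m in unique(rows$measure)) {
    i <- rows$subject == s & rows$load == l & rows$measure == m
    rows$value[i & rows$observation == "avg"] <-
      mean(rows$value[i & rows$observation != "avg"])
  }
  class(rows) <- c("sw_metric_table", "data.frame")
  rows
}

test_that("site correction removes site offsets without touching group effects", {
  tab <- make_table(effect = function(g, l, o) ifelse(g == "SZ", -0.05, 0))
  tab$value <- tab$value + ifelse(tab$site == "B", 0.2, 0)   # planted offset
  cor <- correct_site_effects(tab)
  for (obs in c("1", "2")) {
    sub <- cor[cor$measure == "C_net" & cor$load == "L1" &
               cor$observation == obs, ]
    expect_lt(abs(mean(sub$value[sub$site == "A"]) -
                  mean(sub$value[sub$site == "B"])), 1e-10)
  }
  # balanced groups across sites: group difference unchanged
  d0 <- with(tab[tab$measure == "C_net" & tab$observation == "avg" &
                 tab$load == "L1", ],
             mean(value[group == "HC"]) - mean(value[group == "SZ"]))
  d1 <- with(cor[cor$measure == "C_net" & cor$observation == "avg" &
                 cor$load == "L1", ],
             mean(value[group == "HC"]) - mean(value[group == "SZ"]))
  expect_equal(d0, d1, tolerance = 1e-10)
  # single site: identity with a warning
  tabs <- make_table(sites = "A")
  expect_warning(out <- correct_site_effects(tabs), "single site")
  expect_equal(out$value, tabs$value)
})

test_that("two-way ANOVA matches the textbook sums-of-squares oracle", {
  tab <- make_table(effect = function(g, l, o)
    ifelse(g == "SZ" & l == "L3", -0.08, 0))
  a <- anova_group_by_load(tab, "C_net")
  d <- tab[tab$measure == "C_net" & tab$observation == "avg", ]
  o <- oracle_anova2(d$value, d$group, d$load)
  expect_equal(a$F, o$F, tolerance = 1e-8)
  expect_equal(a$p, o$p, tolerance = 1e-8)
  expect_lt(a$p[a$term == "group:load"], 0.05)
  # degenerate table: all values identical
  tab0 <- make_table(sd = 0)
  tab0$value <- 0.5
  a0 <- anova_group_by_load(tab0, "C_net")
  expect_equal(a0$p, rep(1, 3))
})

test_that("interaction power at the default planted effect is high", {
  # planted SZ-L3 shift of one subject-level SD: detected in most replicates
  hits <- 0
  for (s in 1:20) {
    tab <- make_table(n_per_group = 35, n_obs = 2, seed = s,
                      effect = function(g, l, o)
                        ifelse(g == "SZ" & l == "L3", -0.05, 0))
    a <- anova_group_by_load(tab, "C_net")
    hits <- hits + (a$p[a$term == "group:load"] < 0.05)
  }
  expect_gte(hits, 16)                                     # >= 80%
})

test_that("BH adjustment equals the definitional step-up oracle", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_correct(p), oracle_bh(p), tolerance = 1e-12)
  }
  p <- runif(20)
  expect_true(all(fdr_correct(p) >= p))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-observation group tests respect the FDR family and cross-load comparisons", {
  tab <- make_table(n_obs = 8, effect = function(g, l, o)
    ifelse(g == "SZ" & l == "L3" & o == "3", -0.4, 0))
  gt <- group_tests_per_observation(tab, "C_net", load = "L3")
  expect_equal(nrow(gt), 9)                                # 8 obs + avg
  expect_equal(gt$p_fdr[gt$observation != "avg"],
               oracle_bh(gt$p_raw[gt$observation != "avg"]))
  sig <- gt$observation[!is.na(gt$p_fdr) & gt$p_fdr < 0.05]
  expect_equal(sig, "3")                                   # only the planted one
  # cross-load comparison spec (HC at L5 vs SZ at L3)
  cx <- group_tests_per_observation(tab, "C_net",
                                    comparison = list(a = c("HC", "L5"),
                                                      b = c("SZ", "L3")))
  expect_equal(nrow(cx), 9)
  # identical groups: no rejections after FDR in most null replicates
  fp <- 0
  for (s in 1:20) {
    nulltab <- make_table(n_obs = 8, seed = 100 + s)
    g0 <- group_tests_per_observation(nulltab, "C_net", load = "L1")
    fp <- fp + any(g0$p_fdr < 0.05, na.rm = TRUE)
  }
  expect_lte(fp, 2)                                        # >= 90% clean
})

test_that("load-contrast tests detect the planted V shape and stay flat under the null", {
  tab <- make_table(n_per_group = 20, effect = function(g, l, o)
    ifelse(g == "SZ" & l == "L3", -0.1, 0))
  dec <- load_contrast_tests(tab, "C_net", "L1", "L3", "decrease")
  inc <- load_contrast_tests(tab, "C_net", "L3", "L5", "increase")
  expect_lt(dec$p[dec$group == "SZ"], 0.05)
  expect_lt(inc$p[inc$group == "SZ"], 0.05)
  expect_gt(dec$p[dec$group == "HC"], 0.05)
  # identical loads: t = 0, one-tailed p = 0.5
  tab0 <- make_table(sd = 0)
  tab0$value <- 0.4
  t0 <- load_contrast_tests(tab0, "C_net", "L1", "L3", "increase")
  expect_equal(t0$t, c(0, 0))
  expect_equal(t0$p, c(0.5, 0.5))
  # missing pair errors with the subject named
  tabm <- tab[!(tab$subject == "S001" & tab$load == "L3"), ]
  expect_error(load_contrast_tests(tabm, "C_net", "L1", "L3", "decrease"),
               "S001")
})

test_that("behaviour correlations recover exact and planted relationships", {
  tab <- make_table(n_per_group = 10, n_obs = 2)
  avg <- tab[tab$measure == "C_net" & tab$observation == "avg" &
             tab$load == "L3", ]
  behav <- data.frame(subject = avg$subject, group = avg$group, load = "L3",
                      accuracy = 0.95, rt_ms = 900 - 400 * avg$value)
  bc <- behavior_correlations(tab, behav, "C_net", "L3")
  expect_equal(bc$r[bc$scope == "all"], -1, tolerance = 1e-10)
  # shuffled RT: small correlation
  set.seed(3)
  behav$rt_ms <- sample(behav$rt_ms)
  bc2 <- behavior_correlations(tab, behav, "C_net", "L3")
  expect_lt(abs(bc2$r[bc2$scope == "all"]), 0.6)
  behav$rt_ms <- 700
  expect_error(behavior_correlations(tab, behav, "C_net", "L3"),
               "zero variance")
})

test_that("motion summaries follow the frame-to-frame displacement convention", {
  z <- matrix(0, 10, 6)
  m0 <- motion_summaries(z)
  expect_equal(unlist(m0), c(mean_motion = 0, max_motion = 0,
                             mean_rotation = 0, n_movements = 0))
  # single 1 mm step in x across 10 frames: mean over the 9 displacements
  z1 <- z; z1[6:10, 1] <- 1
  m1 <- motion_summaries(z1)
  expect_equal(m1$max_motion, 1)
  expect_equal(m1$mean_motion, 1 / 9)
  expect_equal(m1$n_movements, 1)
  # rotations only
  z2 <- z; z2[, 5] <- seq(0, 0.009, length.out = 10)
  m2 <- motion_summaries(z2)
  expect_equal(m2$mean_motion, 0)
  expect_gt(m2$mean_rotation, 0)
  expect_error(motion_summaries(z[, 1:5]), "6 columns")
  expect_error(motion_summaries(z[1, , drop = FALSE]), "2 frames")
})
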