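test_that("per-load sample covariance converges to the planted covariance", {
  # long noiseless series: law of large numbers on the block samples
  A <- sample_planted_graph(8, 4, 0.2, seed = 1)
  covs <- list(L1 = graph_to_covariance(A, 3),
               L3 = graph_to_covariance(A, 3),
               L5 = graph_to_covariance(A, 3))
  sch <- make_design_schedule(n_runs = 114, gap_policy = "none", seed = 2)
  runs <- simulate_subject_timecourses(sch, covs, activation_amplitude = 0,
                                       noise_sd = 0, drift_amplitude = 0,
                                       seed = 3)
  segs <- unlist(lapply(seq_along(runs), function(r)
    extract_blocks(runs[[r]], sch, run = r)), recursive = FALSE)
  ls <- concat_by_load(segs)
  expect_gte(ncol(ls$L1), 5000)
  S <- cov(t(ls$L1))
  expect_lt(norm(S - covs$L1, "F") / norm(covs$L1, "F"), 0.05)
})

test_that("simulated time courses are seed-deterministic with schedule-set length", {
  coh <- tiny_cohort()
  sch <- coh$design[[1]]
  covs <- lapply(stats::setNames(LOADS, LOADS), function(l)
    graph_to_covariance(coh$truth$graphs[[1]][[l]], 5))
  a <- simulate_subject_timecourses(sch, covs, 0.15, 0.1, 0.1, seed = 7)
  b <- simulate_subject_timecourses(sch, covs, 0.15, 0.1, 0.1, seed = 7)
  expect_identical(a, b)
  expect_equal(ncol(a[[1]]), 180)                 # 6 min at TR 2 s
  expect_equal(length(a), 3)
  bad <- covs
  bad$L3 <- bad$L3[1:10, 1:10]
  expect_error(simulate_subject_timecourses(sch, bad), "node count")
})

test_that("reaction times follow the planted clustering coupling", {
  truth <- data.frame(subject = sprintf("S%03d", 1:200),
                      group = rep(c("HC", "SZ"), each = 100),
                      load = "L3",
                      clustering = runif(200, 0.2, 0.5))
  # slope 0: RT independent of clustering
  p0 <- default_cohort_params(rt_clustering_slope = 0)
  b0 <- simulate_behavior(truth, p0, seed = 1)
  expect_lt(abs(cor(b0$rt_ms[1:100], truth$clustering[1:100])), 0.2)
  # strong slope, vanishing noise: correlation -> -1 within a cell
  p1 <- default_cohort_params(rt_clustering_slope = 500,
                              rt_noise_sd = list(HC = 1e-6, SZ = 1e-6))
  b1 <- simulate_behavior(truth, p1, seed = 1)
  expect_lt(cor(b1$rt_ms[1:100], truth$clustering[1:100]), -0.999)
  expect_true(all(b1$accuracy >= 0.9))
})

test_that("cohort reaction times rise with load and accuracies stay high", {
  coh <- generate_cohort(n_per_group = 12, seed = 6)
  b <- coh$behavior
  for (g in GROUPS) {
    m <- tapply(b$rt_ms[b$group == g], b$load[b$group == g], mean)
    expect_true(m[["L1"]] < m[["L3"]] && m[["L3"]] < m[["L5"]])
  }
  expect_true(all(b$accuracy >= 0.9 & b$accuracy <= 1))
})

test_that("motion traces have 6 rigid-body columns and scale with the step size", {
  m <- simulate_motion(100, step_sd = c(0.02, 4e-4), seed = 1)
  expect_equal(dim(m), c(100, 6))
  big <- simulate_motion(100, step_sd = c(0.2, 4e-3), seed = 1)
  expect_gt(motion_summaries(big)$mean_motion, motion_summaries(m)$mean_motion)
})

test_that("cohort generation is a pure function of (params, seed)", {
  a <- generate_cohort(n_per_group = 2, seed = 5)
  b <- generate_cohort(n_per_group = 2, seed = 5)
  expect_identical(a$timecourses, b$timecourses)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$truth$clustering, b$truth$clustering)
  d <- generate_cohort(n_per_group = 2, seed = 6)
  expect_false(identical(a$timecourses, d$timecourses))
})

test_that("planted clustering ordering matches the rewiring table", {
  coh <- generate_cohort(n_per_group = 10, seed = 8)
  cl <- coh$truth$clustering
  agg <- tapply(cl$clustering, list(cl$group, cl$load), mean)
  # the SZ deficit is planted at the medium load only
  expect_lt(agg["SZ", "L3"], agg["HC", "L3"] - 0.05)
  expect_lt(abs(agg["SZ", "L1"] - agg["HC", "L1"]), 0.05)
  expect_lt(abs(agg["SZ", "L5"] - agg["HC", "L5"]), 0.05)
  # truth graphs are connected
  expect_true(all(vapply(coh$truth$graphs[[1]], is_connected_network,
                         logical(1))))
})

test_that("cohorts round-trip losslessly through the on-disk layout", {
  coh <- tiny_cohort()
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(validate_inputs(dir)$ok)
  back <- read_cohort(dir)
  expect_equal(back$subjects, coh$subjects)
  expect_equal(back$timecourses, coh$timecourses, tolerance = 1e-15)
  expect_equal(back$behavior, coh$behavior, tolerance = 1e-12)
  expect_equal(back$truth$graphs[[1]], coh$truth$graphs[[1]],
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$design[[1]]), as.data.frame(coh$design[[1]]))
  unlink(dir, recursive = TRUE)
})

test_that("input validation reports broken layouts precisely", {
  coh <- tiny_cohort()
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  # truncate one series below its schedule
  f <- file.path(dir, "S001_run1_timeseries.tsv")
  m <- swnet:::read_matrix_tsv(f)
  swnet:::write_matrix_tsv(m[, 1:50], f)
  v <- validate_inputs(dir)
  expect_false(v$ok)
  expect_true(any(grepl("50 TRs", v$problems)))
  # behaviour missing one subject
  b <- read.csv(file.path(dir, "behavior.csv"))
  write.csv(b[b$subject != "S002", ], file.path(dir, "behavior.csv"),
            row.names = FALSE)
  v2 <- validate_inputs(dir)
  expect_true(any(grepl("S002", v2$problems)))
  unlink(dir, recursive = TRUE)
})
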