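# On-disk interchange formats: tab-separated node-by-TR matrices with JSON
# sidecars, JSON design schedules, CSV behaviour and motion tables.

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE))
  names(df) <- as.character(seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a cohort to a directory
#'
#' Lays out the cohort in plain-text interchange formats: per subject/run
#' tab-separated node-by-TR matrices with JSON sidecars (subject, group,
#' site, run), JSON design schedules, a behaviour CSV (`subject`, `group`,
#' `load`, `accuracy`, `rt_ms`) and per subject/run motion CSVs (`frame`,
#' `tx`, `ty`, `tz`, `rx`, `ry`, `rz`). The truth channel is serialized as
#' JSON (edge lists and the clustering table).
#'
#' @param cohort an `sw_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects$subject) {
    write_design_json(cohort$design[[s]],
                      file.path(dir, sprintf("%s_design.json", s)))
    runs <- cohort$timecourses[[s]]
    for (r in seq_along(runs)) {
      base <- file.path(dir, sprintf("%s_run%d", s, r))
      write_matrix_tsv(runs[[r]], paste0(base, "_timeseries.tsv"))
      jsonlite::write_json(
        list(subject = s,
             group = cohort$subjects$group[cohort$subjects$subject == s],
             site = cohort$subjects$site[cohort$subjects$subject == s],
             run = r, tr_seconds = cohort$tr_seconds),
        paste0(base, "_timeseries.json"), auto_unbox = TRUE)
      mo <- as.data.frame(cohort$motion[[s]][[r]])
      mo <- cbind(frame = seq_len(nrow(mo)), mo)
      utils::write.csv(mo, paste0(base, "_motion.csv"), row.names = FALSE)
    }
  }
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  truth <- list(
    clustering = cohort$truth$clustering,
    seed = cohort$truth$seed,
    edges = lapply(cohort$truth$graphs, function(gl)
      lapply(gl, function(A) {
        idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
        list(n = nrow(A), i = idx[, 1], j = idx[, 2])
      })))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Inverse of [write_cohort()].
#'
#' @param dir directory written by [write_cohort()].
#' @return An `sw_cohort` (the `params` element of the truth channel is not
#'   round-tripped).
#' @export
read_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, "_timeseries\\.json$", full.names = TRUE))
  if (!length(sidecars)) stop("no time-series sidecars found in ", dir,
                              call. = FALSE)
  meta <- do.call(rbind, lapply(sidecars, function(p) {
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    data.frame(subject = j$subject, group = j$group, site = j$site,
               run = j$run, tr_seconds = j$tr_seconds,
               stringsAsFactors = FALSE)
  }))
  subjects <- unique(meta[, c("subject", "group", "site")])
  subjects <- subjects[order(subjects$subject), ]
  rownames(subjects) <- NULL
  tcs <- list(); designs <- list(); motions <- list()
  for (s in subjects$subject) {
    designs[[s]] <- read_design_json(file.path(dir, sprintf("%s_design.json", s)))
    runs <- sort(meta$run[meta$subject == s])
    tcs[[s]] <- lapply(runs, function(r)
      read_matrix_tsv(file.path(dir, sprintf("%s_run%d_timeseries.tsv", s, r))))
    motions[[s]] <- lapply(runs, function(r) {
      mo <- utils::read.csv(file.path(dir, sprintf("%s_run%d_motion.csv", s, r)))
      as.matrix(mo[, c("tx", "ty", "tz", "rx", "ry", "rz")])
    })
  }
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
                              stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    graphs <- lapply(tj$edges, function(gl) lapply(gl, function(e) {
      A <- matrix(0L, e$n, e$n)
      idx <- cbind(e$i, e$j)
      if (length(e$i)) { A[idx] <- 1L; A[idx[, c(2, 1), drop = FALSE]] <- 1L }
      A
    }))
    truth <- list(graphs = graphs, clustering = as.data.frame(tj$clustering),
                  seed = tj$seed)
  }
  structure(list(design = designs, subjects = subjects, timecourses = tcs,
                 behavior = behavior, motion = motions, truth = truth,
                 tr_seconds = meta$tr_seconds[1]),
            class = "sw_cohort")
}

#' Validate an on-disk cohort
#'
#' Checks the interchange layout: sidecar/series pairing, consistent TR and
#' node counts, series long enough for their schedules, behaviour
#' completeness, and motion column counts.
#'
#' @param dir cohort directory.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(dir) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))
  sidecars <- sort(list.files(dir, "_timeseries\\.json$", full.names = TRUE))
  if (!length(sidecars)) {
    return(list(ok = FALSE, problems = "no *_timeseries.json sidecars found"))
  }
  n_nodes <- NULL; trs <- NULL; subs <- character()
  for (p in sidecars) {
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    subs <- union(subs, j$subject)
    trs <- union(trs, j$tr_seconds)
    mp <- sub("\\.json$", ".tsv", p)
    if (!file.exists(mp)) { note("%s: missing series matrix %s", p, mp); next }
    m <- read_matrix_tsv(mp)
    if (is.null(n_nodes)) n_nodes <- nrow(m)
    if (nrow(m) != n_nodes)
      note("%s: node count %d differs from %d", mp, nrow(m), n_nodes)
    dp <- file.path(dir, sprintf("%s_design.json", j$subject))
    if (!file.exists(dp)) { note("%s: missing design %s", p, dp); next }
    sch <- read_design_json(dp)
    blk <- sch[sch$run == j$run, ]
    need <- max(round((blk$probe_onset + blk$probe_dur) / attr(sch, "tr_seconds")))
    if (ncol(m) < need)
      note("%s: series has %d TRs but block %d of run %d needs %d",
           mp, ncol(m), blk$block[which.max(blk$probe_onset)], j$run, need)
    mop <- file.path(dir, sprintf("%s_run%d_motion.csv", j$subject, j$run))
    if (file.exists(mop)) {
      mo <- utils::read.csv(mop)
      if (!all(c("tx", "ty", "tz", "rx", "ry", "rz") %in% names(mo)))
        note("%s: motion file lacks the 6 rigid-body columns", mop)
    }
  }
  if (length(trs) > 1)
    note("inconsistent tr_seconds across sidecars: %s",
         paste(trs, collapse = ", "))
  bp <- file.path(dir, "behavior.csv")
  if (!file.exists(bp)) {
    note("missing behavior.csv")
  } else {
    b <- utils::read.csv(bp, stringsAsFactors = FALSE)
    miss <- setdiff(subs, unique(b$subject))
    if (length(miss))
      note("behavior.csv missing subject(s): %s", paste(miss, collapse = ", "))
  }
  list(ok = !length(problems), problems = problems)
}

#' Write / read connectivity matrices
#'
#' Each subject-by-load Fisher-z matrix is written as an N-by-N
#' tab-separated file with a JSON sidecar carrying its provenance
#' (subject, group, site, load, shrinkage weight, sample count).
#'
#' @param conn an `sw_connectivity` object.
#' @param dir output directory (created if missing).
#' @return `write_connectivity` returns `dir`; `read_connectivity` an
#'   `sw_connectivity`.
#' @export
write_connectivity <- function(conn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(conn$meta))) {
    s <- conn$meta$subject[r]; l <- conn$meta$load[r]
    z <- conn$z[[s]][[l]]
    base <- file.path(dir, sprintf("%s_%s_zmatrix", s, l))
    write_matrix_tsv(z, paste0(base, ".tsv"))
    jsonlite::write_json(
      list(subject = s, group = conn$meta$group[r], site = conn$meta$site[r],
           load = l, shrinkage_weight = attr(z, "shrinkage_weight"),
           n_samples = attr(z, "n_samples")),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(dir) {
  sidecars <- sort(list.files(dir, "_zmatrix\\.json$", full.names = TRUE))
  if (!length(sidecars)) stop("no *_zmatrix.json sidecars in ", dir,
                              call. = FALSE)
  meta <- list(); z <- list()
  for (p in sidecars) {
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    m <- read_matrix_tsv(sub("\\.json$", ".tsv", p))
    attr(m, "shrinkage_weight") <- j$shrinkage_weight
    attr(m, "n_samples") <- j$n_samples
    z[[j$subject]][[j$load]] <- m
    meta[[length(meta) + 1L]] <- data.frame(
      subject = j$subject, group = j$group, site = j$site, load = j$load,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  meta <- meta[order(match(meta$subject, names(z)),
                     match(meta$load, LOADS)), ]
  rownames(meta) <- NULL
  structure(list(z = z, meta = meta, n_nodes = nrow(z[[1]][[1]]),
                 shrinkage = "as-read"),
            class = "sw_connectivity")
}
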