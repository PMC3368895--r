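# Preprocessing of node time series: optional voxel-block averaging,
# zero-phase Butterworth band-pass filtering, truncation into encode+probe
# block segments and load-wise concatenation.

#' Average voxel time courses into node (spatial block) time courses
#'
#' @param voxel_matrix voxels-by-time matrix.
#' @param block_assignment integer/character vector, one entry per voxel,
#'   naming the block each voxel belongs to; `NA` voxels are dropped.
#' @return nodes-by-time matrix, one row per block, rows ordered by the sort
#'   order of the block labels.
#' @export
average_voxel_blocks <- function(voxel_matrix, block_assignment) {
  if (!is.matrix(voxel_matrix))
    stop("'voxel_matrix' must be a matrix", call. = FALSE)
  if (length(block_assignment) != nrow(voxel_matrix))
    stop("one block assignment per voxel row is required", call. = FALSE)
  keep <- !is.na(block_assignment)
  labs <- sort(unique(block_assignment[keep]))
  if (!length(labs)) stop("no assigned voxels", call. = FALSE)
  out <- matrix(NA_real_, length(labs), ncol(voxel_matrix),
                dimnames = list(as.character(labs), NULL))
  for (i in seq_along(labs)) {
    rows <- which(keep & block_assignment == labs[i])
    if (!length(rows))
      stop(sprintf("block '%s' has no voxels", labs[i]), call. = FALSE)
    out[i, ] <- colMeans(voxel_matrix[rows, , drop = FALSE])
  }
  out
}

# Zero-phase Butterworth application: odd-reflection padding plus
# steady-state initial conditions, forward and backward passes (compiled).
# Both matter because the high-pass corner period can exceed the run
# length, where naive forward-backward filtering has large edge transients.

# Steady-state initial delay state for a unit-amplitude input (companion
# matrix solve), as in scipy.signal.lfilter_zi.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  comp <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  solve(diag(n - 1) - t(comp), b[2:n] - a[2:n] * b[1])
}

#' Band-pass filter node time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass with cutoffs
#' `c(low_factor, high_factor) / (2 * tr_seconds)` Hz, i.e. the factors are
#' applied to the Nyquist frequency of the TR sampling. At TR 2 s the default
#' band is 0.0025-0.225 Hz, which retains the 0.167 Hz encode and 0.026 Hz
#' probe task frequencies while removing drift and high-frequency noise.
#'
#' @param series numeric vector, or nodes-by-time matrix (rows filtered
#'   independently).
#' @param tr_seconds repetition time in seconds.
#' @param low_factor,high_factor band edges as fractions of Nyquist,
#'   `0 < low < high < 1`.
#' @param order Butterworth order (default 5).
#' @return Filtered series, same shape as the input.
#' @export
bandpass_filter <- function(series, tr_seconds, low_factor = 0.01,
                            high_factor = 0.9, order = 5L) {
  stopifnot_scalar_num(tr_seconds, "tr_seconds", positive = TRUE)
  if (!(low_factor > 0 && high_factor < 1 && low_factor < high_factor))
    stop("band edges must satisfy 0 < low_factor < high_factor < 1 (fractions of Nyquist)",
         call. = FALSE)
  n <- if (is.matrix(series)) ncol(series) else length(series)
  if (n <= 3L * order)
    stop(sprintf("series length %d too short for filter order %d", n, order),
         call. = FALSE)
  bf <- signal::butter(order, c(low_factor, high_factor), type = "pass")
  zi <- lfilter_zi(bf$b, bf$a)
  if (is.matrix(series)) {
    cpp_filtfilt_rows(bf$b, bf$a, zi, series)
  } else {
    drop(cpp_filtfilt_rows(bf$b, bf$a, zi, matrix(series, nrow = 1)))
  }
}

#' Truncate a run's series into encode+probe block segments
#'
#' One segment per block of the schedule, keeping only the encode and probe
#' TRs (the 2 s learn prompt is discarded). Segments carry provenance
#' (`run`, `block`, `load`, TR span) as attributes.
#'
#' @param series nodes-by-time matrix for one run.
#' @param schedule an [make_design_schedule()] object.
#' @param run which run of the schedule `series` corresponds to.
#' @return List of nodes-by-TR segment matrices.
#' @export
extract_blocks <- function(series, schedule, run = 1L) {
  tr <- attr(schedule, "tr_seconds")
  blk <- schedule[schedule$run == run, , drop = FALSE]
  out <- vector("list", nrow(blk))
  for (b in seq_len(nrow(blk))) {
    i0 <- round(blk$encode_onset[b] / tr) + 1L
    i1 <- round((blk$probe_onset[b] + blk$probe_dur[b]) / tr)
    if (i1 > ncol(series))
      stop(sprintf("block %d of run %d extends past the series end (needs TR %d, have %d)",
                   blk$block[b], run, i1, ncol(series)), call. = FALSE)
    seg <- series[, i0:i1, drop = FALSE]
    attr(seg, "run") <- run
    attr(seg, "block") <- blk$block[b]
    attr(seg, "load") <- blk$load[b]
    attr(seg, "tr_span") <- c(i0, i1)
    out[[b]] <- seg
  }
  out
}

#' Concatenate block segments by working-memory load
#'
#' Segments (from [extract_blocks()], possibly over several runs) are grouped
#' by their load label and concatenated in (run, onset) order, restoring the
#' canonical order regardless of input order.
#'
#' @param segments list of segments with `run`, `block`, `load`, `tr_span`
#'   attributes.
#' @param strict error (`TRUE`) or warn (`FALSE`, default) when loads have
#'   unequal block counts.
#' @return Named list (`L1`, `L3`, `L5`) of nodes-by-time matrices, each with
#'   a `provenance` attribute (data frame `run`, `block`, `start`, `end`,
#'   giving every source block's TR span and its column range in the
#'   concatenation).
#' @export
concat_by_load <- function(segments, strict = FALSE) {
  if (!length(segments)) return(stats::setNames(list(), character()))
  meta <- data.frame(
    idx = seq_along(segments),
    run = vapply(segments, function(s) attr(s, "run"), numeric(1)),
    block = vapply(segments, function(s) attr(s, "block"), numeric(1)),
    load = vapply(segments, function(s) attr(s, "load"), character(1)))
  counts <- table(meta$load)
  if (length(unique(counts)) > 1) {
    msg <- paste("unequal block counts across loads:",
                 paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  loads <- intersect(LOADS, unique(meta$load))
  out <- lapply(loads, function(l) {
    m <- meta[meta$load == l, , drop = FALSE]
    m <- m[order(m$run, m$block), , drop = FALSE]
    segs <- segments[m$idx]
    lens <- vapply(segs, ncol, integer(1))
    ends <- cumsum(lens)
    x <- do.call(cbind, segs)
    attr(x, "provenance") <- data.frame(
      run = m$run, block = m$block,
      start = c(1L, head(ends, -1) + 1L), end = ends)
    attr(x, "load") <- l
    x
  })
  stats::setNames(out, loads)
}

#' Preprocess a cohort into load-wise series
#'
#' Runs the full preprocessing chain per subject: band-pass filter each run
#' (filtering is applied to whole runs, before block truncation), truncate
#' into encode+probe segments, and concatenate by load.
#'
#' @param cohort an `sw_cohort` (or a compatible list with `timecourses`,
#'   `design`, `subjects`, `tr_seconds`).
#' @param low_factor,high_factor,order see [bandpass_filter()].
#' @param filter apply the band-pass filter (`TRUE`).
#' @return An object of class `sw_loadseries`: list with `series` (per
#'   subject, named list of per-load nodes-by-time matrices), `subjects`,
#'   `tr_seconds`.
#' @export
preprocess_cohort <- function(cohort, low_factor = 0.01, high_factor = 0.9,
                              order = 5L, filter = TRUE) {
  series <- lapply(cohort$subjects$subject, function(s) {
    sch <- cohort$design[[s]]
    runs <- cohort$timecourses[[s]]
    segs <- list()
    for (r in seq_along(runs)) {
      x <- runs[[r]]
      if (filter)
        x <- bandpass_filter(x, cohort$tr_seconds, low_factor, high_factor,
                             order)
      segs <- c(segs, extract_blocks(x, sch, run = r))
    }
    concat_by_load(segs)
  })
  names(series) <- cohort$subjects$subject
  structure(list(series = series, subjects = cohort$subjects,
                 tr_seconds = cohort$tr_seconds,
                 settings = list(low_factor = low_factor,
                                 high_factor = high_factor, order = order,
                                 filter = filter)),
            class = "sw_loadseries")
}
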