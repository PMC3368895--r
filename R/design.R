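# Block-design schedule for the Sternberg working-memory task:
# each block is a 2 s "Learn" prompt, a 6 s encode epoch and a 38 s probe
# epoch; every run holds two blocks of each load (1, 3 or 5 digits) in
# pseudo-random order, with fixation filling the run out to 6 minutes.

PROMPT_DUR <- 2
ENCODE_DUR <- 6
PROBE_DUR <- 38
N_PROBES <- 14
RUN_SECONDS <- 360

#' Create a block-design schedule
#'
#' Builds the prompt/encode/probe block timing for a multi-run working-memory
#' experiment on a repetition-time (TR) grid. Each run contains
#' `blocks_per_load_per_run` blocks of each of the three loads (`L1`, `L3`,
#' `L5`) in a seeded pseudo-random order; fixation gaps are split evenly
#' around the blocks so that every run spans the same total duration.
#'
#' @param tr_seconds repetition time in seconds; must divide all epoch
#'   durations (prompt 2 s, encode 6 s, probe 38 s) and the fixation gaps.
#' @param n_runs number of runs.
#' @param blocks_per_load_per_run blocks of each load per run.
#' @param gap_policy `"even"` (fixation split evenly into the gaps before
#'   each block and after the last) or `"none"` (blocks back-to-back).
#' @param run_seconds total run duration in seconds used by `"even"`.
#' @param seed integer seed controlling the block orders.
#' @return An object of class `sw_design`: a data frame with one row per
#'   block (`run`, `block`, `load`, `prompt_onset`, `prompt_dur`,
#'   `encode_onset`, `encode_dur`, `probe_onset`, `probe_dur`, `n_probes`,
#'   all times in seconds) with attributes `tr_seconds` and `run_seconds`.
#' @examples
#' sch <- make_design_schedule(seed = 1)
#' table(sch$load)            # six blocks per load across the three runs
#' @export
make_design_schedule <- function(tr_seconds = 2, n_runs = 3,
                                 blocks_per_load_per_run = 2,
                                 gap_policy = c("even", "none"),
                                 run_seconds = RUN_SECONDS, seed = NULL) {
  gap_policy <- match.arg(gap_policy)
  stopifnot_scalar_num(tr_seconds, "tr_seconds", positive = TRUE)
  for (d in c(prompt = PROMPT_DUR, encode = ENCODE_DUR, probe = PROBE_DUR)) {
    if (abs(d / tr_seconds - round(d / tr_seconds)) > 1e-9)
      stop(sprintf("tr_seconds = %g does not divide the %g s epoch duration",
                   tr_seconds, d), call. = FALSE)
  }
  block_dur <- PROMPT_DUR + ENCODE_DUR + PROBE_DUR
  n_blocks <- 3L * blocks_per_load_per_run
  if (gap_policy == "even") {
    total_gap <- run_seconds - n_blocks * block_dur
    if (total_gap < 0)
      stop("blocks do not fit in run_seconds", call. = FALSE)
    gap <- total_gap / (n_blocks + 1)
    if (abs(gap / tr_seconds - round(gap / tr_seconds)) > 1e-9)
      stop(sprintf("fixation gap of %g s is not a multiple of tr_seconds", gap),
           call. = FALSE)
  } else {
    gap <- 0
  }

  rows <- with_seed(seed, {
    out <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      loads <- sample(rep(LOADS, blocks_per_load_per_run))
      onset <- gap
      blocks <- vector("list", n_blocks)
      for (b in seq_len(n_blocks)) {
        blocks[[b]] <- data.frame(
          run = r, block = b, load = loads[b],
          prompt_onset = onset, prompt_dur = PROMPT_DUR,
          encode_onset = onset + PROMPT_DUR, encode_dur = ENCODE_DUR,
          probe_onset = onset + PROMPT_DUR + ENCODE_DUR, probe_dur = PROBE_DUR,
          n_probes = N_PROBES, stringsAsFactors = FALSE)
        onset <- onset + block_dur + gap
      }
      out[[r]] <- do.call(rbind, blocks)
    }
    do.call(rbind, out)
  })
  structure(rows,
            tr_seconds = tr_seconds,
            run_seconds = if (gap_policy == "even") run_seconds
                          else n_blocks * block_dur,
            class = c("sw_design", "data.frame"))
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf("Block design: %d run(s), %d blocks/run, TR = %g s, run = %g s\n",
              max(x$run), sum(x$run == x$run[1]),
              attr(x, "tr_seconds"), attr(x, "run_seconds")))
  print.data.frame(x, ...)
  invisible(x)
}

# Number of TRs per run implied by the schedule.
run_length_tr <- function(schedule) {
  as.integer(round(attr(schedule, "run_seconds") / attr(schedule, "tr_seconds")))
}

#' Write / read a design schedule as JSON
#'
#' @param schedule an [make_design_schedule()] object.
#' @param path file path.
#' @return `read_design_json` returns an `sw_design` object.
#' @export
write_design_json <- function(schedule, path) {
  runs <- lapply(split(as.data.frame(schedule), schedule$run), function(df) {
    list(blocks = df[, setdiff(names(df), "run")])
  })
  jsonlite::write_json(
    list(tr_seconds = attr(schedule, "tr_seconds"),
         run_seconds = attr(schedule, "run_seconds"),
         runs = runs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- do.call(rbind, lapply(seq_along(j$runs), function(r) {
    df <- as.data.frame(j$runs[[r]]$blocks)
    df$run <- r
    df
  }))
  rows <- rows[, c("run", "block", "load", "prompt_onset", "prompt_dur",
                   "encode_onset", "encode_dur", "probe_onset", "probe_dur",
                   "n_probes")]
  structure(rows, tr_seconds = j$tr_seconds, run_seconds = j$run_seconds,
            class = c("sw_design", "data.frame"))
}
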