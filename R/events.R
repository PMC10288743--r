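#' Construct an event schedule
#'
#' An event schedule lists the task blocks of a block-design run as
#' `(condition, onset_s, duration_s)` rows. Times are seconds from the start
#' of the recording; each block occupies the half-open interval
#' `[onset, onset + duration)`. Rows are sorted by onset, blocks must not
#' overlap, and all task durations must equal the configured task period
#' within one sample.
#'
#' @param condition Character vector of block conditions (`"SON"` or `"MI"`).
#' @param onset_s Numeric vector of block onsets in seconds (>= 0).
#' @param duration_s Numeric vector of block durations in seconds (> 0).
#' @param task_s Nominal task period the durations are validated against
#'   (default 30 s).
#' @param sampling_rate_hz Sample grid used for the duration tolerance.
#' @return A tibble of class `event_schedule`, sorted by onset.
#' @export
new_event_schedule <- function(condition, onset_s, duration_s, task_s = 30,
                               sampling_rate_hz = 10) {
  if (!all(condition %in% .conditions)) {
    stop("unknown condition label: ",
         paste(setdiff(condition, .conditions), collapse = ", "))
  }
  if (any(onset_s < 0)) stop("block onsets must be >= 0")
  if (any(duration_s <= 0)) stop("block durations must be > 0")
  if (any(abs(duration_s - task_s) > 1 / sampling_rate_hz)) {
    stop("block durations must equal the task period (", task_s,
         " s) within one sample")
  }
  sched <- tibble::tibble(
    condition = condition, onset_s = onset_s, duration_s = duration_s
  )
  if (is.unsorted(sched$onset_s)) {
    warning("event rows were not sorted by onset; sorting")
    sched <- sched[order(sched$onset_s), ]
  }
  ends <- sched$onset_s + sched$duration_s
  if (nrow(sched) > 1 && any(sched$onset_s[-1] < ends[-nrow(sched)] - 1e-9)) {
    stop("validation error: overlapping blocks in event schedule")
  }
  structure(sched, class = c("event_schedule", class(sched)),
            task_s = task_s)
}

#' Read / write an event schedule
#'
#' Three-column tab-separated file with header `onset_s`, `duration_s`,
#' `condition`. Rows are sorted on read (with a warning if the file was
#' unsorted); overlapping blocks and unknown condition labels are rejected.
#'
#' @param path File path.
#' @param task_s,sampling_rate_hz Passed to [new_event_schedule()].
#' @return An `event_schedule` (for `read_events`); `path` invisibly (for
#'   `write_events`).
#' @export
read_events <- function(path, task_s = 30, sampling_rate_hz = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- utils::read.delim(path, check.names = FALSE)
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(tbl))) {
    stop("format error: expected columns ", paste(need, collapse = ", "))
  }
  new_event_schedule(
    condition = as.character(tbl$condition),
    onset_s = as.numeric(tbl$onset_s),
    duration_s = as.numeric(tbl$duration_s),
    task_s = task_s, sampling_rate_hz = sampling_rate_hz
  )
}

#' @rdname read_events
#' @param schedule An `event_schedule`.
#' @export
write_events <- function(schedule, path) {
  out <- data.frame(
    onset_s = sprintf("%.17g", schedule$onset_s),
    duration_s = sprintf("%.17g", schedule$duration_s),
    condition = schedule$condition
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the block-design paradigm schedule
#'
#' Two runs, one per auditory condition: each run starts with a 60 s baseline
#' followed by 8 blocks of 30 s task + 40 s recovery, and the runs are
#' separated by a 60 s gap. The condition order is either fixed or drawn from
#' the current RNG stream.
#'
#' @param paradigm List with fields `baseline_s`, `n_blocks`, `task_s`,
#'   `recovery_s`, `inter_run_gap_s` (see [cohort_spec()]).
#' @param run_order `"random"` (draw the order of the two conditions from the
#'   ambient RNG), `"fixed"` (SON first), or an explicit 2-vector of
#'   condition names.
#' @return An `event_schedule` of `2 * n_blocks` rows.
#' @export
#' @examples
#' sched <- build_paradigm(run_order = "fixed")
#' nrow(sched)    # 16 blocks
#' sched$onset_s[sched$condition == "SON"][1]  # first SON onset at 60 s
build_paradigm <- function(paradigm = default_paradigm(),
                           run_order = c("random", "fixed")) {
  if (is.character(run_order) && length(run_order) == 2) {
    order <- match.arg(run_order, .conditions, several.ok = TRUE)
    if (anyDuplicated(order)) stop("run_order must name each condition once")
  } else {
    run_order <- match.arg(run_order)
    order <- if (run_order == "fixed") .conditions else sample(.conditions)
  }
  run_span <- paradigm$baseline_s +
    paradigm$n_blocks * (paradigm$task_s + paradigm$recovery_s)
  starts <- c(0, run_span + paradigm$inter_run_gap_s)
  rows <- lapply(seq_along(order), function(r) {
    onsets <- starts[r] + paradigm$baseline_s +
      (seq_len(paradigm$n_blocks) - 1) * (paradigm$task_s + paradigm$recovery_s)
    tibble::tibble(
      condition = order[r], onset_s = onsets, duration_s = paradigm$task_s
    )
  })
  rows <- dplyr::bind_rows(rows)
  new_event_schedule(rows$condition, rows$onset_s, rows$duration_s,
                     task_s = paradigm$task_s)
}

#' @rdname build_paradigm
#' @export
default_paradigm <- function() {
  list(baseline_s = 60, n_blocks = 8, task_s = 30, recovery_s = 40,
       inter_run_gap_s = 60, run_order = "random")
}

# Total recording span implied by a paradigm (both runs plus the gap).
paradigm_duration_s <- function(paradigm = default_paradigm()) {
  run_span <- paradigm$baseline_s +
    paradigm$n_blocks * (paradigm$task_s + paradigm$recovery_s)
  2 * run_span + paradigm$inter_run_gap_s
}
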