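#' Epoch window definitions
#'
#' All windows are half-open `[start, end)` in seconds relative to the block
#' onset, evaluated on the sample grid with onsets snapped to the nearest
#' sample. Defaults: epochs span -5 to +45 s, the analysed (baseline
#' corrected) span is -3 to +40 s, the subtracted baseline is the mean over
#' -3 to 0 s, the mean-concentration feature averages 2 to 20 s, and the
#' fitting slope is estimated over 5 to 15 s.
#'
#' @param segment,analysis,baseline,mean_window,slope_window Two-element
#'   numeric vectors `(start_s, end_s)` relative to onset.
#' @return A list of class `epoch_windows`.
#' @export
epoch_windows <- function(segment = c(-5, 45), analysis = c(-3, 40),
                          baseline = c(-3, 0), mean_window = c(2, 20),
                          slope_window = c(5, 15)) {
  contains <- function(outer, inner) {
    inner[1] >= outer[1] - 1e-9 && inner[2] <= outer[2] + 1e-9
  }
  w <- list(segment = segment, analysis = analysis, baseline = baseline,
            mean_window = mean_window, slope_window = slope_window)
  if (!contains(analysis, baseline)) stop("baseline must lie inside analysis")
  if (!contains(segment, analysis)) stop("analysis must lie inside segment")
  if (!contains(analysis, mean_window) || !contains(analysis, slope_window)) {
    stop("feature windows must lie inside the analysis window")
  }
  structure(w, class = "epoch_windows")
}

# Indices of epoch samples whose onset-relative time falls in [start, end).
window_index <- function(t_rel, window) {
  which(t_rel >= window[1] - 1e-9 & t_rel < window[2] - 1e-9)
}

#' Segment a cleaned series into stimulus-locked epochs
#'
#' Cuts one epoch per scheduled block, spanning the segment window around the
#' (sample-snapped) onset. Epochs whose window extends past the recording are
#' flagged invalid rather than truncated.
#'
#' @param hb An `hb_timeseries` (any units; typically z-scored).
#' @param schedule An `event_schedule`.
#' @param windows An [epoch_windows()].
#' @return A named list (one entry per condition) of `epoch_set` objects:
#'   arrays `hbo`/`hbr` indexed `(epoch, sample, channel)`, the
#'   onset-relative time grid `t_rel`, onset times, `valid` flags and a
#'   `retained` array `(epoch, channel, chromophore)` initialized to the
#'   valid epochs.
#' @export
segment_epochs <- function(hb, schedule, windows = epoch_windows()) {
  fs <- hb$sampling_rate_hz
  n <- ncol(hb$hbo)
  n_ch <- nrow(hb$hbo)
  off <- seq(round(windows$segment[1] * fs),
             round(windows$segment[2] * fs) - 1L)
  t_rel <- off / fs
  out <- list()
  for (cond in unique(schedule$condition)) {
    onsets <- schedule$onset_s[schedule$condition == cond]
    k <- length(onsets)
    hbo <- array(NA_real_, dim = c(k, length(off), n_ch),
                 dimnames = list(NULL, NULL, hb$channels))
    hbr <- hbo
    valid <- logical(k)
    for (e in seq_len(k)) {
      i_on <- round((onsets[e] - hb$t0_s) * fs) + 1L
      idx <- i_on + off
      if (idx[1] < 1 || idx[length(idx)] > n) {
        valid[e] <- FALSE
        next
      }
      valid[e] <- TRUE
      hbo[e, , ] <- t(hb$hbo[, idx, drop = FALSE])
      hbr[e, , ] <- t(hb$hbr[, idx, drop = FALSE])
    }
    retained <- array(rep(valid, n_ch * 2), dim = c(k, n_ch, 2),
                      dimnames = list(NULL, hb$channels, c("HbO", "HbR")))
    out[[cond]] <- structure(
      list(subject_id = hb$subject_id, group = hb$group, condition = cond,
           t_rel = t_rel, hbo = hbo, hbr = hbr, onsets_s = onsets,
           valid = valid, retained = retained, units = hb$units,
           baseline_corrected = FALSE),
      class = "epoch_set"
    )
  }
  out
}

#' Flag motion-contaminated epochs for rejection
#'
#' Applies [artifact_score()] to every epoch x channel x chromophore segment
#' and clears its `retained` flag when the score exceeds one. Rejected
#' epochs are carried as missing downstream, never silently zeroed.
#'
#' @param es An `epoch_set`.
#' @param config A [preprocess_config()] supplying the thresholds.
#' @return The `epoch_set` with updated `retained` flags.
#' @export
apply_rejection <- function(es, config = preprocess_config()) {
  for (e in seq_along(es$valid)) {
    if (!es$valid[e]) next
    for (ci in seq_len(dim(es$hbo)[3])) {
      if (artifact_score(es$hbo[e, , ci], config)$reject) {
        es$retained[e, ci, "HbO"] <- FALSE
      }
      if (artifact_score(es$hbr[e, , ci], config)$reject) {
        es$retained[e, ci, "HbR"] <- FALSE
      }
    }
  }
  es
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch, channel and chromophore, the mean over the baseline
#' window (default -3 to 0 s before onset), so every corrected epoch has
#' zero pre-stimulus mean. Idempotent: correcting twice equals correcting
#' once.
#'
#' @param es An `epoch_set`.
#' @param windows An [epoch_windows()].
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(es, windows = epoch_windows()) {
  bidx <- window_index(es$t_rel, windows$baseline)
  if (length(bidx) == 0) stop("empty baseline window")
  for (e in seq_along(es$valid)) {
    if (!es$valid[e]) next
    for (ci in seq_len(dim(es$hbo)[3])) {
      es$hbo[e, , ci] <- es$hbo[e, , ci] - mean(es$hbo[e, bidx, ci])
      es$hbr[e, , ci] <- es$hbr[e, , ci] - mean(es$hbr[e, bidx, ci])
    }
  }
  es$baseline_corrected <- TRUE
  es
}

#' Block-average retained epochs
#'
#' Pointwise mean over retained epochs only, per channel and chromophore.
#' Channels with zero retained epochs yield `NA` curves and are reported in
#' `n_retained`.
#'
#' @param es An `epoch_set`.
#' @return List with `t_rel`, matrices `hbo`/`hbr` `(sample, channel)`, and
#'   an `n_retained` matrix `(channel, chromophore)`.
#' @export
block_average <- function(es) {
  n_ch <- dim(es$hbo)[3]
  hbo <- matrix(NA_real_, length(es$t_rel), n_ch,
                dimnames = list(NULL, dimnames(es$hbo)[[3]]))
  hbr <- hbo
  n_ret <- matrix(0L, n_ch, 2,
                  dimnames = list(dimnames(es$hbo)[[3]], c("HbO", "HbR")))
  for (ci in seq_len(n_ch)) {
    keep_o <- which(es$retained[, ci, "HbO"])
    keep_r <- which(es$retained[, ci, "HbR"])
    n_ret[ci, ] <- c(length(keep_o), length(keep_r))
    if (length(keep_o) > 0) {
      hbo[, ci] <- colMeans(es$hbo[keep_o, , ci, drop = FALSE])
    }
    if (length(keep_r) > 0) {
      hbr[, ci] <- colMeans(es$hbr[keep_r, , ci, drop = FALSE])
    }
  }
  list(t_rel = es$t_rel, hbo = hbo, hbr = hbr, n_retained = n_ret)
}

#' Mean-concentration feature
#'
#' Arithmetic mean of the response curve over the mean window (default 2 to
#' 20 s after onset, half-open on the sample grid).
#'
#' @param curve Numeric vector on the epoch time grid.
#' @param t_rel Onset-relative times of `curve` in seconds.
#' @param windows An [epoch_windows()].
#' @return The mean value (same units as `curve`), or `NA` if the window is
#'   missing from the grid.
#' @export
mean_feature <- function(curve, t_rel, windows = epoch_windows()) {
  idx <- window_index(t_rel, windows$mean_window)
  if (length(idx) == 0) return(NA_real_)
  mean(curve[idx])
}

#' Fitting-slope feature
#'
#' Ordinary least-squares slope of the response curve against time over the
#' slope window (default 5 to 15 s after onset), in curve units per second.
#'
#' @inheritParams mean_feature
#' @return The OLS slope, or `NA` if the window is missing.
#' @export
slope_feature <- function(curve, t_rel, windows = epoch_windows()) {
  idx <- window_index(t_rel, windows$slope_window)
  if (length(idx) < 3) stop("slope window must contain at least 3 samples")
  tt <- t_rel[idx]
  yy <- curve[idx]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

# Feature rows for one subject's epoch sets (already baseline-corrected and
# rejection-flagged). Builds plain vectors and one tibble at the end.
subject_features <- function(epoch_sets, windows, mode) {
  acc <- list(condition = character(), channel = character(),
              chromophore = character(), epoch_index = character(),
              mean_conc = numeric(), slope = numeric(), retained = logical())
  push <- function(cond, ch, chrom, ei, m, s, keep) {
    acc$condition[length(acc$condition) + 1] <<- cond
    acc$channel[length(acc$channel) + 1] <<- ch
    acc$chromophore[length(acc$chromophore) + 1] <<- chrom
    acc$epoch_index[length(acc$epoch_index) + 1] <<- ei
    acc$mean_conc[length(acc$mean_conc) + 1] <<- m
    acc$slope[length(acc$slope) + 1] <<- s
    acc$retained[length(acc$retained) + 1] <<- keep
  }
  for (es in epoch_sets) {
    chs <- dimnames(es$hbo)[[3]]
    if (mode == "block-avg") {
      avg <- block_average(es)
      for (ci in seq_along(chs)) {
        for (chrom in c("HbO", "HbR")) {
          curve <- if (chrom == "HbO") avg$hbo[, ci] else avg$hbr[, ci]
          ok <- avg$n_retained[ci, chrom] > 0
          push(es$condition, chs[ci], chrom, "block-avg",
               if (ok) mean_feature(curve, es$t_rel, windows) else NA_real_,
               if (ok) slope_feature(curve, es$t_rel, windows) else NA_real_,
               ok)
        }
      }
    } else {
      for (e in seq_along(es$valid)) {
        for (ci in seq_along(chs)) {
          for (chrom in c("HbO", "HbR")) {
            keep <- es$retained[e, ci, chrom]
            curve <- if (chrom == "HbO") es$hbo[e, , ci] else es$hbr[e, , ci]
            push(es$condition, chs[ci], chrom, as.character(e - 1L),
                 if (keep) mean_feature(curve, es$t_rel, windows) else NA_real_,
                 if (keep) slope_feature(curve, es$t_rel, windows) else NA_real_,
                 keep)
          }
        }
      }
    }
  }
  sid <- epoch_sets[[1]]$subject_id
  grp <- epoch_sets[[1]]$group
  tibble::tibble(
    subject_id = sid, group = grp, condition = acc$condition,
    channel = acc$channel, chromophore = acc$chromophore,
    epoch_index = acc$epoch_index, mean_conc = acc$mean_conc,
    slope = acc$slope, retained = acc$retained
  )
}

#' Extract the feature table from cleaned series
#'
#' Segments each subject's cleaned series, applies trial rejection and
#' baseline correction, and computes the mean-concentration and
#' fitting-slope features. In `per-epoch` mode every retained trial yields
#' one feature row; in `block-avg` mode features are computed on the
#' block-averaged curve. Rejected trials appear as rows with `retained =
#' FALSE` and missing features.
#'
#' @param hbs Named list of `hb_timeseries` (one per subject).
#' @param schedules Named list of `event_schedule` aligned with `hbs`.
#' @param windows An [epoch_windows()].
#' @param config A [preprocess_config()] (rejection thresholds).
#' @param mode `"per-epoch"` (default) or `"block-avg"`.
#' @return A tidy tibble, one row per (subject, condition, channel,
#'   chromophore, epoch).
#' @export
build_feature_table <- function(hbs, schedules, windows = epoch_windows(),
                                config = preprocess_config(),
                                mode = c("per-epoch", "block-avg")) {
  mode <- match.arg(mode)
  out <- lapply(names(hbs), function(sid) {
    sets <- segment_epochs(hbs[[sid]], schedules[[sid]], windows)
    sets <- lapply(sets, apply_rejection, config = config)
    sets <- lapply(sets, baseline_correct, windows = windows)
    subject_features(sets, windows, mode)
  })
  dplyr::bind_rows(out)
}

#' Write a feature table as TSV
#' @param features Tibble from [build_feature_table()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
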