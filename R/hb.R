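#' Construct an HbO/HbR concentration time series
#'
#' Per-channel oxygenated (HbO) and deoxygenated (HbR) hemoglobin
#' concentration-change series, as produced by modified Beer-Lambert law
#' inversion and subsequent cleaning. The `units` tag records whether values
#' are micromolar concentration changes (`"uM"`) or z-scores (`"z"`); the
#' `processing_log` lists every applied operation with its parameters, in
#' application order.
#'
#' @param subject_id Subject identifier.
#' @param group `"HC"`, `"MCS"` or `"VS"`.
#' @param hbo,hbr Numeric matrices indexed `(channel, sample)`; must share
#'   shape.
#' @param channels Channel labels (length `nrow(hbo)`).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param units `"uM"` or `"z"`.
#' @param t0_s Start time of sample 1.
#' @param processing_log List of `list(step = , params = )` entries.
#' @return An object of class `hb_timeseries`.
#' @export
new_hb_timeseries <- function(subject_id, group, hbo, hbr, channels,
                              sampling_rate_hz = 10, units = "uM",
                              t0_s = 0, processing_log = list()) {
  hb <- structure(
    list(
      subject_id = as.character(subject_id),
      group = match.arg(group, .groups),
      sampling_rate_hz = sampling_rate_hz,
      channels = channels,
      hbo = hbo, hbr = hbr,
      units = match.arg(units, c("uM", "z")),
      t0_s = t0_s,
      processing_log = processing_log
    ),
    class = "hb_timeseries"
  )
  validate_hb(hb)
}

#' @rdname new_hb_timeseries
#' @param hb An `hb_timeseries`.
#' @export
validate_hb <- function(hb) {
  if (!identical(dim(hb$hbo), dim(hb$hbr))) {
    stop("hbo and hbr must share shape and time axis")
  }
  if (nrow(hb$hbo) != length(hb$channels)) {
    stop("channel labels do not match the channel dimension")
  }
  if (hb$units == "z") {
    for (m in list(hb$hbo, hb$hbr)) {
      means <- rowMeans(m)
      sds <- apply(m, 1, sd)
      if (any(abs(means) > 1e-6) || any(abs(sds - 1) > 1e-6)) {
        stop("z units require per-channel mean ~0 and sd ~1 over the full series")
      }
    }
  }
  hb
}

#' @export
print.hb_timeseries <- function(x, ...) {
  cat(sprintf(
    "<hb_timeseries> subject %s (%s): %d channels x %d samples @ %g Hz [%s]\n",
    x$subject_id, x$group, nrow(x$hbo), ncol(x$hbo), x$sampling_rate_hz,
    x$units
  ))
  if (length(x$processing_log) > 0) {
    cat("  log:", paste(vapply(x$processing_log, `[[`, "", "step"),
                        collapse = " -> "), "\n")
  }
  invisible(x)
}

# Append one processing step to the log.
log_step <- function(hb, step, params = list()) {
  hb$processing_log <- c(hb$processing_log, list(list(step = step, params = params)))
  hb
}

#' Steps applied to an HbO/HbR series, in order
#'
#' @param hb An `hb_timeseries`.
#' @return Character vector of processing step names.
#' @export
processing_steps <- function(hb) {
  vapply(hb$processing_log, `[[`, "", "step")
}
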