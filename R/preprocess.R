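#' Default extinction coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at 760 and
#' 830 nm, in cm^-1 per micromolar, from a standard published compilation.
#' The table is editable configuration: every result in this package depends
#' only on forward/inverse consistency of the 2x2 system, not on the specific
#' values.
#'
#' @return Tibble with columns `wavelength_nm`, `e_hbo`, `e_hbr`.
#' @export
default_extinction <- function() {
  tibble::tibble(
    wavelength_nm = c(760, 830),
    e_hbo = c(5.864e-4, 9.740e-4),
    e_hbr = c(1.5485e-3, 6.930e-4)
  )
}

# 2x2 matrix [wavelength, chromophore] from an extinction table.
extinction_matrix <- function(extinction) {
  E <- as.matrix(extinction[c("e_hbo", "e_hbr")])
  rownames(E) <- extinction$wavelength_nm
  E
}

#' Preprocessing configuration
#'
#' Parameters of the cleaning chain applied to every recording, in order:
#' optical-density conversion, modified Beer-Lambert inversion, band-pass
#' filtering, correlation-based signal improvement (CBSI), and z-scoring.
#' Epoch-level trial rejection happens during epoching and uses the
#' `rejection` thresholds declared here.
#'
#' @param i0_definition Reference-intensity definition for the optical-density
#'   step: `"whole-series"` (geometric mean over the recording, the default),
#'   `"first-60s"` (geometric mean over the initial baseline), or
#'   `"reference"` (the exact reference attached by a forward model).
#' @param extinction Extinction table, see [default_extinction()].
#' @param dpf Differential pathlength factor per wavelength (default 6 at
#'   both; the common adult value).
#' @param d_cm Source-detector separation in cm (default 3).
#' @param band_hz Band-pass edges in Hz (default `c(0.01, 0.2)`), removing
#'   drift below and cardiac/respiratory oscillations above the band.
#' @param filter_order Butterworth order (default 3); applied
#'   forward-backward, so the effective response is zero-phase.
#' @param cbsi_enabled Apply CBSI motion correction (default `TRUE`). The off
#'   switch exists because strict CBSI forces perfectly anti-correlated
#'   HbO/HbR, which same-sign group responses cannot survive.
#' @param rejection List with `max_abs_z` (default 5) and `max_jump_z`
#'   (default 3): an epoch is rejected when its absolute z-amplitude or
#'   sample-to-sample z-jump exceeds these declared, configurable thresholds.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(i0_definition = c("whole-series", "first-60s",
                                                "reference"),
                              extinction = default_extinction(),
                              dpf = c(6, 6), d_cm = 3,
                              band_hz = c(0.01, 0.2), filter_order = 3,
                              cbsi_enabled = TRUE,
                              rejection = list(max_abs_z = 5, max_jump_z = 3)) {
  i0_definition <- match.arg(i0_definition)
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2])) {
    stop("band edges must satisfy 0 < low < high")
  }
  if (any(dpf <= 0)) stop("dpf must be positive")
  if (d_cm <= 0) stop("d_cm must be positive")
  E <- extinction_matrix(extinction)
  if (abs(det(E)) < 1e-12 * max(abs(E))^2) {
    stop("extinction matrix is singular (condition number ",
         format(kappa(E)), ")")
  }
  structure(
    list(i0_definition = i0_definition, extinction = extinction, dpf = dpf,
         d_cm = d_cm, band_hz = band_hz, filter_order = filter_order,
         cbsi_enabled = cbsi_enabled, rejection = rejection),
    class = "preprocess_config"
  )
}

#' Convert raw intensity to optical density change
#'
#' `dOD(t, lambda) = -log10(I(t, lambda) / I0(lambda))` per channel and
#' wavelength. `I0` is the geometric mean of the intensity over the defining
#' window (whole series or first 60 s), so the mean of `dOD` over that window
#' is exactly zero; with `"reference"`, the reference attached by
#' [forward_mbll()] is used and the round trip is exact.
#'
#' @param rec An `optical_recording`.
#' @param i0_definition `"whole-series"`, `"first-60s"`, `"reference"`, or a
#'   numeric `channel x wavelength` matrix of reference intensities.
#' @return A list of class `od_series`: `od` array `(channel, wavelength,
#'   sample)`, plus channels, wavelengths and metadata.
#' @export
intensity_to_od <- function(rec, i0_definition = "whole-series") {
  validate_recording(rec)
  d <- dim(rec$intensity)
  if (is.matrix(i0_definition)) {
    i0 <- i0_definition
    i0_label <- "explicit"
  } else if (identical(i0_definition, "reference")) {
    if (is.null(rec$i0_reference)) {
      stop("recording carries no reference intensities")
    }
    i0 <- rec$i0_reference
    i0_label <- "reference"
  } else {
    i0_label <- match.arg(i0_definition, c("whole-series", "first-60s"))
    win <- if (i0_label == "first-60s") {
      seq_len(min(d[3], round(60 * rec$sampling_rate_hz)))
    } else {
      seq_len(d[3])
    }
    i0 <- apply(log(rec$intensity[, , win, drop = FALSE]), c(1, 2), mean)
    i0 <- exp(i0)  # geometric mean
  }
  od <- array(NA_real_, dim = d,
              dimnames = list(rec_channel_labels(rec), rec$wavelengths_nm, NULL))
  for (j in 1:2) {
    od[, j, ] <- -log10(rec$intensity[, j, ] / i0[, j])
  }
  structure(
    list(od = od, channels = rec_channel_labels(rec),
         wavelengths_nm = rec$wavelengths_nm,
         sampling_rate_hz = rec$sampling_rate_hz,
         subject_id = rec$subject_id, group = rec$group, t0_s = rec$t0_s,
         log = list(list(step = "intensity_to_od",
                         params = list(i0_definition = i0_label)))),
    class = "od_series"
  )
}

#' Invert the modified Beer-Lambert law
#'
#' Per channel and sample, solves the 2x2 linear system
#' `dOD(lambda_j) = d * DPF(lambda_j) * (eHbO(lambda_j) * dHbO +
#' eHbR(lambda_j) * dHbR)` for `(dHbO, dHbR)` in micromolar.
#'
#' @param od An `od_series` from [intensity_to_od()].
#' @param config A [preprocess_config()].
#' @return An `hb_timeseries` in micromolar with the inversion logged.
#' @export
od_to_hb <- function(od, config = preprocess_config()) {
  E <- extinction_matrix(config$extinction)
  A <- config$d_cm * diag(config$dpf) %*% E
  if (abs(det(A)) < 1e-14 * max(abs(A))^2) {
    stop("singular MBLL system (condition number ", format(kappa(A)), ")")
  }
  Ainv <- solve(A)
  od1 <- od$od[, 1, , drop = TRUE]
  od2 <- od$od[, 2, , drop = TRUE]
  if (is.null(dim(od1))) {
    od1 <- matrix(od1, nrow = length(od$channels))
    od2 <- matrix(od2, nrow = length(od$channels))
  }
  hbo <- Ainv[1, 1] * od1 + Ainv[1, 2] * od2
  hbr <- Ainv[2, 1] * od1 + Ainv[2, 2] * od2
  new_hb_timeseries(
    od$subject_id, od$group, hbo, hbr, od$channels,
    sampling_rate_hz = od$sampling_rate_hz, units = "uM", t0_s = od$t0_s,
    processing_log = c(od$log, list(list(
      step = "od_to_hb",
      params = list(dpf = config$dpf, d_cm = config$d_cm)
    )))
  )
}

# Extend a series at both ends by AR (Burg) linear prediction. Keeps the
# forward-backward filter's edge transients out of the data: a sinusoid is
# continued exactly, broadband signals approximately, so no junction
# discontinuity excites the slow high-pass poles.
ar_extend <- function(x, pad, order = 50, fit_window = 3000) {
  n <- length(x)
  order <- min(order, max(1, floor(n / 3)))
  # the extension only needs local behavior, so fit near the edge
  safe_pred <- function(v, fill) {
    v <- v[max(1, length(v) - fit_window + 1):length(v)]
    tryCatch({
      fit <- ar(v, aic = FALSE, order.max = order, method = "burg")
      a <- fit$ar
      # deterministic AR extrapolation, recursion run in C
      as.numeric(stats::filter(
        rep(0, pad), a, method = "recursive",
        init = rev(tail(v, length(a))) - fit$x.mean
      )) + fit$x.mean
    }, error = function(e) rep(fill, pad))
  }
  fwd <- safe_pred(x, x[n])
  bwd <- rev(safe_pred(rev(x), x[1]))
  c(bwd, x, fwd)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Butterworth band-pass of the configured order applied forward-backward
#' (two passes, zero net phase, squared magnitude response). The series is
#' extended at both ends by AR linear prediction before filtering and the
#' extensions are discarded afterwards, so filter edge transients decay
#' inside the padding rather than inside the data.
#'
#' @param hb An `hb_timeseries`.
#' @param config A [preprocess_config()] supplying `band_hz` and
#'   `filter_order`.
#' @return The filtered `hb_timeseries` (band-passed, so near zero mean).
#' @export
bandpass <- function(hb, config = preprocess_config()) {
  fs <- hb$sampling_rate_hz
  if (config$band_hz[2] >= fs / 2) stop("band edge at or above Nyquist")
  n <- ncol(hb$hbo)
  if (n <= 3 * config$filter_order) stop("series too short to filter")
  bf <- signal::butter(config$filter_order, config$band_hz / (fs / 2),
                       type = "pass")
  pad <- min(n - 1, round(3 * fs / config$band_hz[1]))
  apply_bp <- function(m) {
    t(apply(m, 1, function(x) {
      if (all(x == x[1])) return(rep(0, length(x)))  # constant in, zero out
      y <- signal::filtfilt(bf, ar_extend(x, pad))
      y[(pad + 1):(pad + length(x))]
    }))
  }
  hb$hbo <- apply_bp(hb$hbo)
  hb$hbr <- apply_bp(hb$hbr)
  log_step(hb, "bandpass",
           list(band_hz = config$band_hz, order = config$filter_order,
                design = "butterworth", passes = 2))
}

#' Correlation-based signal improvement (CBSI)
#'
#' Channel-by-channel motion correction assuming true HbO and HbR are
#' anti-correlated while motion moves both together: with
#' `alpha = sd(hbo) / sd(hbr)`, the corrected signals are
#' `hbo' = (hbo - alpha * hbr) / 2` and `hbr' = -hbo' / alpha`, which makes
#' the corrected pair exactly anti-correlated.
#'
#' @param hb An `hb_timeseries`.
#' @return The corrected `hb_timeseries` with per-channel `alpha` logged.
#' @export
cbsi_correct <- function(hb) {
  alphas <- numeric(nrow(hb$hbo))
  for (ci in seq_len(nrow(hb$hbo))) {
    s_o <- sd(hb$hbo[ci, ])
    s_r <- sd(hb$hbr[ci, ])
    if (s_r == 0) {
      stop("CBSI undefined: zero-variance HbR in channel ", hb$channels[ci])
    }
    alpha <- s_o / s_r
    corrected <- (hb$hbo[ci, ] - alpha * hb$hbr[ci, ]) / 2
    hb$hbo[ci, ] <- corrected
    hb$hbr[ci, ] <- -corrected / alpha
    alphas[ci] <- alpha
  }
  log_step(hb, "cbsi", list(alpha = alphas))
}

#' Z-score normalization
#'
#' Per channel and chromophore, over the full recording:
#' `(x - mean(x)) / sd(x)`. Sets the units tag to `"z"`.
#'
#' @param hb An `hb_timeseries`.
#' @return The normalized `hb_timeseries` (units `"z"`).
#' @export
zscore_hb <- function(hb) {
  zrows <- function(m) {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      stop("z-score undefined: zero variance in channel ",
           hb$channels[which(sds == 0)[1]])
    }
    (m - rowMeans(m)) / sds
  }
  hb$hbo <- zrows(hb$hbo)
  hb$hbr <- zrows(hb$hbr)
  hb$units <- "z"
  validate_hb(log_step(hb, "zscore", list(scope = "full recording")))
}

#' Motion-artifact score of a series or epoch
#'
#' Scores a z-scored segment by its worst absolute amplitude and worst
#' sample-to-sample jump, each relative to its threshold; the segment is
#' rejected when either ratio exceeds one.
#'
#' @param x Numeric vector in z units (or raw values divided by their scale).
#' @param config A [preprocess_config()] supplying the `rejection`
#'   thresholds.
#' @return List with `score` (max of the two threshold ratios), `reject`
#'   (logical), `max_abs`, `max_jump`.
#' @export
artifact_score <- function(x, config = preprocess_config()) {
  max_abs <- max(abs(x))
  max_jump <- if (length(x) > 1) max(abs(diff(x))) else 0
  score <- max(max_abs / config$rejection$max_abs_z,
               max_jump / config$rejection$max_jump_z)
  list(score = score, reject = score > 1, max_abs = max_abs,
       max_jump = max_jump)
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order: optical-density conversion, modified Beer-Lambert
#' inversion, band-pass filter, CBSI (unless disabled), z-score. Epoch-level
#' trial rejection is applied later, during epoching.
#'
#' @param rec An `optical_recording`.
#' @param config A [preprocess_config()].
#' @return An `hb_timeseries` in z units with a complete processing log.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  od <- intensity_to_od(rec, config$i0_definition)
  hb <- od_to_hb(od, config)
  hb <- bandpass(hb, config)
  if (config$cbsi_enabled) hb <- cbsi_correct(hb)
  zscore_hb(hb)
}
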