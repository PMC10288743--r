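#' Canonical hemodynamic response kernel
#'
#' Single-gamma response kernel with an optional delayed undershoot,
#' normalized to unit peak so that a profile amplitude in micromolar equals
#' the evoked peak concentration change. The primary lobe
#' `(t/p)^a * exp(a * (1 - t/p))` peaks at `t = peak_s`; the undershoot is the
#' same shape delayed threefold and scaled by `undershoot_ratio`, so the net
#' kernel never drops below `-undershoot_ratio` and its argmax stays within
#' one sample of `peak_s` for the ratios used here.
#'
#' @param t Time in seconds (>= 0); values at `t < 0` return 0.
#' @param peak_s Time-to-peak in seconds (default 6).
#' @param undershoot_ratio Undershoot depth as a fraction of the peak, in
#'   `[0, 1)` (default 0.1).
#' @param shape Dimensionless gamma shape parameter (default 4).
#' @return Kernel values, unit peak.
#' @export
#' @examples
#' gamma_hrf(0)                   # 0
#' tg <- seq(0, 40, by = 0.1)
#' tg[which.max(gamma_hrf(tg))]   # ~6 s
gamma_hrf <- function(t, peak_s = 6, undershoot_ratio = 0.1, shape = 4) {
  if (!is.finite(peak_s) || peak_s <= 0) stop("peak_s must be positive")
  if (undershoot_ratio < 0 || undershoot_ratio >= 1) {
    stop("undershoot_ratio must be in [0, 1)")
  }
  lobe <- function(t, p) ifelse(t <= 0, 0, (t / p)^shape * exp(shape * (1 - t / p)))
  raw <- function(t) lobe(t, peak_s) - undershoot_ratio * lobe(t, 3 * peak_s)
  # normalize to unit peak on a dense internal grid
  tg <- seq(0, 6 * peak_s, by = peak_s / 600)
  raw(t) / max(raw(tg))
}
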