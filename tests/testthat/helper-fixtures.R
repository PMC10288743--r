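# Small in-code fixtures shared across test files.

# A tiny valid recording: default montage, short series of positive
# intensities with known structure.
tiny_recording <- function(n = 100, seed = 7, fs = 10) {
  set.seed(seed)
  intensity <- array(exp(rnorm(5 * 2 * n, 0, 0.01)), dim = c(5, 2, n))
  new_optical_recording("T01", "HC", intensity, sampling_rate_hz = fs)
}

# An hb series holding a pure tone in every channel.
tone_hb <- function(freq_hz, duration_s = 600, fs = 10, n_ch = 1, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  m <- matrix(rep(amp * sin(2 * pi * freq_hz * t), n_ch),
              nrow = n_ch, byrow = TRUE)
  new_hb_timeseries("tone", "HC", m, m, paste0("CH", seq_len(n_ch)),
                    sampling_rate_hz = fs)
}

# Random-noise hb series.
noise_hb <- function(n = 2000, n_ch = 2, seed = 11, fs = 10) {
  set.seed(seed)
  hbo <- matrix(rnorm(n_ch * n), n_ch, n)
  hbr <- matrix(rnorm(n_ch * n), n_ch, n)
  new_hb_timeseries("N01", "HC", hbo, hbr, paste0("CH", seq_len(n_ch)),
                    sampling_rate_hz = fs)
}

# A zeroed response-profile table (null cohort).
null_profiles <- function() {
  p <- default_profiles()
  p$amp_hbo <- 0
  p$amp_hbr <- 0
  p
}

# Deterministic epoch set: one condition, k identical or supplied epochs.
# values: array (epoch, sample, channel); t_rel on the default segment grid.
manual_epoch_set <- function(values, fs = 10, condition = "SON") {
  k <- dim(values)[1]
  n_ch <- dim(values)[3]
  t_rel <- seq(-5 * fs, 45 * fs - 1) / fs
  stopifnot(dim(values)[2] == length(t_rel))
  structure(
    list(subject_id = "M01", group = "HC", condition = condition,
         t_rel = t_rel, hbo = values, hbr = values,
         onsets_s = seq(60, by = 70, length.out = k),
         valid = rep(TRUE, k),
         retained = array(TRUE, dim = c(k, n_ch, 2),
                          dimnames = list(NULL, paste0("CH", seq_len(n_ch)),
                                          c("HbO", "HbR"))),
         units = "z", baseline_corrected = FALSE),
    class = "epoch_set"
  )
}
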