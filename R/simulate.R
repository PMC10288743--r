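#' Group-specific hemodynamic response profiles
#'
#' One profile per group x condition gives the signed peak amplitudes (in
#' micromolar) of the evoked HbO and HbR responses plus the kernel timing
#' parameters. The defaults encode the group phenomenology this package
#' studies: healthy controls show *negative* (inverted) activation on both
#' chromophores, patients show positive activation that is larger in the
#' vegetative state than in the minimally conscious state, so that for the
#' own-name condition `amp(VS) > amp(MCS) > 0 > amp(HC)` on both
#' chromophores. HbR amplitudes are independent of HbO (not forced
#' anti-correlated) because same-sign HbO/HbR group responses are part of the
#' phenomenon being modelled.
#'
#' @return A tibble with columns `group`, `condition`, `amp_hbo`, `amp_hbr`
#'   (micromolar), `hrf_peak_s`, `hrf_undershoot_ratio`.
#' @export
default_profiles <- function() {
  tibble::tibble(
    group     = rep(.groups, each = 2),
    condition = rep(.conditions, 3),
    amp_hbo   = c(-0.5, -0.2, 0.3, 0.1, 0.6, 0.2),
    amp_hbr   = c(-0.15, -0.06, 0.09, 0.03, 0.18, 0.06),
    hrf_peak_s = 6,
    hrf_undershoot_ratio = 0.1
  )
}

#' Physiological and instrumental noise specification
#'
#' Sinusoidal cardiac, respiratory and Mayer-wave components (random phase per
#' channel and chromophore), a random-walk drift, white measurement noise, and
#' Poisson-timed motion artifacts: one-sample spikes with exponential decay
#' (tau = 0.5 s) and persistent step offsets. Amplitudes are micromolar.
#' The defaults put the single-epoch evoked signal-to-noise ratio near one,
#' which is why block averaging over the 8 task repetitions is needed to
#' recover response signs reliably.
#'
#' @param cardiac,respiratory,mayer Lists with `freq_hz` and `amp`.
#' @param drift Random-walk increment standard deviation (micromolar per
#'   sample).
#' @param white White-noise standard deviation (micromolar).
#' @param artifact_spike_rate_per_min,artifact_step_rate_per_min Poisson rates
#'   of the two motion-artifact classes.
#' @param artifact_amp Artifact amplitude (micromolar).
#' @param oscillator_coherence_s Phase-coherence time of the oscillatory
#'   components in seconds (default 30). Physiological oscillations are
#'   quasi-periodic, not phase-locked over a whole recording; each component
#'   is simulated as a sinusoid whose phase diffuses with this coherence
#'   time, so its spectrum is a narrow line at `freq_hz` but it is not
#'   coherent with the task block grid.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cardiac = list(freq_hz = 1.1, amp = 0.2),
                       respiratory = list(freq_hz = 0.25, amp = 0.1),
                       mayer = list(freq_hz = 0.1, amp = 0.05),
                       drift = 0.005, white = 0.3,
                       artifact_spike_rate_per_min = 0.5,
                       artifact_step_rate_per_min = 0.2,
                       artifact_amp = 5,
                       oscillator_coherence_s = 30) {
  spec <- list(
    cardiac = cardiac, respiratory = respiratory, mayer = mayer,
    drift = drift, white = white,
    artifact_spike_rate_per_min = artifact_spike_rate_per_min,
    artifact_step_rate_per_min = artifact_step_rate_per_min,
    artifact_amp = artifact_amp,
    oscillator_coherence_s = oscillator_coherence_s
  )
  amps <- c(cardiac$amp, respiratory$amp, mayer$amp, drift, white,
            artifact_spike_rate_per_min, artifact_step_rate_per_min,
            artifact_amp)
  if (any(amps < 0)) stop("noise amplitudes and rates must be >= 0")
  structure(spec, class = "noise_spec")
}

#' Null noise specification (all amplitudes zero)
#' @return A `noise_spec` with every amplitude and rate set to 0.
#' @export
silent_noise <- function() {
  noise_spec(cardiac = list(freq_hz = 1.1, amp = 0),
             respiratory = list(freq_hz = 0.25, amp = 0),
             mayer = list(freq_hz = 0.1, amp = 0),
             drift = 0, white = 0,
             artifact_spike_rate_per_min = 0,
             artifact_step_rate_per_min = 0, artifact_amp = 0)
}

#' Cohort specification for the synthetic-data generator
#'
#' Defines a complete simulated study: group sizes, response profiles, noise,
#' the block paradigm, the forward optical model, and the master seed. The
#' default group sizes match the study population this package emulates
#' (15 healthy controls, 4 minimally conscious, 14 vegetative state).
#'
#' @param n_per_group Named counts for `HC`, `MCS`, `VS`.
#' @param profiles Response profile table, see [default_profiles()]; must
#'   cover every group x condition with exactly one row.
#' @param noise A [noise_spec()].
#' @param paradigm See [default_paradigm()].
#' @param mbll Forward-model parameters: `extinction` (see
#'   [default_extinction()]), `dpf`, `d_cm`, `i0`.
#' @param sampling_rate_hz Sampling rate (default 10 Hz).
#' @param seed Master integer seed; all subject-level randomness derives from
#'   it deterministically.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 15, MCS = 4, VS = 14),
                        profiles = default_profiles(),
                        noise = noise_spec(),
                        paradigm = default_paradigm(),
                        mbll = list(extinction = default_extinction(),
                                    dpf = c(6, 6), d_cm = 3, i0 = 1),
                        sampling_rate_hz = 10,
                        seed = 1) {
  if (!all(.groups %in% names(n_per_group))) {
    stop("n_per_group must name counts for HC, MCS and VS")
  }
  if (any(n_per_group < 0)) stop("group counts must be >= 0")
  cover <- dplyr::count(profiles, .data$group, .data$condition)
  if (nrow(cover) != 6 || any(cover$n != 1)) {
    stop("profiles must cover every group x condition exactly once")
  }
  structure(
    list(n_per_group = n_per_group, profiles = profiles, noise = noise,
         paradigm = paradigm, mbll = mbll,
         sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Unit-peak evoked response to one task block: boxcar convolved with the
# unit-peak kernel, renormalized so the block response peaks at 1.
block_response <- function(task_s, fs, peak_s = 6, undershoot_ratio = 0.1) {
  kt <- seq(0, 8 * peak_s, by = 1 / fs)
  kern <- gamma_hrf(kt, peak_s, undershoot_ratio)
  box <- rep(1, round(task_s * fs))
  r <- stats::convolve(c(box, numeric(length(kern))), rev(kern),
                       type = "open")[seq_len(length(box) + length(kern) - 1)]
  r / max(r)
}

#' Simulate an HbO/HbR concentration series for one subject
#'
#' Ground-truth hemodynamics: per condition, the evoked response is the
#' profile amplitude times a unit-peak block response placed at every
#' scheduled onset, plus sinusoidal cardiac/respiratory/Mayer components with
#' random phases, random-walk drift, white noise, and Poisson-timed spike and
#' step motion artifacts (injected with equal amplitude into both
#' chromophores, as scalp motion moves both). All randomness is drawn from
#' the ambient RNG stream; seed it for reproducibility.
#'
#' @param schedule An `event_schedule`.
#' @param profiles Profile rows covering every scheduled condition (for one
#'   group).
#' @param noise A [noise_spec()].
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param subject_id,group Metadata.
#' @param n_channels Number of channels (default 5).
#' @return A list with `hb` (an `hb_timeseries`, micromolar) and `truth`
#'   (list with the injected `amplitudes` tibble and `artifacts` tibble).
#' @export
simulate_hb <- function(schedule, profiles, noise = noise_spec(),
                        duration_s = paradigm_duration_s(), fs = 10,
                        subject_id = "sim", group = "HC", n_channels = 5) {
  conds <- unique(schedule$condition)
  if (!all(conds %in% profiles$condition)) {
    stop("profiles must cover all scheduled conditions")
  }
  for (comp in c("cardiac", "respiratory", "mayer")) {
    if (noise[[comp]]$amp > 0 && noise[[comp]]$freq_hz >= fs / 2) {
      stop(comp, " frequency violates the Nyquist limit (", fs / 2, " Hz)")
    }
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  channels <- paste0("CH", seq_len(n_channels))

  # evoked component, shared across channels, per chromophore
  evoked <- list(hbo = numeric(n), hbr = numeric(n))
  amp_rows <- list()
  for (cond in conds) {
    prof <- profiles[profiles$condition == cond, ][1, ]
    shape <- block_response(schedule$duration_s[schedule$condition == cond][1],
                            fs, prof$hrf_peak_s, prof$hrf_undershoot_ratio)
    unit <- numeric(n)
    for (on in schedule$onset_s[schedule$condition == cond]) {
      i0 <- round(on * fs) + 1L
      idx <- i0:min(n, i0 + length(shape) - 1L)
      unit[idx] <- unit[idx] + shape[seq_along(idx)]
    }
    evoked$hbo <- evoked$hbo + prof$amp_hbo * unit
    evoked$hbr <- evoked$hbr + prof$amp_hbr * unit
    amp_rows[[cond]] <- tibble::tibble(
      condition = cond, amp_hbo = prof$amp_hbo, amp_hbr = prof$amp_hbr
    )
  }

  hbo <- matrix(0, n_channels, n, dimnames = list(channels, NULL))
  hbr <- hbo
  artifacts <- list()
  minutes <- duration_s / 60
  for (ci in seq_len(n_channels)) {
    # channel-specific artifacts, common to both chromophores
    art <- numeric(n)
    n_spike <- rpois(1, noise$artifact_spike_rate_per_min * minutes)
    n_step <- rpois(1, noise$artifact_step_rate_per_min * minutes)
    if (n_spike > 0) {
      at <- sort(runif(n_spike, 0, duration_s))
      for (a in at) {
        i0 <- min(n, round(a * fs) + 1L)
        idx <- i0:min(n, i0 + round(5 * 0.5 * fs))
        sign_a <- sample(c(-1, 1), 1)
        art[idx] <- art[idx] +
          sign_a * noise$artifact_amp * exp(-(t[idx] - t[i0]) / 0.5)
      }
      artifacts[[length(artifacts) + 1]] <- tibble::tibble(
        channel = channels[ci], type = "spike", time_s = at
      )
    }
    if (n_step > 0) {
      at <- sort(runif(n_step, 0, duration_s))
      for (a in at) {
        i0 <- min(n, round(a * fs) + 1L)
        art[i0:n] <- art[i0:n] + sample(c(-1, 1), 1) * noise$artifact_amp
      }
      artifacts[[length(artifacts) + 1]] <- tibble::tibble(
        channel = channels[ci], type = "step", time_s = at
      )
    }
    # phase-diffusion scale for quasi-periodic oscillators
    coh <- noise$oscillator_coherence_s %||% 30
    phase_sd <- if (is.finite(coh) && coh > 0) 1 / sqrt(fs * coh) else 0
    for (chrom in c("hbo", "hbr")) {
      osc <- numeric(n)
      for (comp in c("cardiac", "respiratory", "mayer")) {
        cs <- noise[[comp]]
        if (cs$amp > 0) {
          phase <- runif(1, 0, 2 * pi) +
            if (phase_sd > 0) cumsum(rnorm(n, 0, phase_sd)) else 0
          osc <- osc + cs$amp * sin(2 * pi * cs$freq_hz * t + phase)
        }
      }
      drift <- if (noise$drift > 0) cumsum(rnorm(n, 0, noise$drift)) else numeric(n)
      white <- if (noise$white > 0) rnorm(n, 0, noise$white) else numeric(n)
      series <- evoked[[chrom]] + osc + drift + white + art
      if (chrom == "hbo") hbo[ci, ] <- series else hbr[ci, ] <- series
    }
  }

  truth <- list(
    amplitudes = dplyr::bind_rows(amp_rows),
    artifacts = if (length(artifacts) > 0) dplyr::bind_rows(artifacts) else
      tibble::tibble(channel = character(), type = character(),
                     time_s = numeric())
  )
  hb <- new_hb_timeseries(subject_id, group, hbo, hbr, channels,
                          sampling_rate_hz = fs, units = "uM",
                          processing_log = list(list(step = "simulate_hb",
                                                     params = list())))
  list(hb = hb, truth = truth)
}

#' Forward modified Beer-Lambert model
#'
#' Maps concentration changes to raw intensities:
#' `dOD(lambda) = d * DPF(lambda) * (eHbO(lambda) * dHbO + eHbR(lambda) * dHbR)`
#' and `I = I0 * 10^(-dOD)`. The reference intensities used are attached to
#' the returned recording so an inversion can reuse them exactly.
#'
#' @param hb An `hb_timeseries` in micromolar.
#' @param extinction Extinction table, see [default_extinction()].
#' @param dpf Differential pathlength factors, one per wavelength.
#' @param d_cm Source-detector separation in cm.
#' @param i0 Reference intensity: scalar or `channel x wavelength` matrix.
#' @param montage Montage for the output recording.
#' @return An `optical_recording` with strictly positive intensities.
#' @export
forward_mbll <- function(hb, extinction = default_extinction(),
                         dpf = c(6, 6), d_cm = 3, i0 = 1,
                         montage = default_montage()) {
  E <- extinction_matrix(extinction)
  if (abs(det(E)) < 1e-12 * max(abs(E))^2) stop("extinction matrix is singular")
  n_ch <- nrow(hb$hbo)
  if (nrow(montage$channels) != n_ch) {
    keep <- montage$channels$channel %in% hb$channels
    if (sum(keep) != n_ch) stop("montage does not cover the series channels")
    montage$channels <- montage$channels[keep, ]
  }
  n <- ncol(hb$hbo)
  wl <- as.numeric(rownames(E))
  if (is.matrix(i0)) {
    i0m <- i0
  } else {
    i0m <- matrix(i0, n_ch, 2)
  }
  if (any(i0m <= 0)) stop("i0 must be strictly positive")
  intensity <- array(NA_real_, dim = c(n_ch, 2, n),
                     dimnames = list(hb$channels, wl, NULL))
  for (j in 1:2) {
    od <- d_cm * dpf[j] * (E[j, 1] * hb$hbo + E[j, 2] * hb$hbr)
    intensity[, j, ] <- i0m[, j] * 10^(-od)
  }
  new_optical_recording(hb$subject_id, hb$group, intensity, montage,
                        sampling_rate_hz = hb$sampling_rate_hz,
                        wavelengths_nm = wl, t0_s = hb$t0_s,
                        i0_reference = i0m)
}

#' Generate a seeded synthetic cohort
#'
#' One raw optical recording per subject, with subject-level seeds and
#' per-subject run order derived deterministically from the master seed, plus
#' a tidy ground-truth manifest. Identical specs (including seed) produce
#' bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (list of `optical_recording`),
#'   `schedules` (list of `event_schedule`), `truth` (per-subject ground
#'   truth) and `manifest` (tibble: subject, group, seed, run order, true
#'   amplitudes).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n_total <- sum(spec$n_per_group)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  subject_seeds <- if (n_total > 0) {
    sample.int(.Machine$integer.max - 1L, n_total)
  } else integer(0)
  duration <- paradigm_duration_s(spec$paradigm)

  recordings <- list(); schedules <- list(); truths <- list()
  manifest <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sid <- sprintf("%s%02d", groups[i], sum(groups[seq_len(i)] == groups[i]))
    set.seed(subject_seeds[i])
    sched <- build_paradigm(spec$paradigm, run_order = spec$paradigm$run_order)
    prof <- spec$profiles[spec$profiles$group == groups[i], ]
    sim <- simulate_hb(sched, prof, spec$noise, duration,
                       spec$sampling_rate_hz, subject_id = sid,
                       group = groups[i])
    rec <- forward_mbll(sim$hb, spec$mbll$extinction, spec$mbll$dpf,
                        spec$mbll$d_cm, spec$mbll$i0)
    recordings[[sid]] <- rec
    schedules[[sid]] <- sched
    truths[[sid]] <- sim$truth
    manifest[[i]] <- tibble::tibble(
      subject_id = sid, group = groups[i], seed = subject_seeds[i],
      first_condition = sched$condition[1],
      amp_hbo_SON = prof$amp_hbo[prof$condition == "SON"],
      amp_hbr_SON = prof$amp_hbr[prof$condition == "SON"],
      amp_hbo_MI = prof$amp_hbo[prof$condition == "MI"],
      amp_hbr_MI = prof$amp_hbr[prof$condition == "MI"],
      n_artifacts = nrow(sim$truth$artifacts)
    )
  }
  manifest <- if (n_total > 0) dplyr::bind_rows(manifest) else
    tibble::tibble(subject_id = character(), group = character(),
                   seed = integer(), first_condition = character(),
                   amp_hbo_SON = numeric(), amp_hbr_SON = numeric(),
                   amp_hbo_MI = numeric(), amp_hbr_MI = numeric(),
                   n_artifacts = integer())
  list(recordings = recordings, schedules = schedules, truth = truths,
       manifest = manifest)
}

#' Write a cohort manifest as TSV
#' @param cohort Result of [generate_cohort()].
#' @param path Output path.
#' @export
write_manifest <- function(cohort, path) {
  readr::write_tsv(cohort$manifest, path)
  invisible(path)
}
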