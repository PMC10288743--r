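test_that("optical-density conversion matches the log-ratio formula", {
  rec <- tiny_recording(n = 80)
  od <- intensity_to_od(rec)
  # direct oracle: -log10(I / geometric mean)
  for (ci in c(1, 4)) {
    for (wl in 1:2) {
      x <- rec$intensity[ci, wl, ]
      i0 <- exp(mean(log(x)))
      expect_equal(od$od[ci, wl, ], -log10(x / i0), tolerance = 1e-12)
      # mean over the defining window is exactly zero
      expect_lt(abs(mean(od$od[ci, wl, ])), 1e-12)
    }
  }
  # constant intensity gives zero OD (up to log/exp round-off)
  recc <- tiny_recording()
  recc$intensity[] <- 3
  expect_lt(max(abs(intensity_to_od(recc)$od)), 1e-12)
  # I = I0 / 10 at one sample gives dOD = 1 there
  rec1 <- tiny_recording()
  rec1$intensity[] <- 1
  rec1$intensity[1, 1, 10] <- 1 / 10
  od1 <- intensity_to_od(rec1, i0_definition = matrix(1, 5, 2))
  expect_equal(od1$od[1, 1, 10], 1, tolerance = 1e-12)
})

test_that("first-60s reference window centres the baseline only", {
  rec <- tiny_recording(n = 900)  # 90 s at 10 Hz
  od <- intensity_to_od(rec, "first-60s")
  for (wl in 1:2) {
    expect_lt(abs(mean(od$od[2, wl, 1:600])), 1e-12)
  }
})

test_that("MBLL inversion equals the explicit 2x2 inverse and round-trips", {
  cfg <- preprocess_config()
  set.seed(2)
  hb <- noise_hb(n = 300, n_ch = 5)
  rec <- forward_mbll(hb)
  back <- od_to_hb(intensity_to_od(rec, "reference"), cfg)
  scale <- max(abs(hb$hbo))
  expect_lt(max(abs(back$hbo - hb$hbo)) / scale, 1e-9)
  expect_lt(max(abs(back$hbr - hb$hbr)) / scale, 1e-9)
  # Cramer's-rule oracle on random OD pairs
  E <- as.matrix(default_extinction()[c("e_hbo", "e_hbr")])
  A <- cfg$d_cm * diag(cfg$dpf) %*% E
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  od <- intensity_to_od(rec, "reference")
  manual_hbo <- (od$od[3, 1, ] * A[2, 2] - A[1, 2] * od$od[3, 2, ]) / det_a
  manual_hbr <- (A[1, 1] * od$od[3, 2, ] - od$od[3, 1, ] * A[2, 1]) / det_a
  expect_equal(back$hbo[3, ], manual_hbo, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$hbr[3, ], manual_hbr, tolerance = 1e-12, ignore_attr = TRUE)
  # zero OD gives zero concentrations
  zero <- od
  zero$od[] <- 0
  z <- od_to_hb(zero, cfg)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
})

test_that("degenerate extinction tables are rejected with a condition report", {
  bad <- default_extinction()
  bad$e_hbr <- bad$e_hbo
  expect_error(preprocess_config(extinction = bad), "singular")
})

test_that("band-pass meets its stopband and passband contract", {
  # 1.1 Hz (cardiac) tone on a 600 s series: >= 40 dB attenuation
  out <- bandpass(tone_hb(1.1))
  expect_lt(sqrt(mean(out$hbo^2)) / sqrt(0.5), 0.01)
  # 0.05 Hz tone: within 1 dB of unity
  out <- bandpass(tone_hb(0.05))
  ratio <- sqrt(mean(out$hbo^2)) / sqrt(mean(tone_hb(0.05)$hbo^2))
  expect_gt(ratio, 10^(-1 / 20))
  expect_lt(ratio, 10^(1 / 20))
  # zero series stays zero; short series errors
  zz <- tone_hb(0.05)
  zz$hbo[] <- 0
  zz$hbr[] <- 0
  expect_true(all(bandpass(zz)$hbo == 0))
  short <- new_hb_timeseries("s", "HC", matrix(1:5, 1), matrix(1:5, 1), "CH1")
  expect_error(bandpass(short), "too short")
  # long-series output is centred (high-pass removes the mean)
  set.seed(3)
  nh <- noise_hb(n = 6000, n_ch = 1)
  expect_lt(abs(mean(bandpass(nh)$hbo)), 0.01)
})

test_that("CBSI makes HbO and HbR exactly anti-correlated and fixes its own output", {
  set.seed(8)
  hb <- noise_hb(n = 1500, n_ch = 3)
  out <- cbsi_correct(hb)
  for (ci in 1:3) {
    expect_equal(cor(out$hbo[ci, ], out$hbr[ci, ]), -1, tolerance = 1e-10)
  }
  # fixed point: input already satisfying hbr = -hbo / alpha is unchanged
  twice <- cbsi_correct(out)
  expect_equal(twice$hbo, out$hbo, tolerance = 1e-12)
  expect_equal(twice$hbr, out$hbr, tolerance = 1e-12)
  # zero-variance HbR is an error
  flat <- hb
  flat$hbr[2, ] <- 1
  expect_error(cbsi_correct(flat), "zero-variance")
})

test_that("CBSI attenuates a motion step injected into both chromophores", {
  set.seed(9)
  n <- 2000
  base_o <- rnorm(n)
  base_r <- rnorm(n)
  alpha0 <- sd(base_o) / sd(base_r)
  step <- c(rep(0, n / 2), rep(8, n / 2))
  hb <- new_hb_timeseries("a", "HC",
                          matrix(base_o + step, 1),
                          matrix(base_r + step / alpha0, 1), "CH1")
  out <- cbsi_correct(hb)
  jump_in <- abs(mean(hb$hbo[1, (n / 2 + 1):n]) - mean(hb$hbo[1, 1:(n / 2)]))
  jump_out <- abs(mean(out$hbo[1, (n / 2 + 1):n]) - mean(out$hbo[1, 1:(n / 2)]))
  expect_lt(jump_out, jump_in / 2)
})

test_that("z-scoring centres and scales each channel and is affine-invariant", {
  set.seed(10)
  hb <- noise_hb(n = 800, n_ch = 2)
  z <- zscore_hb(hb)
  expect_equal(z$units, "z")
  for (ci in 1:2) {
    expect_lt(abs(mean(z$hbo[ci, ])), 1e-10)
    expect_lt(abs(sd(z$hbo[ci, ]) - 1), 1e-10)
  }
  # a > 0 affine transform leaves the z-scores unchanged
  ab <- hb
  ab$hbo <- 3.2 * ab$hbo + 5
  ab$hbr <- 0.7 * ab$hbr - 2
  z2 <- zscore_hb(ab)
  expect_equal(z2$hbo, z$hbo, tolerance = 1e-10)
  expect_equal(z2$hbr, z$hbr, tolerance = 1e-10)
  # two channels with identical shapes at different scales z-score identically
  sh <- hb
  sh$hbo[2, ] <- 10 * sh$hbo[1, ]
  zs <- zscore_hb(sh)
  expect_equal(zs$hbo[1, ], zs$hbo[2, ], tolerance = 1e-10)
  flat <- hb
  flat$hbo[1, ] <- 4
  expect_error(zscore_hb(flat), "zero variance")
})

test_that("artifact scoring applies the declared amplitude and jump rules", {
  cfg <- preprocess_config()
  z <- artifact_score(rep(0, 100), cfg)
  expect_false(z$reject)
  expect_equal(z$score, 0)
  # a 10-z spike against the default 5-z threshold: rejected with score 2
  spiky <- c(rep(0, 50), 10, rep(0, 49))
  s <- artifact_score(spiky, cfg)
  expect_true(s$reject)
  expect_equal(s$max_abs / cfg$rejection$max_abs_z, 2)
  expect_gte(s$score, 2)
  # a slow large ramp trips only the amplitude rule
  ramp <- seq(0, 6, length.out = 500)
  r <- artifact_score(ramp, cfg)
  expect_true(r$reject)
  expect_lt(r$max_jump, cfg$rejection$max_jump_z)
})

test_that("the preprocessing chain is linear before z-scoring", {
  cfg <- preprocess_config()
  set.seed(12)
  hb <- noise_hb(n = 1200, n_ch = 2)
  chain <- function(h) cbsi_correct(bandpass(od_to_hb(
    intensity_to_od(forward_mbll(h), "reference"), cfg), cfg))
  a <- 2.7
  scaled <- hb
  scaled$hbo <- a * scaled$hbo
  scaled$hbr <- a * scaled$hbr
  y1 <- chain(scaled)
  y0 <- chain(hb)
  expect_equal(y1$hbo, a * y0$hbo, tolerance = 1e-5)
  expect_equal(y1$hbr, a * y0$hbr, tolerance = 1e-5)
})

test_that("the processing log proves the pipeline order", {
  set.seed(13)
  sched <- build_paradigm(run_order = "fixed")
  prof <- default_profiles()[default_profiles()$group == "MCS", ]
  sim <- simulate_hb(sched, prof, noise_spec(), n_channels = 2)
  hb <- preprocess_recording(forward_mbll(sim$hb))
  expect_equal(
    processing_steps(hb),
    c("intensity_to_od", "od_to_hb", "bandpass", "cbsi", "zscore")
  )
  # CBSI can be switched off and then drops out of the log
  hb2 <- preprocess_recording(forward_mbll(sim$hb),
                              preprocess_config(cbsi_enabled = FALSE))
  expect_false("cbsi" %in% processing_steps(hb2))
})

test_that("epochs containing uncorrected steps are rejected, clean ones kept", {
  # Artifact amplitude far above noise, CBSI off so steps stay uncorrected.
  # The step rate keeps steps rare (about one per recording): the z-scoring
  # that precedes rejection uses the recording's own standard deviation, so
  # many simultaneous large steps would mask each other.
  ns <- noise_spec()
  ns$artifact_amp <- 20
  ns$artifact_spike_rate_per_min <- 0
  ns$artifact_step_rate_per_min <- 0.05
  cfg <- preprocess_config(cbsi_enabled = FALSE)
  sched <- build_paradigm(run_order = "fixed")
  prof <- null_profiles()[null_profiles()$group == "HC", ]
  hit <- miss <- false_rej <- clean <- 0
  for (s in 1:25) {
    set.seed(300 + s)
    sim <- simulate_hb(sched, prof, ns, n_channels = 3)
    hb <- preprocess_recording(forward_mbll(sim$hb), cfg)
    sets <- lapply(segment_epochs(hb, sched), apply_rejection, config = cfg)
    steps <- sim$truth$artifacts[sim$truth$artifacts$type == "step", ]
    for (es in sets) {
      for (ci in seq_len(dim(es$hbo)[3])) {
        ch <- dimnames(es$hbo)[[3]][ci]
        st <- steps$time_s[steps$channel == ch]
        for (e in seq_along(es$onsets_s)) {
          lo <- es$onsets_s[e] - 5
          hi <- es$onsets_s[e] + 45
          has_step <- any(st >= lo & st < hi)
          rejected <- !es$retained[e, ci, "HbO"]
          if (has_step && rejected) hit <- hit + 1
          if (has_step && !rejected) miss <- miss + 1
          if (!has_step && rejected) false_rej <- false_rej + 1
          if (!has_step && !rejected) clean <- clean + 1
        }
      }
    }
  }
  expect_gte(hit / (hit + miss), 0.9)
  expect_lte(false_rej / (false_rej + clean), 0.1)
})
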