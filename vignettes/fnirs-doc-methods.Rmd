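---
title: "Methods: simulating and analysing block-design prefrontal fNIRS in disorders of consciousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing block-design prefrontal fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsdoc)
```

## The problem and the model

Patients with prolonged disorders of consciousness cannot report awareness,
but their cortex may still respond to sound. The design analysed here plays
two auditory stimuli — the subject's own name (SON, passive) and a motor
imagery instruction (MI, active) — in a block paradigm, while dual-wavelength
near-infrared light (760/830 nm, 10 Hz) monitors oxy- and deoxyhemoglobin
concentration changes over the left prefrontal cortex through five
source-detector channels at 3 cm separation. The analysis asks whether the
evoked response distinguishes healthy controls (HC) from minimally conscious
(MCS) and vegetative state (VS) patients: controls show *negative*
("inverted") activation — HbO and HbR both fall during the task — while
patients show positive activation that grows as the level of consciousness
falls.

`fnirsdoc` implements that analysis end to end, together with a synthetic
cohort generator that encodes the group phenomenology as ground truth, so
the pipeline can be validated without clinical recordings.

## The paradigm and its arithmetic

Each condition is one run: 60 s baseline, then 8 blocks of 30 s task + 40 s
recovery, i.e. 60 + 8×70 = 620 s per run; the two runs are separated by
60 s, and their order is randomized per subject. At 10 Hz a whole recording
is 13 000 samples. Epochs span −5..45 s around each onset (500 samples);
half-open windows `[start, end)` on the sample grid are used everywhere, with
onsets snapped to the nearest sample, so every windowed quantity is exactly
reproducible. The spacing of the blocks means the response tail of one block
(gamma kernel plus undershoot, ≈60 s total support) bleeds marginally
(≈1–2 % of the peak) into the next epoch's baseline window; this is a real
property of the paradigm, not an artifact of the implementation, and the
tests account for it.

## The generator

Evoked responses are `amplitude × (task boxcar ⊛ unit-peak gamma kernel)`,
the per-block regressor renormalized to unit peak so a profile amplitude in
µM *is* the evoked peak. The kernel `(t/p)^4 exp(4(1 − t/p))` peaks at
`p = 6` s; an optional undershoot (default ratio 0.1) is the same shape
delayed threefold, which keeps the argmax within one sample of `p`.

Default profile amplitudes (µM, HbO/HbR): HC −0.5/−0.15 (SON) and
−0.2/−0.06 (MI); MCS +0.3/+0.09 and +0.1/+0.03; VS +0.6/+0.18 and
+0.2/+0.06. These are free parameters — the study they emulate reports no
physical amplitudes — chosen once so that the single-epoch signal-to-noise
ratio is near one and the orderings `VS > MCS > 0 > HC` (SON, both
chromophores) hold; all claims the package tests are therefore sign and
ordering claims, not absolute concentrations. HbR amplitudes are
independent of HbO (same sign, roughly 30 % of the magnitude) because
same-sign HbO/HbR group responses are part of the phenomenon.

Noise defaults (µM): quasi-periodic oscillations at 1.1 Hz (cardiac, 0.2),
0.25 Hz (respiratory, 0.1) and 0.1 Hz (Mayer, 0.05); random-walk drift with
0.005 per-sample increments; white noise 0.3; Poisson motion artifacts —
one-sample spikes with 0.5 s exponential decay (0.5/min) and persistent
steps (0.2/min), both at 5 µM, injected into both chromophores of a channel
as scalp motion would be. The oscillators carry phase diffusion with a 30 s
coherence time: physiological rhythms are quasi-periodic, and a
deterministic sinusoid at 0.1 Hz would complete exactly 7 cycles per 70 s
block — phase-locked to the paradigm — which would act as a spurious
per-recording offset common to every epoch. Channels receive independent
noise; real recordings share systemic physiology across channels, which is
one of the ways the generator is simpler than reality.

What passing tests on this generator do **not** show: performance under
correlated cross-channel physiology, non-Gaussian drift, partial optode
coupling loss, or any real anatomical variability. The generator's purpose
is to make the pipeline's *logic* falsifiable, not to claim realism beyond
the listed structure.

## Preprocessing choices

* **Reference intensity.** ΔOD = −log₁₀(I/I₀) with I₀ the *geometric* mean
  over the defining window (whole series by default, first 60 s
  selectable). The geometric mean is the unique choice that makes the mean
  of ΔOD over the window exactly zero (the arithmetic mean leaves a
  Jensen-gap offset). A forward-simulated recording carries its true
  reference, so round-trip tests use `"reference"` and recover
  concentrations to machine precision; with the centred definitions,
  recovery holds up to a constant per-channel offset, which the high-pass
  filter and baseline correction remove anyway.
* **Extinction coefficients and DPF.** Shipped as an editable table
  (760/830 nm values from a standard compilation, cm⁻¹µM⁻¹); differential
  pathlength factor 6.0 at both wavelengths; separation 3 cm. No result in
  the package depends on the specific values, only on forward/inverse
  consistency of the 2×2 system, whose condition is checked.
* **Band-pass.** 3rd-order Butterworth, 0.01–0.2 Hz, applied
  forward-backward (zero phase, squared magnitude). Edge handling matters
  at a 0.01 Hz corner: filtering a finite series excites slow transients at
  its ends that can dwarf the stopband floor. Each series is therefore
  extended at both ends by AR (Burg, order 50, fitted to the 300 s nearest
  the edge) linear prediction for 300 s before filtering, and the
  extensions are discarded afterwards. A sinusoid is continued exactly, so
  the measured stopband attenuation at 1.1 Hz exceeds 90 dB and the
  passband at 0.05 Hz is flat to ≪1 dB.
* **CBSI.** With α = σ(hbo)/σ(hbr): hbo′ = (hbo − α·hbr)/2 and
  hbr′ = −hbo′/α, per channel over the full recording. The corrected pair
  is exactly anti-correlated by construction. That is deliberately in
  tension with the same-sign group curves the analysis reports: strict CBSI
  output cannot show same-sign HbO/HbR. The switch `cbsi_enabled = FALSE`
  exists so users can reproduce either reading; with CBSI on, every HbR
  result is the scaled mirror of HbO, and the package reports it as such
  rather than pretending independence.
* **Trial rejection.** An epoch is rejected when its z-amplitude exceeds 5
  or its per-sample z-jump exceeds 3 — declared, configurable stand-ins for
  a qualitative "serious artifacts" rule. Because z-scoring uses the
  recording's own standard deviation, many simultaneous large artifacts
  partially mask each other (the scale inflates); the rejection contract is
  therefore tested at about one large step per recording. With CBSI on,
  common-mode steps are largely corrected before rejection ever sees them.
* **Order.** OD → MBLL → band-pass → CBSI → z-score, with epoch-level
  rejection at segmentation time; the `processing_log` of every series
  records the applied steps in order, and a test asserts the order.

## Features and observation units

The mean concentration is the arithmetic mean over 2–20 s after onset; the
fitting slope is the OLS slope over 5–15 s (units per second). Both are
linear and shift-equivariant, which the property tests exercise. Features
can be computed per retained trial (per-epoch mode, the default) or on the
block average. The distinction matters statistically:

* **Per-epoch mode** pools trials × channels as observations. Successive
  epoch features are weakly correlated through slow in-band noise —
  band-passed drift and Mayer activity — and with 8-trial clusters even a
  small correlation overdisperses a rank statistic that assumes
  exchangeability, pushing its null rejection rate above the nominal level
  (the acceptance script reports the measured rate in both modes).
  The package keeps this mode because pooled observations are the only way
  to obtain the very large |Z| magnitudes this style of analysis reports,
  but every result row carries its mode label.
* **Block-average mode** has one observation per subject × channel;
  averaging 8 epochs 70 s apart suppresses the slow-noise correlation and
  the observations are exchangeable under the null. The package's null
  calibration check runs in this mode, and the acceptance script reports
  the per-epoch null rate alongside so the overdispersion is visible
  rather than hidden. A mixed model over the subject/channel/trial nesting
  would be the fully principled treatment; it is out of scope here.

## Statistics

Mann–Whitney U uses midranks, the tie-corrected normal σ_U, no continuity
correction, and a signed Z (negative when the first sample ranks lower);
an exact enumeration (`mwu_exact_p`) backs it for small samples.
Kruskal–Wallis applies the standard tie correction, with the convention
H = 0, p = 1 when all pooled values are identical. Both match their base-R
counterparts, which the tests use as independent cross-checks, and KW on
two groups equals Z² exactly. The KS normality screen fits the sample's own
mean and sd and uses the asymptotic p — conservative, which is acceptable
for a screen whose role is to justify rank tests. No multiple-testing
correction is applied by default, mirroring the analysis style the package
reproduces; `p.adjust` can be applied to the results table by the user.

## Numerical conventions and degenerate inputs

Half-open windows with a 10⁻⁹ s grid tolerance; onset snapping to the
nearest sample; baseline mean over the 30 samples in [−3, 0) s (so a ramp
epoch `value = t` corrects to `t + 1.55`, the exact grid mean, not the
continuous-time 1.5); zero-variance channels are errors for CBSI and
z-scoring rather than NaN propagation; constant series pass the band-pass
as exact zeros; epochs extending past the recording are flagged invalid and
never truncated; rejected trials are carried as missing rows, never silent
zeros. Cohort generation derives per-subject seeds from the master seed, so
identical specifications are bit-identical.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to make their statistical
assertions decisive at desk scale: the null-calibration check uses 80
seeded 4-subject cohorts (1 280 Mann–Whitney contrasts on block-averaged
features); the phenomenology check uses 20 seeded cohorts at the study's
group sizes (15/4/14); the step-rejection contract uses 25 seeded
3-channel recordings at about one large step each. The acceptance script
uses 60 null cohorts and 8 full cohorts per run.

## Known limitations

* CBSI's anti-correlation constraint makes HbR results redundant with HbO;
  interpret HbR rows accordingly (or disable CBSI).
* The z-score-then-threshold rejection rule self-masks when artifacts
  dominate the recording's variance.
* Per-epoch pooling overdisperses rank tests under temporally correlated
  noise (see above); its headline p-values should be read as descriptive.
* The generator omits cross-channel physiological correlation and models
  all amplitudes in arbitrary-unit optical space via a fixed extinction
  table; absolute µM values are not meaningful claims.
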