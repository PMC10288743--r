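#!/usr/bin/env Rscript
# Simulate the study cohort: 15 healthy controls, 4 minimally conscious and
# 14 vegetative-state patients, each measured with the 5-channel prefrontal
# montage under the two-run block paradigm (8 x 30 s blocks per condition).
# Writes the ground-truth manifest and one raw-intensity TSV per subject.

suppressMessages(library(fnirsdoc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
outdir <- file.path("results", "cohort")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(seed = seed)
cohort <- generate_cohort(spec)
write_manifest(cohort, file.path(outdir, "manifest.tsv"))
for (sid in names(cohort$recordings)) {
  write_recording(cohort$recordings[[sid]],
                  file.path(outdir, paste0(sid, "_raw.tsv")))
  write_events(cohort$schedules[[sid]],
               file.path(outdir, paste0(sid, "_events.tsv")))
}
cat("Simulated", length(cohort$recordings), "subjects (seed", seed, ")\n")
cat("Manifest:", file.path(outdir, "manifest.tsv"), "\n")
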