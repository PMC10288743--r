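#!/usr/bin/env Rscript
# Segment the cleaned series into stimulus-locked epochs (-5..45 s), apply
# trial rejection and baseline correction, and extract the two features:
# mean concentration over 2-20 s and fitting slope over 5-15 s, in both
# per-epoch and block-average modes.

suppressMessages(library(fnirsdoc))

cohort_dir <- file.path("results", "cohort")
clean_dir <- file.path("results", "cleaned")
outdir <- "results"
manifest <- readr::read_tsv(file.path(cohort_dir, "manifest.tsv"),
                            show_col_types = FALSE)

read_clean <- function(sid, group) {
  tbl <- readr::read_tsv(file.path(clean_dir, paste0(sid, "_clean.tsv")),
                         show_col_types = FALSE)
  chs <- unique(sub("_Hb[OR]$", "", names(tbl)[-1]))
  hbo <- t(as.matrix(tbl[paste0(chs, "_HbO")]))
  hbr <- t(as.matrix(tbl[paste0(chs, "_HbR")]))
  new_hb_timeseries(sid, group, hbo, hbr, chs, units = "z")
}

hbs <- list(); schedules <- list()
for (i in seq_len(nrow(manifest))) {
  sid <- manifest$subject_id[i]
  hbs[[sid]] <- read_clean(sid, manifest$group[i])
  schedules[[sid]] <- read_events(file.path(cohort_dir,
                                            paste0(sid, "_events.tsv")))
}

for (mode in c("per-epoch", "block-avg")) {
  ft <- build_feature_table(hbs, schedules, mode = mode)
  path <- file.path(outdir, paste0("features_", gsub("-", "_", mode), ".tsv"))
  write_features(ft, path)
  cat(mode, "features:", nrow(ft), "rows,",
      sum(!ft$retained), "rejected ->", path, "\n")
}
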