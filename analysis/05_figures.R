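#!/usr/bin/env Rscript
# Group-averaged hemodynamic response curves: per group and condition, the
# across-subject mean +/- SEM of the channel-averaged block-average response
# over the -3..40 s analysis window.

suppressMessages(library(fnirsdoc))

cohort_dir <- file.path("results", "cohort")
clean_dir <- file.path("results", "cleaned")
manifest <- readr::read_tsv(file.path(cohort_dir, "manifest.tsv"),
                            show_col_types = FALSE)

read_clean <- function(sid, group) {
  tbl <- readr::read_tsv(file.path(clean_dir, paste0(sid, "_clean.tsv")),
                         show_col_types = FALSE)
  chs <- unique(sub("_Hb[OR]$", "", names(tbl)[-1]))
  new_hb_timeseries(sid, group,
                    t(as.matrix(tbl[paste0(chs, "_HbO")])),
                    t(as.matrix(tbl[paste0(chs, "_HbR")])), chs, units = "z")
}

hbs <- list(); schedules <- list()
for (i in seq_len(nrow(manifest))) {
  sid <- manifest$subject_id[i]
  hbs[[sid]] <- read_clean(sid, manifest$group[i])
  schedules[[sid]] <- read_events(file.path(cohort_dir,
                                            paste0(sid, "_events.tsv")))
}

curves <- group_curves(hbs, schedules)
readr::write_tsv(curves, "results/group_curves.tsv")
p <- plot_group_curves(curves)
ggplot2::ggsave("results/group_curves.png", p, width = 7, height = 8, dpi = 150)
cat("Wrote results/group_curves.tsv and results/group_curves.png\n")
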