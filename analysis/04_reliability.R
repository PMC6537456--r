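#!/usr/bin/env Rscript
# Step 4 -- intra-clip reliability of the resting shear modulus.
#
# For each protocol time point, builds the subjects x frames matrix of
# ROI-mean moduli (five frames per 5-s clip) and computes the two-way
# consistency single-measure ICC and the SEM (typical error).

library(swefatigue)

cohort <- read_cohort("results/dataset")
tps <- cohort$config$timepoints
rows <- lapply(seq_along(tps), function(ti) {
  m <- t(vapply(cohort$sessions, function(ss)
    roi_frame_modulus(ss[[ti]]$clip), numeric(cohort$config$n_frames)))
  r <- icc_sem(m)
  data.frame(timepoint = tps[ti], icc_pct = 100 * r$icc, sem_kpa = r$sem,
             n_subjects = r$n_subjects, n_frames = r$n_measures)
})
rel <- do.call(rbind, rows)
data.table::fwrite(rel, "results/reliability.tsv", sep = "\t")

cat("intra-clip reliability per time point:\n")
print(rel, row.names = FALSE, digits = 4)
cat("-> results/reliability.tsv\n")
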