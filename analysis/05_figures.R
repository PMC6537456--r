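#!/usr/bin/env Rscript
# Step 5 (optional) -- time-course figures.
#
# Relative-change time courses (mean +/- SEM over subjects) for the
# voluntary, evoked and elastographic quantities.  Figures are run-time
# artifacts; every number they show is in the step-3 tables.

library(swefatigue)
library(ggplot2)

analysis <- analyze_cohort("results/dataset")
tps <- analysis$timepoints
n <- length(unique(analysis$metrics$subject))

plot_q <- list(mvc = "MVC torque", mu = "Resting VL shear modulus",
               db_pot = "Potentiated doublet", tw_p = "Potentiated twitch",
               emd = "EMD", ct = "CT", mrtd = "MRTD")
ch <- analysis$changes[analysis$changes$quantity %in% names(plot_q), ]
ch$label <- unlist(plot_q[ch$quantity])
ch$timepoint <- factor(ch$timepoint, levels = tps)
ch$sem <- ch$change_sd_pct / sqrt(n)

p <- ggplot(ch, aes(timepoint, change_mean_pct, group = label)) +
  geom_hline(yintercept = 0, linetype = 3) +
  geom_errorbar(aes(ymin = change_mean_pct - sem,
                    ymax = change_mean_pct + sem), width = 0.2) +
  geom_line() + geom_point() +
  facet_wrap(~label, scales = "free_y") +
  labs(x = NULL, y = "Change from control (%)",
       title = "Fatigue time courses (mean ± SEM)") +
  theme_bw()
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
ggsave("results/figures/time_courses.png", p, width = 10, height = 7,
       dpi = 150)
cat("figure -> results/figures/time_courses.png\n")
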