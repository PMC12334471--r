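#!/usr/bin/env Rscript
# Stage 1: generate the synthetic regional DELT dataset.
#
# Emulates the structure of a multi-agency Chesapeake-style survey at a
# desk-friendly scale: 57 species, 7 agencies, 9 ecoregions, 1,196 streams,
# 46 landscape predictors, marginal DELT prevalence calibrated to 1.4%.
# Writes the observation and predictor tables (and the ground truth, kept
# separate from everything the fitting stages read).

library(deltscape)

seed <- 20260101L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- study_mimic_config(seed = seed)
sim <- simulate_delt_dataset(cfg)

write_fish_observations(sim$observations,
                        file.path(out_dir, "observations_synthetic.csv"))
write.csv(sim$predictors, file.path(out_dir, "predictors_synthetic.csv"),
          row.names = FALSE)
truth <- data.frame(parameter = c("beta0",
                                  paste0("beta[", names(sim$truth$beta), "]"),
                                  paste0("eta[", names(sim$truth$eta), "]")),
                    value = c(sim$truth$beta0, sim$truth$beta,
                              sim$truth$eta))
write.csv(truth, file.path(out_dir, "ground_truth_synthetic.csv"),
          row.names = FALSE)

cat("simulated", nrow(sim$observations), "fish across",
    length(unique(sim$observations$stream_id)), "streams\n")
cat("species:", length(unique(sim$observations$species)),
    " agencies:", length(unique(sim$observations$agency)),
    " ecoregions:", length(unique(sim$observations$ecoregion)), "\n")
cat(sprintf("marginal DELT prevalence: %.4f (target 0.014)\n",
            mean(sim$observations$delt)))
cat("wrote", out_dir, "\n")
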