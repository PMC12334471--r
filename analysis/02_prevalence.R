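#!/usr/bin/env Rscript
# Stage 2: naive prevalence summaries and focal-species selection.
#
# Computes observed (non-model) DELT prevalence overall, per species and
# per stream, and applies the focal-species rule (prevalence >= 5% and
# n > 100) that gates the species-specific landscape models.

library(deltscape)

obs <- read_fish_observations("results/data/observations_synthetic.csv")$observations
obs <- filter_observation_window(obs, 2008, 2019)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

overall <- compute_naive_prevalence(obs, "overall")
by_species <- compute_naive_prevalence(obs, "species")
by_stream <- compute_naive_prevalence(obs, "stream")

write.csv(by_species, "results/tables/prevalence_by_species.csv",
          row.names = FALSE)
write.csv(by_stream, "results/tables/prevalence_by_stream.csv",
          row.names = FALSE)

focal <- select_focal_species(by_species)
writeLines(focal, "results/tables/focal_species.txt")

cat(sprintf("overall observed DELT prevalence: %.2f%% (%d of %d fish)\n",
            100 * overall$prevalence, overall$n_delt, overall$n_inspected))
cat(sprintf("species prevalence range: %.1f%% to %.1f%%\n",
            100 * min(by_species$prevalence),
            100 * max(by_species$prevalence)))
cat(sprintf("streams with any DELT: %.0f%%\n",
            100 * mean(by_stream$n_delt > 0)))
cat("focal species (>=5% prevalence, n > 100):",
    if (length(focal)) paste(focal, collapse = ", ") else "none", "\n")
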