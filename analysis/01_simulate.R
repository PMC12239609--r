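#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Simulates the two trial networks used throughout the analysis: a
# methods-evaluation MET ("d4-like": 14 genotypes, half of them
# photoperiod-insensitive controls, in 37 environments spanning short- and
# long-day conditions) and a diversity-panel MET ("d5-like": 236 genotypes
# in 19 environments whose sensed-daylength coverage has the characteristic
# gap between roughly 12.4 and 14.5 h). Writes the phenotype tables and the
# ground-truth parameter tables under results/.

suppressPackageStartupMessages(library(maizePRN))

dir.create("results", showWarnings = FALSE)
seed <- 42

for (preset in c("d4-like", "d5-like")) {
  cfg <- sim_preset(preset, seed = seed)
  envs <- simulate_network(cfg)
  panel <- simulate_panel(cfg)
  sim <- simulate_met(envs, panel, cfg)
  tag <- sub("-like", "", preset)

  env_tab <- do.call(rbind, lapply(envs, function(e) {
    data.frame(env_id = e$env_id, latitude = e$latitude,
               longitude = e$longitude, sowing_date = e$sowing_date)
  }))
  write.csv(env_tab, sprintf("results/%s_environments.csv", tag),
            row.names = FALSE)
  write.csv(panel, sprintf("results/%s_panel_truth.csv", tag),
            row.names = FALSE)
  write.csv(sim$met, sprintf("results/%s_phenotypes.csv", tag),
            row.names = FALSE)
  write.csv(sim$truth, sprintf("results/%s_observation_truth.csv", tag),
            row.names = FALSE)

  cat(sprintf(
    "%s: %d environments (lat %.1f-%.1f N), %d genotypes (%d insensitive),",
    preset, length(envs), min(env_tab$latitude), max(env_tab$latitude),
    nrow(panel), sum(panel$group == "insensitive")), "\n")
  cat(sprintf("  %d phenotype records, %d pairs dropped; days to anthesis %d-%d\n",
              nrow(sim$met),
              if (is.null(sim$dropped)) 0L else nrow(sim$dropped),
              min(sim$met$days_to_anthesis), max(sim$met$days_to_anthesis)))
}
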