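#!/usr/bin/env Rscript
# Generate the six synthetic input tables (with ground-truth sidecars) that
# the downstream stages consume: sediment-trap deployments, day/night tow
# pairs, fish respiration totals, subduction profiles, float fates and
# per-experiment ecosystem metrics.

suppressPackageStartupMessages(library(bcpbudget))
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = 1)

traps <- generate_trap_deployments(cfg)
tows <- generate_tow_pairs(cfg)
fates <- generate_float_fates(cfg)
subd <- generate_subduction_profiles(cfg)
metrics <- generate_ecosystem_metrics(cfg)

write_synthetic_table(traps, "results/inputs", "traps")
write_synthetic_table(tows, "results/inputs", "tows")
write_synthetic_table(fates, "results/inputs", "fates")
write_synthetic_table(subd, "results/inputs", "subduction")
write_table_csv(metrics, "results/inputs/metrics.csv")

set.seed(2)
fish <- data.frame(
  experiment_id = unique(tows$tows$experiment_id),
  total_respiration_mmolC_m2_d = pmax(0.05, rnorm(cfg$n_tow_pairs, 0.8, 0.3)))
write_table_csv(fish, "results/inputs/fish.csv")

message(sprintf(
  "wrote %d trap deployments (b_true = %.2f), %d tow pairs, %d float fates, %d subduction profiles",
  cfg$n_deployments, cfg$b_true, cfg$n_tow_pairs, nrow(fates$fates),
  cfg$n_subduction_profiles))
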