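#!/usr/bin/env Rscript
# Active transport by diel vertical migrators: euphausiid daytime
# net-avoidance adjustment, migrant residence distribution from night-day
# biomass differences, allometric respiration + 31% excretion at residence
# depth, the fish residence-density term, and the bootstrap regional mean.

suppressPackageStartupMessages(library(bcpbudget))
dir.create("results", showWarnings = FALSE)

tows <- adjust_euphausiid_day(read_tow_csv("results/inputs/tows.csv"))
fish <- read_fish_csv("results/inputs/fish.csv")
bio <- bioenergetics_params()

profiles <- lapply(unique(tows$experiment_id), function(e) {
  zoop <- zoop_transport_profile(
    residence_distribution(tows[tows$experiment_id == e, ], bio), bio, e)
  tot <- fish$total_respiration_mmolC_m2_d[fish$experiment_id == e]
  sum_transport_profiles(list(zoop, fish_transport_profile(tot, bio, e)))
})

regional <- regional_mean_bootstrap(profiles, n_boot = 2000, seed = 21)
write_table_csv(regional, "results/active_transport_regional.csv")
at100 <- regional[regional$horizon_m == 100, ]
message(sprintf(
  "summed active transport across 100 m: %.2f (95%% CI %.2f-%.2f) mmol C m-2 d-1 over %d experiments",
  at100$mean, at100$lower, at100$upper, length(profiles)))
print(regional, row.names = FALSE)
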