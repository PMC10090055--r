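# Small in-code fixtures shared across test files.

# A tow table for one experiment with arbitrary (taxon, size, stratum)
# biomass. `night` and `day` are named lists: taxon -> 9-vector of
# concentrations (mg C m-3) over the 0-450 m strata.
make_tow <- function(night, day, experiment_id = "E01",
                     size_bin = size_bin_table()$size_bin[6],
                     temperature = NULL) {
  strata <- data.frame(top = seq(0, 400, 50), bottom = seq(50, 450, 50))
  temp <- temperature %||% (15 - 9 * (strata$top + 25) / 450)
  rows <- list()
  for (tx in names(night)) {
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = experiment_id, taxon = tx, size_bin = size_bin,
      stratum_top_m = rep(strata$top, 2), stratum_bottom_m = rep(strata$bottom, 2),
      day_night = rep(c("night", "day"), each = 9),
      biomass_mgC_m3 = c(night[[tx]], day[[tx]]),
      temperature_C = rep(temp, 2))
  }
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Trap table with exact power-law fluxes and constant sigma.
make_exact_traps <- function(f100, b, depths = c(100, 200, 400), sigma = 1) {
  rows <- lapply(seq_along(f100), function(i) {
    data.frame(deployment_id = sprintf("D%02d", i), cruise = "C01",
               depth_m = depths,
               flux_mean_mmolC_m2_d = f100[i] * (depths / 100)^(-b),
               flux_sd_mmolC_m2_d = sigma, n_reps = 3, euphotic_depth_m = 75)
  })
  do.call(rbind, rows)
}

# Bioenergetics parameters giving a mass- and temperature-independent
# carbon-specific respiration rate `rate` (d-1) for every listed taxon.
constant_rate_params <- function(rate, taxa = c("copepods", "euphausiids",
                                                "chaetognaths", "others"),
                                 excretion_fraction = 0.31) {
  conv <- 0.87 * 12.011e-3 * 24 / 22.414   # specific rate per exp(a0) at a1 = 1
  bioenergetics_params(
    coefficients = data.frame(taxon = taxa, a0 = log(rate / conv), a1 = 1, a2 = 0),
    carbon_fraction_dw = 1, respiratory_quotient = 0.87,
    excretion_fraction = excretion_fraction)
}

# Float fate table from explicit vectors.
make_fates <- function(release, fate, elapsed, final = release,
                       cohort = "Y01") {
  data.frame(release_depth_m = release, fate = fate, elapsed_time_yr = elapsed,
             final_depth_m = final, cohort = cohort)
}
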