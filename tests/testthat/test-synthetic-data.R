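test_that("noiseless trap fluxes lie exactly on the generating power law", {
  cfg <- synth_config(seed = 7, n_deployments = 6, b_true = 0.72,
                      cv_triplicate = 0, trap_depths = c(100, 200, 500))
  out <- generate_trap_deployments(cfg)
  d <- merge(out$deployments, out$truth, by = "deployment_id")
  expected <- d$f100_true * (d$depth_m / 100)^(-0.72)
  expect_lt(max(abs(d$flux_mean_mmolC_m2_d / expected - 1)), 1e-12)
  expect_true(all(d$flux_sd_mmolC_m2_d == 0))
  # hand arithmetic: f100 = 9, z = 200, b = 0.72 -> 5.464 (5.5 at 2 s.f.)
  expect_equal(9 * (200 / 100)^(-0.72), 5.4641, tolerance = 1e-4)
})

test_that("trap generator applies replicate noise with the requested CV and rejects shallow traps", {
  cfg <- synth_config(seed = 11, n_deployments = 400, trap_depths = c(100, 300),
                      cv_triplicate = 0.2)
  out <- generate_trap_deployments(cfg)
  d <- merge(out$deployments, out$truth, by = "deployment_id")
  ratio <- d$flux_mean_mmolC_m2_d / (d$f100_true * (d$depth_m / 100)^(-0.9))
  # replicate means are unbiased with SD = cv/sqrt(3)
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(ratio), 0.2 / sqrt(3), tolerance = 0.15)
  expect_error(generate_trap_deployments(
    synth_config(trap_depths = c(40, 100))), "shallower than 50")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synth_config(seed = 5, n_deployments = 4, n_tow_pairs = 2,
                      n_floats_per_depth = 50)
  expect_identical(generate_trap_deployments(cfg), generate_trap_deployments(cfg))
  expect_identical(generate_tow_pairs(cfg), generate_tow_pairs(cfg))
  expect_identical(generate_float_fates(cfg), generate_float_fates(cfg))
  expect_identical(generate_subduction_profiles(cfg),
                   generate_subduction_profiles(cfg))
  expect_identical(generate_ecosystem_metrics(cfg), generate_ecosystem_metrics(cfg))
})

test_that("zero migrant fraction yields identical day and night tow tables", {
  cfg <- synth_config(seed = 3, n_tow_pairs = 2,
                      migrant_fraction_by_taxon = c(copepods = 0, euphausiids = 0,
                                                    chaetognaths = 0, others = 0),
                      euphausiid_day_avoidance = 1)
  tows <- generate_tow_pairs(cfg)$tows
  day <- tows[tows$day_night == "day", ]
  night <- tows[tows$day_night == "night", ]
  key <- c("experiment_id", "taxon", "size_bin", "stratum_top_m")
  day <- day[do.call(order, day[key]), ]
  night <- night[do.call(order, night[key]), ]
  expect_equal(day$biomass_mgC_m3, night$biomass_mgC_m3)
})

test_that("night-minus-day integrated difference above a horizon recovers the migrant ground truth", {
  cfg <- synth_config(seed = 9, n_tow_pairs = 3, euphausiid_day_avoidance = 1)
  out <- generate_tow_pairs(cfg)
  for (e in unique(out$tows$experiment_id)) {
    tow <- out$tows[out$tows$experiment_id == e, ]
    tru <- out$truth[out$truth$experiment_id == e, ]
    mb <- migrant_biomass_below(tow, 100)
    # all residence depths are >= 100 m, so the 100-m horizon sees the total
    expect_equal(mb$migrant_mgC_m2[order(mb$taxon, mb$size_bin)],
                 tru$migrant_mgC_m2[order(tru$taxon, tru$size_bin)],
                 tolerance = 1e-12)
    # above 450 m the difference counts only migrants residing below 450 m
    deep <- sum(tru$migrant_mgC_m2[tru$residence_top_m >= 450])
    expect_equal(sum(migrant_biomass_below(tow, 450)$migrant_mgC_m2), deep,
                 tolerance = 1e-9)
  }
})

test_that("deep residence parameters place all migrants below the tow's 450-m floor", {
  cfg <- synth_config(seed = 4, n_tow_pairs = 2,
                      residence_depth_params = list(copepods = c(500, 1),
                                                    euphausiids = c(500, 1),
                                                    chaetognaths = c(500, 1),
                                                    others = c(500, 1)),
                      euphausiid_day_avoidance = 1)
  out <- generate_tow_pairs(cfg)
  expect_true(all(out$truth$residence_top_m == 450))
  for (e in unique(out$tows$experiment_id)) {
    tow <- out$tows[out$tows$experiment_id == e, ]
    tru <- out$truth[out$truth$experiment_id == e, ]
    expect_equal(sum(migrant_biomass_below(tow, 450)$migrant_mgC_m2),
                 sum(tru$migrant_mgC_m2), tolerance = 1e-9)
  }
})

test_that("float fates follow the exponential entrainment hazard", {
  # hazard enormous: everything is entrained almost immediately
  cfg <- synth_config(seed = 6, release_depths = c(100, 200),
                      n_floats_per_depth = 4000, launch_cohorts = 2,
                      entrainment_hazard_scale = 50, hazard_depth_efolding = 1e9,
                      boundary_fraction = 0, horizon_years = 500)
  out <- generate_float_fates(cfg)
  expect_true(all(out$fates$fate == "mixed_layer"))
  expect_equal(mean(out$fates$elapsed_time_yr), 1 / 50, tolerance = 0.05)
  # hazard zero: everything survives to the horizon
  cfg0 <- synth_config(seed = 6, release_depths = c(100),
                       n_floats_per_depth = 100, launch_cohorts = 1,
                       entrainment_hazard_scale = 0, boundary_fraction = 0)
  out0 <- generate_float_fates(cfg0)
  expect_true(all(out0$fates$fate == "survived"))
  expect_true(all(out0$fates$elapsed_time_yr == 500))
  expect_error(generate_float_fates(synth_config(release_depths = c(100, 250))),
               "subset")
})

test_that("subduction profiles decay exponentially and stay non-negative", {
  cfg <- synth_config(seed = 8)
  out <- generate_subduction_profiles(cfg)
  expect_true(all(out$profiles$flux_mmolC_m2_d >= 0))
  fr <- vapply(unique(out$profiles$experiment_id), function(e) {
    p <- out$profiles[out$profiles$experiment_id == e, ]
    fraction_remineralized(p$depth_m, p$flux_mmolC_m2_d, 100, 200)
  }, numeric(1))
  expected <- 1 - exp(-100 / out$truth$efolding_m)
  expect_equal(unname(fr), expected, tolerance = 1e-6)
  # default e-folding of ~74 m loses about three quarters of the flux by 200 m
  expect_gt(mean(fr), 0.6)
  expect_lt(mean(fr), 0.85)
  zero <- generate_subduction_profiles(synth_config(subduction_amplitude = 0))
  expect_true(all(zero$profiles$flux_mmolC_m2_d == 0))
})
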