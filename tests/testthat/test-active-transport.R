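test_that("euphausiid daytime adjustment matches integrals and leaves other taxa untouched", {
  night <- list(euphausiids = c(2, 2, rep(0, 7)), copepods = rep(1, 9))
  day <- list(euphausiids = c(0.5, 0.5, rep(0, 7)), copepods = rep(1, 9))
  tow <- make_tow(night, day)
  adj <- adjust_euphausiid_day(tow)
  de <- adj$taxon == "euphausiids" & adj$day_night == "day"
  expect_equal(adj$biomass_mgC_m3[de], tow$biomass_mgC_m3[de] * 4)
  expect_identical(adj$biomass_mgC_m3[adj$taxon == "copepods"],
                   tow$biomass_mgC_m3[tow$taxon == "copepods"])
  # already balanced -> identity
  tow2 <- make_tow(list(euphausiids = rep(1, 9)), list(euphausiids = rep(1, 9)))
  expect_equal(adjust_euphausiid_day(tow2), tow2)
  tow3 <- make_tow(list(euphausiids = rep(1, 9)), list(euphausiids = rep(0, 9)))
  expect_error(adjust_euphausiid_day(tow3), "scaling undefined")
})

test_that("migrant biomass below a horizon is the floored night-minus-day integral above it", {
  # 100 mg night vs 40 mg day in the upper 100 m -> 60 mg migrates below
  night <- list(copepods = c(1.2, 0.8, rep(0.1, 7)))
  day <- list(copepods = c(0.5, 0.3, rep(0.1, 6), 1.2))
  tow <- make_tow(night, day)
  expect_equal(migrant_biomass_below(tow, 100)$migrant_mgC_m2, 60)
  same <- make_tow(list(copepods = rep(1, 9)), list(copepods = rep(1, 9)))
  expect_equal(migrant_biomass_below(same, 300)$migrant_mgC_m2, 0)
  # reverse migration floors at zero instead of going negative
  rev <- make_tow(list(copepods = rep(0.2, 9)), list(copepods = rep(0.5, 9)))
  expect_equal(migrant_biomass_below(rev, 200)$migrant_mgC_m2, 0)
  expect_error(migrant_biomass_below(tow, 225), "stratum edge")
})

test_that("residence distribution telescopes and places a single migrant class in its stratum", {
  # migrants sit in 0-100 m at night and 300-350 m by day
  night <- list(copepods = c(0.6, 0.6, rep(0, 7)))
  day <- list(copepods = c(0, 0, 0, 0, 0, 0, 1.2, 0, 0))
  prof <- residence_distribution(make_tow(night, day))
  expect_equal(prof$biomass_mgC_m2[prof$stratum_top_m == 300], 60)
  expect_equal(sum(prof$biomass_mgC_m2), 60)
  # no day-night difference -> all-zero profile
  flat <- residence_distribution(make_tow(list(copepods = rep(1, 9)),
                                          list(copepods = rep(1, 9))))
  expect_true(all(flat$biomass_mgC_m2 == 0))
})

test_that("residence column sums equal migrant biomass below 100 m on generated tows", {
  out <- generate_tow_pairs(synth_config(seed = 13, n_tow_pairs = 3,
                                         euphausiid_day_avoidance = 1))
  for (e in unique(out$tows$experiment_id)) {
    tow <- out$tows[out$tows$experiment_id == e, ]
    prof <- residence_distribution(tow)
    mb <- migrant_biomass_below(tow, 100)
    sums <- stats::aggregate(biomass_mgC_m2 ~ taxon + size_bin, prof, sum)
    m <- merge(sums, mb, by = c("taxon", "size_bin"))
    expect_equal(m$biomass_mgC_m2, m$migrant_mgC_m2, tolerance = 1e-12)
  }
})

test_that("allometric specific respiration behaves monotonically in mass and temperature", {
  p <- bioenergetics_params()
  r_small <- specific_respiration("copepods", 0.01, 10, p)
  r_big <- specific_respiration("copepods", 1, 10, p)
  expect_gt(r_small, r_big)                 # mass exponent < 1
  expect_gt(specific_respiration("copepods", 0.1, 20, p),
            specific_respiration("copepods", 0.1, 10, p))
  co <- p$coefficients; co$a0 <- co$a0 + log(2)
  p2 <- bioenergetics_params(coefficients = co)
  expect_equal(specific_respiration("copepods", 0.1, 10, p2),
               2 * specific_respiration("copepods", 0.1, 10, p))
  expect_error(specific_respiration("salps", 0.1, 10, p), "salps")
})

test_that("zooplankton transport integrates biomass x rate x (1 + excretion)", {
  night <- list(copepods = c(1.2, 0.8, rep(0, 7)))
  day <- list(copepods = c(0.5, 0.3, 0, 0, 0, 0, 1.2, 0, 0))  # 60 at 300-350 m
  tow <- make_tow(night, day)
  prof <- residence_distribution(tow, constant_rate_params(0.05))
  tp <- zoop_transport_profile(prof, constant_rate_params(0.05))
  # 100 mg C m-2 resident below 100 m... here 60 mg: flux = 60*0.05*1.31 mg
  expect_equal(transport_flux_at(tp, 100) * 12.011, 60 * 0.05 * 1.31,
               tolerance = 1e-9)
  tp0 <- zoop_transport_profile(prof, constant_rate_params(0.05,
                                                           excretion_fraction = 0))
  expect_equal(transport_flux_at(tp0, 100) * 1.31, transport_flux_at(tp, 100),
               tolerance = 1e-12)
  # flux non-increasing with depth, zero at the profile floor
  expect_true(all(diff(tp$flux$flux_mmolC_m2_d) <= 0))
  expect_equal(transport_flux_at(tp, 600), 0)
})

test_that("transport recovered from generated tows matches the analytic ground truth", {
  out <- generate_tow_pairs(synth_config(seed = 17, n_tow_pairs = 2))
  p <- constant_rate_params(0.03)
  for (e in unique(out$tows$experiment_id)) {
    tow <- adjust_euphausiid_day(out$tows[out$tows$experiment_id == e, ])
    tp <- zoop_transport_profile(residence_distribution(tow, p), p)
    truth_total <- sum(out$truth$migrant_mgC_m2[out$truth$experiment_id == e])
    analytic <- truth_total * 0.03 * 1.31 / 12.011
    expect_equal(transport_flux_at(tp, 100), analytic, tolerance = 1e-9)
  }
})

test_that("scaling all biomass scales every transport flux linearly", {
  out <- generate_tow_pairs(synth_config(seed = 19, n_tow_pairs = 1,
                                         euphausiid_day_avoidance = 1))
  tow <- out$tows
  p <- constant_rate_params(0.04)
  tp1 <- zoop_transport_profile(residence_distribution(tow, p), p)
  tow2 <- tow; tow2$biomass_mgC_m3 <- tow2$biomass_mgC_m3 * 3
  tp3 <- zoop_transport_profile(residence_distribution(tow2, p), p)
  expect_equal(tp3$flux$flux_mmolC_m2_d, 3 * tp1$flux$flux_mmolC_m2_d,
               tolerance = 1e-12)
})

test_that("fish residence density reproduces normal tail masses across horizons", {
  fp <- fish_transport_profile(1)
  expect_equal(transport_flux_at(fp, 100), 1)
  expect_equal(transport_flux_at(fp, 450), 0.5, tolerance = 1e-2)
  expect_equal(transport_flux_at(fp, 550), 0.0228, tolerance = 5e-3)
  expect_equal(transport_flux_at(fp, 600), 0)
  expect_true(all(diff(fp$flux$flux_mmolC_m2_d) <= 0))
  fp2 <- fish_transport_profile(2.5)
  expect_equal(fp2$flux$flux_mmolC_m2_d, 2.5 * fp$flux$flux_mmolC_m2_d)
})

test_that("summed zoop+fish profiles keep the non-increasing flux invariant", {
  out <- generate_tow_pairs(synth_config(seed = 23, n_tow_pairs = 1))
  p <- bioenergetics_params()
  tow <- adjust_euphausiid_day(out$tows)
  tot <- sum_transport_profiles(list(
    zoop_transport_profile(residence_distribution(tow, p), p),
    fish_transport_profile(0.8, p)))
  expect_true(all(diff(tot$flux$flux_mmolC_m2_d) <= 0))
  expect_equal(transport_flux_at(tot, 100),
               transport_flux_at(zoop_transport_profile(
                 residence_distribution(tow, p), p), 100) + 0.8,
               tolerance = 1e-12)
})

test_that("bootstrap regional means collapse for identical profiles and cover the truth", {
  fp <- fish_transport_profile(1)
  same <- regional_mean_bootstrap(list(fp, fp, fp), n_boot = 300, seed = 1)
  expect_equal(same$lower, same$upper)
  expect_equal(same$mean[same$horizon_m == 100], 1)
  expect_warning(regional_mean_bootstrap(list(fp, fp), n_boot = 50, seed = 1),
                 "n_boot")
  # interval coverage of the true mean across synthetic replicates, at the
  # study's ensemble size (9 experiments, lognormal spread)
  set.seed(31)
  true_mean <- exp(log(2) + 0.4^2 / 2)
  hit <- 0
  for (r in 1:60) {
    profs <- lapply(rlnorm(9, log(2), 0.4), fish_transport_profile)
    ci <- regional_mean_bootstrap(profs, n_boot = 400, seed = r)
    row <- ci[ci$horizon_m == 100, ]
    hit <- hit + (row$lower <= true_mean && true_mean <= row$upper)
  }
  expect_gte(hit / 60, 0.85)
})
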