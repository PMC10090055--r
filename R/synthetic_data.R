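#' Configuration for the synthetic study-emulating data generators
#'
#' Bundles every knob of the synthetic input tables. The defaults emulate the
#' sampling design of the field study the package models: ~99 triplicate
#' sediment-trap deployments spanning an order of magnitude in 100-m export,
#' nine day/night-paired depth-stratified tow experiments (0--450 m in 50-m
#' strata), thirteen subduction flux profiles, and Lagrangian float cohorts
#' released at eight depths and tracked for 500 years.
#'
#' @param seed integer global seed; each generator derives its own child seed
#'   from it so tables can be regenerated independently.
#' @param n_deployments number of sediment-trap deployments.
#' @param b_true true power-law attenuation exponent (dimensionless).
#' @param f100_range interval (mmol C m-2 d-1) from which each deployment's
#'   true 100-m export is drawn uniformly.
#' @param trap_depths trap crosspiece depths (m); all must be >= 50 m.
#' @param cv_triplicate coefficient of variation of the multiplicative
#'   lognormal noise applied to each trap replicate (0 = noiseless).
#' @param n_replicates replicate tubes per crosspiece (triplicate by default).
#' @param n_tow_pairs number of day/night-paired tow experiments.
#' @param taxa zooplankton taxa present in the tows.
#' @param migrant_fraction_by_taxon named fraction of each taxon's biomass
#'   that undergoes diel vertical migration.
#' @param residence_depth_params named list of c(mean, sd) (m) of daytime
#'   residence depth per taxon.
#' @param euphausiid_day_avoidance multiplicative daytime net-avoidance bias
#'   applied to euphausiids (1 = no avoidance).
#' @param n_subduction_profiles number of subduction flux-vs-depth profiles.
#' @param subduction_amplitude mean 100-m subduction flux (mmol C m-2 d-1).
#' @param subduction_amplitude_cv lognormal experiment-to-experiment spread.
#' @param subduction_efolding e-folding attenuation length (m) below 100 m.
#' @param release_depths float release depths; must be a subset of the eight
#'   canonical depths c(100, 150, 200, 300, 400, 500, 750, 1000).
#' @param n_floats_per_depth total floats per release depth (split across
#'   launch cohorts).
#' @param launch_cohorts number of launch-year cohorts.
#' @param entrainment_hazard_scale mixed-layer entrainment hazard (yr-1) at
#'   100 m; default 1/102 so the expected sequestration time at 100 m is the
#'   ~102 yr scale typical of the region.
#' @param hazard_depth_efolding e-folding depth (m) of the hazard decline;
#'   default 350 m puts the expected time at 1000 m near 1335 yr.
#' @param boundary_fraction fraction of floats that exit through a domain
#'   boundary at a recorded time.
#' @param horizon_years simulation horizon (yr); floats still sequestered at
#'   the horizon are recorded as "survived".
#' @param sst_mean,npp_mean surface temperature (deg C) and vertically
#'   integrated net primary production (mmol C m-2 d-1) used for the flat
#'   regional grids and as the centre of the per-experiment ecosystem metrics.
#' @param n_experiments number of Lagrangian experiments the tables are
#'   attributed to.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_deployments = 99,
                         b_true = 0.9,
                         f100_range = c(2.6, 41),
                         trap_depths = c(100, 150, 250, 400),
                         cv_triplicate = 0.2,
                         n_replicates = 3,
                         n_tow_pairs = 9,
                         taxa = c("copepods", "euphausiids", "chaetognaths", "others"),
                         migrant_fraction_by_taxon = c(copepods = 0.4, euphausiids = 0.5,
                                                       chaetognaths = 0.3, others = 0.3),
                         residence_depth_params = list(copepods = c(250, 40),
                                                       euphausiids = c(225, 35),
                                                       chaetognaths = c(300, 50),
                                                       others = c(400, 80)),
                         euphausiid_day_avoidance = 0.7,
                         n_subduction_profiles = 13,
                         subduction_amplitude = 3.8,
                         subduction_amplitude_cv = 0.3,
                         subduction_efolding = 74,
                         release_depths = c(100, 150, 200, 300, 400, 500, 750, 1000),
                         n_floats_per_depth = 1000,
                         launch_cohorts = 5,
                         entrainment_hazard_scale = 1 / 102,
                         hazard_depth_efolding = 350,
                         boundary_fraction = 0.02,
                         horizon_years = 500,
                         sst_mean = 15,
                         npp_mean = 64.3,
                         n_experiments = 13) {
  cfg <- list(seed = as.integer(seed), n_deployments = n_deployments,
              b_true = b_true, f100_range = f100_range, trap_depths = trap_depths,
              cv_triplicate = cv_triplicate, n_replicates = n_replicates,
              n_tow_pairs = n_tow_pairs, taxa = taxa,
              migrant_fraction_by_taxon = migrant_fraction_by_taxon,
              residence_depth_params = residence_depth_params,
              euphausiid_day_avoidance = euphausiid_day_avoidance,
              n_subduction_profiles = n_subduction_profiles,
              subduction_amplitude = subduction_amplitude,
              subduction_amplitude_cv = subduction_amplitude_cv,
              subduction_efolding = subduction_efolding,
              release_depths = release_depths,
              n_floats_per_depth = n_floats_per_depth,
              launch_cohorts = launch_cohorts,
              entrainment_hazard_scale = entrainment_hazard_scale,
              hazard_depth_efolding = hazard_depth_efolding,
              boundary_fraction = boundary_fraction,
              horizon_years = horizon_years,
              sst_mean = sst_mean, npp_mean = npp_mean,
              n_experiments = n_experiments)
  counts <- c("n_deployments", "n_replicates", "n_tow_pairs",
              "n_subduction_profiles", "n_floats_per_depth", "launch_cohorts",
              "n_experiments")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stopf("synth_config: %s must be >= 1", nm)
  }
  if (cfg$cv_triplicate < 0) stopf("synth_config: cv_triplicate must be >= 0")
  if (cfg$b_true <= 0) stopf("synth_config: b_true must be > 0")
  if (cfg$horizon_years <= 0) stopf("synth_config: horizon_years must be > 0")
  if (cfg$boundary_fraction < 0 || cfg$boundary_fraction >= 1)
    stopf("synth_config: boundary_fraction must be in [0, 1)")
  structure(cfg, class = "synth_config")
}

experiment_ids <- function(n) sprintf("E%02d", seq_len(n))

#' Generate synthetic sediment-trap deployments
#'
#' Each deployment draws a true 100-m export uniformly from `f100_range`; the
#' noiseless flux at depth z is `f100 * (z/100)^(-b_true)`. Replicate tubes
#' receive multiplicative lognormal noise with coefficient of variation
#' `cv_triplicate` (mean-one, so the noiseless limit is exact); the reported
#' flux is the replicate mean and the reported uncertainty the replicate
#' sample standard deviation.
#'
#' @param cfg a [synth_config()].
#' @return list with `deployments` (data frame in the trap CSV layout) and
#'   `truth` (per-deployment true `f100` and the shared `b_true`).
#' @export
generate_trap_deployments <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(cfg$trap_depths < 50))
    stopf("generate_trap_deployments: trap depths shallower than 50 m are not supported (power law undefined near the surface)")
  set.seed(child_seed(cfg$seed, 1))
  n <- cfg$n_deployments
  exps <- experiment_ids(cfg$n_experiments)
  sdlog <- sqrt(log(1 + cfg$cv_triplicate^2))
  rows <- vector("list", n)
  truth <- data.frame(deployment_id = sprintf("D%03d", seq_len(n)),
                      experiment_id = exps[(seq_len(n) - 1L) %% cfg$n_experiments + 1L],
                      f100_true = runif(n, cfg$f100_range[1], cfg$f100_range[2]),
                      b_true = cfg$b_true)
  for (i in seq_len(n)) {
    ez <- round(runif(1, 50, 100))
    true_flux <- truth$f100_true[i] * (cfg$trap_depths / 100)^(-cfg$b_true)
    reps <- vapply(true_flux, function(mu)
      mu * rlnorm(cfg$n_replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog),
      numeric(cfg$n_replicates))
    reps <- matrix(reps, nrow = cfg$n_replicates)
    rows[[i]] <- data.frame(
      deployment_id = truth$deployment_id[i],
      cruise = sprintf("C%02d", (i - 1L) %% 11L + 1L),
      depth_m = cfg$trap_depths,
      flux_mean_mmolC_m2_d = colMeans(reps),
      flux_sd_mmolC_m2_d = apply(reps, 2, sd),
      n_reps = cfg$n_replicates,
      euphotic_depth_m = ez)
  }
  list(deployments = do.call(rbind, rows), truth = truth)
}

#' Table of logarithmic zooplankton size bins
#'
#' Eleven bins spanning <0.2 mm to >10 mm: nine logarithmically spaced
#' interior bins plus two open end bins. Representative length is the
#' geometric mean of the bin edges (open bins: edge scaled by the square root
#' of the bin ratio); representative body carbon uses a generic
#' length--carbon power law (editable coefficients).
#'
#' @param l_min,l_max interior edge range (mm).
#' @param length_carbon_a,length_carbon_b coefficients of
#'   `massC = a * L^b` (mg C, L in mm); order-of-magnitude defaults for
#'   mixed mesozooplankton.
#' @return data frame with bin label, edges, representative length and mass.
#' @export
size_bin_table <- function(l_min = 0.2, l_max = 10,
                           length_carbon_a = 0.0055, length_carbon_b = 2.85) {
  edges <- exp(seq(log(l_min), log(l_max), length.out = 10))
  ratio <- edges[2] / edges[1]
  lo <- c(l_min / ratio, edges)
  hi <- c(edges, l_max * ratio)
  label <- c(sprintf("<%.2gmm", l_min),
             sprintf("%.2g-%.2gmm", edges[-10], edges[-1]),
             sprintf(">%.2gmm", l_max))
  rep_len <- sqrt(lo * hi)
  data.frame(size_bin = label, lower_mm = c(0, edges), upper_mm = c(edges, Inf),
             rep_length_mm = rep_len,
             rep_mass_mgC = length_carbon_a * rep_len^length_carbon_b)
}

tow_strata <- function() data.frame(top = seq(0, 400, 50), bottom = seq(50, 450, 50))

# Background (non-migrant) vertical allocation over the 0-450 m strata:
# exponentially declining with depth, identical day and night.
background_weights <- function() {
  mids <- seq(25, 425, 50)
  w <- exp(-mids / 150)
  w / sum(w)
}

#' Generate synthetic day/night-paired tow tables
#'
#' Builds, per experiment and taxon, a size spectrum of column biomass, a
#' non-migrant background profile identical day and night, and a migrant pool
#' placed in the upper 100 m at night. During the day each (taxon, size
#' class) resides at a single depth drawn from its taxon's residence normal,
#' snapped to its 50-m stratum; draws at or below 450 m land in the 450--600 m
#' stratum, which the 0--450 m tow cannot see. Euphausiid daytime biomass is
#' additionally scaled by a net-avoidance factor. Tables are otherwise
#' noise-free so that night-minus-day differences recover the migrant ground
#' truth exactly.
#'
#' @param cfg a [synth_config()].
#' @return list with `tows` (data frame in the tow CSV layout) and `truth`
#'   (migrant biomass per experiment/taxon/size class with its residence
#'   stratum).
#' @export
generate_tow_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(cfg$taxa) == 0) stopf("generate_tow_pairs: taxa list is empty")
  set.seed(child_seed(cfg$seed, 2))
  bins <- size_bin_table()
  strata <- tow_strata()
  bw <- background_weights()
  mids <- (strata$top + strata$bottom) / 2
  base_total <- c(copepods = 300, euphausiids = 150, chaetognaths = 60, others = 80)
  # fixed size spectrum: lognormal over representative length, per taxon mode
  spec_mode <- c(copepods = 1, euphausiids = 8, chaetognaths = 10, others = 3)
  exps <- experiment_ids(cfg$n_experiments)[seq_len(cfg$n_tow_pairs)]
  tow_rows <- list(); truth_rows <- list()
  for (e in exps) {
    sst <- cfg$sst_mean + rnorm(1, 0, 1.5)
    temp <- sst - (sst - 5) * pmin(mids, 600) / 600
    for (tx in cfg$taxa) {
      tot <- (base_total[tx] %||% 100) * rlnorm(1, 0, 0.3)
      mode <- spec_mode[tx] %||% 2
      sw <- exp(-0.5 * ((log(bins$rep_length_mm) - log(mode)) / 0.9)^2)
      sw <- sw / sum(sw)
      mfrac <- unname(cfg$migrant_fraction_by_taxon[tx] %||% 0)
      rp <- cfg$residence_depth_params[[tx]] %||% c(300, 50)
      for (s in seq_len(nrow(bins))) {
        B <- tot * sw[s]                      # column total, mg C m-2
        M <- mfrac * B                        # migrant pool
        bg_conc <- (B - M) * bw / 50          # mg C m-3 per stratum
        night_conc <- bg_conc
        night_conc[1:2] <- night_conc[1:2] + M * c(0.6, 0.4) / 50
        rz <- max(100, rnorm(1, rp[1], rp[2]))
        res_top <- if (rz >= 450) 450 else 50 * floor(rz / 50)
        res_bottom <- if (rz >= 450) 600 else res_top + 50
        day_conc <- bg_conc
        if (res_top < 450) {
          k <- which(strata$top == res_top)
          day_conc[k] <- day_conc[k] + M / 50
        }
        avoid <- if (tx == "euphausiids") cfg$euphausiid_day_avoidance else 1
        tow_rows[[length(tow_rows) + 1L]] <- data.frame(
          experiment_id = e, taxon = tx, size_bin = bins$size_bin[s],
          stratum_top_m = rep(strata$top, 2),
          stratum_bottom_m = rep(strata$bottom, 2),
          day_night = rep(c("night", "day"), each = nrow(strata)),
          biomass_mgC_m3 = c(night_conc, day_conc * avoid),
          temperature_C = rep(temp, 2))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          experiment_id = e, taxon = tx, size_bin = bins$size_bin[s],
          residence_top_m = res_top, residence_bottom_m = res_bottom,
          migrant_mgC_m2 = M)
      }
    }
  }
  list(tows = do.call(rbind, tow_rows), truth = do.call(rbind, truth_rows))
}

#' Generate synthetic Lagrangian float fate records
#'
#' Toy model of passive carbon parcels: each float holds its release depth
#' fixed and is entrained into the mixed layer after an exponential waiting
#' time with hazard `entrainment_hazard_scale * exp(-(z - 100) /
#' hazard_depth_efolding)`. Floats still sequestered at `horizon_years` are
#' censored as "survived"; a configurable fraction instead exits through a
#' domain boundary at a uniformly drawn time. Because depth is held fixed,
#' the censored-mean estimator has the analytic fixed point 1/hazard(z).
#'
#' @param cfg a [synth_config()].
#' @return list with `fates` (data frame in the fate CSV layout) and `truth`
#'   (per-depth hazard and expected sequestration time).
#' @export
generate_float_fates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  canonical <- c(100, 150, 200, 300, 400, 500, 750, 1000)
  if (!all(cfg$release_depths %in% canonical))
    stopf("generate_float_fates: release depths must be a subset of {%s} m",
          paste(canonical, collapse = ", "))
  set.seed(child_seed(cfg$seed, 3))
  rows <- list()
  hz <- cfg$entrainment_hazard_scale *
    exp(-(cfg$release_depths - 100) / cfg$hazard_depth_efolding)
  per_cohort <- rep(cfg$n_floats_per_depth %/% cfg$launch_cohorts, cfg$launch_cohorts)
  per_cohort[1] <- per_cohort[1] + cfg$n_floats_per_depth %% cfg$launch_cohorts
  for (d in seq_along(cfg$release_depths)) {
    z <- cfg$release_depths[d]
    for (co in seq_len(cfg$launch_cohorts)) {
      n <- per_cohort[co]
      if (n == 0) next
      t_ent <- if (hz[d] > 0) rexp(n, rate = hz[d]) else rep(Inf, n)
      is_boundary <- runif(n) < cfg$boundary_fraction
      fate <- ifelse(is_boundary, "boundary",
                     ifelse(t_ent > cfg$horizon_years, "survived", "mixed_layer"))
      elapsed <- ifelse(fate == "boundary", runif(n, 0, cfg$horizon_years),
                        pmin(t_ent, cfg$horizon_years))
      rows[[length(rows) + 1L]] <- data.frame(
        release_depth_m = z, fate = fate, elapsed_time_yr = elapsed,
        final_depth_m = z, cohort = sprintf("Y%02d", co))
    }
  }
  truth <- data.frame(release_depth_m = cfg$release_depths, hazard_yr = hz,
                      expected_g_yr = 1 / hz)
  list(fates = do.call(rbind, rows), truth = truth)
}

#' Generate synthetic subduction flux-vs-depth profiles
#'
#' Rapidly attenuating physical-pump profiles: per experiment an amplitude at
#' 100 m drawn lognormally around `subduction_amplitude` and an exponential
#' decay below 100 m with e-folding near `subduction_efolding` m (the default
#' 74 m loses ~74% of the 100-m flux by 200 m).
#'
#' @param cfg a [synth_config()].
#' @return list with `profiles` (data frame in the subduction CSV layout) and
#'   `truth` (per-experiment amplitude and e-folding length).
#' @export
generate_subduction_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, 4))
  depths <- seq(100, 1000, by = 25)
  exps <- experiment_ids(cfg$n_experiments)[seq_len(cfg$n_subduction_profiles)]
  sdlog <- sqrt(log(1 + cfg$subduction_amplitude_cv^2))
  rows <- list(); truth <- list()
  for (e in exps) {
    A <- if (cfg$subduction_amplitude == 0) 0 else
      cfg$subduction_amplitude * rlnorm(1, -sdlog^2 / 2, sdlog)
    ef <- max(20, rnorm(1, cfg$subduction_efolding, 8))
    flux <- A * exp(-(depths - 100) / ef)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = e, depth_m = depths, flux_mmolC_m2_d = flux,
      euphotic_depth_m = round(runif(1, 50, 100)))
    truth[[length(truth) + 1L]] <- data.frame(experiment_id = e,
                                              amplitude_100m = A, efolding_m = ef)
  }
  list(profiles = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate per-experiment ecosystem metrics
#'
#' Emulates the covariate table used by the rank-correlation screen: a latent
#' upwelling intensity drives cool surface temperature, high surface nitrate
#' and chlorophyll, high integrated primary production and a shallow euphotic
#' zone.
#'
#' @param cfg a [synth_config()].
#' @return data frame with one row per experiment.
#' @export
generate_ecosystem_metrics <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, 5))
  n <- cfg$n_experiments
  u <- rnorm(n)                                  # latent upwelling intensity
  data.frame(
    experiment_id = experiment_ids(n),
    sst_C = cfg$sst_mean - 2 * u + rnorm(n, 0, 0.5),
    surface_nitrate_uM = pmax(0.01, 2 * exp(0.8 * u) + rnorm(n, 0, 0.2)),
    surface_chl_mg_m3 = pmax(0.01, exp(0.7 * u) + rnorm(n, 0, 0.1)),
    npp_mmolC_m2_d = pmax(1, cfg$npp_mean * exp(0.6 * u) * rlnorm(n, 0, 0.1)),
    euphotic_depth_m = round(pmin(120, pmax(30, 75 - 20 * u + rnorm(n, 0, 5)))))
}

#' Flat regional SST and NPP grids for the e-ratio extrapolation
#'
#' @param cfg a [synth_config()].
#' @param nx,ny grid dimensions.
#' @return list of two matrices, `sst` (deg C) and `npp` (mmol C m-2 d-1).
#' @export
generate_flat_grids <- function(cfg, nx = 10, ny = 10) {
  stopifnot(inherits(cfg, "synth_config"))
  list(sst = matrix(cfg$sst_mean, nx, ny), npp = matrix(cfg$npp_mean, nx, ny))
}
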