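#' End-to-end pipeline configuration
#'
#' @param seed global seed; fans out to all stochastic stages.
#' @param synthetic a [synth_config()] (synthetic inputs are generated when
#'   `paths` is `NULL`).
#' @param paths optional named list of input table paths (`traps`, `tows`,
#'   `fish`, `subduction`, `fates`, `metrics`); validated before use.
#' @param mcmc an [mcmc_config()] for the attenuation fit.
#' @param bio a [bioenergetics_params()].
#' @param region a [region_config()].
#' @param eratio an [e_ratio_model()].
#' @param n_boot bootstrap resamples for regional means.
#' @param n_draws Monte Carlo draws for budget uncertainty.
#' @param out_dir optional directory for per-stage artifacts (CSV/JSON).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, synthetic = synth_config(seed = seed),
                            paths = NULL,
                            mcmc = mcmc_config(n_iter = 2e5, n_burn = 2e4,
                                               thin = 10, adapt = TRUE,
                                               seed = seed),
                            bio = bioenergetics_params(),
                            region = region_config(),
                            eratio = e_ratio_model(),
                            n_boot = 1000, n_draws = 2000, out_dir = NULL) {
  structure(list(seed = as.integer(seed), synthetic = synthetic, paths = paths,
                 mcmc = mcmc, bio = bio, region = region, eratio = eratio,
                 n_boot = n_boot, n_draws = n_draws, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full export-and-sequestration pipeline
#'
#' Chains the stages in study order: input generation (or ingestion and
#' validation), the Bayesian attenuation fit and regional flux curve, the
#' migrant bioenergetics and fish active transport with bootstrap regional
#' means, the physical-pump regional profile, the censored-mean
#' sequestration-time curve with cohort uncertainty, and the pathway budget
#' integration with the export-efficiency metrics and the rank-correlation
#' screen. Deterministic given the configuration seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list with per-stage results and the final `budgets` table.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  warnings_log <- character()
  log_warn <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w)) }

  ## ---- stage: inputs -------------------------------------------------
  if (is.null(cfg$paths)) {
    traps <- generate_trap_deployments(cfg$synthetic)
    tows <- generate_tow_pairs(cfg$synthetic)
    fates <- generate_float_fates(cfg$synthetic)
    subd <- generate_subduction_profiles(cfg$synthetic)
    metrics <- generate_ecosystem_metrics(cfg$synthetic)
    trap_tab <- traps$deployments; tow_tab <- tows$tows
    fate_tab <- fates$fates; sub_tab <- subd$profiles
    set.seed(child_seed(cfg$seed, 6))
    fish_tab <- data.frame(
      experiment_id = unique(tow_tab$experiment_id),
      total_respiration_mmolC_m2_d =
        pmax(0.05, rnorm(length(unique(tow_tab$experiment_id)), 0.8, 0.3)))
    truth <- list(traps = traps$truth, tows = tows$truth,
                  fates = fates$truth, subduction = subd$truth)
  } else {
    report <- validate_tables(cfg$paths)
    if (nrow(report) > 0) {
      bad <- report[1, ]
      stopf("run_pipeline: stage 'inputs' failed on table '%s' (row %s, field %s): %s",
            bad$table, bad$row, bad$field, bad$message)
    }
    trap_tab <- read_trap_csv(cfg$paths$traps)
    tow_tab <- read_tow_csv(cfg$paths$tows)
    fish_tab <- read_fish_csv(cfg$paths$fish)
    sub_tab <- read_subduction_csv(cfg$paths$subduction)
    fate_tab <- read_fates_csv(cfg$paths$fates)
    metrics <- read_metrics_csv(cfg$paths$metrics)
    truth <- NULL
  }

  ## ---- stage: trap_flux ----------------------------------------------
  post <- withCallingHandlers(
    fit_attenuation_mcmc(floor_trap_sd(trap_tab), cfg$mcmc),
    warning = function(w) { log_warn(w); invokeRestart("muffleWarning") })
  grids <- generate_flat_grids(cfg$synthetic)
  F100_bar <- regional_F100(grids$npp, grids$sst, cfg$eratio)
  set.seed(child_seed(cfg$seed, 7))
  n_post <- length(post$b_samples)
  # regional F100 draws: e-ratio coefficient uncertainty on the flat grid
  F100_draws <- vapply(seq_len(n_post), function(i) {
    m <- e_ratio_model(slope = max(1e-6, rnorm(1, cfg$eratio$slope, cfg$eratio$slope_sd)),
                       intercept = rnorm(1, cfg$eratio$intercept, cfg$eratio$intercept_sd))
    regional_F100(grids$npp, grids$sst, m)
  }, numeric(1))
  curve <- flux_curve(F100_bar, mean(post$b_samples),
                      F100_samples = F100_draws, b_samples = post$b_samples)

  ## ---- stage: active_transport ---------------------------------------
  tow_tab <- adjust_euphausiid_day(tow_tab)
  exp_ids <- unique(tow_tab$experiment_id)
  zoop_profiles <- lapply(exp_ids, function(e) {
    prof <- residence_distribution(tow_tab[tow_tab$experiment_id == e, ], cfg$bio)
    zoop_transport_profile(prof, cfg$bio, experiment_id = e)
  })
  fish_profiles <- lapply(exp_ids, function(e) {
    tot <- fish_tab$total_respiration_mmolC_m2_d[fish_tab$experiment_id == e]
    fish_transport_profile(if (length(tot)) tot[1] else 0, cfg$bio,
                           experiment_id = e)
  })
  total_profiles <- Map(function(z, f) sum_transport_profiles(list(z, f)),
                        zoop_profiles, fish_profiles)
  at_regional <- withCallingHandlers(
    regional_mean_bootstrap(total_profiles, cfg$n_boot,
                            seed = child_seed(cfg$seed, 8)),
    warning = function(w) { log_warn(w); invokeRestart("muffleWarning") })

  ## ---- stage: physical_pump ------------------------------------------
  pp_regional <- regional_mean_profile(sub_tab, cfg$n_boot,
                                       seed = child_seed(cfg$seed, 9))

  ## ---- stage: sequestration ------------------------------------------
  horizon <- cfg$synthetic$horizon_years
  gcurve <- estimate_g(fate_tab, horizon)
  gcurve$cohort_sd_yr <- if ("cohort" %in% names(fate_tab) &&
                             length(unique(fate_tab$cohort)) >= 2)
    cohort_uncertainty(fate_tab, horizon) else NULL

  ## ---- stage: budget --------------------------------------------------
  region <- cfg$region
  zmax <- min(region$max_integration_depth, 4000)
  grid_sink <- seq(100, zmax, by = 5)
  sink_budget <- pathway_budget(
    "sinking", curve$F100_mean, grid_sink,
    remineralization_density(curve, grid_sink),
    flux_at_depth(curve, zmax), gcurve, region)

  at_mean <- stats::aggregate(
    vol_rate_mmolC_m3_d ~ top + bottom,
    do.call(rbind, lapply(total_profiles, function(p) p$strata)),
    function(x) sum(x) / length(total_profiles))
  at_mean <- at_mean[order(at_mean$top), ]
  at_grid <- seq(min(at_mean$top), max(at_mean$bottom), by = 1)
  at_rate <- at_mean$vol_rate_mmolC_m3_d[
    pmin(nrow(at_mean), findInterval(at_grid, at_mean$top))]
  at_export <- at_regional$mean[at_regional$horizon_m == 100]
  at_budget <- pathway_budget("active_transport", at_export, at_grid, at_rate,
                              0, gcurve, region)

  pp_dens <- profile_remineralization_density(pp_regional$depth_m, pp_regional$mean)
  pp_budget <- pathway_budget(
    "subduction", approx(pp_regional$depth_m, pp_regional$mean, 100, rule = 2)$y,
    (pp_dens$top_m + pp_dens$bottom_m) / 2, pp_dens$density_mmolC_m3_d,
    pp_regional$mean[length(pp_regional$mean)], gcurve, region)

  budgets <- list(sinking = sink_budget, active_transport = at_budget,
                  subduction = pp_budget)
  exports <- c(sinking = sink_budget$export_100,
               active_transport = at_budget$export_100,
               subduction = pp_budget$export_100)
  fractions <- pathway_fractions(exports)

  ## per-experiment export proportions for the correlation screen
  screen <- NULL
  if (!is.null(truth)) {
    sink_by_exp <- stats::aggregate(f100_true ~ experiment_id, truth$traps, mean)
    at_by_exp <- data.frame(
      experiment_id = exp_ids,
      at_export = vapply(total_profiles, function(p)
        transport_flux_at(p, 100), numeric(1)))
    sub_by_exp <- stats::aggregate(flux_mmolC_m2_d ~ experiment_id,
                                   sub_tab[sub_tab$depth_m == 100, ], mean)
    tab <- Reduce(function(a, b) merge(a, b, by = "experiment_id", all = TRUE),
                  list(metrics, sink_by_exp, at_by_exp, sub_by_exp))
    tab$prop_sinking <- tab$f100_true / tab$npp_mmolC_m2_d
    tab$prop_active <- tab$at_export / tab$npp_mmolC_m2_d
    tab$prop_subduction <- tab$flux_mmolC_m2_d / tab$npp_mmolC_m2_d
    keep <- complete.cases(tab[, c("prop_sinking", "sst_C")])
    if (sum(keep) >= 5)
      screen <- tryCatch(
        correlation_screen(tab[keep, ],
                           c("prop_sinking", "prop_active", "prop_subduction"),
                           c("sst_C", "surface_nitrate_uM", "surface_chl_mg_m3",
                             "npp_mmolC_m2_d")),
        error = function(e) NULL)
  }

  result <- list(config = cfg, posterior = post, flux_curve = curve,
                 active_transport = list(profiles = total_profiles,
                                         regional = at_regional),
                 physical_pump = pp_regional, g_curve = gcurve,
                 budgets = budgets, budget_table = budget_table(budgets),
                 exports_100 = exports, pathway_fractions = fractions,
                 correlation_screen = screen, truth = truth,
                 warnings = warnings_log,
                 provenance = list(seed = cfg$seed,
                                   package_version = as.character(
                                     utils::packageVersion("bcpbudget"))))

  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(result, cfg$out_dir)
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(result$budget_table, file.path(dir, "budget_table.csv"))
  write_table_csv(result$posterior$summary, file.path(dir, "posterior_summary.csv"))
  write_table_csv(result$active_transport$regional,
                  file.path(dir, "active_transport_regional.csv"))
  write_table_csv(result$physical_pump, file.path(dir, "subduction_regional.csv"))
  gc <- result$g_curve
  jsonlite::write_json(
    list(provenance = result$provenance,
         g_curve = list(depth_m = gc$depth_m, g_yr = gc$g_yr,
                        iterations = gc$iterations, converged = gc$converged),
         exports_100 = as.list(result$exports_100),
         pathway_fractions = as.list(result$pathway_fractions),
         warnings = result$warnings),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
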