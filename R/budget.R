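#' Regional configuration for sequestration accounting
#'
#' @param domain_area_km2 study-region area (default 1.7e5 km2).
#' @param carbon_molar_mass g per mol C (12.011).
#' @param days_per_year 365.25.
#' @param max_integration_depth deepest resolved depth of the
#'   remineralization integrals (m).
#' @param deep_g_value sequestration time (yr) assigned to carbon passing
#'   the deepest resolved horizon; defaults to the curve's deepest knot
#'   value when `NULL`.
#' @return object of class `region_config`.
#' @export
region_config <- function(domain_area_km2 = 1.7e5, carbon_molar_mass = 12.011,
                          days_per_year = 365.25, max_integration_depth = 4000,
                          deep_g_value = NULL) {
  vals <- c(domain_area_km2, carbon_molar_mass, days_per_year,
            max_integration_depth)
  if (any(vals <= 0)) stopf("region_config: all quantities must be positive")
  structure(list(domain_area_km2 = domain_area_km2,
                 carbon_molar_mass = carbon_molar_mass,
                 days_per_year = days_per_year,
                 max_integration_depth = max_integration_depth,
                 deep_g_value = deep_g_value),
            class = "region_config")
}

#' Areal sequestration stock from a remineralization profile
#'
#' Trapezoid integral over depth of sequestration time times
#' remineralization density, `int g(z) r(z) dz`, plus the flux still passing
#' the deepest resolved horizon multiplied by the deep sequestration time.
#' The (mmol C m-2 d-1 x yr) product is converted to mol C m-2 via
#' days-per-year / 1000.
#'
#' @param depth_m depth grid (m) of the density profile.
#' @param density_mmolC_m3_d remineralization density on that grid (>= 0).
#' @param flux_at_zmax flux passing the deepest grid depth, mmol C m-2 d-1.
#' @param g a `sequestration_curve` (or any function of depth returning yr).
#' @param region a [region_config()].
#' @return areal sequestration, mol C m-2.
#' @export
sequestration_integral <- function(depth_m, density_mmolC_m3_d, flux_at_zmax,
                                   g, region = region_config()) {
  stopifnot(inherits(region, "region_config"))
  if (any(density_mmolC_m3_d < 0))
    stopf("sequestration_integral: negative remineralization density")
  if (flux_at_zmax < 0) stopf("sequestration_integral: negative deep flux")
  gf <- if (inherits(g, "sequestration_curve")) g$fun else g
  deep_g <- region$deep_g_value %||%
    (if (inherits(g, "sequestration_curve")) g$g_yr[length(g$g_yr)]
     else gf(1e6))
  o <- order(depth_m)
  z <- depth_m[o]; r <- density_mmolC_m3_d[o]
  inner <- pracma::trapz(z, gf(z) * r)
  (inner + flux_at_zmax * deep_g) * region$days_per_year / 1000
}

#' Mean sequestration duration of an export pathway
#'
#' The areal stock divided by the annualized 100-m export:
#' `areal * 1000 / (export_100 * days_per_year)`.
#'
#' @param areal areal sequestration, mol C m-2.
#' @param export_100 export across 100 m, mmol C m-2 d-1 (> 0).
#' @param region a [region_config()].
#' @return mean duration, yr.
#' @export
mean_duration <- function(areal, export_100, region = region_config()) {
  if (export_100 <= 0) stopf("mean_duration: export must be > 0")
  areal * 1000 / (export_100 * region$days_per_year)
}

#' Regional sequestration stock
#'
#' @param areal areal sequestration, mol C m-2.
#' @param region a [region_config()].
#' @return regional stock, Pg C.
#' @export
regional_total <- function(areal, region = region_config()) {
  if (any(areal < 0)) stopf("regional_total: areal stock must be >= 0")
  areal * region$carbon_molar_mass * region$domain_area_km2 * 1e6 / 1e15
}

#' Export efficiency and mesopelagic transfer efficiency
#'
#' EZ-ratio = export at the euphotic-zone base / NPP; T100 = export 100 m
#' below the euphotic-zone base / export at its base.
#'
#' @param export_at_ez export at the euphotic-zone base, mmol C m-2 d-1.
#' @param export_at_ez_plus_100 export 100 m deeper.
#' @param npp net primary production, mmol C m-2 d-1 (> 0).
#' @return named vector c(ez_ratio, t100).
#' @export
ez_ratio_t100 <- function(export_at_ez, export_at_ez_plus_100, npp) {
  if (npp <= 0) stopf("ez_ratio_t100: NPP must be > 0")
  if (export_at_ez <= 0)
    stopf("ez_ratio_t100: export at the euphotic-zone base must be > 0 for T100")
  c(ez_ratio = export_at_ez / npp,
    t100 = export_at_ez_plus_100 / export_at_ez)
}

#' Pathway shares of export across a horizon
#'
#' @param exports vector of pathway exports at a common horizon (typically
#'   named sinking / active_transport / subduction).
#' @return fractions summing to exactly 1.
#' @export
pathway_fractions <- function(exports) {
  if (any(exports < 0)) stopf("pathway_fractions: exports must be >= 0")
  s <- sum(exports)
  if (s == 0) stopf("pathway_fractions: all exports are zero")
  exports / s
}

#' Spearman rank-correlation screen of export proportions vs ecosystem metrics
#'
#' For every (pathway, metric) column pair, the average-rank Spearman
#' coefficient with a two-sided t-approximation p-value,
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom. Pairs with a
#' constant column are reported as missing.
#'
#' @param data data frame holding both sets of columns.
#' @param pathway_cols names of the export-proportion columns.
#' @param metric_cols names of the ecosystem-metric columns.
#' @param min_n minimum paired observations (default 5).
#' @return data frame `pathway`, `metric`, `n`, `rho`, `p_value`.
#' @export
correlation_screen <- function(data, pathway_cols, metric_cols, min_n = 5) {
  out <- expand.grid(pathway = pathway_cols, metric = metric_cols,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$rho <- NA_real_; out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- data[[out$pathway[i]]]; y <- data[[out$metric[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    out$n[i] <- n
    if (n < min_n)
      stopf("correlation_screen: pair (%s, %s) has %d < %d paired observations",
            out$pathway[i], out$metric[i], n, min_n)
    if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) next  # constant
    rho <- cor(x[ok], y[ok], method = "spearman")
    out$rho[i] <- rho
    if (abs(rho) >= 1) {
      out$p_value[i] <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      out$p_value[i] <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  out
}

#' Assemble a pathway budget row
#'
#' Combines a pathway's 100-m export and remineralization profile with the
#' sequestration-time curve into the areal stock, mean duration and regional
#' total, with percentile intervals propagated from paired draws of the
#' upstream uncertainties when supplied.
#'
#' @param pathway pathway label.
#' @param export_100 export across 100 m, mmol C m-2 d-1.
#' @param depth_m,density_mmolC_m3_d remineralization density profile.
#' @param flux_at_zmax flux passing the deepest grid depth.
#' @param g a `sequestration_curve`.
#' @param region a [region_config()].
#' @param draws optional list of draws for uncertainty propagation: each
#'   element a list with `export_100`, `density` (same grid) and
#'   `flux_at_zmax`; draws are paired by index across quantities.
#' @param level interval coverage.
#' @return object of class `pathway_budget`.
#' @export
pathway_budget <- function(pathway, export_100, depth_m, density_mmolC_m3_d,
                           flux_at_zmax, g, region = region_config(),
                           draws = NULL, level = 0.95) {
  areal <- sequestration_integral(depth_m, density_mmolC_m3_d, flux_at_zmax,
                                  g, region)
  out <- list(pathway = pathway, export_100 = export_100,
              depth_m = depth_m, density_mmolC_m3_d = density_mmolC_m3_d,
              areal_molC_m2 = areal,
              mean_duration_yr = mean_duration(areal, export_100, region),
              regional_PgC = regional_total(areal, region),
              intervals = NULL)
  if (!is.null(draws)) {
    areal_d <- vapply(draws, function(d)
      sequestration_integral(depth_m, d$density, d$flux_at_zmax, g, region),
      numeric(1))
    exp_d <- vapply(draws, function(d) d$export_100, numeric(1))
    dur_d <- ifelse(exp_d > 0, areal_d * 1000 / (exp_d * region$days_per_year), NA)
    out$intervals <- data.frame(
      quantity = c("export_100", "areal_molC_m2", "mean_duration_yr", "regional_PgC"),
      rbind(percentile_interval(exp_d, level),
            percentile_interval(areal_d, level),
            percentile_interval(dur_d, level),
            percentile_interval(regional_total(pmax(areal_d, 0), region), level)))
    names(out$intervals)[2:3] <- c("lower", "upper")
  }
  structure(out, class = "pathway_budget")
}

#' @export
print.pathway_budget <- function(x, ...) {
  cat(sprintf("%s: export %.2g mmol C m-2 d-1 at 100 m; %.0f mol C m-2 areal; %.0f yr mean duration; %.2g Pg C regional\n",
              x$pathway, x$export_100, x$areal_molC_m2, x$mean_duration_yr,
              x$regional_PgC))
  invisible(x)
}

#' Summarize pathway budgets as a one-row-per-pathway table
#'
#' @param budgets list of `pathway_budget`s.
#' @return data frame shaped like the regional summary table (export, mean
#'   duration, areal and regional sequestration per pathway).
#' @export
budget_table <- function(budgets) {
  stopifnot(all(vapply(budgets, inherits, logical(1), "pathway_budget")))
  data.frame(
    pathway = vapply(budgets, function(b) b$pathway, character(1)),
    export_100_mmolC_m2_d = vapply(budgets, function(b) b$export_100, numeric(1)),
    mean_duration_yr = vapply(budgets, function(b) b$mean_duration_yr, numeric(1)),
    areal_molC_m2 = vapply(budgets, function(b) b$areal_molC_m2, numeric(1)),
    regional_PgC = vapply(budgets, function(b) b$regional_PgC, numeric(1)))
}
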