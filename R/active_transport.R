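#' Bioenergetics parameters for migrant respiration and excretion
#'
#' Carbon-specific respiration follows the classic allometric form
#' `ln R = a0 + a1 ln(DW) + a2 T` with R the individual respiration in
#' ul O2 ind-1 h-1, DW the body dry weight in mg and T the ambient
#' temperature in deg C. Oxygen consumption is converted to respired carbon
#' through a respiratory quotient and divided by body carbon to give a
#' carbon-specific rate (d-1). The default coefficients are editable
#' transcription-style values for mesozooplankton allometries (mass exponent
#' ~0.8, temperature coefficient 0.069 ~ Q10 of 2); users fitting a specific
#' taxon should supply the coefficients from the relevant compilation.
#'
#' @param coefficients data frame with columns `taxon`, `a0`, `a1`, `a2`.
#' @param respiratory_quotient mol CO2 respired per mol O2 consumed.
#' @param carbon_fraction_dw body carbon as a fraction of dry weight.
#' @param excretion_fraction dissolved organic carbon excretion as a
#'   fraction of respiration (default 0.31).
#' @param fish_residence_mean,fish_residence_sd daytime residence depth of
#'   vertically migrating mesopelagic fish: normal with mean 450 m, sd 50 m.
#' @param profile_floor_m deepest depth of the resolved transport profile.
#' @param deep_temperature_C temperature assigned to the 450--600 m
#'   residence stratum (below the tow's sensor range).
#' @param size_bins size-bin table (see [size_bin_table()]) used to assign a
#'   representative body mass per bin.
#' @return object of class `bioenergetics_params`.
#' @export
bioenergetics_params <- function(coefficients = data.frame(
                                   taxon = c("copepods", "euphausiids",
                                             "chaetognaths", "others"),
                                   a0 = c(-0.40, -0.25, -0.45, -0.30),
                                   a1 = c(0.80, 0.79, 0.80, 0.79),
                                   a2 = c(0.069, 0.069, 0.069, 0.069)),
                                 respiratory_quotient = 0.87,
                                 carbon_fraction_dw = 0.40,
                                 excretion_fraction = 0.31,
                                 fish_residence_mean = 450,
                                 fish_residence_sd = 50,
                                 profile_floor_m = 600,
                                 deep_temperature_C = 6,
                                 size_bins = size_bin_table()) {
  if (fish_residence_sd <= 0)
    stopf("bioenergetics_params: fish residence sd must be > 0")
  if (excretion_fraction < 0)
    stopf("bioenergetics_params: excretion_fraction must be >= 0")
  structure(list(coefficients = coefficients,
                 respiratory_quotient = respiratory_quotient,
                 carbon_fraction_dw = carbon_fraction_dw,
                 excretion_fraction = excretion_fraction,
                 fish_residence_mean = fish_residence_mean,
                 fish_residence_sd = fish_residence_sd,
                 profile_floor_m = profile_floor_m,
                 deep_temperature_C = deep_temperature_C,
                 size_bins = size_bins),
            class = "bioenergetics_params")
}

validate_tow <- function(tow) {
  req <- c("experiment_id", "taxon", "size_bin", "stratum_top_m",
           "stratum_bottom_m", "day_night", "biomass_mgC_m3")
  miss <- setdiff(req, names(tow))
  if (length(miss)) stopf("tow table: missing column(s) %s", paste(miss, collapse = ", "))
  if (any(tow$biomass_mgC_m3 < 0)) stopf("tow table: biomass must be >= 0")
  if (!all(tow$day_night %in% c("day", "night")))
    stopf("tow table: day_night must be 'day' or 'night'")
  tow
}

tow_integral <- function(tow, taxon, phase) {
  sub <- tow[tow$taxon == taxon & tow$day_night == phase, ]
  sum(sub$biomass_mgC_m3 * (sub$stratum_bottom_m - sub$stratum_top_m))
}

#' Adjust daytime euphausiid biomass for net avoidance
#'
#' Euphausiids avoid nets most effectively in daylight, biasing daytime
#' biomass low. All daytime euphausiid strata are multiplied by the ratio of
#' the nighttime to daytime vertically integrated biomass so the integrals
#' match; other taxa are untouched.
#'
#' @param tow tow data frame (single experiment).
#' @param taxon taxon label treated as euphausiids.
#' @return adjusted tow data frame.
#' @export
adjust_euphausiid_day <- function(tow, taxon = "euphausiids") {
  tow <- validate_tow(tow)
  if (!taxon %in% tow$taxon)
    stopf("adjust_euphausiid_day: taxon '%s' not present in the tow", taxon)
  for (e in unique(tow$experiment_id)) {
    sel <- tow$experiment_id == e
    day_int <- tow_integral(tow[sel, ], taxon, "day")
    night_int <- tow_integral(tow[sel, ], taxon, "night")
    if (day_int == 0 && night_int == 0) next
    if (day_int == 0)
      stopf("adjust_euphausiid_day: experiment %s has zero daytime euphausiid biomass but nonzero nighttime biomass; scaling undefined", e)
    k <- sel & tow$taxon == taxon & tow$day_night == "day"
    tow$biomass_mgC_m3[k] <- tow$biomass_mgC_m3[k] * night_int / day_int
  }
  tow
}

#' Migrant biomass residing below a depth horizon
#'
#' For each (taxon, size class), the night-minus-day biomass difference
#' vertically integrated above the horizon, floored at zero (reverse
#' migrants are not counted). A single-experiment tow is expected.
#'
#' @param tow tow data frame.
#' @param horizon depth horizon (m); must coincide with a stratum edge.
#' @return data frame with `taxon`, `size_bin`, `migrant_mgC_m2`.
#' @export
migrant_biomass_below <- function(tow, horizon) {
  tow <- validate_tow(tow)
  edges <- sort(unique(c(tow$stratum_top_m, tow$stratum_bottom_m)))
  if (!horizon %in% edges)
    stopf("migrant_biomass_below: horizon %g m is not a stratum edge", horizon)
  above <- tow[tow$stratum_bottom_m <= horizon, ]
  keys <- unique(tow[, c("taxon", "size_bin")])
  mig <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- above[above$taxon == keys$taxon[i] & above$size_bin == keys$size_bin[i], ]
    thick <- sub$stratum_bottom_m - sub$stratum_top_m
    night <- sum(sub$biomass_mgC_m3[sub$day_night == "night"] *
                   thick[sub$day_night == "night"])
    day <- sum(sub$biomass_mgC_m3[sub$day_night == "day"] *
                 thick[sub$day_night == "day"])
    mig[i] <- max(0, night - day)
  }
  data.frame(keys, migrant_mgC_m2 = mig, row.names = NULL)
}

#' Daytime residence distribution of migrant biomass
#'
#' Differences the migrant-below-horizon curve across the 50-m horizons
#' 100, 150, ..., 450 m: biomass residing in [h, h+50) is
#' `migrant_biomass_below(h) - migrant_biomass_below(h + 50)`, floored at
#' zero; the residue still unaccounted for below 450 m is assigned to a
#' single 450--600 m stratum (the deepest depths zooplankton commonly reach).
#' Temperature per stratum is taken from the daytime tow (the deep stratum
#' uses `deep_temperature_C`), and each size bin carries its representative
#' body mass.
#'
#' @param tow tow data frame (single experiment).
#' @param params a [bioenergetics_params()].
#' @return object of class `migrant_profile`: data frame with taxon,
#'   size_bin, residence stratum, biomass (mg C m-2), temperature and
#'   representative mass.
#' @export
residence_distribution <- function(tow, params = bioenergetics_params()) {
  tow <- validate_tow(tow)
  horizons <- seq(100, 450, by = 50)
  mb <- lapply(horizons, function(h) migrant_biomass_below(tow, h)$migrant_mgC_m2)
  keys <- unique(tow[, c("taxon", "size_bin")])
  # stratum temperature from the daytime tow
  day <- tow[tow$day_night == "day", ]
  strat_temp <- function(top) {
    t <- day$temperature_C[day$stratum_top_m == top]
    if (length(t)) mean(t) else params$deep_temperature_C
  }
  out <- list()
  for (k in seq_along(horizons)) {
    top <- horizons[k]
    biom <- if (k < length(horizons)) pmax(0, mb[[k]] - mb[[k + 1]]) else mb[[k]]
    bottom <- if (k < length(horizons)) top + 50 else 600
    temp <- if (k < length(horizons)) strat_temp(top) else params$deep_temperature_C
    out[[k]] <- data.frame(keys, stratum_top_m = top, stratum_bottom_m = bottom,
                           biomass_mgC_m2 = biom, temperature_C = temp,
                           row.names = NULL)
  }
  prof <- do.call(rbind, out)
  prof$rep_mass_mgC <- params$size_bins$rep_mass_mgC[
    match(prof$size_bin, params$size_bins$size_bin)]
  class(prof) <- c("migrant_profile", class(prof))
  prof
}

#' Carbon-specific respiration rate from allometry
#'
#' @param taxon taxon label (matched against the coefficient table).
#' @param body_mass body carbon mass, mg C.
#' @param temperature ambient temperature, deg C.
#' @param params a [bioenergetics_params()].
#' @return carbon-specific respiration rate, d-1.
#' @export
specific_respiration <- function(taxon, body_mass, temperature,
                                 params = bioenergetics_params()) {
  if (any(body_mass <= 0)) stopf("specific_respiration: body mass must be > 0")
  co <- params$coefficients
  idx <- match(taxon, co$taxon)
  if (anyNA(idx))
    stopf("specific_respiration: no allometric coefficients for taxon '%s'",
          paste(unique(taxon[is.na(idx)]), collapse = "', '"))
  dw <- body_mass / params$carbon_fraction_dw
  r_ul_o2_h <- exp(co$a0[idx] + co$a1[idx] * log(dw) + co$a2[idx] * temperature)
  # ul O2 h-1 -> umol O2 h-1 (22.414 ul/umol at STP) -> mg C h-1 -> mg C d-1
  resp_mgC_d <- r_ul_o2_h / 22.414 * params$respiratory_quotient * 12.011e-3 * 24
  resp_mgC_d / body_mass
}

split_strata_50m <- function(strata) {
  # slice wide strata (e.g. the 450-600 m residence stratum) into 50-m
  # pieces at the same volumetric rate so profiles share a common grid
  pieces <- lapply(seq_len(nrow(strata)), function(i) {
    tops <- seq(strata$top[i], strata$bottom[i] - 50, by = 50)
    data.frame(top = tops, bottom = tops + 50,
               vol_rate_mmolC_m3_d = strata$vol_rate_mmolC_m3_d[i])
  })
  out <- do.call(rbind, pieces)
  agg <- stats::aggregate(vol_rate_mmolC_m3_d ~ top + bottom, out, sum)
  agg[order(agg$top), ]
}

transport_profile_new <- function(strata, experiment_id = NA_character_,
                                  pathway = "active_transport") {
  # strata: data frame top, bottom, vol_rate_mmolC_m3_d; horizons from edges
  strata <- split_strata_50m(strata)
  horizons <- sort(unique(c(strata$top, strata$bottom)))
  flux <- vapply(horizons, function(h) {
    sub <- strata[strata$top >= h, ]
    sum(sub$vol_rate_mmolC_m3_d * (sub$bottom - sub$top))
  }, numeric(1))
  structure(list(experiment_id = experiment_id, pathway = pathway,
                 strata = strata,
                 flux = data.frame(horizon_m = horizons,
                                   flux_mmolC_m2_d = flux)),
            class = "transport_profile")
}

#' @export
print.transport_profile <- function(x, ...) {
  f100 <- x$flux$flux_mmolC_m2_d[x$flux$horizon_m == 100]
  cat(sprintf("Transport profile (%s%s): flux across 100 m = %.3g mmol C m-2 d-1\n",
              x$pathway,
              if (is.na(x$experiment_id)) "" else paste0(", ", x$experiment_id),
              if (length(f100)) f100 else NA))
  invisible(x)
}

#' Transport flux across a horizon
#'
#' @param profile a `transport_profile`.
#' @param horizon depth horizon(s), m (must be stratum edges).
#' @return flux in mmol C m-2 d-1.
#' @export
transport_flux_at <- function(profile, horizon) {
  stopifnot(inherits(profile, "transport_profile"))
  idx <- match(horizon, profile$flux$horizon_m)
  if (anyNA(idx))
    stopf("transport_flux_at: horizon not on the profile's stratum edges")
  profile$flux$flux_mmolC_m2_d[idx]
}

#' Active-transport profile of migrating zooplankton
#'
#' Converts a daytime residence distribution into volumetric respiration +
#' excretion per stratum (biomass times the carbon-specific allometric rate
#' at the stratum temperature, times 1 + excretion fraction, divided by
#' stratum thickness) and integrates it into flux across each horizon.
#'
#' @param profile a [residence_distribution()] result.
#' @param params a [bioenergetics_params()].
#' @param experiment_id optional label.
#' @return a `transport_profile` (fluxes in mmol C m-2 d-1, volumetric rates
#'   in mmol C m-3 d-1).
#' @export
zoop_transport_profile <- function(profile, params = bioenergetics_params(),
                                   experiment_id = NA_character_) {
  stopifnot(inherits(profile, "migrant_profile"))
  rate <- specific_respiration(profile$taxon, profile$rep_mass_mgC,
                               profile$temperature_C, params)
  # mg C m-2 d-1 per row, converted to mmol and to a volumetric rate
  row_flux <- profile$biomass_mgC_m2 * rate * (1 + params$excretion_fraction) / 12.011
  thick <- profile$stratum_bottom_m - profile$stratum_top_m
  agg <- stats::aggregate(list(vol = row_flux / thick),
                          by = list(top = profile$stratum_top_m,
                                    bottom = profile$stratum_bottom_m),
                          FUN = sum)
  names(agg)[names(agg) == "vol"] <- "vol_rate_mmolC_m3_d"
  transport_profile_new(agg, experiment_id, "zooplankton")
}

#' Active-transport profile of vertically migrating fish
#'
#' Distributes the bioenergetic respiration + excretion total over depth
#' according to the fish daytime residence density: normal with mean 450 m
#' and sd 50 m, truncated below at 100 m and renormalized so the flux across
#' 100 m equals the input total; the small tail below the profile floor is
#' absorbed into the deepest stratum.
#'
#' @param total_respiration total fish-mediated flux across 100 m,
#'   mmol C m-2 d-1.
#' @param params a [bioenergetics_params()].
#' @param experiment_id optional label.
#' @return a `transport_profile`.
#' @export
fish_transport_profile <- function(total_respiration,
                                   params = bioenergetics_params(),
                                   experiment_id = NA_character_) {
  if (total_respiration < 0)
    stopf("fish_transport_profile: total respiration must be >= 0")
  mu <- params$fish_residence_mean; s <- params$fish_residence_sd
  tops <- seq(100, params$profile_floor_m - 50, by = 50)
  Z <- 1 - pnorm(100, mu, s)
  upper <- c(tops[-1], Inf)  # deepest stratum absorbs the sub-floor tail
  mass <- (pnorm(upper, mu, s) - pnorm(tops, mu, s)) / Z
  strata <- data.frame(top = tops, bottom = tops + 50,
                       vol_rate_mmolC_m3_d = total_respiration * mass / 50)
  transport_profile_new(strata, experiment_id, "fish")
}

#' Sum transport profiles stratum-wise
#'
#' @param ... `transport_profile` objects on compatible strata.
#' @return a combined `transport_profile`.
#' @export
sum_transport_profiles <- function(...) {
  profs <- list(...)
  if (length(profs) == 1 && is.list(profs[[1]]) &&
      !inherits(profs[[1]], "transport_profile")) profs <- profs[[1]]
  stopifnot(all(vapply(profs, inherits, logical(1), "transport_profile")))
  all_strata <- do.call(rbind, lapply(profs, function(p)
    p$strata[, c("top", "bottom", "vol_rate_mmolC_m3_d")]))
  agg <- stats::aggregate(vol_rate_mmolC_m3_d ~ top + bottom, all_strata, sum)
  transport_profile_new(agg, profs[[1]]$experiment_id, "active_transport")
}

#' Bootstrap regional mean of transport profiles
#'
#' Resamples experiments with replacement, averages the flux across each
#' horizon per resample and returns the arithmetic mean with a central
#' percentile interval.
#'
#' @param profiles list of `transport_profile`s (one per experiment) or a
#'   numeric matrix (rows = experiments, columns = horizons).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param level interval coverage.
#' @return data frame `horizon_m`, `mean`, `lower`, `upper`, plus the
#'   bootstrap replicate means as attribute `"replicates"`.
#' @export
regional_mean_bootstrap <- function(profiles, n_boot = 1000, seed = 1,
                                    level = 0.95) {
  if (is.list(profiles) && all(vapply(profiles, inherits, logical(1),
                                      "transport_profile"))) {
    horizons <- sort(unique(unlist(lapply(profiles, function(p) p$flux$horizon_m))))
    mat <- t(vapply(profiles, function(p) {
      approx(p$flux$horizon_m, p$flux$flux_mmolC_m2_d, xout = horizons,
             rule = 2)$y
    }, numeric(length(horizons))))
  } else {
    mat <- as.matrix(profiles)
    horizons <- as.numeric(colnames(mat) %||% seq_len(ncol(mat)))
  }
  if (nrow(mat) < 2)
    stopf("regional_mean_bootstrap: need at least 2 experiments")
  if (n_boot < 200) warnf("regional_mean_bootstrap: n_boot < 200")
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, ncol(mat))
  for (r in seq_len(n_boot)) {
    idx <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
    reps[r, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  ci <- apply(reps, 2, percentile_interval, level = level)
  out <- data.frame(horizon_m = horizons, mean = colMeans(mat),
                    lower = ci[1, ], upper = ci[2, ])
  attr(out, "replicates") <- reps
  out
}
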