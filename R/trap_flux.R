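#' Sum of squared normalized misfits of a power-law flux model
#'
#' The likelihood kernel of the attenuation fit: for deployment i with
#' measurements (z_ij, F_ij, sigma_ij) and model flux
#' `f100_i * (z_ij/100)^(-b)`,
#' `SSNM = sum_ij (F_ij - f100_i (z_ij/100)^-b)^2 / sigma_ij^2`.
#'
#' @param deployments trap data frame (columns `deployment_id`, `depth_m`,
#'   `flux_mean_mmolC_m2_d`, `flux_sd_mmolC_m2_d`).
#' @param b power-law exponent.
#' @param f100 per-deployment 100-m flux: named vector (names = deployment
#'   ids) or unnamed vector in order of first appearance.
#' @return non-negative scalar; zero iff every measurement lies exactly on
#'   its deployment's curve.
#' @export
compute_ssnm <- function(deployments, b, f100) {
  d <- validate_trap_deployments(deployments)
  ids <- unique(d$deployment_id)
  if (is.null(names(f100))) {
    if (length(f100) != length(ids))
      stopf("compute_ssnm: f100 has %d values for %d deployments",
            length(f100), length(ids))
    f100 <- setNames(f100, ids)
  }
  fi <- f100[d$deployment_id]
  if (anyNA(fi)) stopf("compute_ssnm: missing f100 for some deployments")
  pred <- fi * (d$depth_m / 100)^(-b)
  sum((d$flux_mean_mmolC_m2_d - pred)^2 / d$flux_sd_mmolC_m2_d^2)
}

validate_trap_deployments <- function(deployments) {
  req <- c("deployment_id", "depth_m", "flux_mean_mmolC_m2_d", "flux_sd_mmolC_m2_d")
  miss <- setdiff(req, names(deployments))
  if (length(miss))
    stopf("trap deployments: missing column(s) %s", paste(miss, collapse = ", "))
  if (any(deployments$depth_m <= 0)) stopf("trap deployments: depths must be positive")
  if (any(deployments$flux_mean_mmolC_m2_d < 0))
    stopf("trap deployments: fluxes must be >= 0")
  bad <- deployments$flux_sd_mmolC_m2_d <= 0 | !is.finite(deployments$flux_sd_mmolC_m2_d)
  if (any(bad))
    stopf("trap deployments: zero or non-finite flux SD in deployment(s) %s; every measurement entering the likelihood needs sigma > 0 (see floor_trap_sd())",
          paste(unique(deployments$deployment_id[bad]), collapse = ", "))
  dup <- tapply(deployments$depth_m, deployments$deployment_id,
                function(z) anyDuplicated(z) > 0)
  if (any(dup))
    stopf("trap deployments: duplicated depths within deployment(s) %s",
          paste(names(dup)[dup], collapse = ", "))
  deployments
}

#' Floor trap flux uncertainties at a fraction of the flux mean
#'
#' Preprocessing helper for deployments whose replicate SD collapsed to zero
#' (or is implausibly small): sigma is floored at `fraction` of the flux
#' mean, with an absolute floor for zero-flux measurements.
#'
#' @param deployments trap data frame.
#' @param fraction floor as a fraction of the flux mean (default 5%).
#' @param abs_floor absolute floor (mmol C m-2 d-1) applied when the flux
#'   mean itself is zero.
#' @return the data frame with floored `flux_sd_mmolC_m2_d`.
#' @export
floor_trap_sd <- function(deployments, fraction = 0.05, abs_floor = 1e-3) {
  floor_val <- pmax(fraction * deployments$flux_mean_mmolC_m2_d, abs_floor)
  deployments$flux_sd_mmolC_m2_d <- pmax(deployments$flux_sd_mmolC_m2_d, floor_val,
                                         na.rm = TRUE)
  deployments
}

#' Metropolis acceptance ratio for the attenuation sampler
#'
#' Returns `exp(-(ssnm_new - ssnm_old)/2) * prior_new / prior_old`, computed
#' in log space so large misfits do not underflow. The caller accepts the
#' proposal when a uniform draw is below `min(1, value)`.
#'
#' @param ssnm_old,ssnm_new misfit at the current and proposed state.
#' @param prior_old,prior_new prior densities at the current and proposed
#'   state (joint over all parameters).
#' @return probability-like scalar (may exceed 1).
#' @export
metropolis_accept_prob <- function(ssnm_old, ssnm_new, prior_old, prior_new) {
  if (!is.finite(ssnm_old) || !is.finite(ssnm_new))
    stopf("metropolis_accept_prob: SSNM values must be finite")
  if (prior_old < 0 || prior_new < 0)
    stopf("metropolis_accept_prob: prior densities must be >= 0")
  if (prior_old == 0)
    stopf("metropolis_accept_prob: current state has zero prior density (invalid chain state)")
  if (prior_new == 0) return(0)
  exp(-0.5 * (ssnm_new - ssnm_old) + (log(prior_new) - log(prior_old)))
}

#' MCMC configuration for the attenuation fit
#'
#' Defaults follow the full-length production chain: 1e7 iterations with the
#' first 1e6 discarded as burn-in, initial exponent 1.2, initial 100-m fluxes
#' 9 mmol C m-2 d-1, normal prior N(1.2, 0.5) on the exponent and a uniform
#' prior on (0, 5000) mmol C m-2 d-1 for every per-deployment flux. Proposal
#' standard deviations are not dictated by the posterior width alone, so an
#' optional pre-burn-in adaptive phase (frozen well before retained samples)
#' can rescale them toward 10--40% acceptance.
#'
#' @param n_iter,n_burn total and burn-in iterations.
#' @param b_init,f_init initial exponent and per-deployment flux; `f_init =
#'   "shallow"` starts each deployment's flux at its shallowest measurement
#'   rescaled to 100 m with `b_init`, which shortens the burn-in transient
#'   for short chains.
#' @param b_prior_mean,b_prior_sd normal prior on the exponent.
#' @param f_prior_bounds uniform prior support for the 100-m fluxes.
#' @param proposal_sd_b,proposal_sd_f random-walk proposal SDs.
#' @param seed RNG seed for the chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param blockwise propose all parameters jointly with a single
#'   accept/reject (the described algorithm); `FALSE` gives a componentwise
#'   variant with better mixing.
#' @param adapt enable the pre-burn-in proposal-scale adaptation.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 1e7, n_burn = 1e6, b_init = 1.2, f_init = 9,
                        b_prior_mean = 1.2, b_prior_sd = 0.5,
                        f_prior_bounds = c(0, 5000),
                        proposal_sd_b = 0.01, proposal_sd_f = 0.5,
                        seed = 1, thin = 100, blockwise = TRUE, adapt = FALSE) {
  if (n_burn >= n_iter) stopf("mcmc_config: n_burn must be < n_iter")
  if (proposal_sd_b <= 0 || proposal_sd_f <= 0)
    stopf("mcmc_config: proposal SDs must be > 0")
  if (thin < 1) stopf("mcmc_config: thin must be >= 1")
  structure(list(n_iter = n_iter, n_burn = n_burn, b_init = b_init,
                 f_init = f_init, b_prior_mean = b_prior_mean,
                 b_prior_sd = b_prior_sd, f_prior_bounds = f_prior_bounds,
                 proposal_sd_b = proposal_sd_b, proposal_sd_f = proposal_sd_f,
                 seed = as.integer(seed), thin = thin, blockwise = blockwise,
                 adapt = adapt),
            class = "mcmc_config")
}

#' Fit the power-law flux attenuation by Metropolis MCMC
#'
#' Samples the posterior of the shared attenuation exponent b and the
#' per-deployment 100-m fluxes under the normalized-misfit likelihood
#' `exp(-SSNM/2)` with a normal prior on b and uniform priors on the fluxes.
#' By default all parameters are proposed jointly from independent normal
#' random walks with a single accept/reject per iteration.
#'
#' @param deployments trap data frame (see [compute_ssnm()]).
#' @param cfg an [mcmc_config()].
#' @return object of class `attenuation_posterior`: `b_samples`,
#'   `f100_samples` (matrix, one column per deployment), `acceptance_rate`,
#'   a `summary` data frame (mean, median, central 95% interval per
#'   parameter) and the frozen proposal scale.
#' @export
fit_attenuation_mcmc <- function(deployments, cfg = mcmc_config()) {
  stopifnot(inherits(cfg, "mcmc_config"))
  d <- validate_trap_deployments(deployments)
  ids <- unique(d$deployment_id)
  d <- d[order(match(d$deployment_id, ids), d$depth_m), , drop = FALSE]
  dep_idx <- match(d$deployment_id, ids) - 1L
  f_init <- if (identical(cfg$f_init, "shallow")) {
    vapply(ids, function(id) {
      sub <- d[d$deployment_id == id, ]
      j <- which.min(sub$depth_m)
      min(max(sub$flux_mean_mmolC_m2_d[j] * (sub$depth_m[j] / 100)^cfg$b_init,
              1e-3), 4999)
    }, numeric(1))
  } else rep_len(cfg$f_init, length(ids))
  set.seed(cfg$seed)
  res <- metropolis_chain_cpp(
    flux = d$flux_mean_mmolC_m2_d, sdv = d$flux_sd_mmolC_m2_d,
    depth = d$depth_m, dep = dep_idx, n_dep = length(ids),
    b_init = cfg$b_init, f_init = f_init,
    b_prior_mean = cfg$b_prior_mean, b_prior_sd = cfg$b_prior_sd,
    f_lo = cfg$f_prior_bounds[1], f_hi = cfg$f_prior_bounds[2],
    prop_b = cfg$proposal_sd_b, prop_f = cfg$proposal_sd_f,
    n_iter = cfg$n_iter, n_burn = cfg$n_burn, thin = cfg$thin,
    blockwise = cfg$blockwise, adapt = cfg$adapt)
  if (res$acceptance_rate < 0.01)
    warnf("fit_attenuation_mcmc: post-burn-in acceptance rate %.2g%% < 1%%; consider smaller proposal SDs (currently proposal_sd_b = %g, proposal_sd_f = %g) or adapt = TRUE",
          100 * res$acceptance_rate, cfg$proposal_sd_b, cfg$proposal_sd_f)
  colnames(res$f_samples) <- ids
  summ <- function(x) c(mean = mean(x), median = median(x),
                        q2.5 = unname(quantile(x, 0.025)),
                        q97.5 = unname(quantile(x, 0.975)))
  stats <- rbind(b = summ(res$b_samples),
                 t(apply(res$f_samples, 2, summ)))
  structure(list(b_samples = res$b_samples, f100_samples = res$f_samples,
                 acceptance_rate = res$acceptance_rate,
                 proposal_scale = res$scale,
                 summary = data.frame(parameter = rownames(stats), stats,
                                      row.names = NULL),
                 deployment_ids = ids, config = cfg),
            class = "attenuation_posterior")
}

#' @export
print.attenuation_posterior <- function(x, ...) {
  b <- x$summary[x$summary$parameter == "b", ]
  cat(sprintf("Attenuation posterior: b = %.3f (95%% CI %.3f-%.3f), %d deployments, acceptance %.1f%%\n",
              b$mean, b$q2.5, b$q97.5, length(x$deployment_ids),
              100 * x$acceptance_rate))
  invisible(x)
}

#' Regional power-law flux curve
#'
#' `F(z) = F100 * (z/100)^(-b)` for z >= 100 m, with optional posterior /
#' Monte Carlo draws of both parameters for uncertainty propagation.
#'
#' @param F100_mean regional mean 100-m flux (mmol C m-2 d-1).
#' @param b_mean regional mean attenuation exponent.
#' @param F100_samples,b_samples optional draws for propagation.
#' @return object of class `flux_curve`.
#' @export
flux_curve <- function(F100_mean, b_mean, F100_samples = NULL, b_samples = NULL) {
  if (F100_mean <= 0 || b_mean <= 0)
    stopf("flux_curve: F100_mean and b_mean must be > 0")
  structure(list(F100_mean = F100_mean, b_mean = b_mean,
                 F100_samples = F100_samples, b_samples = b_samples,
                 valid_from = 100),
            class = "flux_curve")
}

#' Evaluate the regional flux curve at depth
#'
#' @param curve a [flux_curve()].
#' @param z depth(s), m; must be >= 100 m (the curve is undefined above its
#'   100-m anchor).
#' @return flux in mmol C m-2 d-1.
#' @export
flux_at_depth <- function(curve, z) {
  stopifnot(inherits(curve, "flux_curve"))
  if (any(z < curve$valid_from))
    stopf("flux_at_depth: curve undefined above %g m", curve$valid_from)
  curve$F100_mean * (z / 100)^(-curve$b_mean)
}

#' Monte Carlo uncertainty interval for the flux curve at depth
#'
#' Nonparametric propagation: draws (F100, b) pairs from the stored samples
#' (with replacement, independently when the sample vectors differ in
#' length), evaluates the curve per draw and returns a central percentile
#' interval.
#'
#' @param curve a [flux_curve()] carrying `F100_samples` and `b_samples`.
#' @param z depth, m.
#' @param n_draws Monte Carlo draws.
#' @param seed RNG seed.
#' @param level interval coverage (default 0.95).
#' @return length-2 vector (lower, upper).
#' @export
propagate_flux_uncertainty <- function(curve, z, n_draws = 1e4, seed = 1,
                                       level = 0.95) {
  stopifnot(inherits(curve, "flux_curve"))
  if (is.null(curve$F100_samples) || is.null(curve$b_samples))
    stopf("propagate_flux_uncertainty: curve carries no parameter samples")
  if (any(z < curve$valid_from))
    stopf("propagate_flux_uncertainty: curve undefined above %g m", curve$valid_from)
  if (n_draws < 100) warnf("propagate_flux_uncertainty: n_draws < 100")
  set.seed(seed)
  nf <- length(curve$F100_samples); nb <- length(curve$b_samples)
  if (nf == nb) {
    idx <- sample.int(nf, n_draws, replace = TRUE)
    fs <- curve$F100_samples[idx]; bs <- curve$b_samples[idx]
  } else {
    fs <- curve$F100_samples[sample.int(nf, n_draws, replace = TRUE)]
    bs <- curve$b_samples[sample.int(nb, n_draws, replace = TRUE)]
  }
  percentile_interval(fs * (z / 100)^(-bs), level)
}

#' Remineralization density of the sinking-flux curve
#'
#' The per-metre loss of flux, `-dF/dz = b * F100 * 100^b * z^(-b-1)`
#' (mmol C m-3 d-1); its integral from 100 m to infinity equals F100.
#'
#' @param curve a [flux_curve()].
#' @param z depth(s), m (>= 100).
#' @return density in mmol C m-3 d-1.
#' @export
remineralization_density <- function(curve, z) {
  stopifnot(inherits(curve, "flux_curve"))
  if (any(z < curve$valid_from))
    stopf("remineralization_density: curve undefined above %g m", curve$valid_from)
  b <- curve$b_mean
  b * curve$F100_mean * 100^b * z^(-b - 1)
}

#' Empirical e-ratio model (export efficiency vs SST)
#'
#' Linear model `e-ratio = slope * SST + intercept` relating the fraction of
#' net primary production exported as sinking particles to sea-surface
#' temperature; the defaults are the regional regression coefficients
#' (slope 0.056 +- 0.008 per deg C, intercept -0.698 +- 0.122).
#'
#' @param slope,intercept regression coefficients.
#' @param slope_sd,intercept_sd their standard errors (for Monte Carlo
#'   propagation).
#' @return object of class `e_ratio_model`.
#' @export
e_ratio_model <- function(slope = 0.056, intercept = -0.698,
                          slope_sd = 0.008, intercept_sd = 0.122) {
  if (slope <= 0) stopf("e_ratio_model: slope must be > 0")
  structure(list(slope = slope, intercept = intercept,
                 slope_sd = slope_sd, intercept_sd = intercept_sd),
            class = "e_ratio_model")
}

#' Export efficiency from sea-surface temperature
#'
#' Evaluates the linear e-ratio model and clips the result into [0, 1] (the
#' regression line goes negative at low SST, where a negative export
#' fraction has no meaning); clipping is reported via a message.
#'
#' @param sst sea-surface temperature(s), deg C.
#' @param model an [e_ratio_model()].
#' @return e-ratio value(s) in [0, 1].
#' @export
e_ratio <- function(sst, model = e_ratio_model()) {
  stopifnot(inherits(model, "e_ratio_model"))
  if (any(!is.finite(sst))) stopf("e_ratio: SST must be finite")
  raw <- model$slope * sst + model$intercept
  clipped <- pmin(1, pmax(0, raw))
  n_clip <- sum(clipped != raw)
  if (n_clip > 0)
    message(sprintf("e_ratio: clipped %d of %d value(s) into [0, 1]",
                    n_clip, length(raw)))
  clipped
}

#' Regional mean 100-m sinking flux from NPP and SST fields
#'
#' Applies the e-ratio model cellwise (`flux = e_ratio(SST) * NPP`) and
#' returns the area-weighted mean over valid cells.
#'
#' @param npp_field net primary production grid (mmol C m-2 d-1).
#' @param sst_field congruent SST grid (deg C).
#' @param model an [e_ratio_model()].
#' @param weights optional congruent grid of cell areas/weights.
#' @return regional mean flux, mmol C m-2 d-1.
#' @export
regional_F100 <- function(npp_field, sst_field, model = e_ratio_model(),
                          weights = NULL) {
  if (!all(dim(as.matrix(npp_field)) == dim(as.matrix(sst_field))))
    stopf("regional_F100: NPP and SST grids are not congruent")
  npp <- as.numeric(npp_field); sst <- as.numeric(sst_field)
  w <- if (is.null(weights)) rep(1, length(npp)) else as.numeric(weights)
  ok <- is.finite(npp) & is.finite(sst) & is.finite(w)
  if (!any(ok)) stopf("regional_F100: no valid cells in the input grids")
  flux <- suppressMessages(e_ratio(sst[ok], model)) * npp[ok]
  sum(flux * w[ok]) / sum(w[ok])
}
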