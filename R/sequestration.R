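#' Shape-preserving interpolant of sequestration time versus depth
#'
#' Fits a Fritsch--Carlson monotone piecewise-cubic Hermite interpolant
#' through the (depth, g) knots. Evaluation clamps to the knot range:
#' constant at g(min depth) above the shallowest knot and at g(max depth)
#' below the deepest knot, mirroring the assumption that carbon
#' remineralized below the deepest release depth carries that depth's
#' sequestration time.
#'
#' @param depth_m knot depths (m), strictly increasing after sorting.
#' @param g_yr sequestration time at each knot (yr).
#' @return a function of depth.
#' @export
fit_g_interpolant <- function(depth_m, g_yr) {
  if (length(depth_m) < 2) stopf("fit_g_interpolant: need at least 2 knots")
  if (anyDuplicated(depth_m)) stopf("fit_g_interpolant: duplicate knot depths")
  o <- order(depth_m)
  z <- depth_m[o]; g <- g_yr[o]
  f <- splinefun(z, g, method = "monoH.FC")
  lo <- z[1]; hi <- z[length(z)]
  function(zz) f(pmin(pmax(zz, lo), hi))
}

validate_fates <- function(fates, horizon) {
  req <- c("release_depth_m", "fate", "elapsed_time_yr", "final_depth_m")
  miss <- setdiff(req, names(fates))
  if (length(miss)) stopf("fate table: missing column(s) %s",
                          paste(miss, collapse = ", "))
  if (!all(fates$fate %in% c("mixed_layer", "survived", "boundary")))
    stopf("fate table: fate must be one of mixed_layer, survived, boundary")
  if (any(fates$elapsed_time_yr <= 0 | fates$elapsed_time_yr > horizon + 1e-9))
    stopf("fate table: elapsed times must lie in (0, horizon]")
  srv <- fates$fate == "survived"
  if (any(abs(fates$elapsed_time_yr[srv] - horizon) > 1e-6))
    stopf("fate table: survived floats must have elapsed time equal to the horizon")
  fates
}

#' Mean sequestration time from float fates (iterative censored-mean)
#'
#' Solves, per release depth z, the fixed point
#' `g(z) = ( sum t_mld + sum (t_f + g(z_final)) + sum (t_b + g(z_final)) ) / n_z`,
#' where the three sums run over floats entrained into the mixed layer,
#' floats still sequestered at the simulation horizon, and floats that hit a
#' domain boundary. The expected remaining time `g(z_final)` of censored
#' floats is read from the current shape-preserving interpolant through the
#' release-depth knots, with final depths clamped into the 100--1000 m knot
#' support (constant beyond). Sweeps update the whole depth vector at once
#' until the largest change is below `tol`. With no censored floats the
#' estimator reduces to the plain sample mean in one sweep.
#'
#' @param fates fate data frame (`release_depth_m`, `fate`,
#'   `elapsed_time_yr`, `final_depth_m`, optionally `cohort`).
#' @param horizon simulation horizon, yr.
#' @param tol convergence tolerance on g, yr.
#' @param max_iter maximum fixed-point sweeps.
#' @return object of class `sequestration_curve`: knot depths, g values, the
#'   interpolating function (`fun`), iteration count, convergence flag and
#'   final residual.
#' @export
estimate_g <- function(fates, horizon, tol = 0.1, max_iter = 1000) {
  fates <- validate_fates(fates, horizon)
  depths <- sort(unique(fates$release_depth_m))
  by_depth <- split(fates, fates$release_depth_m)[as.character(depths)]
  n_mld <- vapply(by_depth, function(d) sum(d$fate == "mixed_layer"), numeric(1))
  if (any(n_mld == 0))
    stopf("estimate_g: release depth(s) %s have no mixed-layer fates; mean sequestration time is undefined without escape mass",
          paste(depths[n_mld == 0], collapse = ", "))
  clamp <- function(z) pmin(pmax(z, 100), 1000)
  g <- vapply(by_depth, function(d) {
    t <- d$elapsed_time_yr[d$fate == "mixed_layer"]
    if (length(t)) mean(t) else horizon
  }, numeric(1))
  make_fun <- function(gv) {
    if (length(depths) == 1) function(z) rep.int(gv, length(z))
    else fit_g_interpolant(depths, gv)
  }
  iter <- 0; converged <- FALSE; resid <- Inf
  while (iter < max_iter) {
    iter <- iter + 1
    fun <- make_fun(g)
    g_new <- vapply(seq_along(depths), function(k) {
      d <- by_depth[[k]]
      cens <- d$fate != "mixed_layer"
      tot <- sum(d$elapsed_time_yr[!cens]) +
        sum(d$elapsed_time_yr[cens] + fun(clamp(d$final_depth_m[cens])))
      tot / nrow(d)
    }, numeric(1))
    resid <- max(abs(g_new - g))
    g <- g_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("estimate_g: no convergence after %d sweeps (last residual %.4g yr at knots [%s])",
          max_iter, resid, paste(signif(g, 6), collapse = ", "))
  structure(list(depth_m = depths, g_yr = unname(g), fun = make_fun(g),
                 iterations = iter, converged = converged, residual = resid,
                 horizon = horizon, cohort_sd_yr = NULL),
            class = "sequestration_curve")
}

#' Evaluate a sequestration-time curve
#'
#' @param object a `sequestration_curve`.
#' @param z depth(s), m.
#' @param ... unused.
#' @return sequestration time(s), yr (constant beyond the knot range).
#' @export
predict.sequestration_curve <- function(object, z, ...) object$fun(z)

#' @export
print.sequestration_curve <- function(x, ...) {
  cat(sprintf("Sequestration-time curve: %d knots, g(%g m) = %.0f yr ... g(%g m) = %.0f yr (%d sweeps)\n",
              length(x$depth_m), x$depth_m[1], x$g_yr[1],
              x$depth_m[length(x$depth_m)], x$g_yr[length(x$g_yr)],
              x$iterations))
  invisible(x)
}

#' Launch-cohort uncertainty of the sequestration-time curve
#'
#' Re-estimates g(z) separately for each launch-year cohort and returns the
#' per-depth standard deviation across cohorts.
#'
#' @param fates fate data frame with a `cohort` column.
#' @param horizon simulation horizon, yr.
#' @param ... passed to [estimate_g()].
#' @return data frame `depth_m`, `g_sd_yr`, with the per-cohort estimates as
#'   attribute `"by_cohort"`.
#' @export
cohort_uncertainty <- function(fates, horizon, ...) {
  if (!"cohort" %in% names(fates)) stopf("cohort_uncertainty: no cohort column")
  cohorts <- unique(fates$cohort)
  if (length(cohorts) < 2)
    stopf("cohort_uncertainty: need at least 2 launch cohorts")
  ests <- lapply(cohorts, function(co)
    estimate_g(fates[fates$cohort == co, ], horizon, ...))
  depths <- ests[[1]]$depth_m
  for (e in ests) if (!identical(e$depth_m, depths))
    stopf("cohort_uncertainty: cohorts cover different release depths")
  gmat <- vapply(ests, function(e) e$g_yr, numeric(length(depths)))
  gmat <- matrix(gmat, nrow = length(depths))
  out <- data.frame(depth_m = depths, g_sd_yr = apply(gmat, 1, sd))
  attr(out, "by_cohort") <- setNames(ests, cohorts)
  out
}
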