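test_that("SSNM is zero at an exact fit and matches hand arithmetic", {
  d1 <- data.frame(deployment_id = "D01", depth_m = 200,
                   flux_mean_mmolC_m2_d = 5, flux_sd_mmolC_m2_d = 1)
  b <- 0.5
  expect_equal(compute_ssnm(d1, b, c(D01 = 5 * 2^b)), 0)
  d2 <- data.frame(deployment_id = "D01", depth_m = c(100, 200),
                   flux_mean_mmolC_m2_d = c(10, 5), flux_sd_mmolC_m2_d = 1)
  expect_equal(compute_ssnm(d2, 1, c(D01 = 9)), (10 - 9)^2 + (5 - 4.5)^2)
})

test_that("SSNM equals an independent double-loop reference on random inputs", {
  set.seed(42)
  for (rep in 1:5) {
    n_dep <- sample(2:6, 1)
    rows <- list()
    for (i in 1:n_dep) {
      nz <- sample(2:5, 1)
      rows[[i]] <- data.frame(deployment_id = sprintf("D%02d", i),
                              depth_m = sort(runif(nz, 60, 900)),
                              flux_mean_mmolC_m2_d = runif(nz, 0.1, 20),
                              flux_sd_mmolC_m2_d = runif(nz, 0.1, 3))
    }
    d <- do.call(rbind, rows)
    b <- runif(1, 0.3, 1.5)
    f100 <- setNames(runif(n_dep, 1, 30), sprintf("D%02d", 1:n_dep))
    ref <- 0
    for (i in 1:n_dep) {
      sub <- d[d$deployment_id == names(f100)[i], ]
      for (j in seq_len(nrow(sub))) {
        pred <- f100[i] * (sub$depth_m[j] / 100)^(-b)
        ref <- ref + (sub$flux_mean_mmolC_m2_d[j] - pred)^2 / sub$flux_sd_mmolC_m2_d[j]^2
      }
    }
    expect_equal(compute_ssnm(d, b, f100), unname(ref), tolerance = 1e-12)
  }
})

test_that("zero replicate SD is rejected with the deployment named, and flooring repairs it", {
  d <- make_exact_traps(c(9, 12), 0.8)
  d$flux_sd_mmolC_m2_d[3] <- 0
  expect_error(compute_ssnm(d, 0.8, c(9, 12)), "D01")
  expect_silent(compute_ssnm(floor_trap_sd(d), 0.8, c(9, 12)))
  expect_equal(floor_trap_sd(d)$flux_sd_mmolC_m2_d[3],
               0.05 * d$flux_mean_mmolC_m2_d[3])
})

test_that("Metropolis acceptance ratio follows the likelihood-times-prior form", {
  expect_equal(metropolis_accept_prob(3, 3, 0.2, 0.2), 1)
  expect_equal(metropolis_accept_prob(3, 5, 0.2, 0.2), exp(-1))
  expect_equal(metropolis_accept_prob(3, 1, 0.2, 0.1), exp(1) / 2)
  expect_equal(metropolis_accept_prob(3, 3, 0.2, 0), 0)  # outside prior support
  expect_error(metropolis_accept_prob(3, 3, 0, 0.2), "zero prior")
  expect_error(metropolis_accept_prob(Inf, 3, 1, 1), "finite")
})

test_that("flux curve is exact at 100 m, strictly decreasing and log-log linear", {
  cv <- flux_curve(9, 0.72)
  expect_equal(flux_at_depth(cv, 100), 9)
  z <- seq(100, 2000, by = 10)
  f <- flux_at_depth(cv, z)
  expect_true(all(diff(f) < 0))
  slope <- coef(lm(log(f) ~ log(z)))[2]
  expect_equal(unname(slope), -0.72, tolerance = 1e-12)
  expect_error(flux_at_depth(cv, 50), "undefined above")
})

test_that("remineralization density conserves flux and gives the 100-200 m loss fraction", {
  cv <- flux_curve(9, 0.72)
  z <- seq(100, 3000, by = 1)
  dens <- remineralization_density(cv, z)
  expect_true(all(dens > 0) && all(diff(dens) < 0))
  total <- pracma::trapz(z, dens) + flux_at_depth(cv, 3000)
  expect_lt(abs(total / 9 - 1), 1e-3)
  frac <- 1 - flux_at_depth(cv, 200) / flux_at_depth(cv, 100)
  expect_equal(round(100 * frac), 39)
})

test_that("e-ratio line is clipped into [0, 1] with its roots where the printed fit crosses", {
  expect_equal(suppressMessages(e_ratio(15)), 0.056 * 15 - 0.698)
  expect_equal(suppressMessages(e_ratio(12.464)), 0, tolerance = 1e-6)
  expect_message(out <- e_ratio(40), "clipped")
  expect_equal(out, 1)
  expect_error(e_ratio(NA), "finite")
})

test_that("regional 100-m flux is the area-weighted e-ratio x NPP mean", {
  npp <- matrix(64.3, 5, 5); sst <- matrix(15, 5, 5)
  expect_equal(regional_F100(npp, sst), 0.142 * 64.3, tolerance = 1e-12)
  expect_equal(regional_F100(matrix(0, 3, 3), matrix(20, 3, 3)), 0)
  set.seed(1)
  npp <- matrix(runif(20, 10, 120), 4, 5)
  sst <- matrix(runif(20, 10, 22), 4, 5)
  w <- matrix(runif(20, 0.5, 2), 4, 5)
  brute <- 0; wsum <- 0
  for (i in 1:4) for (j in 1:5) {
    er <- min(1, max(0, 0.056 * sst[i, j] - 0.698))
    brute <- brute + er * npp[i, j] * w[i, j]; wsum <- wsum + w[i, j]
  }
  expect_equal(regional_F100(npp, sst, weights = w), brute / wsum,
               tolerance = 1e-12)
  expect_error(regional_F100(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2)),
               "no valid cells")
})

test_that("Monte Carlo flux intervals collapse for degenerate draws and widen with depth", {
  cv <- flux_curve(9, 0.72, F100_samples = 9, b_samples = 0.72)
  ci <- propagate_flux_uncertainty(cv, 500, n_draws = 500, seed = 1)
  expect_equal(ci[1], ci[2])
  set.seed(2)
  cv2 <- flux_curve(9, 0.72, F100_samples = rnorm(2000, 9, 1.1),
                    b_samples = rnorm(2000, 0.72, 0.02))
  w <- vapply(c(200, 500, 1000, 2000), function(z)
    diff(propagate_flux_uncertainty(cv2, z, n_draws = 4000, seed = 3) /
           flux_at_depth(cv2, z)),
    numeric(1))
  expect_true(all(diff(w) > 0))  # relative width grows as b-uncertainty compounds
  expect_warning(propagate_flux_uncertainty(cv2, 200, n_draws = 50, seed = 1),
                 "n_draws")
})
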