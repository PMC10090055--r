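g_reference_curve <- function() {
  fit_g_interpolant(c(100, 150, 200, 300, 400, 500, 750, 1000),
                    c(102, 170, 240, 380, 520, 660, 1000, 1335))
}

test_that("sequestration integral reduces to g0 x total remineralization for constant g", {
  z <- seq(100, 1000, 1)
  cv <- flux_curve(9, 0.72)
  r <- remineralization_density(cv, z)
  R <- pracma::trapz(z, r)
  g0 <- 300
  out <- sequestration_integral(z, r, flux_at_zmax = 0,
                                g = function(z) rep(g0, length(z)),
                                region = region_config(deep_g_value = g0))
  expect_equal(out, g0 * R * 365.25 / 1000, tolerance = 1e-12)
  expect_error(sequestration_integral(z, -r, 0, g_reference_curve()), "negative")
})

test_that("sequestration integral converges under grid refinement and is linear and monotone", {
  cv <- flux_curve(9, 0.72)
  g <- g_reference_curve()
  val <- function(dz) {
    z <- seq(100, 2000, dz)
    sequestration_integral(z, remineralization_density(cv, z),
                           flux_at_depth(cv, 2000), g)
  }
  expect_lt(abs(val(1) / val(2) - 1), 1e-3)
  # linear in the density profile
  z <- seq(100, 2000, 5)
  r <- remineralization_density(cv, z)
  a <- sequestration_integral(z, r, 0, g)
  expect_equal(sequestration_integral(z, 2.5 * r, 0, g), 2.5 * a,
               tolerance = 1e-12)
  # monotone in g
  g_hi <- fit_g_interpolant(c(100, 1000), c(200, 2000))
  g_lo <- fit_g_interpolant(c(100, 1000), c(100, 1000))
  expect_gt(sequestration_integral(z, r, 1, g_hi),
            sequestration_integral(z, r, 1, g_lo))
})

test_that("mean duration and regional totals invert the areal stock consistently", {
  region <- region_config()
  expect_equal(mean_duration(1931, 9.0, region), 1931 * 1000 / (9 * 365.25))
  expect_equal(mean_duration(0, 9.0, region), 0)
  expect_error(mean_duration(100, 0, region), "> 0")
  # inverse identity under constant g
  g0 <- 250; R <- 4
  areal <- g0 * R * 365.25 / 1000
  expect_equal(mean_duration(areal, R, region), g0, tolerance = 1e-12)
  expect_equal(regional_total(0, region), 0)
})

test_that("EZ-ratio and transfer efficiency follow their defining ratios", {
  out <- ez_ratio_t100(9, 9 * 2^(-0.72), 64.3)
  expect_equal(unname(out["t100"]), 2^(-0.72))
  expect_equal(unname(out["ez_ratio"]), 9 / 64.3)
  expect_equal(unname(ez_ratio_t100(5, 1, 5)["ez_ratio"]), 1)
  expect_error(ez_ratio_t100(5, 1, 0), "NPP")
  expect_error(ez_ratio_t100(0, 1, 10), "> 0")
})

test_that("pathway fractions normalize exactly and are permutation-equivariant", {
  x <- c(sinking = 9.0, active_transport = 2.9, subduction = 3.8)
  fr <- pathway_fractions(x)
  expect_equal(sum(fr), 1)
  expect_equal(unname(pathway_fractions(x[c(3, 1, 2)])), unname(fr[c(3, 1, 2)]))
  expect_equal(unname(pathway_fractions(c(1, 0, 0))), c(1, 0, 0))
  expect_error(pathway_fractions(c(0, 0, 0)), "zero")
})

test_that("rank-correlation screen matches rank-then-Pearson and flags constant columns", {
  d <- data.frame(p = 1:8, m_up = (1:8)^2, m_down = -(1:8)^3 + 0.5)
  out <- correlation_screen(d, "p", c("m_up", "m_down"))
  expect_equal(out$rho, c(1, -1))
  expect_equal(out$p_value, c(0, 0))
  set.seed(7)
  d2 <- data.frame(p = sample(1:5, 40, replace = TRUE) + runif(40),
                   m = rnorm(40), k = rep(2, 40))
  out2 <- correlation_screen(d2, "p", c("m", "k"))
  ref <- cor(rank(d2$p), rank(d2$m))   # independent average-rank route
  expect_equal(out2$rho[1], ref, tolerance = 1e-12)
  tref <- ref * sqrt(38 / (1 - ref^2))
  expect_equal(out2$p_value[1], 2 * pt(-abs(tref), 38), tolerance = 1e-12)
  expect_true(is.na(out2$rho[2]) && is.na(out2$p_value[2]))  # constant metric
  expect_error(correlation_screen(d[1:3, ], "p", "m_up"), "paired observations")
})

test_that("pathway budgets propagate paired draws into ordered intervals", {
  g <- g_reference_curve()
  z <- seq(100, 1000, 5)
  cv <- flux_curve(9, 0.72)
  r <- remineralization_density(cv, z)
  draws <- lapply(seq(0.8, 1.2, length.out = 25), function(s)
    list(export_100 = 9 * s, density = r * s,
         flux_at_zmax = flux_at_depth(cv, 1000) * s))
  pb <- pathway_budget("sinking", 9, z, r, flux_at_depth(cv, 1000), g,
                       draws = draws)
  expect_s3_class(pb, "pathway_budget")
  expect_true(all(pb$intervals$lower <= pb$intervals$upper))
  areal_row <- pb$intervals[pb$intervals$quantity == "areal_molC_m2", ]
  expect_true(areal_row$lower <= pb$areal_molC_m2 &&
                pb$areal_molC_m2 <= areal_row$upper)
  tab <- budget_table(list(pb))
  expect_equal(tab$export_100_mmolC_m2_d, 9)
  expect_equal(tab$areal_molC_m2, pb$areal_molC_m2)
})
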