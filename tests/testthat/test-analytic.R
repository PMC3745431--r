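test_that("residualized interaction SDs match their numerical derivation", {
  # re-derive each constant by residualizing the product column on the
  # intercept and both main effects in a large simulated sample
  set.seed(301)
  expected <- c(cont_cont = 1, cont_dich = 0.5, dich_dich = 0.25)
  for (kind in pair_kinds()) {
    pred <- draw_predictors(kind, 1e6)
    res <- lm.fit(cbind(1, pred$x1, pred$x2), pred$x1x2)$residuals
    expect_lt(abs(sd(res) - expected[[kind]]), 0.01)
    expect_equal(residual_sd_interaction(kind), unname(expected[[kind]]))
  }
  expect_error(residual_sd_interaction("both_cont"), "unsupported")
})

test_that("with beta3 = 0 analytic power equals alpha exactly", {
  grid <- scenario_grid(alphas = c(0.05, 0.15), ns = c(50, 1000), beta3s = 0)
  out <- analytic_power(grid)
  expect_equal(out$power, out$alpha, tolerance = 1e-10)
})

test_that("noncentrality follows beta3 * sqrt(n) * resid_sd / sigma", {
  grid <- scenario_grid(alphas = 0.05, ns = 400, beta3s = 0.26,
                        sigma = 2)
  out <- analytic_power(grid)
  expect_equal(
    out$noncentrality,
    0.26 * sqrt(400) * residual_sd_interaction(out$pair_kind) / 2
  )
})

test_that("analytic power is monotone in alpha, n and |beta3|, and
           symmetric in the sign of beta3", {
  by_alpha <- analytic_power(scenario_grid(ns = 300, beta3s = 0.14,
                                           pair_kinds = "cont_cont"))
  expect_true(all(diff(by_alpha$power) > 0))
  by_n <- analytic_power(scenario_grid(alphas = 0.05, beta3s = 0.14,
                                       pair_kinds = "cont_dich"))
  expect_true(all(diff(by_n$power) > 0))
  by_beta <- analytic_power(scenario_grid(alphas = 0.05, ns = 300,
                                          pair_kinds = "dich_dich"))
  expect_true(all(diff(by_beta$power) > 0))
  pos <- analytic_power(one_cell("cont_cont", 200, 0.26))
  neg <- analytic_power(one_cell("cont_cont", 200, -0.26))
  expect_equal(pos$power, neg$power, tolerance = 1e-12)
})

test_that("dichotomization orders power: cont_cont >= cont_dich >= dich_dich", {
  grid <- scenario_grid(alphas = 0.05, ns = c(50, 300, 1000),
                        beta3s = c(0.14, 0.39))
  out <- analytic_power(grid)
  wide <- tidyr::pivot_wider(out[, c("pair_kind", "n", "beta3", "power")],
                             names_from = "pair_kind",
                             values_from = "power")
  expect_true(all(wide$cont_cont >= wide$cont_dich))
  expect_true(all(wide$cont_dich >= wide$dich_dich))
})

test_that("the large-df limit agrees with the normal approximation", {
  grid <- scenario_grid(alphas = c(0.05, 0.20), ns = 1000,
                        beta3s = c(0.05, 0.14, 0.26, 0.39))
  out <- analytic_power(grid)
  z <- qnorm(1 - out$alpha / 2)
  normal_approx <- pnorm(out$noncentrality - z) +
    pnorm(-out$noncentrality - z)
  expect_lt(max(abs(out$power - normal_approx)), 0.005)
})

test_that("analytic power reproduces the elevated-rate threshold findings", {
  # 80% power at the 15% error rate for cont_cont, n = 300, beta3 = 0.14
  expect_gte(analytic_power(one_cell("cont_cont", 300, 0.14,
                                     alpha = 0.15))$power, 0.80)
  # and at the 10% rate for cont_cont, n = 50, beta3 = 0.39
  expect_gte(analytic_power(one_cell("cont_cont", 50, 0.39,
                                     alpha = 0.10))$power, 0.80)
})

test_that("min_alpha_for_power finds the smallest adequate level", {
  expect_equal(min_alpha_for_power("cont_cont", 300, 0.14), 0.15)
  expect_equal(min_alpha_for_power("cont_cont", 50, 0.39), 0.10)
  # a huge effect is already powered at the smallest grid level
  expect_equal(min_alpha_for_power("cont_cont", 1000, 5), 0.05)
  # a small effect at small n is out of reach on the whole grid:
  # power at alpha = 0.20 is only ~0.23
  cap <- analytic_power(one_cell("cont_cont", 50, 0.05, alpha = 0.20))$power
  expect_lt(cap, 0.25)
  expect_true(is.na(min_alpha_for_power("cont_cont", 50, 0.05)))
  expect_error(min_alpha_for_power("cont_cont", 50, 0.39,
                                   alpha_grid = numeric(0)), "empty")
  expect_error(min_alpha_for_power("cont_cont", 50, 0.39,
                                   alpha_grid = c(0.2, 0.1)), "ascending")
})

test_that("analytic power rejects designs without residual df", {
  expect_error(
    analytic_power(tibble::tibble(pair_kind = "cont_cont", n = 4L,
                                  beta3 = 0.39, alpha = 0.05)),
    "at least 10"
  )
})
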