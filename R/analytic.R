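#' Residualized SD of the interaction column
#'
#' The population standard deviation of the product term after projecting
#' out the intercept and both main effects, under the generator's
#' distributions (standard-normal predictors, median-split 0/1 indicators
#' for dichotomous ones).  This is the constant that scales the
#' noncentrality parameter of the interaction t-test:
#' * `cont_cont`: `Var(Z1 Z2) = 1` and the product is uncorrelated with both
#'   mains, so the residual SD is 1;
#' * `cont_dich`: `Var(Z B) = 1/2`, `Cov(Z B, Z) = 1/2`, leaving residual
#'   variance `1/4`, SD `1/2`;
#' * `dich_dich`: `Var(B1 B2) = 3/16` minus the two main-effect projections
#'   `2 (1/8)^2 / (1/4)` leaves `1/16`, SD `1/4`.
#'
#' The factor-of-two drops explain why median-splitting predictors pushes
#' the power curves down: the effective effect size is halved per
#' dichotomized predictor.
#'
#' @param pair_kind Character vector of [pair_kinds()] values.
#' @return Numeric vector: 1, 0.5 or 0.25 per element.
#' @export
#' @examples
#' residual_sd_interaction(pair_kinds())
residual_sd_interaction <- function(pair_kind) {
  bad <- setdiff(unique(pair_kind), pair_kinds())
  if (length(bad) > 0) {
    rlang::abort(paste0("unsupported pair_kind: ", paste(bad, collapse = ", ")))
  }
  unname(c(cont_cont = 1, cont_dich = 0.5, dich_dich = 0.25)[pair_kind])
}

#' Closed-form power for the interaction t-test
#'
#' Under the generator's model, the interaction t-statistic has a noncentral
#' t distribution with `n - 4` degrees of freedom and noncentrality
#' `beta3 * sqrt(n) * residual_sd_interaction(pair_kind) / sigma`.  Power of
#' the two-sided level-`alpha` test is
#' `P(|T| > t_{1 - alpha/2, n-4})`, including the minor opposite-tail term
#' (it matters only at tiny noncentrality).  With `beta3 = 0` the
#' distribution is central t and power equals `alpha` exactly.
#'
#' The noncentral t (rather than a normal approximation) is used throughout
#' because the default grid includes `n = 50`.
#'
#' @param scenarios A scenario tibble (see [scenario_grid()]).
#' @return A tibble, one row per scenario row, with columns `pair_kind`,
#'   `n`, `beta3`, `alpha`, `resid_sd_interaction`, `noncentrality`,
#'   `critical_value` and `power`.
#' @seealso [simulate_power()] for the Monte Carlo counterpart this formula
#'   cross-checks.
#' @export
#' @examples
#' analytic_power(scenario_grid(alphas = 0.05, ns = 200, beta3s = 0.39,
#'                              pair_kinds = "cont_dich"))
analytic_power <- function(scenarios) {
  scenarios <- validate_scenarios(scenarios)
  if (any(scenarios$n <= 4)) {
    rlang::abort("analytic power needs n > 4 (positive residual df)")
  }
  df <- scenarios$n - 4
  sd_int <- residual_sd_interaction(scenarios$pair_kind)
  ncp <- scenarios$beta3 * sqrt(scenarios$n) * sd_int / scenarios$sigma
  tcrit <- stats::qt(1 - scenarios$alpha / 2, df)
  power <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
  tibble::tibble(
    pair_kind = scenarios$pair_kind,
    n = scenarios$n,
    beta3 = scenarios$beta3,
    alpha = scenarios$alpha,
    resid_sd_interaction = sd_int,
    noncentrality = ncp,
    critical_value = tcrit,
    power = power
  )
}

#' Smallest Type 1 error rate achieving a target power
#'
#' Searches an ascending grid of candidate `alpha` levels and returns the
#' smallest one at which the analytic power of the interaction test reaches
#' `target_power`, or `NA` if none does.  This answers questions of the form
#' "to what level would the Type 1 error rate have to be raised for this
#' design to be adequately powered?".
#'
#' @param pair_kind One of [pair_kinds()].
#' @param n Sample size.
#' @param beta3 Standardized interaction effect size.
#' @param target_power Required power, default 0.80.
#' @param alpha_grid Ascending vector of candidate levels, default the study
#'   grid `c(0.05, 0.10, 0.15, 0.20)`.
#' @param sigma Error SD, default 1.
#' @return The smallest adequate `alpha`, or `NA_real_` if the target is out
#'   of reach on the grid.
#' @export
#' @examples
#' min_alpha_for_power("cont_cont", n = 300, beta3 = 0.14)  # 0.15
min_alpha_for_power <- function(pair_kind, n, beta3, target_power = 0.80,
                                alpha_grid = c(0.05, 0.10, 0.15, 0.20),
                                sigma = 1) {
  if (length(alpha_grid) == 0) rlang::abort("alpha_grid is empty")
  if (is.unsorted(alpha_grid)) {
    rlang::abort("alpha_grid must be sorted in ascending order")
  }
  pow <- analytic_power(scenario_grid(
    alphas = alpha_grid, ns = n, beta3s = beta3, pair_kinds = pair_kind,
    sigma = sigma
  ))
  ok <- pow$alpha[pow$power >= target_power]
  if (length(ok) == 0) NA_real_ else min(ok)
}
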