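#' Variable-pair kinds for the interaction
#'
#' The three supported combinations of predictor types entering the product
#' term: two continuous predictors, one continuous and one dichotomous, or
#' two dichotomous.  Dichotomous predictors are standard-normal variates
#' median-split into 0/1 indicators (see [draw_predictors()]).
#'
#' @return Character vector `c("cont_cont", "cont_dich", "dich_dich")`, in
#'   the canonical enumeration order used throughout the package.
#' @export
#' @examples
#' pair_kinds()
pair_kinds <- function() {
  c("cont_cont", "cont_dich", "dich_dich")
}

#' Build a scenario grid
#'
#' Expands the Cartesian product of Type 1 error rates, sample sizes,
#' standardized interaction effect sizes and variable-pair kinds into a
#' tibble with one row per simulation scenario.  Rows are ordered with
#' `pair_kind` outermost (in [pair_kinds()] order), then `beta3`, then `n`,
#' then `alpha`, all ascending; this order is stable and is the row order of
#' every downstream result table.
#'
#' The outcome model behind every scenario is
#' \deqn{y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_1 x_2 + e,
#'   \quad e \sim N(0, \sigma^2),}
#' with the lower-order coefficients and the error SD fixed at 1 by default.
#' The interaction t-test is invariant to `beta0`, `beta1` and `beta2`, so
#' power depends only on `pair_kind`, `n`, `beta3 / sigma` and `alpha`.
#'
#' @param alphas Numeric vector of nominal Type 1 error rates, each in (0, 1).
#' @param ns Integer vector of sample sizes, each at least 10 (the model
#'   estimates 4 coefficients, so residual degrees of freedom are `n - 4`).
#' @param beta3s Numeric vector of standardized interaction effect sizes
#'   (may include 0 for calibration runs).
#' @param pair_kinds Character vector, a subset of [pair_kinds()].
#' @param beta0,beta1,beta2 Lower-order coefficients of the data-generating
#'   model. Default 1.
#' @param sigma Error standard deviation, must be positive. Default 1.
#' @return A tibble with columns `pair_kind`, `beta3`, `n`, `alpha`,
#'   `beta0`, `beta1`, `beta2`, `sigma`; one row per grid cell.
#' @seealso [default_grid()] for the full 240-cell study grid.
#' @export
#' @examples
#' scenario_grid(alphas = c(0.05, 0.20), ns = 50, beta3s = 0.39)
scenario_grid <- function(alphas = c(0.05, 0.10, 0.15, 0.20),
                          ns = c(50L, 200L, 300L, 500L, 1000L),
                          beta3s = c(0.05, 0.14, 0.26, 0.39),
                          pair_kinds = interpower::pair_kinds(),
                          beta0 = 1, beta1 = 1, beta2 = 1, sigma = 1) {
  grid <- tidyr::expand_grid(
    pair_kind = pair_kinds,
    beta3 = sort(beta3s),
    n = sort(as.integer(ns)),
    alpha = sort(alphas)
  )
  grid <- dplyr::mutate(grid,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, sigma = sigma
  )
  validate_scenarios(grid)
  grid
}

#' The default 240-cell study grid
#'
#' Four Type 1 error rates (5%, 10%, 15%, 20%), five sample sizes (50, 200,
#' 300, 500, 1000), four interaction effect sizes (0.05, 0.14, 0.26, 0.39 —
#' small through large on Cohen's scale) and all three variable-pair kinds:
#' 240 scenarios in total.
#'
#' @return A 240-row scenario tibble (see [scenario_grid()]).
#' @export
#' @examples
#' nrow(default_grid())
default_grid <- function() {
  scenario_grid()
}

#' Validate a scenario tibble
#'
#' Checks the structural invariants every scenario must satisfy: a known
#' `pair_kind`, `n >= 10` (positive residual degrees of freedom with margin),
#' `alpha` strictly inside (0, 1) and `sigma > 0`.  Missing lower-order
#' coefficient columns are filled with the default value 1.
#'
#' @param scenarios A data frame with at least columns `pair_kind`, `n`,
#'   `beta3`, `alpha`.
#' @return The validated tibble, invisibly coerced to include `beta0`,
#'   `beta1`, `beta2`, `sigma` columns.
#' @export
validate_scenarios <- function(scenarios) {
  stopifnot(is.data.frame(scenarios))
  required <- c("pair_kind", "n", "beta3", "alpha")
  missing <- setdiff(required, names(scenarios))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "scenario table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  scenarios <- tibble::as_tibble(scenarios)
  for (col in c("beta0", "beta1", "beta2")) {
    if (!col %in% names(scenarios)) scenarios[[col]] <- 1
  }
  if (!"sigma" %in% names(scenarios)) scenarios$sigma <- 1
  bad_kind <- setdiff(unique(scenarios$pair_kind), pair_kinds())
  if (length(bad_kind) > 0) {
    rlang::abort(paste0(
      "unsupported pair_kind: ", paste(bad_kind, collapse = ", "),
      " (expected one of ", paste(pair_kinds(), collapse = ", "), ")"
    ))
  }
  if (any(scenarios$n < 10)) {
    rlang::abort("sample size n must be at least 10")
  }
  if (any(scenarios$alpha <= 0 | scenarios$alpha >= 1)) {
    rlang::abort("alpha must lie strictly between 0 and 1")
  }
  if (any(scenarios$sigma <= 0)) {
    rlang::abort("sigma must be positive")
  }
  invisible(scenarios)
}

#' Read and write a study configuration file
#'
#' A run configuration is stored as YAML with keys `alphas`, `ns`, `beta3s`,
#' `pair_kinds`, `n_reps`, `seed` and `design`, so a full study is
#' reproducible from one small text file.
#'
#' @param path File path of the YAML configuration.
#' @return `read_run_config()` returns a list with elements `grid` (a
#'   scenario tibble), `n_reps`, `seed` and `design`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("alphas", "ns", "beta3s", "pair_kinds")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "config ", path, " is missing key(s): ", paste(missing, collapse = ", ")
    ))
  }
  grid <- scenario_grid(
    alphas = as.numeric(cfg$alphas),
    ns = as.integer(cfg$ns),
    beta3s = as.numeric(cfg$beta3s),
    pair_kinds = as.character(cfg$pair_kinds)
  )
  list(
    grid = grid,
    n_reps = as.integer(cfg$n_reps %||% 10000L),
    seed = as.integer(cfg$seed %||% 1L),
    design = match.arg(cfg$design %||% "fresh", c("fresh", "fixed"))
  )
}

#' @rdname read_run_config
#' @param grid A scenario tibble (see [scenario_grid()]).
#' @param n_reps,seed,design Simulation settings stored alongside the grid.
#' @return `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(grid, path, n_reps = 10000L, seed = 1L,
                             design = c("fresh", "fixed")) {
  design <- match.arg(design)
  grid <- validate_scenarios(grid)
  cfg <- list(
    alphas = sort(unique(grid$alpha)),
    ns = sort(unique(grid$n)),
    beta3s = sort(unique(grid$beta3)),
    pair_kinds = intersect(pair_kinds(), unique(grid$pair_kind)),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    design = design
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
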