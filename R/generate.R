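#' Draw one set of predictors and their product term
#'
#' Continuous predictors are i.i.d. standard normal.  Dichotomous predictors
#' are obtained by drawing a standard normal latent variate and recoding it
#' to 1 when non-negative and 0 otherwise — a median split at the population
#' median, so the two categories are approximately (binomially) balanced.
#' For `cont_dich`, `x1` is the continuous predictor and `x2` the
#' dichotomous one.  The interaction column is the elementwise product.
#'
#' Draws consume the current R random stream; call `set.seed()` (or use the
#' `seed` arguments of the simulation drivers) for reproducibility.
#'
#' @param pair_kind One of [pair_kinds()].
#' @param n Sample size, at least 10.
#' @return A tibble with columns `x1`, `x2`, `x1x2`, each of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' draw_predictors("cont_dich", 5)
draw_predictors <- function(pair_kind, n) {
  if (length(pair_kind) != 1 || !pair_kind %in% pair_kinds()) {
    rlang::abort(paste0(
      "unsupported pair_kind: ", paste(pair_kind, collapse = ", "),
      " (expected one of ", paste(pair_kinds(), collapse = ", "), ")"
    ))
  }
  n <- as.integer(n)
  if (n < 10) rlang::abort("sample size n must be at least 10")
  tibble::as_tibble(draw_predictors_raw(pair_kind, n))
}

# Plain-list variant without tibble overhead, for the simulation hot loop.
#' @noRd
draw_predictors_raw <- function(pair_kind, n) {
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  if (pair_kind == "dich_dich") x1 <- as.numeric(x1 >= 0)
  if (pair_kind %in% c("cont_dich", "dich_dich")) x2 <- as.numeric(x2 >= 0)
  list(x1 = x1, x2 = x2, x1x2 = x1 * x2)
}

#' Generate one replicate dataset under the interaction model
#'
#' Adds the outcome
#' `y = beta0 + beta1*x1 + beta2*x2 + beta3*x1x2 + e`, with
#' `e ~ N(0, sigma^2)` independent of the predictors, to a predictor set.
#' If `predictors` is `NULL` a fresh set is drawn via [draw_predictors()].
#'
#' @param pair_kind One of [pair_kinds()]; used only when `predictors` is
#'   `NULL`.
#' @param n Sample size.
#' @param beta3 Standardized interaction effect size (0 gives a null model).
#' @param beta0,beta1,beta2 Lower-order coefficients, default 1.
#' @param sigma Error standard deviation, default 1.
#' @param predictors Optional tibble with columns `x1`, `x2`, `x1x2` (e.g.
#'   from [draw_predictors()]) to reuse a fixed design; must have `n` rows.
#' @return A tibble with columns `x1`, `x2`, `x1x2`, `y`.
#' @export
#' @examples
#' set.seed(42)
#' dat <- simulate_replicate("cont_cont", n = 100, beta3 = 0.39)
#' fit_interaction(dat)
simulate_replicate <- function(pair_kind, n, beta3,
                               beta0 = 1, beta1 = 1, beta2 = 1, sigma = 1,
                               predictors = NULL) {
  if (sigma <= 0) rlang::abort("sigma must be positive")
  if (is.null(predictors)) {
    predictors <- draw_predictors(pair_kind, n)
  } else {
    stopifnot(all(c("x1", "x2", "x1x2") %in% names(predictors)))
    if (nrow(predictors) != n) {
      rlang::abort(paste0(
        "predictors have ", nrow(predictors), " rows but n = ", n
      ))
    }
  }
  e <- stats::rnorm(n, sd = sigma)
  dplyr::mutate(
    tibble::as_tibble(predictors),
    y = beta0 + beta1 * .data$x1 + beta2 * .data$x2 + beta3 * .data$x1x2 + e
  )
}

#' Dump a replicate to a delimited text file
#'
#' Writes the four columns `x1`, `x2`, `x1x2`, `y` as CSV at full precision,
#' for debugging or re-analysis outside R.
#'
#' @param data A replicate tibble from [simulate_replicate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_replicate <- function(data, path) {
  stopifnot(all(c("x1", "x2", "x1x2", "y") %in% names(data)))
  readr::write_csv(data[, c("x1", "x2", "x1x2", "y")], path)
  invisible(path)
}
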