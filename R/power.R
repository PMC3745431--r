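#' @keywords internal
#' @noRd
derive_triple_seed <- function(master_seed, index) {
  # Fixed linear mix of the master seed and the 1-based triple index, reduced
  # modulo the Mersenne prime 2^31 - 1.  Deterministic, collision-free for
  # grids of realistic size, and each triple gets its own stream.
  s <- (as.numeric(master_seed) * 48271 + as.numeric(index) * 2654435761) %%
    2147483647
  if (s == 0) s <- 1
  as.integer(s)
}

# Interaction-term p-value from a 4-column design, fast path.
# Returns NA_real_ for a rank-deficient (or pivoted) design so the caller
# can apply its redraw policy.
#' @noRd
interaction_pvalue <- function(X, y, df_resid) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < 4L || any(fit$pivot != 1:4)) {
    return(NA_real_)
  }
  # For an unpivoted QR, (X'X)^{-1}[4,4] = 1 / R[4,4]^2.
  r44 <- fit$qr[4L, 4L]
  s2 <- sum(fit$residuals^2) / df_resid
  tval <- fit$coefficients[4L] * abs(r44) / sqrt(s2)
  2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
}

# One (pair_kind, n, beta3) triple: n_reps interaction p-values.
#' @noRd
simulate_pvalues <- function(pair_kind, n, beta3,
                             beta0 = 1, beta1 = 1, beta2 = 1, sigma = 1,
                             n_reps = 10000L,
                             design = c("fresh", "fixed")) {
  design <- match.arg(design)
  n <- as.integer(n)
  df_resid <- n - 4L
  max_redraws <- 100 * n_reps
  n_redraws <- 0L

  abort_degenerate <- function() {
    rlang::abort(
      paste0(
        "aborting: more than ", max_redraws, " degenerate redraws for ",
        pair_kind, ", n = ", n
      ),
      class = "interpower_degenerate_abort"
    )
  }

  if (design == "fixed") {
    # One realized design; only the error term is redrawn each replicate.
    repeat {
      pred <- draw_predictors_raw(pair_kind, n)
      X <- cbind(1, pred$x1, pred$x2, pred$x1x2)
      qrx <- qr(X)
      if (qrx$rank == 4L) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) abort_degenerate()
    }
    mu <- beta0 + beta1 * pred$x1 + beta2 * pred$x2 + beta3 * pred$x1x2
    xtx_inv44 <- chol2inv(qr.R(qrx)[, order(qrx$pivot), drop = FALSE])[4L, 4L]
    pvals <- numeric(n_reps)
    chunk <- 2000L
    done <- 0L
    while (done < n_reps) {
      m <- min(chunk, n_reps - done)
      E <- matrix(stats::rnorm(n * m, sd = sigma), nrow = n)
      Y <- mu + E
      B <- qr.coef(qrx, Y)
      res <- qr.resid(qrx, Y)
      s2 <- colSums(res^2) / df_resid
      tval <- B[4L, ] / sqrt(s2 * xtx_inv44)
      pvals[done + seq_len(m)] <-
        2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
      done <- done + m
    }
    return(list(p = pvals, n_redraws = n_redraws))
  }

  # fresh design: predictors redrawn every replicate
  pvals <- numeric(n_reps)
  ones <- rep(1, n)
  for (r in seq_len(n_reps)) {
    repeat {
      pred <- draw_predictors_raw(pair_kind, n)
      y <- beta0 + beta1 * pred$x1 + beta2 * pred$x2 +
        beta3 * pred$x1x2 + stats::rnorm(n, sd = sigma)
      p <- interaction_pvalue(cbind(ones, pred$x1, pred$x2, pred$x1x2), y,
                              df_resid)
      if (!is.na(p)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) abort_degenerate()
    }
    pvals[r] <- p
  }
  list(p = pvals, n_redraws = n_redraws)
}

#' Estimate empirical power by Monte Carlo simulation
#'
#' For every scenario row, repeatedly generates a replicate dataset under
#' the interaction model, fits the OLS regression and records the
#' interaction term's two-sided p-value; empirical power is the fraction of
#' replicates with `p < alpha` (strict inequality).  Replicates are shared
#' across rows that differ only in `alpha` — the same stored p-values are
#' thresholded at each level — so power is exactly non-decreasing in `alpha`
#' within a `(pair_kind, beta3, n)` triple.
#'
#' Two replication designs are available. `"fresh"` (the default) redraws
#' the predictors every replicate and estimates unconditional power, the
#' quantity the noncentral-t formula in [analytic_power()] computes.
#' `"fixed"` draws one predictor set per triple and redraws only the error
#' term, estimating power conditional on that realized design; at small `n`
#' this conditioning adds seed-dependent variation.
#'
#' Each triple gets its own RNG seed derived deterministically from `seed`
#' and the triple's position, so any cell can be re-run on its own and grids
#' are reproducible end to end.  A rank-deficient replicate (possible in
#' principle when a dichotomous predictor is drawn all-0 or all-1 at small
#' `n`) is redrawn and counted; the run aborts if redraws exceed
#' `100 * n_reps`.
#'
#' @param scenarios A scenario tibble (see [scenario_grid()]); a single cell
#'   is just a one-row grid.
#' @param n_reps Number of Monte Carlo replicates per triple, default 10000.
#' @param seed Master seed (integer). `NULL` draws one from the current
#'   stream.
#' @param design `"fresh"` or `"fixed"` (see Details).
#' @return A tibble of class `power_estimates`, one row per scenario row, in
#'   scenario order, with columns `pair_kind`, `n`, `beta3`, `alpha`,
#'   `n_reps`, `n_reject`, `power`, `mc_se` (`sqrt(power (1 - power) /
#'   n_reps)`), `design`, `seed` (the triple seed) and `n_redraws`.
#' @seealso [analytic_power()] for the closed-form oracle,
#'   [classify_gain()] for the downstream taxonomy.
#' @export
#' @examples
#' simulate_power(
#'   scenario_grid(alphas = c(0.05, 0.20), ns = 50, beta3s = 0.39,
#'                 pair_kinds = "cont_cont"),
#'   n_reps = 500, seed = 1
#' )
simulate_power <- function(scenarios, n_reps = 10000L, seed = NULL,
                           design = c("fresh", "fixed")) {
  design <- match.arg(design)
  scenarios <- validate_scenarios(scenarios)
  n_reps <- as.integer(n_reps)
  if (n_reps < 1) rlang::abort("n_reps must be at least 1")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)

  key <- paste(scenarios$pair_kind, scenarios$beta3, scenarios$n,
               scenarios$beta0, scenarios$beta1, scenarios$beta2,
               scenarios$sigma, sep = "\r")
  triple_keys <- unique(key)
  triple_idx <- match(key, triple_keys)

  pvals <- vector("list", length(triple_keys))
  redraws <- integer(length(triple_keys))
  seeds <- integer(length(triple_keys))
  for (i in seq_along(triple_keys)) {
    row <- scenarios[match(i, triple_idx), ]
    seeds[i] <- derive_triple_seed(seed, i)
    set.seed(seeds[i])
    sim <- simulate_pvalues(
      row$pair_kind, row$n, row$beta3,
      row$beta0, row$beta1, row$beta2, row$sigma,
      n_reps = n_reps, design = design
    )
    pvals[[i]] <- sim$p
    redraws[i] <- sim$n_redraws
  }

  n_reject <- vapply(
    seq_len(nrow(scenarios)),
    function(j) sum(pvals[[triple_idx[j]]] < scenarios$alpha[j]),
    integer(1)
  )
  power <- n_reject / n_reps
  out <- tibble::tibble(
    pair_kind = scenarios$pair_kind,
    n = scenarios$n,
    beta3 = scenarios$beta3,
    alpha = scenarios$alpha,
    n_reps = n_reps,
    n_reject = n_reject,
    power = power,
    mc_se = sqrt(power * (1 - power) / n_reps),
    design = design,
    seed = seeds[triple_idx],
    n_redraws = redraws[triple_idx]
  )
  class(out) <- c("power_estimates", class(out))
  out
}

#' Null-model calibration check
#'
#' Runs the simulator with the interaction effect forced to zero, where the
#' rejection rate should equal the nominal Type 1 error rate up to Monte
#' Carlo noise, and flags any cell whose empirical rate falls outside
#' `alpha +/- band_se * sqrt(alpha (1 - alpha) / n_reps)`.
#'
#' @param scenarios Scenario tibble; `beta3` is overwritten with 0 and
#'   duplicate cells are dropped.
#' @param n_reps,seed,design Passed to [simulate_power()].
#' @param band_se Half-width of the acceptance band in Monte Carlo standard
#'   errors of the nominal rate, default 4.
#' @return The power table with extra columns `lower`, `upper` and `pass`.
#' @export
calibration_check <- function(scenarios = default_grid(), n_reps = 10000L,
                              seed = NULL, design = c("fresh", "fixed"),
                              band_se = 4) {
  design <- match.arg(design)
  scenarios <- validate_scenarios(scenarios)
  scenarios$beta3 <- 0
  scenarios <- dplyr::distinct(scenarios)
  out <- simulate_power(scenarios, n_reps = n_reps, seed = seed,
                        design = design)
  half <- band_se * sqrt(out$alpha * (1 - out$alpha) / out$n_reps)
  dplyr::mutate(
    out,
    lower = .data$alpha - half,
    upper = .data$alpha + half,
    pass = .data$power >= .data$lower & .data$power <= .data$upper
  )
}
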