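#' Fit the interaction regression and test the product term
#'
#' Ordinary least squares fit of `y ~ x1 + x2 + x1x2` (intercept included)
#' via a QR decomposition, returning the coefficient table together with the
#' interaction term's t-statistic and two-sided p-value from the central t
#' distribution with `n - 4` residual degrees of freedom.
#'
#' @param data A data frame with columns `x1`, `x2`, `x1x2`, `y` (e.g. from
#'   [simulate_replicate()]); at least 5 rows.
#' @return An object of class `interaction_fit`: a list with elements
#'   `coefficients` (named 4-vector), `se`, `statistic`, `p.value` (named
#'   4-vectors), `se_interaction`, `t_interaction`, `p_interaction`,
#'   `sigma_hat`, `df_resid`, `n`, `r.squared`.
#' @seealso [tidy.interaction_fit()], [glance.interaction_fit()]
#' @export
#' @examples
#' set.seed(7)
#' fit <- fit_interaction(simulate_replicate("cont_cont", 200, beta3 = 0.39))
#' tidy(fit)
#' glance(fit)
fit_interaction <- function(data) {
  stopifnot(all(c("x1", "x2", "x1x2", "y") %in% names(data)))
  n <- nrow(data)
  if (n < 5) rlang::abort("need at least 5 observations to fit 4 coefficients")
  X <- cbind(
    `(Intercept)` = rep(1, n),
    x1 = data$x1, x2 = data$x2, x1x2 = data$x1x2
  )
  y <- data$y
  qrx <- qr(X)
  if (qrx$rank < 4L) {
    kept <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(4L), kept)]
    rlang::abort(
      paste0(
        "design matrix is rank-deficient; degenerate column(s): ",
        paste(dropped, collapse = ", ")
      ),
      class = "interpower_rank_deficient"
    )
  }
  beta_hat <- qr.coef(qrx, y)
  resid <- qr.resid(qrx, y)
  df_resid <- n - 4L
  s2 <- sum(resid^2) / df_resid
  R <- qr.R(qrx)[, order(qrx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(R)
  se <- sqrt(s2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tstat <- beta_hat / se
  pval <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = beta_hat,
      se = se,
      statistic = tstat,
      p.value = pval,
      se_interaction = unname(se["x1x2"]),
      t_interaction = unname(tstat["x1x2"]),
      p_interaction = unname(pval["x1x2"]),
      sigma_hat = sqrt(s2),
      df_resid = df_resid,
      n = n,
      r.squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
    ),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Interaction OLS fit (n =", x$n, ", df =", x$df_resid, ")\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy the coefficient table of an interaction fit
#'
#' @param x An `interaction_fit` object.
#' @param ... Unused.
#' @return A 4-row tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p.value)
  )
}

#' One-row model summary of an interaction fit
#'
#' @param x An `interaction_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `statistic`
#'   (interaction t), `p.value` (interaction, two-sided), `df.residual`,
#'   `nobs`.
#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma_hat,
    statistic = x$t_interaction,
    p.value = x$p_interaction,
    df.residual = x$df_resid,
    nobs = x$n
  )
}
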