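# Small deterministic fixtures shared across test files.

# A fixed 8-row dataset with simple values whose normal equations can be
# solved independently of the package's QR path.
fixture_8row <- function() {
  x1 <- c(-1.5, -1.0, -0.5, 0.0, 0.5, 1.0, 1.5, 2.0)
  x2 <- c(1, 0, 1, 0, 1, 0, 1, 0)
  x1x2 <- x1 * x2
  y <- c(0.3, -0.7, 1.1, 0.9, 2.4, 2.1, 3.8, 3.0)
  tibble::tibble(x1 = x1, x2 = x2, x1x2 = x1x2, y = y)
}

# Independent least-squares oracle: explicit normal-equations solve.
# Deliberately a different algorithm from the package's QR decomposition.
normal_equations_fit <- function(data) {
  X <- cbind(1, data$x1, data$x2, data$x1x2)
  XtX <- t(X) %*% X
  Xty <- t(X) %*% data$y
  beta <- solve(XtX, Xty)
  resid <- data$y - X %*% beta
  df <- nrow(X) - 4
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se, df = df,
       t = drop(beta) / se,
       p = 2 * pt(abs(drop(beta) / se), df, lower.tail = FALSE))
}

# One-row scenario helper.
one_cell <- function(pair_kind, n, beta3, alpha = 0.05, ...) {
  scenario_grid(alphas = alpha, ns = n, beta3s = beta3,
                pair_kinds = pair_kind, ...)
}
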