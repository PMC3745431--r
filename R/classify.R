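#' Relative gain in power between two Type 1 error rates
#'
#' `100 * (power_high - power_low) / power_low`, the percentage increase in
#' power obtained by moving from the nominal to the elevated error rate.
#'
#' @param power_low Power at the lower (nominal) rate; must be positive.
#' @param power_high Power at the higher (elevated) rate.
#' @return Relative gain in percent (vectorized).
#' @export
#' @examples
#' relative_gain(0.40, 0.60)  # 50
relative_gain <- function(power_low, power_high) {
  if (any(power_low <= 0)) {
    rlang::abort(paste0(
      "relative gain is undefined when the baseline power is 0; ",
      "such a scenario can only be reported as never_sufficient"
    ))
  }
  100 * (power_high - power_low) / power_low
}

#' Classify scenarios by usefulness of an elevated Type 1 error rate
#'
#' Applies the useful-gain rule to each `(pair_kind, n, beta3)` triple of a
#' power table.  A triple is a *useful gain* when moving from `alpha_low`
#' (default 5%) to `alpha_high` (default 20%) raises power by at least
#' `gain_pct` percent in relative terms *and* power at `alpha_high` reaches
#' `power_floor` (default 80%).  The full taxonomy, assigned with this
#' precedence, is:
#'
#' * `never_sufficient` — power at `alpha_high` is below `power_floor`;
#'   elevating the error rate cannot rescue the design;
#' * `already_sufficient` — power at `alpha_low` already reaches
#'   `power_floor`; elevating the rate only admits spurious interactions;
#' * `useful_gain` — relative gain at least `gain_pct` and power at
#'   `alpha_high` at least `power_floor` (both comparisons inclusive);
#' * `marginal` — reaches the floor at `alpha_high` but with a relative gain
#'   under `gain_pct`.
#'
#' The four categories partition all triples.  Triples whose power sits
#' within `2 * mc_se` of `power_floor` at either level are flagged as
#' borderline, since their category is sensitive to simulation noise;
#' analytic power tables (no `mc_se` column) are never flagged.
#'
#' @param power_tbl A long power table with columns `pair_kind`, `n`,
#'   `beta3`, `alpha`, `power` (e.g. from [simulate_power()] or
#'   [analytic_power()]), containing at least `alpha_low` and `alpha_high`
#'   for every triple.
#' @param alpha_low,alpha_high The two error rates compared, defaults 0.05
#'   and 0.20.
#' @param gain_pct Minimum relative gain in percent, default 10.
#' @param power_floor Minimum acceptable power, default 0.80.
#' @return A tibble of class `gain_taxonomy`, one row per triple, with the
#'   power at each available `alpha` spread into `power_<level>` columns,
#'   `relative_gain_pct`, `category` (factor with the four levels above) and
#'   `borderline`.
#' @export
#' @examples
#' classify_gain(analytic_power(default_grid()))
classify_gain <- function(power_tbl, alpha_low = 0.05, alpha_high = 0.20,
                          gain_pct = 10, power_floor = 0.80) {
  stopifnot(is.data.frame(power_tbl))
  required <- c("pair_kind", "n", "beta3", "alpha", "power")
  missing <- setdiff(required, names(power_tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "power table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (gain_pct <= 0 || power_floor <= 0) {
    rlang::abort("gain_pct and power_floor must be positive")
  }
  has_se <- "mc_se" %in% names(power_tbl)
  tbl <- tibble::as_tibble(power_tbl)
  tbl$alpha_lbl <- format_alpha(tbl$alpha)

  complete <- tbl |>
    dplyr::group_by(.data$pair_kind, .data$beta3, .data$n) |>
    dplyr::summarise(
      has_low = any(abs(.data$alpha - alpha_low) < 1e-12),
      has_high = any(abs(.data$alpha - alpha_high) < 1e-12),
      .groups = "drop"
    )
  bad <- complete[!(complete$has_low & complete$has_high), ]
  if (nrow(bad) > 0) {
    rlang::abort(paste0(
      "power at alpha = ", alpha_low, " and ", alpha_high,
      " is required for every triple; missing for: ",
      paste(sprintf("(%s, n=%d, beta3=%g)", bad$pair_kind, bad$n, bad$beta3),
            collapse = "; ")
    ))
  }

  wide <- tbl |>
    dplyr::select(dplyr::all_of(c("pair_kind", "beta3", "n", "alpha_lbl",
                                  "power"))) |>
    tidyr::pivot_wider(names_from = "alpha_lbl", values_from = "power",
                       names_prefix = "power_")
  low_col <- paste0("power_", format_alpha(alpha_low))
  high_col <- paste0("power_", format_alpha(alpha_high))
  p_low <- wide[[low_col]]
  p_high <- wide[[high_col]]

  gain <- ifelse(p_low > 0, 100 * (p_high - p_low) / p_low, NA_real_)
  category <- dplyr::case_when(
    p_high < power_floor ~ "never_sufficient",
    p_low >= power_floor ~ "already_sufficient",
    p_low > 0 & gain >= gain_pct ~ "useful_gain",
    p_low == 0 ~ "never_sufficient",
    TRUE ~ "marginal"
  )

  borderline <- rep(FALSE, nrow(wide))
  if (has_se) {
    se_tbl <- tbl |>
      dplyr::filter(abs(.data$alpha - alpha_low) < 1e-12 |
                      abs(.data$alpha - alpha_high) < 1e-12) |>
      dplyr::group_by(.data$pair_kind, .data$beta3, .data$n) |>
      dplyr::summarise(
        near_floor = any(abs(.data$power - power_floor) <= 2 * .data$mc_se,
                         na.rm = TRUE),
        .groups = "drop"
      )
    borderline <- se_tbl$near_floor[match(
      paste(wide$pair_kind, wide$beta3, wide$n),
      paste(se_tbl$pair_kind, se_tbl$beta3, se_tbl$n)
    )]
  }

  out <- dplyr::mutate(
    wide,
    relative_gain_pct = gain,
    category = factor(category, levels = taxonomy_levels()),
    borderline = borderline
  )
  class(out) <- c("gain_taxonomy", class(out))
  attr(out, "thresholds") <- list(
    alpha_low = alpha_low, alpha_high = alpha_high,
    gain_pct = gain_pct, power_floor = power_floor
  )
  out
}

#' @keywords internal
#' @noRd
taxonomy_levels <- function() {
  c("useful_gain", "never_sufficient", "already_sufficient", "marginal")
}

#' @keywords internal
#' @noRd
format_alpha <- function(alpha) {
  sub("^0\\.", "", sprintf("%.2f", alpha))
}

#' Count taxonomy categories per variable-pair kind
#'
#' @param taxonomy A `gain_taxonomy` tibble from [classify_gain()].
#' @return A tibble with one row per `pair_kind` and one column per
#'   category, counts summing to the number of triples of that kind.
#' @export
#' @examples
#' taxonomy_counts(classify_gain(analytic_power(default_grid())))
taxonomy_counts <- function(taxonomy) {
  stopifnot(all(c("pair_kind", "category") %in% names(taxonomy)))
  class(taxonomy) <- setdiff(class(taxonomy), "gain_taxonomy")
  taxonomy |>
    dplyr::count(.data$pair_kind, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
}

#' @export
print.gain_taxonomy <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "Useful-gain taxonomy (alpha %.2f -> %.2f, gain >= %g%%, power floor %.2f)\n",
    thr$alpha_low, thr$alpha_high, thr$gain_pct, thr$power_floor
  ))
  print(taxonomy_counts(x))
  useful <- x[x$category == "useful_gain", ]
  if (nrow(useful) > 0) {
    cat("\nUseful-gain scenarios:\n")
    class(useful) <- setdiff(class(useful), "gain_taxonomy")
    print(useful)
  }
  invisible(x)
}
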