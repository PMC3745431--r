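#' Power curves over sample size
#'
#' Draws power against sample size, one line per Type 1 error rate, faceted
#' by interaction effect size (and by variable-pair kind when the table
#' contains more than one).  A dashed horizontal reference line marks 80%
#' power.
#'
#' @param power_tbl A power table from [simulate_power()] or
#'   [analytic_power()], covering at least one `(pair_kind, beta3)` panel.
#' @param pair_kind Optional single kind to restrict the plot to.
#' @return A ggplot object.
#' @export
#' @examples
#' plot_power_curves(analytic_power(default_grid()), pair_kind = "cont_cont")
plot_power_curves <- function(power_tbl, pair_kind = NULL) {
  stopifnot(is.data.frame(power_tbl))
  required <- c("pair_kind", "n", "beta3", "alpha", "power")
  missing <- setdiff(required, names(power_tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "power table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!is.null(pair_kind)) {
    keep <- pair_kind
    power_tbl <- power_tbl[power_tbl$pair_kind %in% keep, ]
  }
  if (nrow(power_tbl) == 0) {
    rlang::abort("no rows to plot after filtering on pair_kind")
  }
  df <- tibble::as_tibble(power_tbl)
  df$alpha_lbl <- sprintf("%d%%", round(100 * df$alpha))
  df$alpha_lbl <- factor(df$alpha_lbl,
                         levels = sprintf("%d%%",
                                          round(100 * sort(unique(df$alpha)))))
  df$beta3_lbl <- sprintf("beta3 == %g", df$beta3)
  multi_kind <- length(unique(df$pair_kind)) > 1
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$n, y = .data$power, colour = .data$alpha_lbl)
  ) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Sample size", y = "Power",
      colour = "Type 1 error rate"
    ) +
    ggplot2::theme_bw()
  if (multi_kind) {
    p + ggplot2::facet_grid(
      pair_kind ~ beta3_lbl,
      labeller = ggplot2::labeller(beta3_lbl = ggplot2::label_parsed)
    )
  } else {
    p + ggplot2::facet_wrap(
      ~beta3_lbl,
      labeller = ggplot2::labeller(beta3_lbl = ggplot2::label_parsed)
    ) +
      ggplot2::ggtitle(unique(df$pair_kind))
  }
}

#' @rdname plot_power_curves
#' @param object A `power_estimates` tibble.
#' @param ... Passed to [plot_power_curves()].
#' @method autoplot power_estimates
#' @export
autoplot.power_estimates <- function(object, ...) {
  plot_power_curves(object, ...)
}

#' Plot the useful-gain taxonomy
#'
#' Tile map of the `(n, beta3)` grid per variable-pair kind, coloured by
#' taxonomy category; borderline cells are outlined.
#'
#' @param object A `gain_taxonomy` tibble from [classify_gain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gain_taxonomy
#' @export
autoplot.gain_taxonomy <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$n_lbl <- factor(df$n, levels = sort(unique(df$n)))
  df$beta3_lbl <- factor(df$beta3, levels = sort(unique(df$beta3)))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$n_lbl, y = .data$beta3_lbl, fill = .data$category)
  ) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::geom_tile(
      data = df[df$borderline, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~pair_kind) +
    ggplot2::labs(x = "Sample size", y = "Interaction effect size",
                  fill = "Category") +
    ggplot2::theme_bw()
}
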