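#' Plot per-TG similarity-bin shares
#'
#' Stacked bars of the percentage of compounds per similarity bin for each
#' TG and approach (very low < 66%, low 66-85%, high > 85% probability of an
#' identical result upon replication).
#'
#' @param object a `"tg_summary"` tibble ([summarize_tg()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tg_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("pct_very_low", "pct_low", "pct_high"),
                        names_to = "bin", values_to = "pct") |>
    mutate(bin = factor(sub("^pct_", "", .data$bin),
                        levels = rev(SIMILARITY_BINS)))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$tg), y = .data$pct,
                               fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~approach, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(
      values = c(very_low = "#c0392b", low = "#f1c40f", high = "#27ae60"),
      breaks = SIMILARITY_BINS,
      labels = c("< 66%", "66-85%", "> 85%"),
      name = "Similarity"
    ) +
    ggplot2::labs(x = "OECD TG", y = "% of compounds") +
    ggplot2::theme_minimal()
}

#' Plot a call cross-tabulation
#'
#' Tile plot of the overall-call distribution over the common compounds of
#' two databases, with concordant cells outlined.
#'
#' @param object a `"call_xtab"` ([cross_tabulate()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.call_xtab <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$call_b, y = .data$call_a,
                               fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = long[long$concordant, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2980b9") +
    ggplot2::labs(x = object$dataset_b, y = object$dataset_a, fill = "n") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity panel
#'
#' Dot plot of the mean paired difference in positive fraction per panel
#' entry, with significant options highlighted.
#'
#' @param object a `"sensitivity_panel"` tibble ([run_panel()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sensitivity_panel <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!d$skipped, , drop = FALSE]
  d$label <- paste0("TG", d$tg, " ", d$variable, ": ", d$option)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_diff, y = .data$label,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "grey40"),
                                name = "p < alpha") +
    ggplot2::labs(x = "Mean difference in positive fraction (option - rest)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
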