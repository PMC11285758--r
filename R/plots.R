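# ggplot2 figures for each result type.

#' @importFrom ggplot2 ggplot aes geom_col geom_hline geom_line geom_point
#'   geom_boxplot labs scale_fill_manual facet_wrap scale_x_log10
NULL

#' Plot a positional bin profile
#'
#' Bar chart of per-bin proportions with the over/under-abundance thresholds
#' drawn as dashed lines; bins are coloured by their call when present.
#'
#' @param object An `lcr_bin_profile` (see [bin_positions()] and
#'   [call_abundance()]).
#' @param over_threshold,under_threshold Threshold lines (defaults 0.08,
#'   0.02).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcr_bin_profile <- function(object, over_threshold = 0.08,
                                     under_threshold = 0.02, ...) {
  object <- as_tibble(object)
  p <- if ("call" %in% names(object)) {
    ggplot(object, aes(x = .data$lower + (.data$upper - .data$lower) / 2,
                       y = .data$proportion, fill = .data$call)) +
      geom_col(width = 0.9 / nrow(object)) +
      scale_fill_manual(values = c(over = "#d95f02", under = "#7570b3",
                                   neutral = "grey60"))
  } else {
    ggplot(object, aes(x = .data$lower + (.data$upper - .data$lower) / 2,
                       y = .data$proportion)) +
      geom_col(width = 0.9 / nrow(object), fill = "grey60")
  }
  p +
    geom_hline(yintercept = over_threshold, linetype = "dashed") +
    geom_hline(yintercept = under_threshold, linetype = "dashed") +
    labs(x = "normalised gene position", y = "proportion of LCRs")
}

#' Plot an accumulation curve
#'
#' @param object An `lcr_accum` object.
#' @param ... Unused.
#' @return A ggplot object (mean richness against sample size, log x).
#' @export
autoplot.lcr_accum <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$size, y = .data$mean_richness)) +
    geom_line() + geom_point() + scale_x_log10() +
    labs(x = "number of LCRs sampled", y = "mean unique LCR types",
         subtitle = sprintf("%s slope: %.3f", object$model, object$slope))
}

#' Plot the purity-gradient profile
#'
#' One line per clade: the fraction of genes with at least one LCR in (or
#' above, for the cumulative convention) each 10% purity bin.
#'
#' @param gradient Output of [purity_gradient_profile()].
#' @return A ggplot object.
#' @export
plot_purity_gradient <- function(gradient) {
  ggplot(gradient, aes(x = .data$lower, y = .data$proportion,
                       colour = .data$clade_id)) +
    geom_line() + geom_point() +
    labs(x = "purity bin lower edge (%)",
         y = "proportion of genes with an LCR", colour = "clade")
}

#' Plot a group comparison
#'
#' Dot plot of group medians per clade for an omega or %GC comparison.
#'
#' @param cmp An `lcr_group_compare` tibble (from [omega_group_compare()] or
#'   [gc_group_compare()]).
#' @param value_label Y-axis label (default "value").
#' @return A ggplot object.
#' @export
plot_group_compare <- function(cmp, value_label = "value") {
  long <- cmp %>%
    select("unit", "median_lcr", "median_other") %>%
    tidyr::pivot_longer(c("median_lcr", "median_other"),
                        names_to = "group", values_to = "median") %>%
    mutate(group = ifelse(.data$group == "median_lcr", "with LCR",
                          "without LCR"))
  ggplot(long, aes(x = .data$unit, y = .data$median, fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = "clade", y = paste("median", value_label), fill = NULL)
}

#' Plot top-k LCR-type proportions
#'
#' Stacked bar of the most abundant LCR types per clade, with the remainder
#' aggregated.
#'
#' @param topk Tibble as produced by [top_k_proportions()], optionally with
#'   a `clade_id` column for faceting.
#' @return A ggplot object.
#' @export
plot_top_k <- function(topk) {
  x <- if ("clade_id" %in% names(topk)) topk$clade_id else "all"
  ggplot(topk, aes(x = x, y = .data$proportion, fill = .data$signature)) +
    geom_col() +
    labs(x = "clade", y = "proportion of LCRs", fill = "LCR type")
}
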