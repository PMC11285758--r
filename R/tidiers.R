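# broom-style tidiers for the package's result objects.

#' Tidy a Fisher test result
#'
#' @param x An `lcr_fisher` object.
#' @param ... Unused.
#' @return One-row tibble with the table cells, odds ratio, p-value,
#'   direction and testability flag.
#' @export
tidy.lcr_fisher <- function(x, ...) {
  tibble(
    n11 = x$n11, n12 = x$n12, n21 = x$n21, n22 = x$n22,
    odds_ratio = x$odds_ratio, p_value = x$p_two_sided,
    direction = x$direction, untestable = x$untestable
  )
}

#' @rdname tidy.lcr_fisher
#' @export
glance.lcr_fisher <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_two_sided,
         direction = x$direction, untestable = x$untestable)
}

#' Tidy an accumulation curve
#'
#' @param x An `lcr_accum` object from [accumulation_curve()].
#' @param ... Unused.
#' @return `tidy()` returns the curve (sample size, mean richness);
#'   `glance()` the fitted slope, model and sizes.
#' @export
tidy.lcr_accum <- function(x, ...) x$curve

#' @rdname tidy.lcr_accum
#' @export
glance.lcr_accum <- function(x, ...) {
  tibble(slope = x$slope, model = x$model, n_lcrs = x$n,
         n_permutations = x$n_permutations)
}

#' @export
print.lcr_accum <- function(x, ...) {
  cat(sprintf(
    "LCR-type accumulation curve: %d LCRs, %d grid points, %s slope %.3f\n",
    x$n, nrow(x$curve), x$model, x$slope
  ))
  invisible(x)
}
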