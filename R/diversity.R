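# LCR-type diversity statistics. Abundances are counts of canonical
# composition signatures; any of these functions also accepts a raw character
# vector of signatures, which is tabulated first.

as_counts <- function(counts) {
  if (is.character(counts)) counts <- table(counts)
  counts <- counts[counts > 0]
  if (any(counts < 0)) abort("negative counts")
  as.numeric(counts)
}

#' LCR-type richness
#'
#' Number of distinct LCR types (canonical signatures) present.
#'
#' @param counts Named count vector, table, or character vector of
#'   signatures.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  length(as_counts(counts))
}

#' Simpson's index of diversity
#'
#' \eqn{D = 1 - \sum p_i^2} over the LCR-type relative abundances. 0 for a
#' single type; approaches 1 as many types share the abundance evenly.
#'
#' @inheritParams richness
#' @return Fraction in \[0, 1).
#' @export
simpson_index <- function(counts) {
  x <- as_counts(counts)
  if (sum(x) < 1) abort("total count must be at least 1")
  unname(vegan::diversity(x, index = "simpson"))
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} (natural log by default); maximal at
#' `log(richness)` for even abundances.
#'
#' @inheritParams richness
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative real.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  x <- as_counts(counts)
  if (sum(x) < 1) abort("total count must be at least 1")
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Per-unit diversity summary
#'
#' Richness, Simpson's and Shannon's indices of LCR types per species (or any
#' other grouping column).
#'
#' @param lcrs LCR annotation tibble with a `signature` column.
#' @param unit Grouping column name (default `"species_id"`).
#'
#' @return Tibble with `unit`, `n_lcrs`, `richness`, `simpson_d`,
#'   `shannon_h`.
#' @export
diversity_by_unit <- function(lcrs, unit = "species_id") {
  stopifnot(unit %in% names(lcrs), "signature" %in% names(lcrs))
  lcrs %>%
    group_by(unit = .data[[unit]]) %>%
    summarise(
      n_lcrs = n(),
      richness = richness(.data$signature),
      simpson_d = simpson_index(.data$signature),
      shannon_h = shannon_index(.data$signature),
      .groups = "drop"
    )
}

#' LCR-type accumulation curve and slope
#'
#' Treats detected LCRs as sampling effort ("area") and unique LCR types as
#' "species": for each sample size on a log-spaced grid, the mean number of
#' unique signatures over random subsamples (without replacement) is
#' computed, and a slope is fitted. The default model regresses richness on
#' the natural log of sample size; `model = "power"` fits the log-log
#' power-law instead.
#'
#' @param signatures Character vector of LCR signatures (one entry per
#'   detected LCR).
#' @param n_permutations Random subsamples per grid point (default 50).
#' @param grid_size Number of log-spaced sample sizes (default 12).
#' @param model `"semilog"` (default) or `"power"`.
#' @param seed Optional integer seed for the subsampling.
#'
#' @return An `lcr_accum` object: list with `curve` (tibble of `size`,
#'   `mean_richness`), `slope`, `model`, `n` and `n_permutations`.
#' @export
accumulation_curve <- function(signatures, n_permutations = 50,
                               grid_size = 12,
                               model = c("semilog", "power"), seed = NULL) {
  model <- match.arg(model)
  n <- length(signatures)
  if (n < 2) abort("need at least 2 LCRs")
  sizes <- unique(pmin(n, pmax(2, round(exp(
    seq(log(2), log(n), length.out = grid_size)
  )))))
  draw <- function() {
    purrr::map_dbl(sizes, function(s) {
      mean(purrr::map_int(seq_len(n_permutations), function(i) {
        length(unique(sample(signatures, s, replace = FALSE)))
      }))
    })
  }
  mean_rich <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  curve <- tibble(size = sizes, mean_richness = mean_rich)
  slope <- if (model == "semilog") {
    if (length(sizes) < 2) NA_real_ else
      unname(coef(lm(mean_richness ~ log(size), data = curve))[2])
  } else {
    unname(coef(lm(log(mean_richness) ~ log(size), data = curve))[2])
  }
  structure(
    list(curve = curve, slope = slope, model = model, n = n,
         n_permutations = n_permutations),
    class = "lcr_accum"
  )
}

#' Top-k LCR-type proportions
#'
#' The `k` most abundant signatures (ties broken alphabetically) with their
#' proportions; all remaining types are aggregated into one `(other)` row.
#' Proportions sum to 1.
#'
#' @inheritParams richness
#' @param k Number of top types to report (default 20).
#'
#' @return Tibble with `signature`, `count`, `proportion`, `rank` (`NA` for
#'   the remainder row).
#' @export
top_k_proportions <- function(counts, k = 20) {
  if (is.character(counts)) counts <- table(counts)
  tab <- tibble(signature = names(counts), count = as.numeric(counts)) %>%
    filter(.data$count > 0) %>%
    arrange(dplyr::desc(.data$count), .data$signature)
  if (nrow(tab) == 0) {
    return(tibble(signature = character(), count = double(),
                  proportion = double(), rank = integer()))
  }
  total <- sum(tab$count)
  top <- head(tab, k) %>% mutate(rank = row_number())
  rest <- sum(tab$count) - sum(top$count)
  out <- bind_rows(
    top,
    tibble(signature = "(other)", count = rest, rank = NA_integer_)
  ) %>%
    mutate(proportion = .data$count / total) %>%
    select("signature", "count", "proportion", "rank")
  out
}
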