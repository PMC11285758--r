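#' Normalised midpoint of a feature along a gene
#'
#' The feature's midpoint position divided by the protein length:
#' `((start0 + end0) / 2) / protein_length`. Vectorised.
#'
#' @param start0,end0 0-based, half-open residue interval(s).
#' @param protein_length Protein length(s) in residues.
#'
#' @return Numeric fractions in \[0, 1).
#' @examples
#' normalized_midpoint(0, 10, 100) # 0.05
#' @export
normalized_midpoint <- function(start0, end0, protein_length) {
  if (any(protein_length <= 0)) abort("protein_length must be positive")
  if (any(end0 > protein_length)) abort("feature extends past protein")
  ((start0 + end0) / 2) / protein_length
}

#' Bin normalised positions
#'
#' Positions in \[0, 1) are assigned to `n_bins` half-open bins
#' \[k/n, (k+1)/n); a position exactly equal to 1 falls in the last bin.
#' Under a uniform positional distribution each of 20 bins is expected to
#' hold about 5% of features.
#'
#' @param positions Numeric vector of fractions in \[0, 1\].
#' @param n_bins Number of bins (20 for amino-acid-specific profiles, 10 for
#'   the PSS/LCR co-distribution).
#'
#' @return An `lcr_bin_profile` tibble with columns `bin` (0-based),
#'   `lower`, `upper`, `count`, `proportion`.
#' @export
bin_positions <- function(positions, n_bins = 20) {
  if (any(is.na(positions)) || any(positions < 0) || any(positions > 1)) {
    abort("positions must lie in [0, 1]")
  }
  bin <- pmin(floor(positions * n_bins), n_bins - 1)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  out <- tibble(
    bin = seq_len(n_bins) - 1L,
    lower = (seq_len(n_bins) - 1) / n_bins,
    upper = seq_len(n_bins) / n_bins,
    count = counts,
    proportion = if (sum(counts) > 0) counts / sum(counts) else rep(0, n_bins)
  )
  class(out) <- c("lcr_bin_profile", class(out))
  attr(out, "n_bins") <- n_bins
  attr(out, "total") <- length(positions)
  out
}

#' Call per-bin over/under-abundance
#'
#' Labels each bin of a positional profile `over` when its proportion is at
#' least `over_threshold` (default 8%), `under` when at most
#' `under_threshold` (default 2%), otherwise `neutral`.
#'
#' @param profile An `lcr_bin_profile` (from [bin_positions()]) or any tibble
#'   with a `proportion` column.
#' @param over_threshold,under_threshold Call thresholds (defaults 0.08 and
#'   0.02).
#'
#' @return `profile` with an added `call` column.
#' @export
call_abundance <- function(profile, over_threshold = 0.08,
                           under_threshold = 0.02) {
  stopifnot("proportion" %in% names(profile))
  profile$call <- dplyr::case_when(
    profile$proportion >= over_threshold ~ "over",
    profile$proportion <= under_threshold ~ "under",
    TRUE ~ "neutral"
  )
  profile
}

#' Purity-gradient profile of LCR-containing genes
#'
#' For each clade and each 10% purity bin, the fraction of genes carrying at
#' least one LCR whose purity falls in the bin (`per_bin` mode) or lies
#' strictly above the bin's lower edge (`cumulative` mode, the default; "at
#' 70% purity" then means purity > 0.7). The cumulative profile is monotone
#' non-increasing across bins.
#'
#' @param lcrs LCR annotation tibble (`gene_id`, `purity`; a `clade_id`
#'   column is taken from `genes` when absent).
#' @param genes Gene table giving the denominator: one row per gene with
#'   `gene_id` and `clade_id` (duplicate gene-species rows are fine).
#' @param mode `"cumulative"` or `"per_bin"`.
#'
#' @return Tibble with `clade_id`, `lower`, `upper` (purity bin edges in
#'   percent), `n_genes`, `proportion`; the convention used is recorded in
#'   the `"mode"` attribute.
#' @export
purity_gradient_profile <- function(lcrs, genes,
                                    mode = c("cumulative", "per_bin")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "clade_id") %in% names(genes)))
  denom <- genes %>% distinct(.data$clade_id, .data$gene_id) %>%
    count(.data$clade_id, name = "n_total")
  if (!"clade_id" %in% names(lcrs)) {
    lcrs <- left_join(lcrs,
                      distinct(genes, .data$gene_id, .data$clade_id),
                      by = "gene_id")
  }
  edges <- tibble(lower = seq(0, 90, by = 10), upper = seq(10, 100, by = 10))
  grid <- tidyr::crossing(denom, edges)
  hit <- purrr::pmap_int(
    list(grid$clade_id, grid$lower, grid$upper),
    function(cl, lo, hi) {
      sub <- lcrs[lcrs$clade_id == cl, , drop = FALSE]
      p <- sub$purity * 100
      keep <- if (mode == "cumulative") p > lo else p > lo & p <= hi
      length(unique(sub$gene_id[keep]))
    }
  )
  out <- grid %>%
    mutate(n_genes = hit, proportion = hit / .data$n_total) %>%
    select("clade_id", "lower", "upper", "n_genes", "proportion")
  attr(out, "mode") <- mode
  out
}

#' Classify a gene as terminal, central or mixed
#'
#' A gene is `terminal` when all its feature midpoints fall in the outer
#' zones (below `terminal_cut` or at/above `1 - terminal_cut`), `central`
#' when all fall in the inner zone, and `mixed` otherwise.
#'
#' @param midpoints Normalised midpoints of the gene's features (LCRs or
#'   PSS), at least one.
#' @param terminal_cut Width of each terminal zone (default 0.1).
#'
#' @return `"terminal"`, `"central"` or `"mixed"`.
#' @export
classify_gene_position <- function(midpoints, terminal_cut = 0.1) {
  if (length(midpoints) == 0) abort("at least one midpoint required")
  is_term <- midpoints < terminal_cut | midpoints >= 1 - terminal_cut
  if (all(is_term)) "terminal" else if (all(!is_term)) "central" else "mixed"
}
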