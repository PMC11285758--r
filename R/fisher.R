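# Selection-evidence integration: PSS/omega table ingestion, Fisher overlap
# and co-occurrence tests, and omega / %GC group comparisons.

new_lcr_fisher <- function(n11, n12, n21, n22, untestable = FALSE,
                           note = NA_character_) {
  if (untestable) {
    or <- NA_real_
    p <- NA_real_
    direction <- "none"
  } else {
    num <- n11 * n22
    den <- n12 * n21
    or <- if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else num / den
    p <- fisher.test(matrix(c(n11, n21, n12, n22), nrow = 2))$p.value
    direction <- if (is.na(or)) "none"
    else if (or > 1) "enrichment"
    else if (or < 1) "depletion"
    else "none"
  }
  structure(
    list(n11 = n11, n12 = n12, n21 = n21, n22 = n22, odds_ratio = or,
         p_two_sided = p, direction = direction, untestable = untestable,
         note = note),
    class = "lcr_fisher"
  )
}

#' @export
print.lcr_fisher <- function(x, ...) {
  cat("Fisher 2x2 test\n")
  cat(sprintf("  table: %d %d / %d %d\n", x$n11, x$n12, x$n21, x$n22))
  if (x$untestable) {
    cat("  untestable:", x$note, "\n")
  } else {
    cat(sprintf("  odds ratio: %.4g   p: %.4g   direction: %s\n",
                x$odds_ratio, x$p_two_sided, x$direction))
  }
  invisible(x)
}

#' Load a table of positively selected sites
#'
#' Applies the strict posterior-probability filter (sites kept only when the
#' Bayes-empirical-Bayes posterior exceeds `threshold`, 0.95 by default) and
#' deduplicates per (gene, site), retaining the maximum posterior.
#'
#' @param pss Data frame with columns `gene_id`, `site` (0-based amino-acid
#'   alignment column) and `posterior` in \[0, 1\]. Extra columns (e.g.
#'   `clade_id`) are preserved.
#' @param threshold Posterior cutoff, strict (default 0.95).
#'
#' @return Filtered, deduplicated tibble.
#' @export
load_pss <- function(pss, threshold = 0.95) {
  stopifnot(all(c("gene_id", "site", "posterior") %in% names(pss)))
  if (any(is.na(pss$posterior)) ||
      any(pss$posterior < 0 | pss$posterior > 1)) {
    abort("posterior outside [0, 1]")
  }
  extra <- setdiff(names(pss), c("gene_id", "site", "posterior"))
  if (nrow(pss) == 0) {
    return(select(as_tibble(pss), "gene_id", "site",
                  dplyr::all_of(extra), "posterior"))
  }
  pss %>%
    as_tibble() %>%
    filter(.data$posterior > threshold) %>%
    group_by(dplyr::across(dplyr::all_of(c("gene_id", "site", extra)))) %>%
    summarise(posterior = max(.data$posterior), .groups = "drop")
}

#' Filter lineage omega values
#'
#' Drops omega (dN/dS) values above `cap` before group comparisons; codeml's
#' free-ratio model occasionally reports degenerate values as high as 999.
#'
#' @param omega Data frame with an `omega` column.
#' @param cap Maximum retained omega (default 2).
#' @return Filtered tibble.
#' @export
filter_omega <- function(omega, cap = 2) {
  stopifnot("omega" %in% names(omega))
  if (any(omega$omega < 0, na.rm = TRUE)) abort("negative omega")
  filter(as_tibble(omega), !is.na(.data$omega), .data$omega <= cap)
}

#' Gene-level co-occurrence test of LCRs and PSS
#'
#' Fisher's exact test on the 2x2 table of per-gene presence flags: genes
#' with both features, LCR only, PSS only, and neither. The odds ratio
#' reported is the unconditional sample OR `(n11 * n22) / (n12 * n21)`
#' (infinite when a denominator cell is 0); the p-value is the exact
#' two-sided hypergeometric probability.
#'
#' @param flags Data frame with logical columns `has_lcr` and `has_pss`, one
#'   row per gene.
#'
#' @return An `lcr_fisher` object; see [tidy.lcr_fisher()].
#' @export
cooccurrence_fisher <- function(flags) {
  stopifnot(all(c("has_lcr", "has_pss") %in% names(flags)), nrow(flags) >= 1)
  n11 <- sum(flags$has_lcr & flags$has_pss)
  n12 <- sum(flags$has_lcr & !flags$has_pss)
  n21 <- sum(!flags$has_lcr & flags$has_pss)
  n22 <- sum(!flags$has_lcr & !flags$has_pss)
  new_lcr_fisher(n11, n12, n21, n22)
}

#' Interval-overlap test between LCRs and PSS
#'
#' Fisher's exact test of positional overlap between two interval sets on a
#' shared coordinate domain, with the contingency table built the way the
#' bedtools fisher tool documents it: `n11` = number of `a` intervals
#' overlapping at least one `b` interval, `n12 = |a| - n11`, `n21` = number
#' of `b` intervals overlapping no `a` interval, and
#' `n22 = max(0, round(domain_length / (mean_len(a) + mean_len(b))) - n11 -
#' n12 - n21)`, an estimate of the number of unoccupied interval-sized slots.
#'
#' @param a Data frame of intervals (`start`, `end`; 0-based half-open) —
#'   the LCR spans.
#' @param b Data frame of intervals — PSS sites as length-1 intervals (a
#'   `site` column is accepted and expanded to `[site, site + 1)`).
#' @param domain_length Length of the coordinate domain (amino-acid
#'   alignment columns).
#'
#' @return An `lcr_fisher` object; untestable (all-NA statistics) when
#'   either side is empty.
#' @export
interval_overlap_fisher <- function(a, b, domain_length) {
  if (!is.null(b) && "site" %in% names(b) && !"start" %in% names(b)) {
    b <- tibble(start = b$site, end = b$site + 1)
  }
  if (is.null(a) || nrow(a) == 0 || is.null(b) || nrow(b) == 0) {
    return(new_lcr_fisher(0L, 0L, 0L, 0L, untestable = TRUE,
                          note = "empty interval set"))
  }
  if (any(a$start < 0 | a$end > domain_length) ||
      any(b$start < 0 | b$end > domain_length)) {
    abort("intervals outside [0, domain_length)")
  }
  overlaps_any <- function(x, y) {
    rowSums(outer(x$start, y$end, `<`) & outer(x$end, y$start, `>`)) > 0
  }
  n11 <- sum(overlaps_any(a, b))
  n12 <- nrow(a) - n11
  n21 <- sum(!overlaps_any(b, a))
  slots <- round(domain_length / (mean(a$end - a$start) +
                                    mean(b$end - b$start)))
  n22 <- max(0, slots - n11 - n12 - n21)
  new_lcr_fisher(n11, n12, n21, n22)
}

#' Three-level LCR/PSS overlap analysis
#'
#' Runs the overlap and co-occurrence analyses at the three scales used for
#' clade-structured data: (i) gene-wise interval overlap on each gene's
#' amino-acid alignment columns, (ii) clade-wise interval overlap on a
#' concatenated coordinate space with per-gene offsets, and (iii) clade-wise
#' co-occurrence of per-gene presence flags. Significance is labelled at
#' `alpha` (default 0.05, two-sided, uncorrected).
#'
#' @param aligned_lcrs Tibble of aligned LCRs (`gene_id`, `col_start`,
#'   `col_end`).
#' @param pss Tibble of retained PSS (`gene_id`, `site`), e.g. from
#'   [load_pss()].
#' @param gene_info One row per gene: `gene_id`, `clade_id`, `n_col` (the
#'   gene's amino-acid alignment length).
#' @param alpha Significance threshold (default 0.05).
#' @param levels Which of the three levels to compute (default all).
#'
#' @return Tibble with one row per test: `level` (`gene`, `clade_overlap`,
#'   `clade_cooccurrence`), `unit`, the table cells, `odds_ratio`, `p`,
#'   `direction`, `significant`, `untestable`.
#' @export
three_level_overlap <- function(aligned_lcrs, pss, gene_info, alpha = 0.05,
                                levels = c("gene", "clade_overlap",
                                           "clade_cooccurrence")) {
  stopifnot(all(c("gene_id", "clade_id", "n_col") %in% names(gene_info)))
  levels <- match.arg(levels, several.ok = TRUE)
  row_of <- function(level, unit, f) {
    tibble(
      level = level, unit = unit, n11 = f$n11, n12 = f$n12, n21 = f$n21,
      n22 = f$n22, odds_ratio = f$odds_ratio, p = f$p_two_sided,
      direction = f$direction,
      significant = !f$untestable & !is.na(f$p_two_sided) &
        f$p_two_sided < alpha,
      untestable = f$untestable
    )
  }
  gene_rows <- if ("gene" %in% levels) {
    purrr::map(seq_len(nrow(gene_info)), function(i) {
      g <- gene_info$gene_id[i]
      a <- aligned_lcrs %>% filter(.data$gene_id == g) %>%
        mutate(start = .data$col_start, end = .data$col_end)
      b <- pss %>% filter(.data$gene_id == g)
      row_of("gene", g, interval_overlap_fisher(a, b, gene_info$n_col[i]))
    })
  } else list()
  clades <- unique(gene_info$clade_id)
  clade_rows <- purrr::map(clades, function(cl) {
    info <- gene_info %>% filter(.data$clade_id == cl) %>%
      arrange(.data$gene_id) %>%
      mutate(offset = cumsum(dplyr::lag(.data$n_col, default = 0)))
    a <- aligned_lcrs %>%
      inner_join(select(info, "gene_id", "offset"), by = "gene_id") %>%
      mutate(start = .data$col_start + .data$offset,
             end = .data$col_end + .data$offset)
    b <- pss %>%
      inner_join(select(info, "gene_id", "offset"), by = "gene_id") %>%
      mutate(start = .data$site + .data$offset,
             end = .data$site + .data$offset + 1)
    ov <- if ("clade_overlap" %in% levels) {
      row_of("clade_overlap", cl,
             interval_overlap_fisher(a, b, sum(info$n_col)))
    } else NULL
    co <- if ("clade_cooccurrence" %in% levels) {
      flags <- info %>%
        mutate(
          has_lcr = .data$gene_id %in% aligned_lcrs$gene_id,
          has_pss = .data$gene_id %in% pss$gene_id
        )
      row_of("clade_cooccurrence", cl, cooccurrence_fisher(flags))
    } else NULL
    bind_rows(ov, co)
  })
  bind_rows(bind_rows(gene_rows), bind_rows(clade_rows))
}

# Shared two-group Wilcoxon comparison used by the omega and %GC analyses.
group_compare <- function(df, value_col, in_group, unit_col = "clade_id") {
  df$.value <- df[[value_col]]
  df$.in <- in_group
  units <- if (unit_col %in% names(df)) unique(df[[unit_col]]) else "all"
  rows <- purrr::map(units, function(u) {
    sub <- if (unit_col %in% names(df)) df[df[[unit_col]] == u, ] else df
    x <- sub$.value[sub$.in]
    y <- sub$.value[!sub$.in]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble(
        unit = u, n_lcr = length(x), n_other = length(y),
        median_lcr = NA_real_, median_other = NA_real_,
        mean_lcr = NA_real_, mean_other = NA_real_, p = NA_real_,
        direction = "untestable"
      ))
    }
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    tibble(
      unit = u, n_lcr = length(x), n_other = length(y),
      median_lcr = median(x), median_other = median(y),
      mean_lcr = mean(x), mean_other = mean(y), p = p,
      direction = if (median(x) < median(y)) "lower"
      else if (median(x) > median(y)) "higher" else "equal"
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("lcr_group_compare", class(out))
  out
}

#' Compare omega between LCR-containing and LCR-free genes
#'
#' Per clade, a two-sided Wilcoxon rank-sum test of lineage omega (dN/dS)
#' values between genes with and without LCRs, after capping omega at
#' `cap` (default 2) to remove degenerate estimates.
#'
#' @param omega Tibble with `gene_id`, `omega` and (optionally) `clade_id`,
#'   `lineage_id`.
#' @param lcr_genes Character vector of LCR-containing gene ids.
#' @param cap Omega cap applied via [filter_omega()].
#'
#' @return An `lcr_group_compare` tibble: per clade, group sizes, medians,
#'   means, Wilcoxon `p` and the direction of the LCR group (`lower` /
#'   `higher`).
#' @export
omega_group_compare <- function(omega, lcr_genes, cap = 2) {
  omega <- filter_omega(omega, cap = cap)
  group_compare(omega, "omega", omega$gene_id %in% lcr_genes)
}

#' Compare %GC between LCR-containing and LCR-free genes
#'
#' Per clade, a two-sided Wilcoxon rank-sum test of per-CDS GC content
#' between genes with and without LCRs.
#'
#' @param genes Tibble with `gene_id`, `cds` and (optionally) `clade_id`.
#' @param lcr_genes Character vector of LCR-containing gene ids.
#'
#' @return An `lcr_group_compare` tibble (see [omega_group_compare()]); the
#'   value compared is `percent_gc(cds)`.
#' @export
gc_group_compare <- function(genes, lcr_genes) {
  genes <- as_tibble(genes)
  genes$gc <- percent_gc(genes$cds)
  group_compare(genes, "gc", genes$gene_id %in% lcr_genes)
}
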