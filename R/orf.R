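STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate open reading frames
#'
#' A CDS passes when it contains only A/C/G/T, its length is a multiple of 3,
#' the first codon is ATG, and no stop codon (TAA/TAG/TGA) occurs before the
#' final codon. A trailing stop codon is permitted. The reason reports the
#' first failed rule, checked in the order: bad character, bad length, no
#' start codon, premature stop. Mixed case and `N` count as bad characters.
#'
#' @param cds Character vector of nucleotide sequences.
#'
#' @return Tibble with columns `cds` (the input), `pass` (logical) and
#'   `reason` (`NA` when passing).
#'
#' @examples
#' check_orf(c("ATGAAATAA", "ATGTAAAAATAA"))
#' @export
check_orf <- function(cds) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return("bad length")
    if (grepl("[^ACGT]", s)) return("bad character")
    if (nchar(s) %% 3 != 0) return("bad length")
    if (substr(s, 1, 3) != "ATG") return("no start codon")
    n_codon <- nchar(s) / 3
    if (n_codon > 1) {
      codons <- substring(s, seq(1, nchar(s) - 3, by = 3),
                          seq(3, nchar(s) - 3, by = 3))
      if (any(codons[-1] %in% STOP_CODONS)) return("premature stop")
    }
    NA_character_
  }
  reason <- purrr::map_chr(cds, one)
  tibble(cds = cds, pass = is.na(reason), reason = reason)
}

#' Apply the minimum-species clade filter
#'
#' After per-sequence ORF filtering, genes represented by fewer than
#' `min_species` species within a clade are removed. Clades in which every
#' gene drops below the threshold are flagged as excluded.
#'
#' @param genes Data frame with columns `gene_id`, `species_id`, `clade_id`
#'   (one row per gene-species sequence that survived the ORF check).
#' @param min_species Minimum surviving species per gene (default 3).
#'
#' @return The retained rows of `genes`, with attributes `removed` (tibble of
#'   dropped genes with their species counts) and `excluded_clades`
#'   (character vector of clades left with no genes at all). Use
#'   [clade_filter_report()] to retrieve them.
#' @export
filter_clade_genes <- function(genes, min_species = 3) {
  stopifnot(all(c("gene_id", "species_id", "clade_id") %in% names(genes)))
  tally <- genes %>%
    distinct(.data$clade_id, .data$gene_id, .data$species_id) %>%
    count(.data$clade_id, .data$gene_id, name = "n_species")
  keep <- filter(tally, .data$n_species >= min_species)
  removed <- filter(tally, .data$n_species < min_species)
  out <- semi_join(genes, keep, by = c("clade_id", "gene_id"))
  excluded <- setdiff(unique(genes$clade_id), unique(out$clade_id))
  attr(out, "removed") <- removed
  attr(out, "excluded_clades") <- excluded
  out
}

#' Report from the clade filter
#'
#' @param genes Result of [filter_clade_genes()].
#' @return List with elements `removed` and `excluded_clades`.
#' @export
clade_filter_report <- function(genes) {
  list(
    removed = attr(genes, "removed"),
    excluded_clades = attr(genes, "excluded_clades")
  )
}

#' Percent GC of coding sequences
#'
#' @param cds Character vector of nucleotide sequences (A/C/G/T).
#' @return Numeric vector: `100 * (G + C) / (A + C + G + T)` per sequence.
#' @examples
#' percent_gc(c("GGCC", "ATAT", "ATGC"))
#' @export
percent_gc <- function(cds) {
  if (any(is.na(cds)) || any(!nzchar(cds))) abort("zero-length CDS")
  gc <- stringr::str_count(cds, "[GC]")
  acgt <- stringr::str_count(cds, "[ACGT]")
  if (any(acgt == 0)) abort("zero-length CDS")
  100 * gc / acgt
}
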