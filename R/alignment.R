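# Codon alignments are held as tibbles with one row per species:
# gene_id, species_id, aligned_cds (string over A/C/G/T/-, length a multiple
# of 3, identical across the rows of a gene). Amino-acid column k (0-based)
# corresponds to nucleotide columns [3k, 3k+3). A codon column is a gap for a
# species when its three characters are "---".

# Split an aligned row into codon strings.
row_codons <- function(aligned) {
  n <- nchar(aligned)
  if (n %% 3 != 0) abort("aligned row length not a multiple of 3")
  substring(aligned, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Map LCR residue coordinates into alignment columns
#'
#' Converts each annotation's residue interval (0-based, half-open, in the
#' species' ungapped protein frame) into amino-acid column coordinates of the
#' gene's codon alignment, walking the species' gap pattern. Internal gaps
#' inside the stretch inflate the column span.
#'
#' @param lcrs LCR annotation tibble (needs `gene_id`, `species_id`,
#'   `start0`, `end0`).
#' @param alignments Alignment tibble (`gene_id`, `species_id`,
#'   `aligned_cds`).
#'
#' @return `lcrs` with added columns `col_start`, `col_end` (0-based,
#'   half-open amino-acid alignment columns).
#' @export
map_to_alignment <- function(lcrs, alignments) {
  stopifnot(all(c("gene_id", "species_id", "start0", "end0") %in% names(lcrs)))
  key_l <- paste(lcrs$gene_id, lcrs$species_id)
  key_a <- paste(alignments$gene_id, alignments$species_id)
  idx <- match(key_l, key_a)
  if (anyNA(idx)) {
    abort(paste0("species missing from alignment: ",
                 paste(unique(key_l[is.na(idx)]), collapse = "; ")))
  }
  res <- purrr::pmap(
    list(lcrs$start0, lcrs$end0, idx),
    function(s, e, i) {
      codons <- row_codons(alignments$aligned_cds[i])
      resid_col <- which(codons != "---") # alignment columns carrying residues
      if (e > length(resid_col)) abort("coordinate overflow")
      c(resid_col[s + 1] - 1L, resid_col[e])
    }
  )
  lcrs %>%
    mutate(
      col_start = purrr::map_int(res, ~ as.integer(.x[1])),
      col_end = purrr::map_int(res, ~ as.integer(.x[2]))
    )
}

# Inverse of map_to_alignment for one species row: alignment column interval
# back to ungapped residue coordinates. Used for round-trip checks.
project_from_alignment <- function(col_start, col_end, aligned_cds) {
  codons <- row_codons(aligned_cds)
  notgap <- codons != "---"
  cum <- cumsum(notgap)
  start0 <- if (col_start == 0) 0L else cum[col_start]
  end0 <- cum[col_end]
  c(start0 = as.integer(start0), end0 = as.integer(end0))
}

#' Group orthologous LCRs by positional overlap
#'
#' Within each gene, aligned LCRs from different species are grouped by
#' single-linkage connectivity under the relation "column intervals overlap
#' by at least `min_overlap` columns". Overlap in the shared alignment frame
#' is the indicator of orthologous repeats; transitivity can join regions
#' that do not directly overlap.
#'
#' @param aligned_lcrs Tibble with `gene_id`, `col_start`, `col_end` (as from
#'   [map_to_alignment()]).
#' @param min_overlap Minimum overlapping columns (default 1).
#'
#' @return Input with added `group_id` (1-based within gene, ordered by group
#'   span start), `span_start`, `span_end` (the group's union interval).
#' @export
group_orthologous <- function(aligned_lcrs, min_overlap = 1) {
  stopifnot(all(c("gene_id", "col_start", "col_end") %in% names(aligned_lcrs)))
  aligned_lcrs %>%
    mutate(.row = row_number()) %>%
    group_by(.data$gene_id) %>%
    group_modify(function(d, key) {
      ord <- order(d$col_start, d$col_end)
      gid <- integer(nrow(d))
      cur <- 0L
      max_end <- -Inf
      for (i in ord) {
        if (cur == 0L || d$col_start[i] > max_end - min_overlap) {
          cur <- cur + 1L
          max_end <- d$col_end[i]
        } else {
          max_end <- max(max_end, d$col_end[i])
        }
        gid[i] <- cur
      }
      d$group_id <- gid
      d %>%
        group_by(.data$group_id) %>%
        mutate(span_start = min(.data$col_start),
               span_end = max(.data$col_end)) %>%
        ungroup()
    }) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}

#' @importFrom dplyr group_modify
NULL

#' Per-column alignment coverage
#'
#' For each amino-acid column of each gene's codon alignment, the fraction of
#' species whose codon at that column is not a gap.
#'
#' @param alignments Alignment tibble (`gene_id`, `species_id`,
#'   `aligned_cds`).
#'
#' @return Tibble with `gene_id`, `col0` (0-based amino-acid column) and
#'   `coverage` in \[0, 1\].
#' @export
alignment_coverage <- function(alignments) {
  if (nrow(alignments) == 0) abort("empty alignment")
  alignments %>%
    group_by(.data$gene_id) %>%
    group_modify(function(d, key) {
      mats <- purrr::map(d$aligned_cds, ~ row_codons(.x) != "---")
      lens <- lengths(mats)
      if (length(unique(lens)) != 1) abort("ragged alignment rows")
      cov <- Reduce(`+`, purrr::map(mats, as.integer)) / nrow(d)
      tibble(col0 = seq_along(cov) - 1L, coverage = cov)
    }) %>%
    ungroup()
}
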