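# Readers and writers for the external formats the pipeline consumes:
# protein/CDS FASTA (headers "species_id|gene_id"), per-gene codon-alignment
# FASTA, and the TSV tables used between stages.

#' Read a gene table from protein and CDS FASTA files
#'
#' Headers must be `species_id|gene_id`. Entries present in only one of the
#' two files get `NA` for the missing sequence.
#'
#' @param protein_fasta,cds_fasta Paths to FASTA files (either may be
#'   `NULL`).
#' @param clade_id Optional clade label added as a column.
#'
#' @return Tibble with `gene_id`, `species_id`, `clade_id` (if given),
#'   `protein`, `cds`.
#' @export
read_gene_fasta <- function(protein_fasta = NULL, cds_fasta = NULL,
                            clade_id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA input")
  }
  parse_one <- function(path, reader, col) {
    x <- reader(path)
    hdr <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 2)
    out <- tibble(species_id = hdr[, 1], gene_id = hdr[, 2],
                  seq = unname(as.character(x)))
    names(out)[3] <- col
    out
  }
  tabs <- list()
  if (!is.null(protein_fasta)) {
    tabs$protein <- parse_one(protein_fasta, Biostrings::readAAStringSet,
                              "protein")
  }
  if (!is.null(cds_fasta)) {
    tabs$cds <- parse_one(cds_fasta, Biostrings::readDNAStringSet, "cds")
  }
  if (length(tabs) == 0) abort("no FASTA input given")
  out <- purrr::reduce(tabs, dplyr::full_join,
                       by = c("species_id", "gene_id"))
  if (!is.null(clade_id)) out$clade_id <- clade_id
  dplyr::relocate(out, "gene_id", "species_id")
}

#' @importFrom rlang :=
NULL

#' Read a per-gene codon alignment from aligned FASTA
#'
#' @param path Aligned FASTA (rows over A/C/G/T/-), headers
#'   `species_id|gene_id` or plain species ids.
#' @param gene_id Gene label used when headers carry no gene part.
#'
#' @return Alignment tibble (`gene_id`, `species_id`, `aligned_cds`).
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA input")
  }
  x <- Biostrings::readBStringSet(path)
  hdr <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 2)
  gid <- ifelse(nzchar(hdr[, 2]), hdr[, 2],
                gene_id %||% tools::file_path_sans_ext(basename(path)))
  tibble(gene_id = gid, species_id = hdr[, 1],
         aligned_cds = toupper(as.character(x)))
}

#' @importFrom rlang %||%
NULL

#' Write a gene table to FASTA
#'
#' Writes `protein` and/or `cds` columns as FASTA with `species_id|gene_id`
#' headers.
#'
#' @param genes Gene tibble.
#' @param protein_fasta,cds_fasta Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_gene_fasta <- function(genes, protein_fasta = NULL, cds_fasta = NULL) {
  hdr <- paste0(">", genes$species_id, "|", genes$gene_id)
  if (!is.null(protein_fasta)) {
    writeLines(rbind(hdr, genes$protein), protein_fasta)
  }
  if (!is.null(cds_fasta)) {
    writeLines(rbind(hdr, genes$cds), cds_fasta)
  }
  invisible(c(protein_fasta, cds_fasta))
}

# 1-based inclusive coordinate columns for human-readable report files.
add_one_based <- function(lcrs) {
  mutate(lcrs, start1 = .data$start0 + 1L, end1 = .data$end0)
}

#' Write LCR annotations as BED
#'
#' Six-column BED with the gene id as chromosome, 0-based half-open residue
#' coordinates, the composition signature as name, the purity (scaled to
#' 0–1000) as score, and `+` strands.
#'
#' @param lcrs LCR annotation tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lcr_bed <- function(lcrs, path) {
  bed <- tibble(
    chrom = lcrs$gene_id, start = lcrs$start0, end = lcrs$end0,
    name = lcrs$signature, score = round(1000 * lcrs$purity), strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
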