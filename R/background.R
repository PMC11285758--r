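#' Estimate background amino-acid frequencies
#'
#' Builds the background model used by the low-complexity scanner: the
#' relative frequency of each of the 20 standard residues across a set of
#' protein sequences. `X` characters are ignored. Residues absent from the
#' input receive a small pseudo-frequency floor so that no residue has zero
#' background probability, and the vector is renormalised to sum to 1.
#'
#' @param proteins Character vector of amino-acid sequences (20-letter
#'   alphabet plus `X`). A data frame with a `protein` column is also
#'   accepted.
#' @param floor Pseudo-frequency assigned to residues that never occur in the
#'   input (default `1e-4`), before renormalisation.
#'
#' @return Named numeric vector of length 20 (names are the residues in
#'   alphabetical order) summing to 1.
#'
#' @examples
#' lcr_background(c("ACDEFGHIKLMNPQRSTVWY"))
#' lcr_background("AAAA")[["A"]]
#' @export
lcr_background <- function(proteins, floor = 1e-4) {
  if (is.data.frame(proteins)) proteins <- proteins$protein
  proteins <- proteins[!is.na(proteins) & nzchar(proteins)]
  if (length(proteins) == 0) abort("no sequences")
  chars <- unlist(strsplit(proteins, ""), use.names = FALSE)
  chars <- chars[chars != "X"]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("bad alphabet: ", paste(bad, collapse = ", ")))
  }
  if (length(chars) == 0) abort("no sequences")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / sum(counts)
  freq[freq == 0] <- floor
  freq <- freq / sum(freq)
  setNames(freq, AA_ALPHABET)
}

# Encode a protein string as integer codes 0..19 (alphabetical residue
# order), with -1 for X. Errors on any other character.
encode_protein <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  codes <- match(chars, AA_ALPHABET) - 1L
  is_x <- chars == "X"
  if (anyNA(codes[!is_x])) {
    bad <- unique(chars[is.na(codes) & !is_x])
    abort(paste0("bad alphabet: ", paste(bad, collapse = ", ")))
  }
  codes[is_x] <- -1L
  codes
}
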