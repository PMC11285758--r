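#' Scan one protein for low-complexity regions
#'
#' Core scanner: enumerates every window of length `m` to `M`, grows candidate
#' residue sets (sizes 1 to 5) greedily from the window's most frequent
#' residues, scores each set by the binomial upper tail
#' \eqn{P(X \ge c)} with \eqn{c} the count of set residues in the window,
#' \eqn{n} the window length and \eqn{p} the summed background frequency of
#' the set, and keeps windows scoring at or below `t`. Retained windows are
#' selected greedily by ascending p-value (ties: longer window, then smaller
#' start), discarding any window that overlaps an already selected one.
#' Adjacent selected windows with identical signatures are merged (their
#' p-value is recomputed on the merged window), which lets reported regions
#' exceed `M` residues.
#'
#' Windows containing `X` are never scored; any other non-standard character
#' is an error.
#'
#' @param protein Amino-acid string (20-letter alphabet plus `X`).
#' @param background Named background frequency vector as returned by
#'   [lcr_background()]; default is uniform (1/20 per residue).
#' @param t P-value threshold (default 0.001).
#' @param m,M Minimum / maximum window length in residues (defaults 5 / 500).
#' @param merge Merge touching selected windows with identical signatures
#'   (default `TRUE`).
#'
#' @return Tibble with one row per detected region: `start0`, `end0`
#'   (0-based, half-open residue coordinates), `signature` (sorted residue
#'   set), `primary_residue`, `purity`, `length_aa`, `pvalue`. Proteins
#'   shorter than `m` yield an empty tibble.
#'
#' @seealso [scan_lcrs()] for the data-frame interface with the standard
#'   post-filters applied.
#' @export
scan_protein <- function(protein, background = NULL, t = 0.001, m = 5,
                         M = 500, merge = TRUE) {
  stopifnot(length(protein) == 1, is.character(protein))
  if (t <= 0 || t > 1) abort("t must be in (0, 1]")
  if (m < 4 || M < m) abort("window bounds must satisfy 4 <= m <= M")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET]
  if (anyNA(background)) abort("background must cover all 20 residues")
  empty <- tibble(
    start0 = integer(), end0 = integer(), signature = character(),
    primary_residue = character(), purity = double(),
    length_aa = integer(), pvalue = double()
  )
  if (nchar(protein) < m) return(empty)
  codes <- encode_protein(protein)
  res <- scan_core_cpp(codes, unname(background), t, as.integer(m),
                       as.integer(M))
  out <- as_tibble(res)
  if (nrow(out) == 0) return(empty)
  if (merge && nrow(out) > 1) out <- merge_adjacent(out, protein, background)
  subseq <- substring(protein, out$start0 + 1, out$end0)
  pur <- compute_purity(subseq)
  out %>%
    mutate(
      primary_residue = pur$primary_residue,
      purity = pur$purity,
      length_aa = .data$end0 - .data$start0
    ) %>%
    select("start0", "end0", "signature", "primary_residue", "purity",
           "length_aa", "pvalue")
}

# Merge runs of touching windows (end == next start) sharing a signature;
# the merged p-value is recomputed on the merged window.
merge_adjacent <- function(windows, protein, background) {
  grp <- cumsum(c(
    TRUE,
    windows$start0[-1] != windows$end0[-nrow(windows)] |
      windows$signature[-1] != windows$signature[-nrow(windows)]
  ))
  windows %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(
      start0 = min(.data$start0),
      end0 = max(.data$end0),
      signature = .data$signature[1],
      pvalue = if (n() == 1) .data$pvalue[1] else {
        sub <- substring(.env$protein, min(.data$start0) + 1, max(.data$end0))
        sig <- strsplit(.data$signature[1], "")[[1]]
        cc <- sum(strsplit(sub, "")[[1]] %in% sig)
        pbinom(cc - 1, nchar(sub), sum(.env$background[sig]),
               lower.tail = FALSE)
      },
      .groups = "drop"
    ) %>%
    select(-".grp") %>%
    arrange(.data$start0)
}

#' Scan a gene table for low-complexity regions
#'
#' Data-frame front end to [scan_protein()]: scans every protein in `genes`,
#' then (by default) applies the standard post-filters of [filter_lcrs()]
#' (length at least 4 residues, no `X`, at most 5 unique residues).
#'
#' @param genes Data frame with columns `gene_id`, `species_id`, `protein`.
#' @param background Background frequencies; estimated from `genes` with
#'   [lcr_background()] when `NULL`.
#' @param apply_filters Apply [filter_lcrs()] to the result (default `TRUE`).
#' @param min_purity Optional purity cut: keep regions with purity strictly
#'   greater than this value (default `NULL`, keep all).
#' @inheritParams scan_protein
#'
#' @return Tibble of LCR annotations with columns `gene_id`, `species_id`,
#'   `start0`, `end0`, `signature`, `primary_residue`, `purity`, `length_aa`,
#'   `pvalue`.
#' @export
scan_lcrs <- function(genes, background = NULL, t = 0.001, m = 5, M = 500,
                      apply_filters = TRUE, min_purity = NULL) {
  stopifnot(all(c("gene_id", "species_id", "protein") %in% names(genes)))
  if (is.null(background)) background <- lcr_background(genes$protein)
  hits <- purrr::pmap(
    list(genes$gene_id, genes$species_id, genes$protein),
    function(g, s, p) {
      h <- scan_protein(p, background, t = t, m = m, M = M)
      if (nrow(h) == 0) return(NULL)
      mutate(h, gene_id = g, species_id = s)
    }
  )
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(
      gene_id = character(), species_id = character(), start0 = integer(),
      end0 = integer(), signature = character(),
      primary_residue = character(), purity = double(),
      length_aa = integer(), pvalue = double()
    ))
  }
  out <- select(out, "gene_id", "species_id", "start0", "end0", "signature",
                "primary_residue", "purity", "length_aa", "pvalue")
  if (apply_filters) {
    key <- paste(out$gene_id, out$species_id)
    prot <- genes$protein[match(key, paste(genes$gene_id, genes$species_id))]
    out <- filter_lcrs(out, substring(prot, out$start0 + 1, out$end0))
  }
  if (!is.null(min_purity)) out <- filter(out, .data$purity > min_purity)
  out
}

#' Apply the standard LCR post-filters
#'
#' Keeps candidate regions that are longer than three residues
#' (`length >= 4`), contain no `X`, and have at most five unique residues in
#' the raw subsequence. Order is preserved.
#'
#' @param candidates Data frame of candidate annotations (needs `start0`,
#'   `end0`).
#' @param subsequences Character vector of the raw subsequences matching
#'   `candidates` row for row.
#'
#' @return The retained rows of `candidates`.
#' @export
filter_lcrs <- function(candidates, subsequences) {
  stopifnot(nrow(candidates) == length(subsequences))
  if (nrow(candidates) == 0) return(candidates)
  len_ok <- (candidates$end0 - candidates$start0) >= 4
  no_x <- !stringr::str_detect(subsequences, "X")
  n_unique <- purrr::map_int(
    strsplit(subsequences, ""),
    ~ length(unique(.x))
  )
  candidates[len_ok & no_x & n_unique <= 5, , drop = FALSE]
}

#' Purity of a low-complexity stretch
#'
#' Purity is the fraction of residues belonging to the stretch's primary
#' (most frequent) amino acid; a 100-residue stretch in which the primary
#' residue occurs 10 times has purity 0.10. Ties for the primary residue are
#' broken alphabetically. With `mode = "signature"`, purity is instead the
#' fraction of residues belonging to a supplied signature set.
#'
#' @param subsequence Character vector of stretches (no `X`, non-empty).
#' @param mode `"primary"` (default) or `"signature"`.
#' @param signature Signature string(s), required for `mode = "signature"`.
#'
#' @return Tibble with columns `primary_residue` and `purity`, one row per
#'   input stretch.
#'
#' @examples
#' compute_purity("AABAB") # A, 0.6
#' @export
compute_purity <- function(subsequence, mode = c("primary", "signature"),
                           signature = NULL) {
  mode <- match.arg(mode)
  if (any(!nzchar(subsequence)) || any(is.na(subsequence))) {
    abort("empty subsequence")
  }
  if (any(stringr::str_detect(subsequence, "X"))) {
    abort("subsequence must not contain X")
  }
  one <- function(s, sig) {
    chars <- strsplit(s, "")[[1]]
    tab <- table(chars)
    primary <- sort(names(tab)[tab == max(tab)])[1]
    if (mode == "primary") {
      tibble(primary_residue = primary,
             purity = as.numeric(tab[primary]) / length(chars))
    } else {
      sigset <- strsplit(sig, "")[[1]]
      tibble(primary_residue = primary,
             purity = sum(chars %in% sigset) / length(chars))
    }
  }
  if (mode == "signature") {
    if (is.null(signature)) abort("signature required for signature mode")
    signature <- rep_len(signature, length(subsequence))
    bind_rows(purrr::map2(subsequence, signature, one))
  } else {
    bind_rows(purrr::map(subsequence, one, sig = NULL))
  }
}

#' Canonical composition signature
#'
#' Collapses a residue multiset to its canonical signature: the unique
#' residues sorted alphabetically and concatenated, so that e.g. ILA, LIA,
#' AIL, IAL, LAI and ALI all become "AIL". Signatures are limited to five
#' residues.
#'
#' @param residues Character vector of residues, or a single string.
#'
#' @return Canonical signature string.
#'
#' @examples
#' canonicalize_composition(c("I", "L", "A"))
#' canonicalize_composition("GAGA")
#' @export
canonicalize_composition <- function(residues) {
  if (length(residues) == 1 && nchar(residues) > 1) {
    residues <- strsplit(residues, "")[[1]]
  }
  u <- sort(unique(residues))
  if (length(u) > 5) abort("signature too large")
  if (length(u) == 0) abort("empty signature")
  paste(u, collapse = "")
}

#' Pairwise robustness of LCR detection between parameter settings
#'
#' Compares two annotation sets produced from the same sequences under
#' different scanner parameters. A pair matches when `gene_id` and
#' `species_id` agree, the residue intervals overlap by at least one residue,
#' and the signatures are identical. Both directed proportions are reported.
#'
#' @param set_a,set_b LCR annotation tibbles (as from [scan_lcrs()]).
#'
#' @return One-row tibble with `n_a`, `n_b`, `matched_a`, `matched_b`,
#'   `prop_a` (= matched_a / n_a) and `prop_b`.
#' @export
parameter_robustness <- function(set_a, set_b) {
  match_count <- function(x, y) {
    if (nrow(x) == 0) return(0L)
    hits <- inner_join(
      x %>% mutate(.row = row_number()),
      y,
      by = c("gene_id", "species_id", "signature"),
      relationship = "many-to-many"
    ) %>%
      filter(.data$start0.x < .data$end0.y & .data$start0.y < .data$end0.x)
    length(unique(hits$.row))
  }
  if (nrow(set_a) == 0) warn("empty set_a: proportion defined as 0")
  ma <- match_count(set_a, set_b)
  mb <- match_count(set_b, set_a)
  tibble(
    n_a = nrow(set_a), n_b = nrow(set_b),
    matched_a = ma, matched_b = mb,
    prop_a = if (nrow(set_a) == 0) 0 else ma / nrow(set_a),
    prop_b = if (nrow(set_b) == 0) 0 else mb / nrow(set_b)
  )
}
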