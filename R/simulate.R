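# Clade-structured synthetic data with planted LCRs, PSS, omega and GC
# effects, plus full ground truth. The generator knows true homology, so
# codon alignments are emitted directly (gap-consistent with the planted
# slippage indels) and no aligner is needed.

# Sense codons per amino acid (standard genetic code).
CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  C = c("TGT", "TGC"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG",
  N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

#' Simulation configuration
#'
#' Validated parameter set for the synthetic clade generator. The defaults
#' describe the study conditions used throughout the package's tests: small
#' clades with realistic protein lengths, a planted-LCR prevalence of 0.4,
#' high-purity planted stretches, terminal positional preference, PSS
#' enriched threefold inside LCR columns, lower omega and elevated GC in
#' LCR-containing genes.
#'
#' @param n_clades Number of clades (default 1).
#' @param species_per_clade Species per clade (default 6).
#' @param genes_per_clade Genes per clade (default 120).
#' @param protein_shape,protein_scale Gamma parameters of the protein-length
#'   distribution (rounded; defaults shape 6, scale 50, i.e. mean 300
#'   residues), clamped to `[protein_min, protein_max]`.
#' @param protein_min,protein_max Length clamp (defaults 100, 800).
#' @param lcr_prevalence Fraction of genes carrying a planted LCR (default
#'   0.4); exactly `round(lcr_prevalence * genes_per_clade)` genes are
#'   planted.
#' @param purity_shape1,purity_shape2 Beta parameters of planted purity
#'   (defaults 8, 2).
#' @param lcr_len_min,lcr_len_mu,lcr_len_size Planted LCR length is
#'   `lcr_len_min + NegBin(mu = lcr_len_mu, size = lcr_len_size)` residues
#'   (defaults 10, 10, 2), capped at a third of the protein.
#' @param terminal_weight Probability that a planted LCR midpoint falls in a
#'   terminal 10% zone of the gene (default 0.5).
#' @param subs_rate Per-residue substitution probability between species
#'   outside the planted stretch (default 0.005).
#' @param indel_sizes,indel_probs Whole-codon slippage offsets per species at
#'   the LCR 3' boundary and their probabilities (defaults -1:2 codons with
#'   probabilities 0.2, 0.4, 0.25, 0.15).
#' @param pss_background_rate Per-alignment-column PSS rate outside LCRs
#'   (default 0.002, so that roughly half the genes carry at least one site
#'   — sites passing the strict posterior filter are rare in real scans).
#' @param pss_in_lcr_ratio Fold-enrichment of the PSS rate inside LCR columns
#'   (default 3).
#' @param pss_decoy_rate Rate of sub-threshold decoy sites (posterior drawn
#'   in \[0.5, 0.95\]) to exercise the posterior filter (default 0.01).
#' @param omega_lcr_mean,omega_other_mean Gamma means of lineage omega for
#'   LCR-containing / LCR-free genes (defaults 0.15, 0.25).
#' @param omega_shape Gamma shape (default 2).
#' @param omega_outlier_rate Probability that a lineage omega is replaced by
#'   the degenerate value 999 (default 0.01).
#' @param gc_shift Strength of the GC-rich synonymous-codon preference in
#'   LCR-containing genes; codon weights are `(1 + gc_shift)^(#G or C)`
#'   (default 0.5). Applied through codon choice only, so protein-level truth
#'   is unchanged.
#' @param seed Integer seed (mandatory).
#'
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_clades = 1, species_per_clade = 6,
                              genes_per_clade = 120, protein_shape = 6,
                              protein_scale = 50, protein_min = 100,
                              protein_max = 800, lcr_prevalence = 0.4,
                              purity_shape1 = 8, purity_shape2 = 2,
                              lcr_len_min = 10, lcr_len_mu = 10,
                              lcr_len_size = 2, terminal_weight = 0.5,
                              subs_rate = 0.005, indel_sizes = -1:2,
                              indel_probs = c(0.2, 0.4, 0.25, 0.15),
                              pss_background_rate = 0.002,
                              pss_in_lcr_ratio = 3, pss_decoy_rate = 0.01,
                              omega_lcr_mean = 0.15,
                              omega_other_mean = 0.25, omega_shape = 2,
                              omega_outlier_rate = 0.01, gc_shift = 0.5,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_clades >= 1, cfg$species_per_clade >= 1, cfg$genes_per_clade >= 1,
    cfg$lcr_prevalence >= 0, cfg$lcr_prevalence <= 1,
    cfg$terminal_weight >= 0, cfg$terminal_weight <= 1,
    cfg$pss_background_rate >= 0, cfg$pss_background_rate <= 1,
    cfg$pss_in_lcr_ratio >= 0, cfg$gc_shift >= 0,
    length(cfg$indel_sizes) == length(cfg$indel_probs),
    all(cfg$indel_sizes %% 1 == 0)
  )
  if (cfg$lcr_len_min + 1 > floor(cfg$protein_min / 3)) {
    abort("infeasible config: LCR longer than protein allows")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-gene seed stream split from the global seed.
gene_seed <- function(seed, clade_index, gene_index) {
  as.integer((as.numeric(seed) + clade_index * 7919 +
                gene_index * 104729) %% 2147483647)
}

# Sample one codon per residue; weights favour GC-rich synonymous codons
# when gc_shift > 0.
sample_codons <- function(residues, gc_shift) {
  out <- character(length(residues))
  for (aa in unique(residues)) {
    codons <- CODON_TABLE[[aa]]
    idx <- which(residues == aa)
    if (length(codons) == 1) {
      out[idx] <- codons
    } else {
      w <- (1 + gc_shift)^stringr::str_count(codons, "[GC]")
      out[idx] <- codons[sample.int(length(codons), length(idx),
                                    replace = TRUE, prob = w)]
    }
  }
  out
}

simulate_gene <- function(cfg, clade_id, clade_index, gene_index, species,
                          is_lcr) {
  withr::with_seed(gene_seed(cfg$seed, clade_index, gene_index), {
    gene_id <- sprintf("%s_g%04d", clade_id, gene_index)
    L <- min(max(round(rgamma(1, shape = cfg$protein_shape,
                              scale = cfg$protein_scale)),
                 cfg$protein_min), cfg$protein_max)
    base <- sample(AA_ALPHABET, L, replace = TRUE)
    base[1] <- "M"
    S <- length(species)
    if (is_lcr) {
      rho <- sample(AA_ALPHABET, 1)
      len <- cfg$lcr_len_min +
        rnbinom(1, size = cfg$lcr_len_size, mu = cfg$lcr_len_mu)
      len <- min(len, floor(L / 3))
      pur <- rbeta(1, cfg$purity_shape1, cfg$purity_shape2)
      mid <- if (runif(1) < cfg$terminal_weight) {
        if (runif(1) < 0.5) runif(1, 0, 0.1) else runif(1, 0.9, 1)
      } else runif(1, 0.1, 0.9)
      start1 <- min(max(round(mid * L - len / 2), 2), L - len + 1)
      d <- sample(cfg$indel_sizes, S, replace = TRUE,
                  prob = cfg$indel_probs)
      d <- pmax(d, -(len - cfg$lcr_len_min)) # never shrink below the floor
    } else {
      rho <- NA_character_
      len <- 0L
      pur <- NA_real_
      start1 <- NA_integer_
      d <- rep(0L, S)
    }
    max_ins <- max(0L, max(d))
    n_col <- L + max_ins
    gc_shift <- if (is_lcr) cfg$gc_shift else 0

    draw_stretch <- function(k) {
      hit <- runif(k) < pur
      res <- character(k)
      res[hit] <- rho
      if (any(!hit)) {
        res[!hit] <- sample(setdiff(AA_ALPHABET, rho), sum(!hit),
                            replace = TRUE)
      }
      res
    }

    rows <- purrr::map(seq_len(S), function(s) {
      res_col <- character(n_col)   # residue per alignment column
      present <- logical(n_col)
      if (is_lcr) {
        anc_pre <- seq_len(start1 - 1)
        anc_str <- start1:(start1 + len - 1)
        anc_post <- if (start1 + len <= L) (start1 + len):L else integer(0)
        col_pre <- anc_pre
        col_str <- anc_str
        col_ins <- if (max_ins > 0) (start1 + len - 1) + seq_len(max_ins)
                   else integer(0)
        col_post <- anc_post + max_ins
        res_col[col_pre] <- base[anc_pre]
        res_col[col_post] <- base[anc_post]
        present[c(col_pre, col_post)] <- TRUE
        keep_len <- len + min(d[s], 0L)
        stretch <- draw_stretch(keep_len + max(d[s], 0L))
        present[col_str[seq_len(keep_len)]] <- TRUE
        res_col[col_str[seq_len(keep_len)]] <- stretch[seq_len(keep_len)]
        if (d[s] > 0) {
          present[col_ins[seq_len(d[s])]] <- TRUE
          res_col[col_ins[seq_len(d[s])]] <-
            stretch[keep_len + seq_len(d[s])]
        }
        lcr_start0 <- start1 - 1L
        lcr_len_s <- keep_len + max(d[s], 0L)
        realized_pur <- mean(stretch == rho)
      } else {
        res_col <- base
        present <- rep(TRUE, L)
        lcr_start0 <- NA_integer_
        lcr_len_s <- NA_integer_
        realized_pur <- NA_real_
      }
      # species-specific substitutions outside the planted stretch
      sub_ok <- present & seq_len(n_col) > 1
      if (is_lcr) {
        sub_ok[start1:(start1 + len - 1 + max_ins)] <- FALSE
      }
      flip <- sub_ok & runif(n_col) < cfg$subs_rate
      if (any(flip)) {
        res_col[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
      }
      codons <- rep("---", n_col)
      codons[present] <- sample_codons(res_col[present], gc_shift)
      protein <- paste(res_col[present], collapse = "")
      list(
        aligned = paste(codons, collapse = ""),
        protein = protein,
        cds = paste0(paste(codons[present], collapse = ""), "TAA"),
        lcr_start0 = lcr_start0,
        lcr_len = lcr_len_s,
        realized_purity = realized_pur
      )
    })

    genes <- tibble::new_tibble(list(
      gene_id = rep(gene_id, S), species_id = species,
      clade_id = rep(clade_id, S),
      protein = purrr::map_chr(rows, "protein"),
      cds = purrr::map_chr(rows, "cds")
    ), nrow = S)
    alignments <- tibble::new_tibble(list(
      gene_id = rep(gene_id, S), species_id = species,
      clade_id = rep(clade_id, S),
      aligned_cds = purrr::map_chr(rows, "aligned")
    ), nrow = S)
    truth_lcrs <- if (is_lcr) {
      t_start <- purrr::map_int(rows, ~ as.integer(.x$lcr_start0))
      t_len <- purrr::map_int(rows, ~ as.integer(.x$lcr_len))
      tibble::new_tibble(list(
        gene_id = rep(gene_id, S), species_id = species,
        clade_id = rep(clade_id, S),
        start0 = t_start, length_aa = t_len, end0 = t_start + t_len,
        residue = rep(rho, S), planted_purity = rep(pur, S),
        realized_purity = purrr::map_dbl(rows, "realized_purity"),
        col_start = rep(start1 - 1L, S),
        col_end = rep(start1 - 1L + len + max_ins, S)
      ), nrow = S)
    } else NULL

    # PSS: enriched inside LCR columns, background elsewhere
    in_lcr <- logical(n_col)
    if (is_lcr) in_lcr[start1:(start1 + len - 1 + max_ins)] <- TRUE
    rate <- ifelse(in_lcr, pmin(1, cfg$pss_background_rate *
                                  cfg$pss_in_lcr_ratio),
                   cfg$pss_background_rate)
    hit <- runif(n_col) < rate
    pss <- if (any(hit)) {
      nh <- sum(hit)
      tibble::new_tibble(list(
        gene_id = rep(gene_id, nh), clade_id = rep(clade_id, nh),
        site = which(hit) - 1L,
        posterior = runif(nh, 0.951, 0.999),
        in_lcr = in_lcr[hit]
      ), nrow = nh)
    } else NULL
    decoy <- runif(n_col) < cfg$pss_decoy_rate & !hit
    if (any(decoy)) {
      nd <- sum(decoy)
      pss <- bind_rows(pss, tibble::new_tibble(list(
        gene_id = rep(gene_id, nd), clade_id = rep(clade_id, nd),
        site = which(decoy) - 1L,
        posterior = runif(nd, 0.5, 0.95), in_lcr = in_lcr[decoy]
      ), nrow = nd))
    }

    omega_mean <- if (is_lcr) cfg$omega_lcr_mean else cfg$omega_other_mean
    om <- rgamma(S, shape = cfg$omega_shape,
                 rate = cfg$omega_shape / omega_mean)
    om[runif(S) < cfg$omega_outlier_rate] <- 999
    omega <- tibble::new_tibble(list(
      gene_id = rep(gene_id, S), clade_id = rep(clade_id, S),
      lineage_id = species, omega = om
    ), nrow = S)

    gene_label <- tibble::new_tibble(list(
      gene_id = gene_id, clade_id = clade_id, has_lcr = is_lcr,
      protein_length = L, n_col = as.integer(n_col),
      lcr_residue = rho, planted_purity = pur,
      lcr_col_start = if (is_lcr) start1 - 1L else NA_integer_,
      lcr_col_end = if (is_lcr) start1 - 1L + len + max_ins
                    else NA_integer_
    ), nrow = 1L)
    list(genes = genes, alignments = alignments, truth_lcrs = truth_lcrs,
         pss = pss, omega = omega, gene_label = gene_label)
  })
}

#' Simulate one synthetic clade
#'
#' Generates a clade of orthologous gene families with planted low-complexity
#' stretches, slippage-style length variation between species, gap-consistent
#' codon alignments, PSS enriched inside LCR columns, lineage omega values
#' drawn lower for LCR-containing genes, elevated GC in LCR-containing genes
#' (via synonymous codon choice only), a species tree, and the complete
#' ground truth. All CDSs pass [check_orf()]. Alignments are stop-trimmed:
#' a row with gaps removed plus the trailing stop codon reproduces the CDS.
#'
#' Exactly `round(lcr_prevalence * genes_per_clade)` genes carry a planted
#' LCR. The same config and seed always produce identical output; a per-gene
#' seed stream makes gene subsets independently reproducible.
#'
#' @param config A [simulation_config()].
#' @param clade_id Clade label (default `"clade01"`).
#' @param clade_index Integer index used in the per-gene seed stream
#'   (default 1).
#'
#' @return List with tibbles `genes` (`gene_id`, `species_id`, `clade_id`,
#'   `protein`, `cds`), `alignments`, `pss` (planted and decoy sites, with an
#'   `in_lcr` truth flag), `omega`, the newick `tree`, the ground `truth`
#'   (list of `lcrs`, `pss`, `genes`, `config`) and `metadata` (alignment
#'   dialect).
#' @export
simulate_clade <- function(config, clade_id = "clade01", clade_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  species <- sprintf("%s_sp%02d", clade_id, seq_len(config$species_per_clade))
  n_lcr <- round(config$lcr_prevalence * config$genes_per_clade)
  parts <- purrr::map(seq_len(config$genes_per_clade), function(i) {
    simulate_gene(config, clade_id, clade_index, i, species,
                  is_lcr = i <= n_lcr)
  })
  tree <- withr::with_seed(
    gene_seed(config$seed, clade_index, 0),
    {
      phy <- ape::rtree(length(species), tip.label = species)
      ape::write.tree(phy)
    }
  )
  pss <- bind_rows(purrr::map(parts, "pss"))
  if (nrow(pss) == 0) {
    pss <- tibble(gene_id = character(), clade_id = character(),
                  site = integer(), posterior = double(),
                  in_lcr = logical())
  }
  list(
    genes = bind_rows(purrr::map(parts, "genes")),
    alignments = bind_rows(purrr::map(parts, "alignments")),
    pss = pss,
    omega = bind_rows(purrr::map(parts, "omega")),
    tree = tree,
    truth = list(
      lcrs = bind_rows(purrr::map(parts, "truth_lcrs")),
      pss = filter(pss, .data$posterior > 0.95),
      genes = bind_rows(purrr::map(parts, "gene_label")),
      config = config
    ),
    metadata = list(alignment_dialect = "stop_trimmed")
  )
}

#' Simulate a multi-clade dataset
#'
#' Runs [simulate_clade()] for `n_clades` clades (labelled `clade01`,
#' `clade02`, ...) and row-binds the outputs.
#'
#' @param config A [simulation_config()].
#' @return List as in [simulate_clade()], with `tree` a named character
#'   vector of newick strings per clade.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  clades <- sprintf("clade%02d", seq_len(config$n_clades))
  sims <- purrr::imap(clades, function(cl, i) {
    simulate_clade(config, clade_id = cl, clade_index = i)
  })
  list(
    genes = bind_rows(purrr::map(sims, "genes")),
    alignments = bind_rows(purrr::map(sims, "alignments")),
    pss = bind_rows(purrr::map(sims, "pss")),
    omega = bind_rows(purrr::map(sims, "omega")),
    tree = setNames(purrr::map_chr(sims, "tree"), clades),
    truth = list(
      lcrs = bind_rows(purrr::map(sims, ~ .x$truth$lcrs)),
      pss = bind_rows(purrr::map(sims, ~ .x$truth$pss)),
      genes = bind_rows(purrr::map(sims, ~ .x$truth$genes)),
      config = config
    ),
    metadata = list(alignment_dialect = "stop_trimmed")
  )
}

#' Corrupt a valid CDS in a controlled way
#'
#' Introduces exactly one ORF defect, for negative fixtures: a premature
#' stop codon, a missing start codon, a non-nucleotide character, or a
#' length that is not a multiple of 3.
#'
#' @param cds Valid CDS string.
#' @param mode One of `"premature_stop"`, `"no_start"`, `"bad_char"`,
#'   `"bad_length"`.
#' @param seed Optional seed for the position choice.
#'
#' @return The corrupted CDS.
#' @export
corrupt_orf <- function(cds, mode = c("premature_stop", "no_start",
                                      "bad_char", "bad_length"),
                        seed = NULL) {
  mode <- match.arg(mode)
  do_corrupt <- function() {
    n_codon <- nchar(cds) / 3
    switch(mode,
      premature_stop = {
        if (n_codon < 3) abort("cds too short for a premature stop")
        pos <- sample(2:(n_codon - 1), 1)
        paste0(substr(cds, 1, (pos - 1) * 3), "TAA",
               substr(cds, pos * 3 + 1, nchar(cds)))
      },
      no_start = paste0("ATT", substr(cds, 4, nchar(cds))),
      bad_char = {
        pos <- sample(nchar(cds), 1)
        paste0(substr(cds, 1, pos - 1), "N",
               substr(cds, pos + 1, nchar(cds)))
      },
      bad_length = {
        if (nchar(cds) < 2) abort("cds too short to shorten")
        substr(cds, 1, nchar(cds) - 1)
      }
    )
  }
  if (is.null(seed)) do_corrupt() else withr::with_seed(seed, do_corrupt())
}
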