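test_that("ORF verdicts follow the four rules with named reasons", {
  res <- check_orf(c(
    "ATGAAATAA",      # minimal valid ORF
    "ATGTAAAAATAA",   # premature stop
    "ATGAAAAA",       # length not a multiple of 3
    "AAAATGTAA",      # no start codon
    "ATGANATAA",      # non-nucleotide character
    "atgaaataa",      # lower case counts as bad characters
    "ATGAAA"          # no trailing stop is still valid
  ))
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$reason[2:6],
               c("premature stop", "bad length", "no start codon",
                 "bad character", "bad character"))
})

test_that("clade filter drops genes below three species and flags clades", {
  genes <- tibble::tibble(
    clade_id = c(rep("cladeA", 5), rep("cladeB", 2)),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3"),
    species_id = c("s1", "s2", "s3", "s1", "s2", "s1", "s2")
  )
  kept <- filter_clade_genes(genes)
  rep <- clade_filter_report(kept)
  expect_equal(unique(kept$gene_id), "g1")
  expect_equal(nrow(kept), 3)
  expect_equal(sort(rep$removed$gene_id), c("g2", "g3"))
  # cladeB lost every gene: excluded outright
  expect_equal(rep$excluded_clades, "cladeB")
})

test_that("LCR coordinates map through gap patterns into columns", {
  # gap-free row: identity mapping
  aln <- tibble::tibble(
    gene_id = "g", species_id = "s",
    aligned_cds = strrep("ATG", 20)
  )
  lcr <- tibble::tibble(gene_id = "g", species_id = "s",
                        start0 = 5L, end0 = 12L)
  m <- map_to_alignment(lcr, aln)
  expect_equal(c(m$col_start, m$col_end), c(5L, 12L))

  # 4 leading aa-gap columns: residues [0,6) land in columns [4,10)
  aln2 <- tibble::tibble(
    gene_id = "g", species_id = "s",
    aligned_cds = paste0(strrep("---", 4), strrep("ATG", 16))
  )
  m2 <- map_to_alignment(
    tibble::tibble(gene_id = "g", species_id = "s", start0 = 0L, end0 = 6L),
    aln2
  )
  expect_equal(c(m2$col_start, m2$col_end), c(4L, 10L))

  # internal gap at column 7 inflates the span of residues [5,8)
  aln3 <- tibble::tibble(
    gene_id = "g", species_id = "s",
    aligned_cds = paste0(strrep("ATG", 7), "---", strrep("ATG", 12))
  )
  m3 <- map_to_alignment(
    tibble::tibble(gene_id = "g", species_id = "s", start0 = 5L, end0 = 8L),
    aln3
  )
  expect_equal(c(m3$col_start, m3$col_end), c(5L, 9L))

  expect_error(
    map_to_alignment(
      tibble::tibble(gene_id = "g", species_id = "missing",
                     start0 = 0L, end0 = 3L), aln),
    "missing"
  )
  expect_error(
    map_to_alignment(
      tibble::tibble(gene_id = "g", species_id = "s",
                     start0 = 0L, end0 = 99L), aln),
    "overflow"
  )
})

test_that("mapping round-trips through fuzzed gap patterns", {
  withr::with_seed(123, {
    for (rep in 1:25) {
      n_col <- sample(10:40, 1)
      gap <- runif(n_col) < 0.3
      if (all(gap)) gap[1] <- FALSE
      codons <- ifelse(gap, "---", "ATG")
      n_res <- sum(!gap)
      s0 <- sample(0:(n_res - 1), 1)
      e0 <- sample((s0 + 1):n_res, 1)
      aln <- tibble::tibble(gene_id = "g", species_id = "s",
                            aligned_cds = paste(codons, collapse = ""))
      m <- map_to_alignment(
        tibble::tibble(gene_id = "g", species_id = "s",
                       start0 = s0, end0 = e0), aln)
      back <- lcrscan:::project_from_alignment(m$col_start, m$col_end,
                                               aln$aligned_cds)
      expect_equal(unname(back), c(s0, e0))
    }
  })
})

test_that("orthologous grouping is single-linkage over column overlap", {
  two <- tibble::tibble(
    gene_id = "g", species_id = c("s1", "s2"),
    col_start = c(5L, 5L), col_end = c(15L, 15L)
  )
  g2 <- group_orthologous(two)
  expect_equal(unique(g2$group_id), 1L)

  disjoint <- tibble::tibble(
    gene_id = "g", species_id = c("s1", "s2"),
    col_start = c(0L, 20L), col_end = c(10L, 30L)
  )
  gd <- group_orthologous(disjoint)
  expect_equal(gd$group_id, c(1L, 2L))

  # transitivity: A-[0,10) B-[8,18) C-[16,26) chain into one group
  chain <- tibble::tibble(
    gene_id = "g", species_id = c("sA", "sB", "sC"),
    col_start = c(0L, 8L, 16L), col_end = c(10L, 18L, 26L)
  )
  gc <- group_orthologous(chain)
  expect_equal(unique(gc$group_id), 1L)
  expect_equal(unique(gc$span_start), 0L)
  expect_equal(unique(gc$span_end), 26L)

  # output partitions the input: every row gets exactly one group
  withr::with_seed(9, {
    fuzz <- tibble::tibble(
      gene_id = sample(c("g1", "g2"), 30, TRUE),
      species_id = paste0("s", 1:30),
      col_start = sample(0:50, 30, TRUE)
    )
    fuzz$col_end <- fuzz$col_start + sample(1:10, 30, TRUE)
  })
  gf <- group_orthologous(fuzz)
  expect_equal(nrow(gf), nrow(fuzz))
  expect_false(any(is.na(gf$group_id)))
  # touching intervals (zero columns shared) do not join
  touch <- tibble::tibble(
    gene_id = "g", species_id = c("s1", "s2"),
    col_start = c(0L, 10L), col_end = c(10L, 20L)
  )
  expect_equal(group_orthologous(touch)$group_id, c(1L, 2L))
})

test_that("alignment coverage counts non-gap codons per column", {
  aln <- tibble::tibble(
    gene_id = "g",
    species_id = paste0("s", 1:4),
    aligned_cds = c("ATGATG", "ATGATG", "ATGATG", "ATG---")
  )
  cov <- alignment_coverage(aln)
  expect_equal(cov$coverage, c(1, 0.75))
  all_cov <- alignment_coverage(dplyr::slice(aln, 1:3))
  expect_equal(all_cov$coverage, c(1, 1))
  expect_error(alignment_coverage(aln[0, ]), "empty")
})

test_that("synthetic terminal-gap alignments show depressed edge coverage", {
  cfg <- simulation_config(genes_per_clade = 40, seed = 31,
                           terminal_weight = 1)
  sim <- simulate_clade(cfg)
  cov <- alignment_coverage(sim$alignments)
  per_gene <- dplyr::group_by(cov, gene_id)
  edges <- dplyr::summarise(
    per_gene,
    edge = mean(coverage[col0 < 0.1 * max(col0) | col0 > 0.9 * max(col0)]),
    centre = mean(coverage[col0 >= 0.45 * max(col0) &
                             col0 <= 0.55 * max(col0)])
  )
  expect_lt(mean(edges$edge), mean(edges$centre))
})
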