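test_that("PSS loading applies the strict posterior filter and dedups", {
  pss <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    site = c(4L, 9L, 2L, 2L, 7L),
    posterior = c(0.96, 0.95, 0.97, 0.99, 0.951)
  )
  kept <- load_pss(pss)
  expect_equal(nrow(kept), 3) # 0.95 dropped (strict), duplicate collapsed
  expect_equal(kept$posterior[kept$gene_id == "g2" & kept$site == 2], 0.99)
  expect_equal(nrow(load_pss(pss[0, ])), 0)
  expect_error(load_pss(dplyr::mutate(pss, posterior = posterior + 1)),
               "\\[0, 1\\]")
})

test_that("omega filtering drops degenerate values", {
  om <- tibble::tibble(gene_id = "g", omega = c(0.1, 1.9, 2, 2.1, 999))
  expect_equal(filter_omega(om)$omega, c(0.1, 1.9, 2))
  expect_error(filter_omega(tibble::tibble(omega = -1)), "negative")
})

test_that("co-occurrence Fisher test reports the sample odds ratio", {
  f <- cooccurrence_fisher(flags_for_table(30, 10, 10, 50))
  expect_equal(f$odds_ratio, 15)
  expect_equal(f$p_two_sided, fisher_oracle_p(30, 10, 10, 50))
  expect_equal(f$direction, "enrichment")

  deg <- cooccurrence_fisher(flags_for_table(5, 0, 0, 7))
  expect_equal(deg$odds_ratio, Inf)
  expect_equal(deg$p_two_sided, fisher_oracle_p(5, 0, 0, 7))

  td <- tidy(deg)
  expect_equal(td$n11, 5)
  expect_equal(td$odds_ratio, Inf)
})

test_that("Fisher p-values match enumeration on small-margin tables", {
  for (n11 in 0:6) for (n12 in 0:4) for (n21 in 0:4) for (n22 in 0:6) {
    if (n11 + n12 + n21 + n22 == 0) next
    f <- cooccurrence_fisher(flags_for_table(n11, n12, n21, n22))
    expect_equal(f$p_two_sided, fisher_oracle_p(n11, n12, n21, n22),
                 tolerance = 1e-10)
  }
})

test_that("co-occurrence test holds its size under independence", {
  reject <- vapply(1:300, function(i) {
    withr::with_seed(5000 + i, {
      flags <- data.frame(
        has_lcr = runif(800) < 0.4,
        has_pss = runif(800) < 0.5
      )
    })
    cooccurrence_fisher(flags)$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("interval-overlap table follows the bedtools-style construction", {
  # fixed toy instance: domain 1000, ten 20-length a, forty 1-length b
  a <- tibble::tibble(start = seq(0, 900, by = 100), end = seq(20, 920, 100))
  withr::with_seed(17, b_pos <- sample(0:999, 40))
  b <- tibble::tibble(start = b_pos, end = b_pos + 1)
  f <- interval_overlap_fisher(a, b, 1000)
  # independent recomputation of the documented table
  hit_a <- vapply(seq_len(nrow(a)), function(i) {
    any(b$start < a$end[i] & b$start >= a$start[i])
  }, logical(1))
  hit_b <- vapply(b$start, function(x) {
    any(x >= a$start & x < a$end)
  }, logical(1))
  n11 <- sum(hit_a)
  n12 <- 10 - n11
  n21 <- sum(!hit_b)
  n22 <- max(0, round(1000 / (20 + 1)) - n11 - n12 - n21)
  expect_equal(c(f$n11, f$n12, f$n21, f$n22), c(n11, n12, n21, n22))
  expect_equal(f$p_two_sided, fisher_oracle_p(n11, n12, n21, n22))
})

test_that("interval-overlap degenerate geometries force the direction", {
  # every b inside some a
  a <- tibble::tibble(start = c(0, 50), end = c(20, 80))
  b <- tibble::tibble(start = c(5, 60, 70), end = c(6, 61, 71))
  f <- interval_overlap_fisher(a, b, 200)
  expect_equal(f$n21, 0)
  expect_equal(f$direction, "enrichment")

  # a and b tiling disjoint halves
  a2 <- tibble::tibble(start = seq(0, 80, 20), end = seq(10, 90, 20))
  b2 <- tibble::tibble(start = 100 + seq(0, 80, 10),
                       end = 101 + seq(0, 80, 10))
  f2 <- interval_overlap_fisher(a2, b2, 200)
  expect_equal(f2$n11, 0)
  expect_equal(f2$direction, "depletion")

  # empty side: untestable verdict, not a p-value
  f3 <- interval_overlap_fisher(a2[0, ], b2, 200)
  expect_true(f3$untestable)
  expect_true(is.na(f3$p_two_sided))
})

test_that("interval-overlap is invariant to order and in-domain shifts", {
  withr::with_seed(29, {
    a <- tibble::tibble(start = sample(0:150, 8))
    a$end <- a$start + sample(5:15, 8, TRUE)
    b_pos <- sample(0:195, 25)
    b <- tibble::tibble(start = b_pos, end = b_pos + 1)
  })
  base <- interval_overlap_fisher(a, b, 300)
  perm <- interval_overlap_fisher(a[sample(8), ], b[sample(25), ], 300)
  expect_equal(tidy(base), tidy(perm))
  shift <- interval_overlap_fisher(
    dplyr::mutate(a, start = start + 50, end = end + 50),
    dplyr::mutate(b, start = start + 50, end = end + 50), 300
  )
  expect_equal(tidy(base), tidy(shift))
})

test_that("three-level analysis recovers planted avoidance and enrichment", {
  cfg_av <- simulation_config(genes_per_clade = 80, species_per_clade = 4,
                              pss_in_lcr_ratio = 0, seed = 61)
  sim_av <- simulate_clade(cfg_av)
  info <- dplyr::transmute(sim_av$truth$genes, gene_id, clade_id, n_col)
  lcr_cols <- dplyr::filter(sim_av$truth$lcrs, species_id ==
                              sim_av$truth$lcrs$species_id[1])
  aligned <- dplyr::transmute(lcr_cols, gene_id, col_start, col_end,
                              purity = realized_purity)
  pss <- load_pss(sim_av$pss)
  res <- three_level_overlap(aligned, pss, info)
  clade <- dplyr::filter(res, level == "clade_overlap")
  expect_equal(clade$direction, "depletion")

  cfg_en <- simulation_config(genes_per_clade = 400, species_per_clade = 1,
                              pss_in_lcr_ratio = 3, seed = 62)
  sim_en <- simulate_clade(cfg_en)
  info2 <- dplyr::transmute(sim_en$truth$genes, gene_id, clade_id, n_col)
  aligned2 <- dplyr::transmute(sim_en$truth$lcrs, gene_id, col_start,
                               col_end)
  res2 <- three_level_overlap(aligned2, load_pss(sim_en$pss), info2,
                              levels = "clade_overlap")
  expect_equal(res2$direction, "enrichment")
  expect_true(res2$significant)

  # single gene without PSS: untestable gene-level verdict
  solo <- three_level_overlap(
    tibble::tibble(gene_id = "g1", col_start = 0L, col_end = 10L),
    tibble::tibble(gene_id = character(), site = integer()),
    tibble::tibble(gene_id = "g1", clade_id = "c", n_col = 100L)
  )
  expect_true(solo$untestable[solo$level == "gene"])
})

test_that("omega comparison excludes outliers and finds the direction", {
  withr::with_seed(71, {
    om <- tibble::tibble(
      gene_id = rep(c(paste0("L", 1:50), paste0("N", 1:50)), each = 10),
      omega = c(rgamma(500, 2, rate = 2 / 0.15),
                rgamma(500, 2, rate = 2 / 0.25))
    )
  })
  om$omega[1] <- 999
  cmp <- omega_group_compare(om, paste0("L", 1:50))
  expect_equal(cmp$n_lcr + cmp$n_other, sum(om$omega <= 2))
  expect_equal(cmp$direction, "lower")
  expect_lt(cmp$p, 0.05)

  # empty group is untestable
  cmp2 <- omega_group_compare(om, character(0))
  expect_equal(cmp2$direction, "untestable")
})

test_that("rank-sum comparison holds its size on identical groups", {
  reject <- vapply(1:300, function(i) {
    withr::with_seed(6000 + i, {
      om <- tibble::tibble(
        gene_id = rep(c("a", "b"), each = 100),
        omega = rgamma(200, 2, rate = 2 / 0.2)
      )
    })
    omega_group_compare(om, "a")$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("percent GC matches direct counting and compares groups", {
  expect_equal(percent_gc(c("GGCC", "ATAT", "ATGC")), c(100, 0, 50))
  expect_error(percent_gc(""), "zero-length")
  genes <- tibble::tibble(
    gene_id = c(paste0("L", 1:30), paste0("N", 1:30)),
    cds = c(rep("GGGCCCGGG", 30), rep("ATTATAATT", 30))
  )
  cmp <- gc_group_compare(genes, paste0("L", 1:30))
  expect_equal(cmp$direction, "higher")
  expect_lt(cmp$p, 0.05)
})
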