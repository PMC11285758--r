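test_that("background frequencies are normalised with a pseudo-floor", {
  bg <- lcr_background("AAAA")
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_equal(unname(bg["A"]), 1 / (1 + 19e-4), tolerance = 1e-12)
  expect_equal(unname(bg["W"]), 1e-4 / (1 + 19e-4), tolerance = 1e-12)

  bg2 <- lcr_background("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(bg2), rep(1 / 20, 20))

  expect_error(lcr_background(character(0)), "no sequences")
  expect_error(lcr_background("ABZ"), "bad alphabet")
})

test_that("background estimation converges to the generating multinomial", {
  probs <- c(0.3, 0.2, 0.1, rep(0.4 / 17, 17))
  names(probs) <- AA20
  withr::with_seed(11, {
    seqs <- replicate(1000, paste(
      sample(AA20, 50, replace = TRUE, prob = probs), collapse = ""
    ))
  })
  bg <- lcr_background(seqs)
  expect_true(all(abs(bg - probs) < 0.01))
})

test_that("purity follows the primary-residue definition", {
  # a 100-residue stretch with 10 copies of the primary residue: purity 10%
  stretch <- paste(c(rep("Q", 10), rep(setdiff(AA20, "Q")[1:18], 5)),
                   collapse = "")
  expect_equal(nchar(stretch), 100)
  expect_equal(compute_purity(stretch)$purity, 0.10)

  expect_equal(compute_purity("AAAA"),
               tibble::tibble(primary_residue = "A", purity = 1.0))
  expect_equal(compute_purity("AABAB")$purity, 0.6)
  # alphabetical tie-break
  expect_equal(compute_purity("AABB")$primary_residue, "A")
  expect_equal(compute_purity("AABB")$purity, 0.5)
  expect_error(compute_purity(""), "empty")

  # permutation invariance
  withr::with_seed(5, {
    s <- random_protein(40)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(compute_purity(s), compute_purity(perm))
  })
})

test_that("composition signatures are canonical", {
  perms <- c("ILA", "LIA", "AIL", "IAL", "LAI", "ALI")
  for (p in perms) expect_equal(canonicalize_composition(p), "AIL")
  expect_equal(canonicalize_composition("Q"), "Q")
  expect_equal(canonicalize_composition(c("G", "A", "G", "A")), "AG")
  expect_error(canonicalize_composition("ACDEFG"), "signature too large")
})

test_that("post-filters enforce length, X and signature-size rules", {
  cand <- tibble::tibble(start0 = c(0, 0, 0, 0, 0, 0),
                         end0 = c(3, 4, 5, 6, 7, 6))
  subs <- c("AAA", "AAAA", "AAXAA", "ACDEFG", "AACDEFG", "AAACDE")
  kept <- filter_lcrs(cand, subs)
  # length 3 removed, 4 retained; X removed; six unique residues removed
  # ("ACDEFG", "AACDEFG"); five or fewer unique retained ("AAACDE")
  expect_identical(kept, cand[c(2, 6), ])
})

test_that("scanner finds a planted homopolymer and nothing swallows it", {
  withr::with_seed(101, {
    flank1 <- random_protein(50)
    flank2 <- random_protein(50)
  })
  prot <- paste0(flank1, strrep("A", 20), flank2)
  hits <- scan_protein(prot, uniform_bg, t = 0.001, m = 5, M = 500)
  containing <- hits[hits$start0 <= 50 & hits$end0 >= 70, ]
  expect_equal(nrow(containing), 1)
  expect_equal(containing$primary_residue, "A")
})

test_that("a pure Q run scores the closed-form binomial tail", {
  hits <- scan_protein(strrep("Q", 10), uniform_bg, t = 0.001, m = 5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start0, 0L)
  expect_equal(hits$end0, 10L)
  expect_equal(hits$purity, 1.0)
  expect_equal(hits$signature, "Q")
  expect_equal(hits$pvalue, 0.05^10)
})

test_that("uniform sequences are almost never annotated at stringent t", {
  counts <- vapply(1:100, function(i) {
    withr::with_seed(3000 + i, {
      prot <- random_protein(200)
    })
    c(nrow(scan_protein(prot, uniform_bg, t = 1e-8, m = 5, M = 500)),
      nrow(scan_protein(prot, uniform_bg, t = 1e-6, m = 5, M = 500)))
  }, numeric(2))
  # at t = 1e-8 the null is essentially clean; at 1e-6 short windows whose
  # five-residue set covers the whole window (p = 0.25^10) sneak under the
  # threshold, so only a rate bound holds there
  expect_gte(sum(counts[1, ] == 0), 95)
  expect_lte(mean(counts[2, ]), 2)
})

test_that("scanner errors on bad alphabet and returns empty below m", {
  expect_error(scan_protein("ACDB", t = 0.5, m = 4), "bad alphabet")
  expect_equal(nrow(scan_protein("ACD", m = 5)), 0)
  # X is tolerated in the protein; windows containing it are never scored
  hits <- scan_protein(paste0(strrep("A", 10), "X", strrep("G", 10)),
                       uniform_bg, t = 0.01, m = 5)
  expect_true(all(hits$signature %in% c("A", "G")))
})

test_that("scanner matches brute-force enumeration on short sequences", {
  cases <- list()
  withr::with_seed(77, {
    for (i in 1:12) cases[[i]] <- random_protein(sample(20:60, 1))
    # seed low-complexity content so selection paths are exercised
    for (i in 13:20) {
      run <- strrep(sample(AA20, 1), sample(6:15, 1))
      cases[[i]] <- paste0(random_protein(sample(5:20, 1)), run,
                           random_protein(sample(5:20, 1)))
    }
  })
  bg <- lcr_background(unlist(cases))
  for (t in c(0.01, 0.001)) {
    for (prot in cases) {
      got <- scan_protein(prot, bg, t = t, m = 5, M = 60)
      want <- brute_scan(prot, bg, t = t, m = 5, M = 60)
      expect_equal(got$start0, want$start0)
      expect_equal(got$end0, want$end0)
      expect_equal(got$signature, want$signature)
      expect_equal(got$pvalue, want$pvalue)
    }
  }
})

test_that("lowering t never adds annotations", {
  withr::with_seed(42, {
    prots <- c(
      replicate(4, paste0(random_protein(40), strrep("S", 12),
                          random_protein(40))),
      replicate(2, random_protein(80))
    )
  })
  for (prot in prots) {
    strict <- scan_protein(prot, uniform_bg, t = 1e-5)
    loose <- scan_protein(prot, uniform_bg, t = 1e-2)
    expect_lte(nrow(strict), nrow(loose))
    if (nrow(strict) > 0) {
      for (i in seq_len(nrow(strict))) {
        # same or merged interval present at the looser threshold
        expect_true(any(
          loose$start0 <= strict$start0[i] & loose$end0 >= strict$end0[i] &
            loose$signature == strict$signature[i]
        ))
      }
    }
  }
})

test_that("planted stretches are recovered with faithful purity", {
  cfg <- simulation_config(genes_per_clade = 60, species_per_clade = 1,
                           seed = 909)
  sim <- simulate_clade(cfg)
  truth <- sim$truth$lcrs
  truth <- truth[truth$realized_purity >= 0.9 & truth$length_aa >= 10, ]
  lcrs <- scan_lcrs(sim$genes)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- lcrs[lcrs$gene_id == truth$gene_id[i] &
                   lcrs$species_id == truth$species_id[i] &
                   lcrs$start0 < truth$end0[i] &
                   lcrs$end0 > truth$start0[i] &
                   lcrs$primary_residue == truth$residue[i], ]
    nrow(cand) > 0 &&
      any(abs(cand$purity - truth$realized_purity[i]) <= 0.1)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("parameter robustness counts overlap-and-signature matches", {
  a <- tibble::tibble(
    gene_id = c("g1", "g2"), species_id = "s", start0 = c(10L, 50L),
    end0 = c(20L, 60L), signature = c("A", "Q")
  )
  expect_equal(parameter_robustness(a, a)$prop_a, 1)
  b <- dplyr::mutate(a, start0 = start0 + 100L, end0 = end0 + 100L)
  expect_equal(parameter_robustness(a, b)$prop_a, 0)
  shifted <- dplyr::mutate(a, start0 = start0 + 2L, end0 = end0 + 2L)
  r <- parameter_robustness(a, shifted)
  expect_equal(r$prop_a, 1)
  expect_equal(r$prop_b, 1)
  expect_warning(parameter_robustness(a[0, ], b), "empty")
})
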