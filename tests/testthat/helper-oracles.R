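# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or closed form, sharing no code with the package
# internals they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

uniform_bg <- stats::setNames(rep(1 / 20, 20), AA20)

# Brute-force scanner: plain-loop enumeration of every window and greedy
# residue set, greedy non-overlapping selection, merge of touching windows
# with equal signatures. Mirrors the documented contract, not the C++ code.
brute_scan <- function(protein, background = uniform_bg, t = 0.001, m = 5,
                       M = 500) {
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  cand <- list()
  for (i in seq_len(L)) {
    for (j in i:min(L, i + M - 1)) {
      len <- j - i + 1
      if (len < m) next
      win <- chars[i:j]
      if ("X" %in% win) next
      counts <- table(factor(win, levels = AA20))
      ord <- order(-as.numeric(counts), AA20)
      best_p <- 2
      best_k <- 0
      for (k in 1:5) {
        set <- AA20[ord[seq_len(k)]]
        if (counts[set[k]] == 0) break
        cc <- sum(counts[set])
        pp <- sum(background[set])
        pv <- if (pp >= 1) 1 else pbinom(cc - 1, len, pp, lower.tail = FALSE)
        if (pv < best_p) {
          best_p <- pv
          best_k <- k
        }
      }
      if (best_p <= t) {
        cand[[length(cand) + 1]] <- list(
          start0 = i - 1L, end0 = j, p = best_p,
          sig = paste(sort(AA20[ord[seq_len(best_k)]]), collapse = "")
        )
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start0 = integer(), end0 = integer(),
                      pvalue = double(), signature = character()))
  }
  p <- vapply(cand, `[[`, 0, "p")
  s <- vapply(cand, `[[`, 0L, "start0")
  e <- vapply(cand, `[[`, 0L, "end0")
  ord <- order(p, -(e - s), s)
  occ <- logical(L)
  keep <- integer(0)
  for (w in ord) {
    span <- (s[w] + 1):e[w]
    if (any(occ[span])) next
    occ[span] <- TRUE
    keep <- c(keep, w)
  }
  keep <- keep[order(s[keep])]
  out <- data.frame(
    start0 = s[keep], end0 = e[keep], pvalue = p[keep],
    signature = vapply(cand[keep], `[[`, "", "sig"),
    stringsAsFactors = FALSE
  )
  # merge touching windows with identical signatures
  i <- 1
  while (i < nrow(out)) {
    if (out$end0[i] == out$start0[i + 1] &&
        out$signature[i] == out$signature[i + 1]) {
      out$end0[i] <- out$end0[i + 1]
      sig <- strsplit(out$signature[i], "")[[1]]
      sub <- chars[(out$start0[i] + 1):out$end0[i]]
      out$pvalue[i] <- pbinom(sum(sub %in% sig) - 1, length(sub),
                              sum(background[sig]), lower.tail = FALSE)
      out <- out[-(i + 1), , drop = FALSE]
    } else {
      i <- i + 1
    }
  }
  rownames(out) <- NULL
  out
}

# Exact two-sided Fisher p by direct hypergeometric enumeration.
fisher_oracle_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  N <- n11 + n12 + n21 + n22
  k <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(k, r1, N - r1, c1)
  obs <- dhyper(n11, r1, N - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Build per-gene presence flags realising a given 2x2 table.
flags_for_table <- function(n11, n12, n21, n22) {
  data.frame(
    has_lcr = rep(c(TRUE, TRUE, FALSE, FALSE), c(n11, n12, n21, n22)),
    has_pss = rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n12, n21, n22))
  )
}

# Closed-form expected richness when sampling s items without replacement
# from a multiset with type counts cnt (hypergeometric inclusion formula).
expected_richness <- function(cnt, s) {
  N <- sum(cnt)
  sum(1 - exp(lchoose(N - cnt, s) - lchoose(N, s)))
}
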