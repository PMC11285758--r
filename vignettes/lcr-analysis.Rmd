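---
title: "Low-complexity regions, purity and selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-complexity regions, purity and selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrscan)
library(dplyr)
```

## The problem

Low-complexity regions (LCRs) are protein stretches built from fewer
amino-acid types than expected — anything from mildly biased compositions to
pure homopeptide runs. They are volatile (replication slippage expands and
contracts them), often GC-rich at the DNA level, and sit in tension with
selection: they generate rapid variation while the genes carrying them tend
to be under strong purifying selection. `lcrscan` implements a desk-scale,
fully testable version of a comparative analysis of LCRs and positively
selected sites (PSS) across clade-structured orthologous gene families:
detection and purity profiling, mapping into codon alignments, positional
and diversity statistics, and Fisher-exact overlap/co-occurrence tests
against PSS, plus omega (dN/dS) and %GC group comparisons.

Two definitions anchor everything:

* **Purity** of an LCR is the fraction of its residues belonging to the
  primary (most frequent) amino acid: a 100-residue stretch whose primary
  residue occurs 10 times has purity 10%. Ties are broken alphabetically.
  A configuration switch (`compute_purity(mode = "signature")`) measures
  instead the fraction covered by the whole signature set; the primary-residue
  definition is the default because that is how purity is defined for the
  gradient analyses.
* The **composition signature** of an LCR is its set of unique residues (at
  most five), written in sorted order, so ILA/LIA/AIL/IAL/LAI/ALI all
  canonicalise to `AIL`. Signatures are the "types" for all diversity
  statistics.

## The scanner

The detector is a from-scratch low-probability-subsequence scanner in the
spirit of compositional-bias tools such as fLPS, not a port of any of them.
For every window of length `m` to `M` it grows candidate residue sets
greedily (sizes 1–5, most frequent residue first, ties alphabetical) and
scores each set with the binomial upper tail

$$P(X \ge c), \qquad X \sim \mathrm{Bin}(n, p),$$

where $c$ is the count of set residues in the window, $n$ the window length
and $p$ the summed background frequency of the set. Windows scoring at or
below the threshold `t` are retained and then selected greedily by ascending
p-value (ties: longer window, then smaller start), discarding overlaps;
touching survivors with identical signatures are merged (and rescored on the
merged window), which is how reported regions can exceed `M`. Detected
regions then pass the three standard post-filters: longer than three
residues, no `X`, at most five unique residues.

Defaults are `t = 0.001`, `m = 5`, `M = 500` — midpoints/endpoints of the
ranges over which the robustness analysis varies them
(`parameter_robustness()` measures the pairwise proportion of regions
re-detected under different settings). The background is estimated from the
input set per clade (`lcr_background()`), with a 1e-4 pseudo-frequency floor
for absent residues.

Two numerical properties are worth knowing. First, the greedy selection is
deterministic, including tie-breaks, and is verified exactly against a
brute-force enumeration oracle on short sequences. Second, the binomial
score has a hard floor per window geometry: a 10-residue window fully
covered by its 5-residue set scores $0.25^{10} \approx 9.5\times10^{-7}$
under a uniform background, so thresholds at or above 1e-6 admit a small
rate of such windows even in i.i.d. uniform sequences (about 0.7 per
200-residue protein; measured in the tests). At the default `t = 0.001`
this is intentional — permissive detection followed by purity filtering
mirrors how the downstream analyses gate on purity > 0.7 — but null
sequences are only essentially clean from about `t = 1e-8` down.

Coordinates are 0-based half-open internally; report files also carry
1-based inclusive columns, labelled as such.

## Orthology, ORF filters and alignment mapping

CDSs are validated (`check_orf()`) by four rules, checked in a fixed order:
only A/C/G/T, length a multiple of 3, ATG start, and no stop codon before
the final codon (a trailing stop is permitted; alignments in this package
are stop-trimmed, and the dialect is recorded in the simulator metadata).
`N`, lower case and any other character fail the alphabet rule. Genes then
need at least three surviving species per clade
(`filter_clade_genes()`); a clade whose genes all fall below the minimum is
flagged as excluded outright.

LCR residue intervals are mapped into amino-acid columns of the per-gene
codon alignment by walking the species' gap pattern (`map_to_alignment()`;
aa column $k$ owns nucleotide columns $[3k, 3k+3)$). Orthologous repeats are
called by positional overlap in that shared frame: single-linkage connected
components under "intervals share at least one column"
(`group_orthologous()`). The one-column overlap and the single-linkage
transitivity are deliberate, parameter-free choices — the overlap threshold
is exposed as `min_overlap` for sensitivity analyses. Per-column alignment
coverage (`alignment_coverage()`) supports the check that positional signals
are not artefacts of ragged terminal alignment.

## Positional and purity profiles

Feature positions are normalised midpoints, $((start+end)/2)/L$. Profiles
use half-open bins $[k/n, (k+1)/n)$ (the last bin closed at 1): 20 bins for
amino-acid-specific LCR profiles, 10 for the LCR/PSS co-distribution. Under
a uniform positional distribution each of 20 bins is expected to hold about
5%; bins at or above 8% are called over-abundant and at or below 2%
under-abundant (`call_abundance()`), matching the thresholds used for the
published positional-preference analyses.

The purity gradient (`purity_gradient_profile()`) reports, per clade and
10%-purity bin, the fraction of genes with at least one LCR in the bin. The
default is the cumulative convention — "at 70% purity" means purity
strictly greater than 0.70 — because the overlap analyses gate on "more
than 70% purity"; the per-bin convention is available for
distribution-shaped figures. Genes are classed terminal/central/mixed by
whether all their feature midpoints fall in the outer 10% zones, all in the
middle, or both (`classify_gene_position()`); the 0.1 cut aligns with the
outermost bins of the 10-bin scheme and is configurable, since no canonical
boundary exists.

## Diversity of LCR types

Treating signatures as species and detected LCRs as sampling effort:
richness is the number of distinct signatures; Simpson's index of diversity
is $D = 1-\sum p_i^2$ and Shannon's is $H = -\sum p_i \ln p_i$ (both
delegated to vegan). Note that $D = 1$ under perfectly even abundances only
asymptotically in the number of types; statements equating evenness with
$D = 1$ are approximations, not properties of the index.

`accumulation_curve()` subsamples the LCR list without replacement on a
log-spaced grid of sample sizes and fits a slope. The default model
regresses mean richness on $\ln(\text{sample size})$; a log–log power law is
available (`model = "power"`). Neither model is claimed to reproduce any
externally published slope values — the functional form behind those is not
derivable from their description — but the degenerate cases are exact: a
single type gives slope 0, all-unique types give power-law slope 1. The
test-suite oracle for the curve is the closed-form hypergeometric
inclusion expectation $E[S_s] = \sum_t \left(1 - \binom{N-c_t}{s} / \binom{N}{s}\right)$.

## Selection integration

PSS tables (gene, aa-alignment site, BEB posterior) are filtered at
posterior **strictly greater than** 0.95 and deduplicated per site keeping
the maximum posterior (`load_pss()`). Lineage omega tables are capped at
$\omega \le 2$ before comparisons (`filter_omega()`), because free-ratio
fits occasionally return degenerate values up to 999.

Three Fisher-exact analyses mirror the three scales of the co-occurrence
question (`three_level_overlap()`):

1. **Gene-wise overlap** — per gene, the bedtools-fisher-style table: LCR
   intervals overlapped by at least one PSS site, LCRs unhit, PSS sites
   outside every LCR, and an estimated count of empty interval-sized slots,
   $n_{22} = \max(0, \mathrm{round}(L/(\bar{\ell}_a + \bar{\ell}_b)) - n_{11} - n_{12} - n_{21})$.
   PSS are length-1 intervals in aa-alignment columns — the only coordinate
   frame the two feature sets share. This table construction is a fixed
   contract; it follows the cited tool's documented heuristic, and its
   null behaviour is accordingly conservative rather than exactly
   OR-centred on 1.
2. **Clade-wise overlap** — the same test on a concatenated coordinate
   space with per-gene offsets.
3. **Clade-wise co-occurrence** — `fisher.test` on per-gene presence flags
   (both / LCR-only / PSS-only / neither).

P-values are exact two-sided hypergeometric (via `stats::fisher.test`,
verified against an independent enumeration oracle on every 2×2 table with
margins up to 30); the odds ratio reported is the unconditional sample OR
$n_{11}n_{22}/n_{12}n_{21}$ (infinite when a denominator cell is zero), not
the conditional MLE. Significance is labelled at $p < 0.05$ two-sided with
no multiple-testing correction, matching the analysis being emulated; a
Benjamini–Hochberg adjustment can be applied to the returned tibble but is
off by default. Empty interval sets yield an `untestable` verdict rather
than a p-value.

Group comparisons of omega and %GC between LCR-containing and LCR-free
genes are two-sided Wilcoxon rank-sum tests per clade, reporting group
sizes, medians, means and direction.

## The synthetic-data generator

`simulate_clade()` emits gene families with complete ground truth so every
stage has a no-download test surface. Its defaults are the package's study
conditions, chosen once to emulate the statistical structure of the real
data at desk scale:

* 6 species and 120 genes per clade; protein lengths
  $\mathrm{round}(\Gamma(\text{shape }6, \text{scale }50))$ clamped to
  [100, 800] (mean ≈ 300 residues, right-skewed like real proteins).
* 40% of genes carry one planted LCR (exactly
  `round(prevalence × genes)`); planted purity ~ Beta(8, 2) (mean 0.8),
  length $10 + \mathrm{NegBin}(\mu = 10, \text{size} = 2)$ residues, and
  midpoints falling in the terminal 10% zones with probability 0.5 —
  the terminal preference the positional analyses look for.
* Species differ by whole-codon slippage indels at the LCR 3' boundary
  (−1 to +2 codons), keeping every sequence in frame, and by a 0.5%
  per-residue substitution rate outside the stretch. The generator knows
  the true homology, so it emits gap-consistent codon alignments directly;
  no aligner is involved.
* PSS sites appear at 0.002 per alignment column outside LCRs and 3× that
  inside LCR columns, with BEB posteriors drawn in (0.951, 0.999); decoy
  sub-threshold sites (posterior 0.5–0.95) exercise the strict filter. The
  background rate makes roughly half the genes PSS-positive — sites passing
  a 0.95 posterior cut are rare in real scans, and co-occurrence analysis
  is only meaningful when presence varies.
* Lineage omega ~ Gamma(shape 2) with mean 0.15 for LCR genes and 0.25 for
  others; 1% of values are replaced by 999 to emulate degenerate
  free-ratio estimates. The %GC effect is applied purely through
  GC-biased synonymous codon choice in LCR genes (weights
  $(1+0.5)^{\#GC}$), so protein-level truth is untouched.
* A single seed drives a per-gene stream-split RNG: the same config and
  seed reproduce byte-identical output, and gene subsets are independently
  reproducible.

What the generator does **not** emulate: realistic substitution processes
(no GTR/codon models), phylogenetically correlated omega, alignment error,
annotation artefacts, or paralogy. Passing tests therefore demonstrate that
the statistics recover planted effects under clean, known-truth conditions
— not that the pipeline is robust to the pathologies of real orthology
calls and alignments.

## Verification scale and design choices

The statistical acceptance checks run at sizes fixed by power analysis, not
by the defaults: planted-LCR recall uses a 200-gene single-species clade
(recall ≥ 0.95 at realized purity ≥ 0.9 under the default scanner
settings); the clade-wise PSS-in-LCR enrichment detection (ratio 3) uses
800-gene single-species clades, where a 40-replicate pilot put power at
1.0 (0.975 at 600 genes, 0.90 at 400 — small clades genuinely cannot
support the claim); type-I checks use 500 replicates of 2000-gene flag
tables and 100-per-group omega draws. Fisher p-values are verified against
enumeration over all 164,000+ tables with margins ≤ 30, and the scanner
against brute force on sequences up to 60 residues.

Known limitations: the scanner's per-window binomial score is not corrected
for the number of windows scanned, so `t` is a per-window (not per-protein)
error rate; the bedtools-style $n_{22}$ slot estimate makes the interval
test's null odds ratio geometry-dependent; and the accumulation-curve slope
depends on the chosen model family. All three are properties of the methods
being emulated and are surfaced as explicit parameters or documented
contracts rather than hidden.
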