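# lcrscan

Detection and evolutionary analysis of protein low-complexity regions
(LCRs), for researchers studying how compositionally biased protein
stretches interact with natural selection across clades of orthologous
genes.

LCRs — from mildly biased residue mixtures to pure homopeptide runs — are
volatile sources of rapid functional variation. `lcrscan` provides a tested,
fully reproducible pipeline for the questions that follow from that:
where do LCRs sit along genes, how pure are they, how diverse are their
composition types across species, and do they overlap and co-occur with
positively selected sites (PSS) more than chance allows?

## What it computes

* **Scanning.** A binomial low-probability-subsequence scanner: every
  window of length *m*–*M* is scored by the tail P(X ≥ c) with X ~
  Bin(n, p), where c counts the residues of a greedily grown candidate set
  (≤ 5 residues) in the window and p is the set's summed background
  frequency; windows with P ≤ t are selected greedily (ascending p-value,
  non-overlapping). Post-filters: length > 3, no X, ≤ 5 unique residues.
* **Purity** = count(primary residue) / length, the fraction of the stretch
  belonging to its most frequent amino acid; profiles across a >0–100%
  purity gradient in 10% bins.
* **Orthologous repeats.** ORF validation, a ≥3-species-per-clade filter,
  mapping of LCR coordinates into codon-alignment columns, and
  single-linkage grouping of repeats by positional overlap in the shared
  alignment frame.
* **Positional preference.** Normalised-midpoint binning (20 bins per
  amino-acid type; 10 bins for the LCR/PSS co-distribution) with over/under
  abundance calls at 8% / 2% against the 5% uniform expectation.
* **Diversity.** Richness, accumulation ("species–area") curves and slopes,
  Simpson's D = 1 − Σp² and Shannon's H = −Σp ln p over canonical
  composition signatures (ILA ≡ AIL).
* **Selection.** PSS ingestion at BEB posterior > 0.95, ω capped at 2,
  Fisher-exact overlap tests at gene and clade scale (bedtools-fisher-style
  tables), clade co-occurrence tests, and Wilcoxon comparisons of ω and %GC
  between LCR-containing and LCR-free genes.
* **Synthetic data.** A clade-structured generator with planted LCRs
  (controlled purity, length, terminal preference), slippage indels,
  PSS enriched inside LCRs, lower-ω and GC-shifted LCR genes, and complete
  ground truth — every statistic above is testable without any download.

## Worked example

```r
library(lcrscan)
library(dplyr)

cfg <- simulation_config(genes_per_clade = 60, species_per_clade = 4,
                         seed = 42)
sim  <- simulate_clade(cfg)
lcrs <- scan_lcrs(sim$genes)

head(select(lcrs, gene_id, species_id, start0, end0, signature,
            primary_residue, purity), 4)
#>   gene_id       species_id   start0  end0 signature primary_residue purity
#> 1 clade01_g0001 clade01_sp01     18    23 DEPVY     D                0.2
#> 2 clade01_g0001 clade01_sp01     23    40 K         K                0.824
#> 3 clade01_g0001 clade01_sp01     43    49 IQSTY     Y                0.333
#> 4 clade01_g0001 clade01_sp01     65    72 ADGLT     D                0.286
```

Row 2 is a genuine planted lysine repeat (17 residues, 82% pure); rows 1, 3
and 4 are the permissive low-purity calls that the purity gate removes
before any selection analysis. Diversity of composition types per species:

```r
diversity_by_unit(lcrs)
#>   unit         n_lcrs richness simpson_d shannon_h
#> 1 clade01_sp01   1399     1339     0.999      7.18
#> 2 clade01_sp02   1414     1352     0.999      7.19
#> 3 clade01_sp03   1455     1392     0.999      7.22
#> 4 clade01_sp04   1444     1383     0.999      7.22
```

Overlap and co-occurrence with PSS, restricted to LCRs with purity > 0.7
and mapped into alignment columns:

```r
aligned <- lcrs %>%
  filter(purity > 0.7) %>%
  map_to_alignment(sim$alignments) %>%
  group_orthologous()
info <- transmute(sim$truth$genes, gene_id, clade_id, n_col)
res  <- three_level_overlap(aligned, load_pss(sim$pss), info)
filter(res, level != "gene")
#>   level              unit     n11  n12  n21  n22 odds_ratio        p direction
#> 1 clade_overlap      clade01   14   48   38  826       6.34  2.08e-6 enrichment
#> 2 clade_cooccurrence clade01   14    9   17   20       1.83  2.98e-1 enrichment
```

The clade-wise interval test finds PSS significantly enriched inside LCRs
(the generator plants them at 3× background density inside LCR columns);
the 60-gene co-occurrence table points the same way but is too small to be
significant on its own. The planted ω effect is recovered cleanly:

```r
omega_group_compare(sim$omega, unique(filter(lcrs, purity > 0.7)$gene_id))
#>   unit    n_lcr n_other median_lcr median_other    p         direction
#> 1 clade01    91     148      0.134        0.224  3.1e-06    lower
```

`run_pipeline(config, out_dir)` chains all stages (scan → ORF/clade filter
→ mapping → profiles → diversity → selection) from a YAML or list config,
writing per-stage TSVs, a JSON report and a hash-bearing run manifest;
`inst/cli/lcrscan.R` is a thin command-line wrapper.

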