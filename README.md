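# haplopair

Identify true allele pairs between the two haplotypes of a diploid genome
assembly, and classify allele-specific expression (ASE), with statistically
defensible filtering instead of raw sequence similarity.

## The problem

In a haplotype-resolved assembly each gene should have one copy per
haplotype — an allele pair at the same locus. Paralogs from ancient
whole-genome, segmental or tandem duplications are often nearly as similar
as the true allele, and when an annotation drops one true allele the
paralog becomes the best hit, corrupting every downstream allele-level
analysis. `haplopair` separates the two classes with a dual statistical
layer over reciprocal-best-hit (RBH) candidates:

1. **Homology**: RBH pairs by protein bit score (builtin aligner or an
   imported 12-column tabular hit file), restricted to corresponding
   chromosomes.
2. **Colinearity**: anchors are chained into synteny blocks by a
   longest-colinear-run dynamic program on gene-order ranks; non-colinear
   pairs are rejected.
3. **Divergence**: per-pair Ka/Ks by the Nei–Gojobori method with
   Jukes–Cantor correction, `d = -(3/4)·ln(1 − 4p/3)`; saturated pairs
   (p ≥ 3/4) are removed.
4. **Ks outlier layer**: either the parametric 3σ rule
   (outlier ⇔ Ks < μ − 3σ or Ks > μ + 3σ) for near-normal Ks
   distributions, or Tukey's fences
   ([Q1 − i·IQR, Q3 + i·IQR], default i = 1.5, outer fence 2i) for
   non-normal ones, with the tunable `i` trading strictness for coverage.
5. **Slope layer**: the same outlier rule applied to per-block slopes of
   rank_b on rank_a (true 1:1 blocks have slope ≈ ±1); aberrant-slope
   blocks are removed.

Surviving pairs are tested for ASE per condition with a negative-binomial
Wald test on median-of-ratios-normalized counts (≥ 3 replicates,
Benjamini–Hochberg adjustment) and classified into five categories:
`No_expression`, `Diff00` (padj > 0.05), `Diff0` (padj ≤ 0.05, |FC| ≤ 2),
`Diff2` (2 < |FC| < 8), `Diff8` (|FC| ≥ 8).

A truth-labelled synthetic-diploid simulator generates the full input set
(FASTA + GFF3 + chromosome map + count matrices) with known allele/paralog
labels, so the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(haplopair)
library(dplyr)

sim <- simulate_diploid(sim_config(), seed = 1)   # 2 chrom pairs x 1000 genes,
                                                  # 100 paralog decoys, 1 inversion
res <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map)
res
#> <allele_set>
#>   1999 RBH pairs -> 1895 alleles (method sigma)
#> # A tibble: 6 × 3
#>   stage           retained removed
#>   <chr>              <int>   <int>
#> 1 rbh                 1999       0
#> 2 same_chromosome     1999       0
#> 3 colinear            1900      99
#> 4 ks_estimable        1900       0
#> 5 ks_filtered         1895       5
#> 6 slope_filtered      1895       0
```

Reading: of 1999 RBH candidates, 99 (the off-diagonal paralog decoys) fail
colinearity, 5 more are flagged as Ks outliers — near-diagonal decoys whose
Ks (0.3–1.0) stands far outside the allelic distribution
(Normal(0.03, 0.01)) — and 1895 pairs survive as alleles. Against the
simulator's truth labels this run has precision 1.00 and recall 0.997.

```r
autoplot(res)                       # colinearity dot plot, coloured by status
alleles <- tidy(res) |> filter(status == "allele")

cnt <- simulate_counts(sim, seed = 1)
ase <- test_allele_pairs(cnt$counts, cnt$design, alleles)
glance(ase)
#> # A tibble: 1 × 6
#>   condition No_expression Diff00 Diff0 Diff2 Diff8
#>   <chr>             <int>  <int> <int> <int> <int>
#> 1 cond01                0   1895     0     0     0
```

With no simulated expression shift essentially everything lands in
`Diff00`, as it should; re-simulating with `fraction_ase = 0.2` moves the
shifted pairs into `Diff8`.

A thin command-line front end mirroring the two-step workflow
(`simulate` / `identify` / `ase` / `plot`) is installed at
`system.file("cli", "haplopair", package = "haplopair")`.

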