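---
title: "Identifying allele pairs and allele-specific expression in haplotype-resolved diploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying allele pairs and allele-specific expression in haplotype-resolved diploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopair)
library(dplyr)
```

## The problem

A haplotype-resolved diploid assembly gives two complete copies of every
chromosome. For most genes the two haplotypes carry one copy each — an
allele pair at the same locus — and comparing the expression of the two
alleles (allele-specific expression, ASE) requires knowing which gene on
haplotype A corresponds to which gene on haplotype B. Sequence similarity
alone is not enough to establish that correspondence: plant genomes carry
paralogs from ancient whole-genome, segmental and tandem duplications that
can be nearly as similar to a gene as its true allele, and when an assembly
or annotation drops one true allele, the paralog becomes the best hit and a
false pair is called.

`haplopair` separates true allele pairs from paralogous look-alikes with a
statistical framework built on two observations:

1. Allelic divergence is *homogeneous*: the synonymous substitution rate
   (Ks) between true alleles reflects the heterozygosity of one individual,
   so allelic Ks values cluster tightly (often approximately normally),
   while paralogous pairs diverged at older duplication events and sit far
   into the right tail.
2. Allelic structure is *positional*: true pairs fall on the diagonal of a
   gene-order dot plot between corresponding chromosomes, in long colinear
   blocks with slope close to ±1; paralogous blocks sit off-diagonal or run
   at aberrant slopes.

## The identification workflow

Candidate pairs are reciprocal best hits (RBH) by protein similarity:
`(a, b)` is kept when `b` is `a`'s best cross-haplotype hit by bit score and
vice versa. Ties are broken deterministically (longer alignment, then lower
e-value, then lexicographically smaller subject id). Built-in scoring uses
local protein alignment (BLOSUM62, gap open 10, extend 0.5) over candidates
that share at least one amino-acid 5-mer; production users can import a
12-column tabular hit file from any external aligner instead.

Candidates then pass through an ordered cascade, and every RBH pair receives
exactly one status — the counts at each stage telescope, which the test
suite asserts:

1. **Chromosome correspondence.** Pairs whose chromosomes are not a
   corresponding pair are rejected (they remain visible in the output with
   status `rejected_cross_chrom`).
2. **Colinearity.** Anchors (RBH pairs with gene-order ranks on their
   chromosomes) are chained per chromosome pair by a weighted
   longest-increasing/decreasing-subsequence dynamic program. An anchor may
   extend a chain when both rank gaps are positive and at most `max_gap`
   (default 25), with a consistent sign in rank_b. The longest chain is
   extracted, its anchors removed, and the program repeated; chains shorter
   than `min_block_size` (default 5) are discarded. Ranks, not base pairs,
   drive chaining and slope, so a perfect 1:1 block has slope ±1 regardless
   of local gene density; bp midpoints are kept for dot plots. Inverted
   blocks are genuine biology (inversions between haplotypes) and are
   retained as colinear — the slope filter, not orientation, decides
   removal.
3. **Divergence.** Each surviving pair is codon-aligned (global protein
   alignment back-translated to codons; columns with a gap, ambiguous base
   or stop in either sequence are dropped) and scored with the
   Nei–Gojobori estimator: per-position synonymous-site fractions with
   changes to stop codons excluded from the denominator, observed
   differences averaged equally over all minimal substitution pathways that
   avoid stop codons, and the Jukes–Cantor correction
   `d = -(3/4) log(1 - 4p/3)`. A proportion at or above 3/4 cannot be
   corrected; such pairs are flagged saturated and removed here — a pair
   whose Ks cannot be estimated cannot pass a Ks filter — and counted
   separately. In the rare case that every substitution pathway between two
   codons passes through a stop, the pair contributes through its remaining
   positions, each classified by its direct single-base change averaged over
   the two sense contexts.
4. **Ks outlier layer.** One of two rules, applied once (no iterative
   re-estimation) to the Ks values of the pairs still alive:
   - *3σ rule* (`method = "sigma"`): flag `Ks < μ − kσ` or `Ks > μ + kσ`,
     with the sample mean and n−1 standard deviation and `k = 3` by
     default. Suits genomes whose allelic Ks is near-normal.
   - *Tukey fences* (`method = "tukey"`): quartiles by linear interpolation
     at rank `1 + (n−1)p` (the common default convention — the rule is
     sensitive to the quantile convention, so it is fixed and documented),
     `IQR = Q3 − Q1`, flag values strictly outside
     `[Q1 − m·IQR, Q3 + m·IQR]` with `m = i` (inner fence, default
     `i = 1.5`) or `m = 2i` (outer). Smaller `i` is stricter; retention is
     monotone in `i`, which the tests check by set inclusion. On a normal
     sample the `i = 1.5` inner fences sit at about ±2.70σ, so Tukey flags
     a superset of what the 3σ rule flags.
   Degenerate inputs are defined rather than errors: σ = 0 flags nothing;
   IQR = 0 flags exactly the values different from Q1.
5. **Slope layer.** The same outlier rule, with the same parameters, is
   applied to the vector of block slopes; all surviving anchors of a
   flagged block are rejected. With fewer blocks than the rule needs
   (2 for sigma, 4 for Tukey) nothing is removed and a warning is issued.

The default order runs the Ks mask before the slope filter; the opposite
order is available (`slope_before_ks = TRUE`) because the two layers are
separable and either reading of "statistical filtering" is defensible. The
Ks mask is computed over colinear, non-saturated pairs only — the population
of candidates still alive — not over all RBH pairs, so upstream junk does
not distort μ, σ or the quartiles. Ka is estimated and reported but never
filtered on: filtering is by synonymous divergence and position only.

## ASE classification

For each allele pair and condition, the two alleles are two count groups
over the condition's replicates (at least 3 by default). Counts are
normalized by median-of-ratios size factors computed over the full matrix.
The per-pair test is a negative-binomial Wald test: method-of-moments
dispersion pooled across the two groups (floored at 10⁻⁸), a log2 fold
change stabilized with a 0.5 pseudocount, and the Wald statistic referred to
a **t distribution with r_a + r_b − 2 degrees of freedom**. The t reference
is deliberate: with dispersion estimated from three replicates per group, a
normal reference rejects far too often (measured ≈ 11% at nominal 5% in a
null simulation), while the small-sample t reference calibrates to ≈ 4–5%.
Numerical agreement with DESeq2 is not claimed; the package owns this
computation, and DESeq2's size factors serve only as an independent
cross-check in the test suite. P-values are Benjamini–Hochberg adjusted
across all pairs within one condition.

Each pair in each condition lands in exactly one of five categories:

| category | rule |
|---|---|
| `No_expression` | neither allele has a single read in any replicate |
| `Diff00` | adjusted p > 0.05, or pair untestable |
| `Diff0` | adjusted p ≤ 0.05 and \|FC\| ≤ 2 |
| `Diff2` | adjusted p ≤ 0.05 and 2 < \|FC\| < 8 |
| `Diff8` | adjusted p ≤ 0.05 and \|FC\| ≥ 8 |

\|FC\| is the linear fold-change magnitude `max(FC, 1/FC) = 2^|log2FC|`, so
the cuts at 2 and 8 correspond to |log2FC| of 1 and 3; the boundary values
belong to `Diff0` and `Diff8` respectively. The linear reading is the one
that makes a threshold of 8 meaningful. Classification is per condition by
default; an aggregation mode (classify on the minimum adjusted p across
conditions) is available but non-default. `No_expression` uses the strict
all-raw-counts-zero rule because no principled TPM threshold presents
itself; the threshold is configurable through the expression summaries.

Summaries mirror the standard ASE figures: per-category counts, boxplots of
Ka, Ks and Ka/Ks for Diff0/Diff2/Diff8 with pairwise rank-sum tests, the
absolute TPM gap per category, and per-chromosome-pair counts of which
haplotype carries the higher-expressed allele with a two-sided sign test.

## The simulator: what it emulates, and what it does not

`simulate_diploid()` builds the truth-labelled test bed every stage is
validated on. Haplotype A genes are random sense-codon sequences (ATG
start, no internal stops, single-exon — adequate because the pipeline
consumes spliced CDS). Haplotype B derives from A by codon-aware mutation:
per-gene target Ks drawn from Normal(0.03, 0.01) — divergence typical of a
heterozygous outcrossing plant — with Ka = 0.3·Ks (purifying selection).
Mutation counts are allocated as expected counts under the
Jukes–Cantor-inverted target (weighted sampling of codons without
replacement) rather than independent per-codon draws; per-codon Bernoulli
noise would broaden and right-skew the realized Ks distribution, and the
filters are designed around a near-normal allelic Ks. The realized
distribution is validated by the package's own estimator: mean within 20%
of target, |skew| < 0.5 at 1000 genes.

Paralog decoys reproduce the failure mode the filters exist for: for each
of 100 donor genes (default), the *true haplotype-B allele is deleted* and
replaced by a heavily mutated duplicate of the donor (Ks uniform in
[0.3, 1]) inserted at a random position on the corresponding B chromosome.
Because the true allele is gone, RBH genuinely mis-pairs donor and decoy —
an easy decoy that merely accompanies the true allele would be rejected by
RBH already and would test nothing. One 50-gene inversion (default) checks
that inverted blocks are chained and retained. Expression is negative
binomial (dispersion 0.1, three replicates, base mean 100) with a
configurable fraction of allelic pairs given a ±4 log2 shift on allele A.

What the simulator does not model — hence what passing tests do *not* show
about real data: tandem arrays with more than two copies, transposable
elements and intergenic sequence, annotation errors (split/merged models),
isoform variation, GC-content and codon-usage bias, read-level noise
(counts are drawn, not aligned), and library-composition effects beyond
global size factors. Real Ks distributions can also be multimodal in
recent polyploids, where the 3σ rule's normality assumption fails — that is
precisely why the tunable Tukey rule is provided.

## Numerical choices and problem sizes

- Quantiles: type-7 interpolation (`1 + (n−1)p`), fixed so worked examples
  are exact.
- NG86 site and pathway tables are precomputed once per session for all 64
  codons; estimates are table lookups, and the test suite compares every
  sense-codon pair against an independent brute-force enumerator at 10⁻⁹.
- Ties in RBH are resolved by documented deterministic keys; chain
  extraction is greedy longest-first, so output is invariant to input
  order.
- Identical seeds give byte-identical TSV outputs.
- Reference validation scales: the recovery run uses 2 chromosome pairs ×
  1000 genes with 100 decoys (precision ≥ 0.99, recall ≥ 0.95 against
  truth); mask calibration uses 10 × 100,000 normal draws; ASE calibration
  uses 1000 null pairs and 500 pairs at 20% ASE. These sizes give stable
  rates while keeping a full validation run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_diploid(sim_config(), seed = 1)
res <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map)
glance(res)        # stage counts: RBH -> colinear -> Ks -> slope -> alleles
autoplot(res)      # colinearity dot plot coloured by status

cnt <- simulate_counts(sim, seed = 1)
alleles <- tidy(res) |> filter(status == "allele")
ase <- test_allele_pairs(cnt$counts, cnt$design, alleles)
glance(ase)        # five-category counts per condition
```

## Known limitations

- RBH is strictly one-to-one; recent tandem duplicates of a still-present
  allele are left unpaired rather than resolved.
- The NG86 estimator ignores transition/transversion and codon-usage bias;
  Ks for the same data will differ (slightly, at allelic distances) from
  maximum-likelihood estimators.
- The NB Wald test is a minimal estimator without dispersion shrinkage;
  at very low counts it is conservative.
- The slope filter assumes at least a handful of blocks per run; genomes
  reduced to one or two giant blocks fall back to Ks filtering alone (with
  a warning).
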