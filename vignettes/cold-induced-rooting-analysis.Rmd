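---
title: "Methods: hormone-set enrichment and co-expression analysis of cold-induced adventitious rooting"
author: "coldroots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hormone-set enrichment and co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldroots)
```

## The experimental design the package models

Alpine perennials such as *Arabis alpina* form adventitious roots (ARs) on
specific stem internodes after prolonged cold. The design this package
analyses is a vernalization time course: plants grown in long days (LD) are
moved to 4&nbsp;°C for 4–21 weeks, and stem internodes are sampled at the end
of cold (`0w`, `4w`, `8w`, `12w`, `16w`, `21w`) and five days after return
to long days (`12w+5dLD`, `16w+5dLD`, `21w+5dLD`), with three biological
replicates of pooled stems per condition. Two data types come out of such an
experiment:

* a gene-level RNA-seq count matrix (~30,000 genes × 27 samples), and
* per-plant scoring tables of AR presence (never number) on each internode
  of the main stem, internodes numbered 1-based from the bottom.

The package implements the downstream analysis of both: differential
expression with a fold-change + adjusted-p filter, a hormone-responsive
gene-set enrichment index with a Monte Carlo overlap test, co-expression
gene selection and clustering with Cluster 3.0 compatible output, and
phenotype percentage summaries — plus a seeded generator producing
synthetic datasets with known ground truth so every stage is testable
without access to any particular deposited dataset.

## Differential expression

DE calling is a deliberately simple negative-binomial Wald test, a
documented stand-in rather than a re-implementation of any full NB-GLM
framework; externally produced DE tables can be substituted via
`import_de()` at any point.

For a contrast of condition $a$ against reference $b$:

1. **Normalization.** Median-of-ratios size factors $s_j$ (reference =
   per-gene geometric mean over samples, restricted to genes with no zero
   count), rescaled to geometric mean 1. If no gene is positive everywhere
   the code falls back to total-count factors with a warning.
2. **Fold change.** $\widehat{q}_{ga}$, $\widehat{q}_{gb}$ are group means
   of normalized counts and
   $\mathrm{LFC}_g = \log_2\frac{\widehat{q}_{ga} + 0.5}{\widehat{q}_{gb} + 0.5}$.
   The 0.5 pseudocount stabilizes genes near zero; fold changes are raw
   (no shrinkage estimator).
3. **Dispersion.** Per-gene method-of-moments estimate of $\alpha$ in
   $\mathrm{Var} = \mu + \alpha\mu^2$, pooled across the two groups,
   floored at $10^{-8}$, then averaged (weight 0.5 each) with the mean
   dispersion of the gene's expression bin (20 bins by rank of base mean,
   at least 50 genes per bin). The equal-weight average is the simplest
   rule that tames the very noisy 3-vs-3 gene-wise estimates without
   letting a global trend swamp genuinely high-dispersion genes.
4. **Test.** Wald statistic $\mathrm{LFC}/\mathrm{SE}$ with the
   delta-method SE
   $\mathrm{Var}(\widehat q) = n^{-2}\sum_j (q/s_j + \alpha q^2)$,
   two-sided p from the normal approximation, Benjamini–Hochberg
   adjustment over the tested genes. Genes with zero counts in every
   sample of the contrast are excluded from testing and from the BH
   family.
5. **DEG filter.** `up` iff $\mathrm{LFC} > 1$ **and** $p_{adj} < 0.05$
   (both strict: "more than 2-fold", "below 0.05"); `down` symmetric;
   otherwise `ns`.

On synthetic truth (10,000 genes, 10% DE at $|\mathrm{LFC}| = 2$, 3 vs 3)
this stand-in keeps the realized FDR under 10% with sensitivity above
0.5 — the validation the test suite performs; no claim is made that it
reproduces the output of any specific external tool.

## The hormone-set enrichment index and its Monte Carlo test

The core statistic asks whether genes responding to a hormone are
over-represented among the up- (or down-) regulated genes of a contrast.
With universe size $M$ (the full gene catalogue), hormone-set size $K$
(inside the universe), $n$ directional DEGs and overlap $k$:

$$E = \frac{k/K}{n/M}$$

$E$ is the ratio of the set's share among directional DEGs to its
genome-wide share; $E > 1$ means enrichment, $E < 1$ depletion. It is
computed as $kM/(Kn)$, one final division of exact integer products. When
$K = 0$ or $n = 0$ the index is undefined and is reported as `NA` with a
reason — never as 0, which would fake perfect depletion.

Significance is assessed by Monte Carlo: draw $n$ genes from the universe
uniformly **without replacement**, 10,000 times by default; the p-value is
the fraction of draws whose intersection with the set is **equal to or
higher** than $k$, reported exactly as $\mathrm{count}/n_{perm}$ (an
add-one correction is available behind a flag but off by default, matching
the plain-ratio convention). Sampling without replacement makes the null
exactly hypergeometric, which the test suite exploits: one $10^5$-draw
null distribution per $(M, K, n)$ instance is compared against
`phyper` upper tails at every achievable $k$, within three binomial
standard errors.

Design choices, fixed once:

* **Universe.** All genes of the annotation (resampling is from the whole
  genome), configurable to expressed-genes-only.
* **Minimum set size 8.** Sets with fewer than 8 effective members are
  reported with an explicit `excluded` flag and never tested — the
  smallest threshold consistent with excluding a 7-gene set while testing
  the rest.
* **One-sided.** Only enrichment is tested; depletion is visible as
  $E < 1$ but gets no p-value.
* **No cross-set correction by default.** Records are starred at raw
  $p < 0.05$; `adjust = TRUE` adds a BH column across tested records.
* **Determinism.** `enrich_all()` derives a per-record sub-seed from the
  master seed and the record key (set, direction, contrast), so results
  are bit-identical under a fixed seed and independent of record order.

### Calibration and the discreteness of the overlap null

Because the overlap count is integer-valued, $P(p_{mc} < 0.05)$ under the
null is at most, and generically strictly below, 0.05: the achievable tail
probabilities jump in steps of the hypergeometric pmf. At the simulation
sizes used here (universe 2,000; sets of 200; ~100 DEGs per direction) the
exact rejection rate, computable in closed form by mixing the binomial
Monte Carlo noise over the hypergeometric overlap distribution, is about
0.036–0.044. The calibration experiment in the test suite therefore runs
1,000 null datasets (enrichment factors 1.0 everywhere, DEG lists from the
generator's truth so that only the overlap test is under the microscope,
1,000 permutations per record) and checks the observed rejection fraction
against $0.05 \pm 3\sqrt{0.05 \cdot 0.95 / 1000}$, the band implied by
dataset-level sampling error; conservatism from discreteness keeps the
rate below 0.05, and anti-conservatism would push it out of the band.

## Synthetic-data generator

`simulate_dataset()` draws, from a single seed with no hidden state:

* per-gene baseline means $\sim$ lognormal(meanlog 4, sdlog 1.5) — median
  ~55 counts with a realistic dynamic range;
* per-gene NB dispersions $\sim$ lognormal(log 0.05, 0.5), the typical
  magnitude for replicated bulk RNA-seq;
* per-contrast DEG labels: a fraction `deg_fraction` (default 0.1) of
  genes per non-reference condition, signs balanced by `lfc_up_share`,
  magnitudes $|N(2, 0.5)|$ on the log2 scale;
* per-sample library-size factors $\sim$ lognormal(0, 0.1), so the
  normalization step is non-trivially exercised;
* counts $\sim \mathrm{NB}(\mu = \mathrm{baseline} \cdot 2^{\mathrm{LFC}}
  \cdot s_j,\ \alpha_g)$.

Hormone-set membership (eight "response to *hormone*" GO terms, default
size 200 — the order of magnitude of such terms in crucifer annotations)
is sampled **uniformly** whenever the planted factor is 1, so the
enrichment null is exact by construction. A planted factor $f$ for a
(set, direction, contrast) fixes the overlap at
$\mathrm{round}(f \cdot nK/M)$ members drawn from that direction's true
DEGs, with the remainder drawn outside all planted strata; infeasible
requests (more members needed than the set or stratum holds) raise an
error naming the binding constraint instead of silently truncating. The
default scale of 2,000 genes keeps the full pipeline fast; the full-size
catalogue (30,510 genes) is supported for profiling.

What the generator does **not** emulate: batch effects, time-course
autocorrelation beyond condition-wise means, gene–gene correlation, and
annotation structure (GO propagation). Passing tests on synthetic data
therefore validate the statistical machinery, not robustness to those
real-data features.

## Co-expression selection and clustering

Counts are normalized, transformed to $\log_2(\text{normalized} + 1)$ per
sample and averaged over replicates per condition, columns ordered along
the time course. Gene selection applies two conjunctive criteria: log2
fold change (highest vs lowest condition mean) $\ge 2$, and max − min of
the values entering clustering $\ge 3$, both inclusive. On the log2 scale
both reduce to the row spread, so the effective default rule is
max − min $\ge 3$; both knobs are kept, and `range_scale = "linear"`
applies the second criterion to de-logged values instead, because the
scale of the spread criterion is a genuine interpretation choice. The
baseline of the fold-change criterion (max-vs-min rather than vs the
pre-cold condition) is likewise a documented interpretation.

Clustering follows the common Cluster 3.0 configuration: per-gene
centering to mean 0 and scaling to unit sum of squares, Pearson
correlation similarity, average-linkage agglomeration (tree heights are
$1 - r$), flat clusters by cutting where the join similarity drops below
0.7 (or at a requested `k`). Genes are processed in lexicographic id
order, making the tree invariant to input order; zero-variance genes,
whose correlation is undefined, are excluded with a warning and listed in
the model object. The tree is validated against a brute-force $O(n^3)$
agglomeration oracle in the test suite. No attempt is made to reproduce
any particular published sub-cluster count: that partition depends on
unstated tool parameters and on the original data.

`write_cdt_gtr()` emits the CDT/GTR pair TreeView consumes, all floats at
a fixed precision (default 6 decimals) so a write–read–write cycle is
byte-identical.

## Phenotype scoring

Scoring tables are long-format records (plant, treatment, organ,
internode, presence ∈ {0,1}). `percent_plants_with_ar()` reports
$100 \cdot$ (#plants with ≥ 1 rooted internode)/(#plants) per treatment;
`percent_per_internode()` reports the per-position percentages
bottom-to-top. Conventions: internodes never scored are omitted (missing,
not 0%); plants without a score at an internode leave that internode's
denominator; percentages are kept at full precision internally and
printed at one decimal (`format_percent()`), the granularity of a
nine-plant cohort where, e.g., 5/9 prints as 55.6. Two invariants tested
throughout: values lie on the lattice $\{0, 100/n, \dots, 100\}$, and the
plant-level percentage dominates every per-internode percentage.

## Problem sizes and numerical choices

The validation suite uses 2,000-gene datasets for end-to-end runs, 10,000
genes for the DE operating characteristics, $10^5$ permutations for the
hypergeometric comparison and 1,000 datasets × 1,000 permutations for
null calibration — sizes chosen so the whole suite completes in minutes
while keeping Monte Carlo error well inside the asserted tolerances.
Other numerical choices collected in one place: dispersion floor
$10^{-8}$; fold-change pseudocount 0.5; serialization precision 6
decimals; correlation cut 0.7; ties in hierarchical merges broken by
lexicographic gene order; `p_mc` granularity $1/n_{perm}$.

## Known limitations

* The Wald normal approximation is optimistic at 2 replicates; with a
  single replicate per group p-values are flagged unreliable.
* The enrichment test treats gene sets as fixed and genes as
  exchangeable; co-expression within a hormone set (present in real data)
  would make the null overlap overdispersed relative to hypergeometric.
* The generator's independence assumptions (above) mean its FDR/power
  numbers are best-case.
* Cluster count at the 0.7 cut is sensitive to the noise level; the
  planted-partition recovery test uses well-separated templates.
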