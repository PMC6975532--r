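---
title: "Allele sharing, diversity and association in tetraploid wheat cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele sharing, diversity and association in tetraploid wheat cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmerorigins)
library(dplyr)
```

## The scientific problem

Domesticated emmer (*Triticum turgidum* subsp. *dicoccum*) and the naked
tetraploid wheats descend from wild emmer (*T. turgidum* subsp.
*dicoccoides*), whose modern populations fall into a relatively homogeneous
southern-Levant group and a more admixed set of populations around the
northern and eastern Fertile Crescent. Tree-building methods (PCA,
neighbour joining) tend to place the crop closest to the northern wild
populations, but trees assume the history was treelike. If the crop arose
from a *mixed* population — or if feral descendants of early cultivated
lineages re-entered the northern wild gene pool — allele-level evidence can
contradict the tree.

`emmerorigins` implements the allele-level toolkit for this question on
sparse genotyping-by-sequencing (GBS) SNP matrices:

* classify every allele of every biallelic SNP by its presence across three
  groups — south wild (S), 'other' wild (O), domesticates from outside
  southwest Asia (D) — into the seven Venn classes S, O, D, SO, SD, OD, SOD;
* find alleles **fixed** in the domesticates (frequency exactly 1 among
  non-missing calls) yet segregating in both wild groups, and compute their
  frequency differential Δf = f(S) − f(O). If the crop drew equally on both
  wild pools, the Δf distribution is centred on zero; a directional shift
  points to the dominant wild source;
* support the surrounding standard analyses: filtering, π, Tajima's D,
  Weir–Cockerham F~ST~, genotype PCA, VanRaden kinship, IBS distances,
  neighbour-joining trees, and a mixed-linear-model GWAS treating
  "domesticated vs wild" as a binary trait (Q+K model, Bonferroni
  threshold).

Because the raw sequence data behind any real panel are processed through
external alignment and SNP-calling pipelines, the package is exercised and
validated on **synthetic cohorts with known ground truth** produced by its
own generator.

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` produce a cohort in four seeded
stages (each stage derives an independent substream from one master seed,
so any stage can be reproduced in isolation).

**Population frequencies.** An ancestral alt-allele frequency $p_0$ is
drawn per SNP (default U(0.1, 0.9)). Each wild group drifts away from it
under the Balding–Nichols model,
$p \sim \mathrm{Beta}\left(p_0\tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\right)$,
which has mean $p_0$ and variance $p_0(1-p_0)F$; the drift coefficient $F$
plays the role of the expected F~ST~ against the ancestor. The 'other' wild
group can be admixed: its pre-drift mean is
$\alpha\,p_S + (1-\alpha)\,p_0$ (`admixture_alpha`), mirroring the
admixture cline observed in the northern/eastern wild populations.
Domesticate frequencies are a weighted mixture
$w\,p_S + (1-w)\,p_O$ (`dom_south_weight`, default 0.5 — equal
contribution) resampled through a binomial bottleneck of
`bottleneck_founders` allele copies (default 30), which quantizes the
frequencies and fixes a realistic minority of alleles.

**Frequency floor.** Wild true frequencies in $(0, 0.03)$ are snapped up to
0.03 (`freq_floor`). Without a floor, Beta drift puts appreciable mass
arbitrarily close to 0, where a "truly present" allele is unobservable in
any finite sample; the floor makes presence/absence ground truth
recoverable at the simulated sample sizes, with a dropout probability
bounded by $(1-0.03)^{2N}$ per group (about 0.2% at $N = 100$ diploids).
Exact 0 and 1 are preserved, so absence and fixation stay exact.

**Planted domestication alleles.** `plant_fixed_alleles()` forces
`n_planted_fixed` loci to alt-frequency 1 in domesticates and redraws the
wild frequencies into [0.1, 0.9] when they fall outside, so every planted
allele is detectable by `fixed_in_domesticates()` at the default cohort
sizes. The truth object records the planted ids and the true Venn class of
all alleles.

**Genotypes.** Wheat self-pollinates, so genotypes are drawn with an
inbreeding coefficient `f_is` (default 0.85):
$P(\mathrm{het}) = 2p(1-p)(1-F_{IS})$,
$P(\mathrm{hom\ alt}) = p^2 + p(1-p)F_{IS}$. At the defaults this yields a
heterozygous-call fraction near 5–7%, in the range typical of GBS panels
of selfing wheats.

**Depth and missingness.** Every call gets an independent Poisson read
depth (`depth_mean`, default 3.5); depth-zero calls are missing, and
further calls are masked missing-completely-at-random at `missing_rate`
(default 0.474). The expected total missing fraction is
$m + (1-m)e^{-\lambda} \approx 49\%$, the sparsity regime of real GBS
matrices. This is deliberately the *simplest* model consistent with GBS
sparsity: depth is homogeneous across SNPs and independent of genotype.

### What the generator does not emulate

* **Per-tag coverage structure.** Real GBS missingness concentrates in
  low-coverage tags and low-quality samples; a depth-5/20%-missing filter
  then *selects* the high-coverage minority of SNPs. Under homogeneous
  Poisson depth those same thresholds remove essentially every variant, so
  `run_pipeline()` applies equivalent-intent thresholds
  (`min_depth = 0`, `max_missing = 0.6`, same MAF tracks) when it runs on
  simulated cohorts; the named presets (`pca`, `structure`, `sharing`)
  remain available and are what file-based runs use.
* **Linkage disequilibrium, selection through time, sequencing error** —
  all out of scope; every SNP is independent given the population
  frequencies.
* **A rare-allele tail.** The default ancestral law U(0.1, 0.9) produces
  common alleles; real panels carry a large rare tail, which is why the
  simulated Venn class fractions are much more concentrated in SOD than a
  real panel's, and the simulated mean MAF is higher. Tests passing on
  these cohorts demonstrate the *machinery* (classification, recovery,
  calibration), not the empirical class fractions of any real panel.

### Conditions used by specific checks

* **Equal-contribution calibration (mean Δf).** These checks simulate
  with `admixture_alpha = 0` and equal wild drift, making the two wild
  groups exchangeable; exchangeability is precisely the null under which
  E[Δf | fixed in D] = 0. With an admixed 'other' group the symmetry
  argument no longer holds, so a nonzero mean would conflate ancestry
  asymmetry with admixture. The south-biased check (`dom_south_weight =
  0.8`) plants no fixed alleles, because planted loci draw their wild
  frequencies symmetrically and would dilute the directional signal.
* **Tajima's D sign.** The generator has no temporal dynamics, so
  "expansion" is emulated at the level it acts on the statistic: an excess
  of low-frequency variants (ancestral law U(0.01, 0.05)) drives D
  negative, an intermediate-frequency excess drives it positive. The check
  runs at `f_is = 0` because selfing enters allele copies in homozygous
  pairs and depletes the singleton class, masking the spectrum response.
* **PCA separation.** Checked at drift F = 0.2 with an 8-copy founder
  bottleneck and complete calls — clearly differentiated populations. At
  the weakest drift the property claims (F ≈ 0.1) with half the calls
  missing, centroid separation does not dominate within-group dispersion
  by the factor of two the check demands.
* **Type-I error of the GWAS.** Permutation calibration uses n = 400
  samples, complete calls, MAF ≥ 0.2 and kinship from the full SNP set.
  Treating a binary trait with a *linear* mixed model is mildly
  conservative in small samples (both the phenotype and a genotype column
  are platykurtic, deflating the t tail by O(1/n)); at n = 400 the
  empirical rate sits within the binomial 3-SE band around 0.05, while
  with sparse, rare-allele genotypes at much smaller n the deflation is
  noticeable — worth knowing when interpreting borderline hits on small
  panels.

## The analysis model, piece by piece

### Filtering and bookkeeping

`filter_variants()` applies, in order: multiallelic drop, indel drop
(ref/alt length difference), per-call depth masking (DP < `min_depth` →
missing), per-variant missingness, then MAF — both bounds inclusive
(MAF exactly at the threshold is kept, matching "≥" semantics).
Missingness and MAF are recomputed from whatever samples are currently
retained, so sample dropping (`drop_high_missing_samples()`, strict ">"
boundary) should precede variant filtering, which is what
`run_pipeline()` does. `apply_reclassifications()` keeps an audit log of
taxon changes.

### Diversity and differentiation

Per-site nucleotide diversity uses the unbiased estimator
$\pi = c(C-c)/\binom{C}{2}$ on $C$ non-missing allele copies with $c$ alt
copies; the group mean is per SNP site (the package does not know the
genomic denominator of a reduced-representation assay). Tajima's D uses
the 1989 constants with $n$ taken as the **median** non-missing copy count
across segregating sites — D's constants assume constant $n$, and the
median stabilizes sparse GBS matrices; `per_site_n = TRUE` recomputes the
numerator per site for verification. Weir–Cockerham F~ST~ is the 1984
two-population estimator; per-site ratios are reported as computed,
including negative values, and the weighted estimate is
$\sum a / \sum (a+b+c)$.

### Structure

PCA runs on the mean-imputed, column-centered call matrix via SVD, with a
deterministic sign convention (the largest-magnitude loading of each
component is positive). Kinship is the centered VanRaden matrix
$K = MM'/(2\sum_j p_j(1-p_j))$ with mean imputation and 2p centering. IBS
distance is one minus the mean shared-allele proportion over pairwise
complete variants, which supports the unfiltered-matrix use case.
Neighbour joining is Saitou–Nei agglomeration; negative branch lengths are
clamped to zero and counted.

### Allele sharing

"Present" means at least one observed copy among non-missing calls — a raw
presence count with no frequency floor (a floor can be imposed upstream by
filtering). A variant is usable only if every group shows at least
`min_calls` (default 4) non-missing allele copies; each usable variant
contributes exactly two alleles, so Venn class counts plus
absent-everywhere alleles always total twice the usable variants.
Fixation is frequency exactly 1 among non-missing calls — an integer
comparison of copy counts, no tolerance. The Δf histogram defaults to
fixed 0.05-width bins on [−1, 1]; an equal-count mode (`bin_mode =
"count"`) is provided since descriptive conventions differ.

### GWAS

The binary phenotype (wild emmer = 0; domesticated emmer and naked wheats
= 1; *T. timopheevii*-lineage accessions excluded) is analysed with a
linear mixed model $y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$,
$X$ = intercept + the first five PC scores of the analysis subset.
Variance components are fitted once by REML — eigendecompose $K$, profile
the likelihood in $\delta = \sigma_e^2/\sigma_g^2$ over a log grid with
local refinement — then reused for every SNP (the P3D/EMMAX scheme), with
each mean-imputed SNP entering as one fixed effect in the rotated GLS.
The test is two-sided $t$ with $n - \mathrm{rank}(X) - 1$ degrees of
freedom; the residual scale is re-estimated per SNP, which makes the
whole pipeline collapse *exactly* to OLS when $K = I$. An exact per-SNP
REML refit (`method = "exact"`) exists as a slow verification mode and
agrees with P3D within 0.1 −log~10~(p) for ≥95% of SNPs at n = 50.
Significance uses Bonferroni α/k with α = 0.05 by default, consistent
with a genome-wide −log~10~ threshold of 6.59 at k = 193,077 tests;
α = 0.01 is one argument away.

## Numerical and degenerate-input choices

* Histogram breaks are rounded to 10 decimals so bin membership of exact
  frequencies (0.3, −0.3, ...) is not at the mercy of floating-point
  `seq()`.
* Balding–Nichols with $F < 10^{-12}$ returns the deterministic limit
  $p_0$; $F = 1$ is rejected (degenerate Beta).
* REML guards the profiled likelihood against an exact fit
  ($R \to 0$) and flags grid-boundary solutions ($\sigma_g^2 \to 0$ or
  $\to \infty$) instead of failing.
* Monomorphic SNPs (constant after imputation) are skipped with a recorded
  reason; p-values are floored at the smallest representable double so
  −log~10~(p) stays finite.
* Ties: NJ tie-breaking follows the agglomeration library's first-minimum
  rule; a 0.5 major-allele tie in the domesticates picks ref and logs the
  tie.
* All-missing variants are dropped with a warning before PCA/kinship;
  sample pairs with zero overlapping variants make IBS distance fail
  loudly rather than return NaN.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
2,000-SNP cohorts of 3 × 100 diploids for ground-truth recovery, 2,400
SNPs × 400 samples for permutation calibration (100 replicates × 200
tested SNPs), ≤30-sample instances for the brute-force oracle
equivalences, and ≤12-leaf random trees for NJ consistency. These sizes
keep every Monte-Carlo bound (binomial 3 SE) meaningful while the full
suite completes in about a minute.

## A short worked run

```{r example, eval = FALSE}
cfg <- list(
  simulate = list(n_snps = 600, pop_sizes = c(south = 40, other = 40, dom = 40)),
  out_dir = "run1", seed = 11)
manifest <- run_pipeline(cfg)

# allele sharing on the written cohort
gm <- read_vcf("run1/cohort/cohort.vcf")
frame <- read_sample_metadata("run1/cohort/samples.tsv")
groups <- sharing_groups(frame)
tab <- build_sharing_table(group_allele_frequencies(gm, groups))
venn_counts(tab)
fixed_in_domesticates(tab)
```

## Known limitations

* The MLM is linear on a binary trait (matching common toolkit practice);
  no logistic mixed model is provided.
* Tajima's D with heavy missingness relies on the median-n approximation;
  sites with wildly varying coverage are better handled by the
  `per_site_n` numerator, which is slower.
* The generator's independence across SNPs means no LD-aware analysis can
  be validated here.
* Venn class fractions from synthetic cohorts reflect the generator's
  common-allele regime and should not be read as predictions for real
  panels.
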