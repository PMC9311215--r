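---
title: "Detecting candidate loci for local adaptation in structured populations"
author: "adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting candidate loci for local adaptation in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Species distributed along environmental gradients can adapt locally: a
minority of loci shift allele frequencies with the environment while the
rest of the genome reflects drift, gene flow and shared history. Two
families of genome scans try to find such loci. Genome scans for outliers
(GSO) flag loci whose differentiation among populations exceeds the neutral
expectation; genotype-environment association (GEA) tests correlate allele
frequencies directly with environmental variables. Both inflate badly when
populations are strongly structured — deeply diverged clades produce large
numbers of highly differentiated loci for purely neutral reasons, and any
variable that co-varies with the clade axis (latitude above all) will
"associate" with them.

`adaptscan` implements a conservative detection pipeline for this setting:

1. quality filtering of a diploid SNP matrix,
2. demographic description (diversity, differentiation, spectra, relative
   migration),
3. a PCA-based Mahalanobis outlier scan with genomic-inflation correction,
4. RDA-based genotype-environment association with per locus x variable
   q-values,
5. **geometric-mean combination** of q-values across methods, and
6. a **random-environment null control** that demotes loci prone to
   spurious association.

Every stage is testable without external data through a hierarchical
Balding-Nichols simulator that generates clades, populations, environmental
gradients, and clinal adaptive loci with known truth labels.

## Data model and filtering

Genotypes are held as an individuals x loci integer matrix of
alternate-allele dosages (0/1/2) with `NA` for missing calls; loci are
unordered de-novo markers, each tagged with the short assembled tag it came
from. Downstream statistics always consult the missingness mask; nothing
imputes silently.

Filters run in a fixed order: individuals above 90% missingness, then loci
above 30% missingness, then one randomly chosen SNP per tag (linked SNPs on
one tag carry almost no independent information), then loci with minor
allele frequency below 0.05. Individual-level filtering runs first so a
nearly empty individual cannot inflate locus missingness; the MAF is
computed on the retained individuals, pooled over populations (a single
global cut-off, the standard practice when no per-population rule is
stated). The order matters and is tested: removing an individual can change
which loci pass the MAF filter.

The MAF filter is not cosmetic for the scan. A near-monomorphic locus
scaled by its binomial standard deviation becomes a sparse spike vector
whose regression scores are strongly non-normal; feeding such loci to the
scan produces exactly the heavy-tailed false positives the filter exists to
prevent.

## Demographic statistics

Diversity and differentiation follow Nei's gene-diversity decomposition:
per-locus observed heterozygosity `Ho` (pooled proportion of heterozygotes
among called individuals), within-population gene diversity
`Hs = mean over populations of 2p(1-p) * n/(n-1)`, total diversity `Ht`
from the unweighted mean of population frequencies, `Fst = (Ht - Hs)/Ht`
and `Fis = 1 - Ho/Hs`. Multi-locus values are ratios of averages, not
averages of ratios — the convention of the standard hierarchical-F
packages, and the one that keeps `Fst = 1` exact under alternate fixation.
Pairwise differentiation uses the Weir-Cockerham (1984) variance
components `a`, `b`, `c` per locus with the multi-locus estimate as the
ratio of summed components; monomorphic loci are excluded and negative
per-locus estimates are reported raw.

Allele-frequency spectra (folded or unfolded, per population, and joint 2D
between clades) use listwise exclusion of loci with missing calls in the
focal population(s), so every retained locus is observed on the same number
of haplotypes. Hypergeometric projection is deliberately not implemented:
the simulator can generate complete data, and projection would add a
modelling assumption the rest of the pipeline never uses.

Directional relative migration follows the pooled-population logic of the
GST method: for each pair a hypothetical pool is formed from the pair's
mean allele frequencies, the GST of each member against the pool measures
how far that member sits from the shared migrant pool, and the island-model
inverse transform `((1/GST) - 1)/4` converts differentiation into a
relative rate into that member. Rates are normalised by the matrix maximum.
GST is floored at `1e-6` so two statistically indistinguishable populations
report the maximal rate 1 instead of an indeterminate ratio of infinities.
The migration-distance comparison is a plain Pearson test over ordered
off-diagonal pairs; matrix entries are not independent, and the plain test
(rather than a Mantel permutation) is kept as the field's reported
convention for this quantity, a documented faithful-to-convention choice.

## The outlier scan

The scan regresses each scaled locus (centred, divided by the binomial
standard deviation `sqrt(2p(1-p))`, missing values mean-imputed on this
scale) on the `k` leading principal axes of the same matrix. Two numerical
choices matter:

* **t-to-normal mapping.** The per-axis regression statistics are
  t-distributed with `n - k - 1` degrees of freedom, not normal. At
  `n = 80` individuals the raw-t tail is enough to produce minimum
  p-values near `1e-6` on 2,000 truly null loci — one to three spurious
  q < 0.05 discoveries per run. Each statistic is therefore mapped to its
  exact normal score, `sign(t) * |qnorm(pt(-|t|, df))|`, after which the
  chi-square reference for the Mahalanobis distance holds and the null
  yields essentially zero spurious discoveries.

* **Tyler's M-estimator of scatter.** The robust covariance of the
  z-vectors is Tyler's M-estimator anchored at the null centre 0. It
  depends on each locus only through the outer product `z z'`, which makes
  the scan exactly invariant to swapping reference and alternate alleles
  at any locus (a flip negates that locus's z-vector), keeps it resistant
  to the outlying loci it is trying to find, and makes it deterministic.
  Estimators that re-estimate location from the point cloud (such as MCD)
  satisfy none of these. Tyler's shape matrix has arbitrary scale; it is
  rescaled to the overall second-moment scale so the genomic inflation
  factor keeps its usual reading of approximately 1 at a well-specified
  null.

The genomic inflation factor is `median(D^2) / median(chi^2_k)` (with even
counts, the median is the mean of the central order statistics); p-values
are the upper chi-square tail of `D^2 / lambda` — upper tail only, as
`D^2` is a squared distance. The number of axes `k` is chosen at the
largest drop in the scree of explained-variance proportions, an automated
stand-in for the visual choice practitioners make; a flat scree (largest
drop below 0.01) falls back to `k = 1` with a warning, and the caller can
always override `k`.

q-values use the Storey-Tibshirani estimator implemented in-package: the
null proportion pi0 is read off a df-3 smoothing spline through
`#{p > lambda} / (m(1 - lambda))` at the largest lambda of a 0.05-0.95
grid; with fewer than 100 p-values or a degenerate estimate it falls back
to pi0 = 1, at which point the q-values coincide with Benjamini-Hochberg
(verified against an independent step-up implementation to 1e-12).

## Genotype-environment association

Environmental variables live at population resolution and are broadcast to
individuals. Preprocessing centres and scales each variable and prunes
collinearity greedily in a configurable priority order (latitude first by
default): a variable is kept iff its squared correlation with every
already-kept variable is at most 0.7 — the threshold is inclusive, so a
pair at exactly 0.7 survives. Missing genotypes are imputed with the modal
genotype within the clade (ties toward the lower dosage code); loci with
zero calls in some population must be removed first, since their apparent
signal is a missingness artefact.

The RDA full model is tested by permutation ANOVA through vegan (the
standard constrained-ordination implementation): pseudo-F with 999
permutations of individuals' environment rows, minimum attainable p of
0.001. Note the permutation is at individual level while environments are
constant within populations, so with strong within-population genetic
correlation the test inherits a degree of pseudo-replication; this mirrors
the conventional usage it reproduces.

Per locus x variable attribution from a multivariate RDA has no single
canonical definition, so the package documents its choice: the raw score
of locus l for variable v is the sum over retained constrained axes
(all axes with positive constrained variance) of the locus loading —
axis weighted by its singular value — times the correlation between v and
the axis site scores. This reduces exactly to the simple locus-variable
correlation when one variable is fitted alone, which anchors the
definition. Scores are standardised per variable to z, converted to
two-tailed normal p-values and per-variable q-values. The constrained
decomposition itself is cross-checked against `vegan::rda` in the tests.

The random-variable null control draws 100 standard-normal variables at
population level (the resolution of the real variables), never prunes
them, and runs each in its own univariate RDA — a joint model with 100
predictors would exceed the rank of any realistic design, and univariate
runs mirror the univariate Bayesian GEA logic. A locus significantly
associated (combined q < 0.05) with five or more of the 100 random
variables is demoted to low confidence: if a locus associates with 5% of
pure noise variables, its association with a real variable is not
trustworthy. The rule applies per locus, and the 4-vs-5 boundary is
tested explicitly.

Since many real variables are deliberately collinear with latitude, the
q-values of the anchor and of every variable with r^2 > 0.7 against it
can be combined by geometric mean into a single per-locus "latitude in the
broad sense" value.

## Geometric-mean combination

Two methods' q-values combine as `sqrt(q_a * q_b)` — the arithmetic mean
on the log scale. Because `min(q_a, q_b) <= sqrt(q_a q_b) <= max(q_a, q_b)`,
the combined significant set always sits between the intersection (both
methods agree; low power) and the union (either method; high false-positive
rate). A locus with q = 0.001 in one method and 0.2 in the other combines
to about 0.0141, significant at 0.05: strong support from one method can
outweigh absence of support from the other. Loci missing from one method's
output receive q = 1 there (with a warning) rather than being dropped, so
only genuinely strong support from the other method can rescue them. Exact
zeros combine to zero through the direct product formula; the log-domain
path used in broad-sense combination floors q at 1e-300 for stability.

## The simulator

`simulate_snp_data()` generates the study conditions the pipeline assumes:
populations evenly spaced on a latitude axis, clades occupying contiguous
blocks; neutral loci drift hierarchically (ancestral frequency
`p0 ~ U(0.05, 0.95)`, clade frequency Beta around p0 with parameter
`f_group`, population frequency Beta around the clade with `f_pop`);
adaptive loci instead follow `logit(p_pop) = logit(p0) + b * latitude`
plus population-level Beta noise; genotypes are Binomial(2, p) per
individual; environmental variables are standardised mixtures
`rho * latitude + sqrt(1 - rho^2) * noise`.

Defaults describe a deep-clade regime: 3 clades x 3 populations x 10
diploids, 2,000 loci, `f_group = 0.75`, `f_pop = 0.15` (composite expected
Fst about 0.79), 6 environmental variables at collinearity 0.8, 2% adaptive
loci at logit slope 2, 2% missingness. Field designs of this kind sample
5-20 individuals per population; `inds_per_pop` accepts a range.

`expected_fst()` returns the composite closed form
`1 - (1 - f_group)(1 - f_pop)`. This is exact only as the number of clades
grows: with G clades the pooled total diversity loses a between-clade
variance term of order `f_group / G`, so the 3-clade default realises a
pooled Fst near 0.67 rather than 0.79. The simulation-versus-formula test
therefore uses a 10-clade design, where the correction is small.

Simulations are bit-reproducible under their seed, and the seed handling
restores the caller's RNG stream. The pipeline fans a single master seed
out to per-stage seeds by fixed offsets so any stage can be reproduced in
isolation.

### What the simulator does and does not emulate

It reproduces hierarchical drift, clinal selection, environmental
collinearity, and (optionally population-biased) missingness. It does
**not** reproduce locus-to-locus heterogeneity of evolutionary history:
under Balding-Nichols drift every neutral locus shares the same `f`, so
conditional on the hierarchy loci are exchangeable. Real genomes are not —
coalescent genealogies, recombination- and mutation-rate variation give
every locus its own effective drift. This matters for interpreting one
result: a *calibrated* scan largely resists exchangeable structure, so the
inflation of neutral outlier counts under strong structure, while
reproduced in direction at study-scale marker panels (about 0.2-0.4% of
10,000 neutral loci significant in the strong-structure regime versus
essentially none in the weak-structure regime), is far smaller here than
the tens of percent reported on real data. Passing the simulation suite
therefore demonstrates the pipeline's statistical control, not that real
datasets will show mild inflation.

## Problem sizes used in the test suite

The packaged checks run at deliberately desk-scale sizes chosen to make
each property measurable: calibration on 20 replicate neutral simulations
of 80 individuals x 2,000 loci; clinal-locus recovery on 10 replicates of
90 individuals x 5,000 loci with 100 random variables each; the
structure contrast on 10 replicate pairs of 150 individuals x 10,000 loci
(the real datasets this design emulates carried 10,987-13,004 loci).

## Known limitations

* Per locus x variable RDA attribution is one documented choice among
  several defensible ones; rankings are stable under the alternatives that
  reduce to univariate correlation, but absolute q-values differ.
* The broad-sense combination inherits the collinearity structure of the
  environment table; with few populations the r^2 > 0.7 set is itself
  noisy.
* The migration network is relative: rates are comparable within one
  analysis, never across datasets.
* `Fst` from the gene-diversity decomposition can dip marginally below 0
  on undifferentiated data because `Hs` carries a small-sample correction
  and `Ht` does not; structured data are unaffected.
* With a single in-house method per track, the combination stage operates
  as self-combination (a geometric mean is idempotent); the adapters for
  external q-value tables exist precisely so a second, independent method
  can be combined in.
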