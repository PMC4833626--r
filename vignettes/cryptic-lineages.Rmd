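---
title: "Discovering cryptic sympatric lineages in highly selfing plants"
author: "cryptline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cryptic sympatric lineages in highly selfing plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptline)
```

## The problem

Highly self-fertilizing annual plants — the motivating system is the North
American hog peanut, an amphicarpic legume whose cleistogamous flowers
obligately self — can harbour several strongly divergent genetic lineages
living side by side at the same sites. Because selfing keeps heterozygosity
near zero and restricts recombination between lineages, a sample of
individuals genotyped at a few thousand reduced-representation (RAD/GBS)
SNPs separates into discrete, highly homozygous clusters that do not follow
geography, with only occasional hybrids. `cryptline` packages the analysis
chain used to detect and characterize such cryptic lineages:

1. genotype QC (missing-data filters, one SNP per RAD locus),
2. descriptive population genetics and PCA-based lineage discovery,
3. forward simulation of F1/F2/F3 hybrids by crossing and selfing, with
   hybrid-index estimation and classification of putative hybrids,
4. per-locus F_ST scans for islands of divergence,
5. selection of small diagnostic SNP panels (an abstraction of
   melt-curve genotyping assays) and assignment of new samples,
6. elliptic Fourier analysis of leaf outlines with trait ANOVA and
   cross-validated LDA.

A synthetic-data module generates genotype matrices, RAD tag sequences,
leaf outlines and trait tables with this statistical structure and with
ground-truth labels, so every stage can be exercised and validated without
external data.

## The generative model behind the synthetic data

The generator uses a two-level hierarchy chosen as the minimal structure
that reproduces the field-observed summary statistics.

**Divergence patterns.** With two alleles and three lineages, a locus can
be (i) shared (all lineages carry the same ancestral frequency), or fixed
for alternate alleles such that exactly one lineage differs from the other
two (three patterns; all three pairs differing simultaneously is impossible
with two alleles). Given target pairwise fixed-difference fractions
$f_{ab}$, the pattern fractions are the solution of the triangle system
$f_{12} = x_2 + x_1$, etc.; target triples violating the simplex
constraints are rejected as infeasible. Locus counts per pattern are
apportioned deterministically (largest remainder), so configured fractions
are exact.

**Calibration to diversity and distance targets.** Users state targets on
the scale of the estimators: a group-level expected heterozygosity
$H_e$ and pairwise Nei's standard distances $D$. The calibration solves,
by fixed-point iteration,

* the shared-locus minor-allele-frequency beta distribution from
  $H_e = x_{\mathrm{shared}}\,E[2pq]\,(1 - F_{ST}\sum_s w_s^2)$, where the
  last factor accounts for pooling drifted site frequencies, and
* the fixed-difference fractions from
  $f_{ab} = 1 - x_{\mathrm{shared}}E[2pq] - \sqrt{J_aJ_b}\,e^{-D_{ab}}$,
  where the gene identities $J_a$ include the expected inflation from
  site drift and finite-sample frequency estimation
  ($E[\hat p^2] = p^2 + \mathrm{Var}(\hat p)$, with
  $\mathrm{Var}(\hat p) \approx pq(1+F_{IS})/2n$ under partial selfing).

The sampling terms matter: without them, plug-in Nei's $D$ overshoots its
target by several standard errors when one lineage has few samples. The
defaults emulate a three-lineage, seven-site survey (group sizes 5/94/29,
$D \approx 0.65/0.65/0.22$, $H_e \approx 0.065$).

**Within-lineage structure.** Per-site allele frequencies drift around
lineage frequencies under a Balding–Nichols beta model whose variance is
$F\,p(1-p)$, so the realized among-site Weir–Cockerham $F_{ST}$ approaches
the configured target (0.10 by default) as loci grow. Individuals are drawn
with inbreeding coefficient $F_{IS} = 1 - 2^{-t}$ after $t$ generations of
selfing from a random-mating base ($t = 5$ by default, giving
$H_o \approx 0.002$ at $H_e = 0.065$, i.e. the near-complete homozygosity
typical of cleistogamous selfers). $t = \infty$ forces exact homozygosity.

**Missingness** is modelled with independent per-individual and per-locus
dropout rates drawn from long-tailed beta distributions with configurable
means (the data-generating process behind RAD missingness is not
identifiable from published summaries; exposing both levels lets either
dominate). **RAD tags** are 93-base sequences whose two haplotypes differ
at exactly the recorded SNP offsets; a configurable fraction of tags
carries a second, fully linked SNP to exercise one-SNP-per-locus selection
and assay-suitability filtering. **Leaf outlines** come from a smooth ovoid
family (a tapered radial curve with low-order harmonic noise) scaled
anisotropically so the bounding-box length:width ratio is exact; group
ratio means/SDs default to the three lineages' reported terminal-leaflet
values. **Traits** are normal draws around group means with SDs
reconstructed from standard errors as $se\sqrt{n}$, assuming near-equal
group sizes (25/26/25) because only the total ANOVA df is published; hair
counts are truncated-normal by default with a Poisson alternative.

What the generator does *not* emulate: linkage disequilibrium beyond
complete within-tag linkage, allele-frequency spectra conditioned on an
explicit coalescent, sequencing error, or spatial autocorrelation among
sites. Passing parameter-recovery tests therefore validates the estimators
and the pipeline plumbing, not the full complexity of real RAD data.

## Estimators and conventions

* **Diversity.** $H_o$ is the mean over loci of the heterozygote fraction
  among non-missing calls. $H_e$ is Nei's unbiased gene diversity with the
  small-sample correction $\tfrac{n}{n-1}(1 - \sum p^2 - H_o/2n)$; the
  estimator is unbiased even under inbreeding. $F_{IS} = 1 - H_o/H_e$,
  undefined (NA) when $H_e = 0$. Allelic richness is rarefied per locus to
  the smallest group's non-missing allele count; private alleles are
  counted over whichever partition (lineages, or sites within a lineage) is
  passed.
* **F_ST.** Weir–Cockerham variance components, per locus, with the
  multilocus value as the ratio of sums $\sum a / \sum(a+b+c)$ — not the
  mean of ratios. Negative per-locus estimates are retained (a truncation
  flag exists for display); monomorphic loci are skipped and counted.
  The estimator uses the observed heterozygote frequency and therefore
  does not assume Hardy–Weinberg proportions, which matters at
  $F_{IS} \approx 0.97$.
* **Nei's D** is the 1972 plug-in estimator
  $-\ln(J_{xy}/\sqrt{J_xJ_y})$ with pairwise deletion of loci missing in
  either population; zero shared identity is flagged as infinite.
* **PCA** codes genotypes as alternate-allele dosage, mean-imputes missing
  calls per locus, centers but does not scale — the convention of standard
  SNP-PCA tools. Lineage clusters are chosen by k-means with the mean
  silhouette over $k = 2..6$.
* **Hybrid simulation** follows the protocol for selfing taxa: F1s from
  random parental pairs, F2 and F3 by one and two rounds of selfing.
  Individual-based gamete sampling is primary (parents are real simulated
  individuals); a frequency-based mode is implicit in the hybrid-index
  likelihood. Heterozygosity halves per selfing generation in expectation,
  while the hybrid-index variance grows — the signature used to stage
  putative hybrids.
* **Hybrid index** is the maximum-likelihood admixture proportion: each
  allele derives from population B with probability $h$, so the per-locus
  alternate-allele probability is $(1-h)p_A + hp_B$ and the log likelihood
  is concave; the maximizer is found by root-finding on the analytic score
  and the reported interval is the 2-log-likelihood-unit support region
  (the published intervals' method is unstated; a 2-unit support region is
  the standard likelihoodist default). A counting estimator over
  fixed-difference loci is available and equals the MLE in the fully
  diagnostic, complete-data case.
* **Hybrid classification** uses per-margin percentile boxes
  (central $1-\alpha$, $\alpha = 0.05$) on the joint (heterozygosity,
  hybrid index) clouds, rather than a Mahalanobis ellipse, because the
  post-selfing margins are strongly non-normal. Because two independent
  95% margins jointly cover only ~90% of genuine class members, strict box
  membership alone would call ~10% of true F2s "uncertain"; the classifier
  therefore admits near-misses within twice the box half-width before
  falling through to the backcross-like / parental / uncertain rules. Box
  half-widths are floored at $10^{-3}$ (the resolution of heterozygosity at
  a few thousand loci) so that degenerate zero-variance classes — e.g. F1s
  between fully inbred, fully diverged parents — still form usable boxes.
* **U-shape index.** The divergence-scan literature describes
  distributions as "distinctly U-shaped" visually; the package summarizes
  this with its own statistic: with per-decile masses $m_1..m_{10}$,
  $u = (2\min(m_1,m_{10}) - \bar m_{4:7}) / (2\min(m_1,m_{10}) + \bar
  m_{4:7})$. Requiring mass in *both* extreme deciles makes a drift-only
  unimodal-low distribution (mass piled near 0 only) score negative while
  divergence-with-gene-flow (background near 0 plus islands near 1) scores
  positive. The statistic is descriptive, not inferential.
* **Diagnostic panels.** A locus is diagnostic when every group is
  monomorphic and the partition sides carry different alleles; assay
  suitability additionally requires exactly one variable site in the
  93-base tag and at least 18 invariant flanking bases on each side — an
  explicit proxy for "suitable priming sites", parameterizable, since
  instrument-specific primer criteria are not reproducible. Panels take the
  $k = 4$ loci with the highest minor-group support (ties by locus id), so
  selection is deterministic. Assignment intersects the group sets admitted
  by the two panels; any evidence for incompatible sides (contradictory
  homozygous calls, or an empty intersection) is a conflict and the sample
  is meant to be discarded, mirroring field practice; heterozygous panel
  calls are reported as evidence for both sides and never silently
  collapsed.
* **Elliptic Fourier analysis** uses the chain (Kuhl–Giardina) formulation
  over the closed polygon with arc-length parameterization. Traversal is
  canonicalized to counterclockwise first. Normalization removes
  translation, starting point and rotation via the first-harmonic ellipse,
  and optionally scale; the half-period ambiguity of the first harmonic is
  resolved by lexicographic comparison of the two candidate coefficient
  vectors, which makes the canonical form deterministic and
  transform-invariant (to $10^{-6}$ in the test suite). One numerical
  subtlety is worth knowing: under arc-length parameterization the
  first-harmonic ellipse of an eccentric ellipse is slightly *rounder*
  than the source (for a 2:1 ellipse, semi-axes ~1.83 and ~1.07, ratio
  ~1.70), a property of the parameterization, not an implementation error;
  the tests validate coefficients against direct numerical Fourier
  integrals of the same parameterization. Requested harmonic counts above
  the outline's Nyquist limit (half the point count) are capped with a
  warning — relevant because published analyses quote 399 harmonics,
  which digitized outlines support but modest synthetic point counts do
  not.
* **Trait ANOVA / LDA.** One-way fixed-effects ANOVA per trait with Tukey
  HSD letters at $\alpha = 0.05$ (Tukey–Kramer under unbalance, as
  implemented by `stats::TukeyHSD`). The LDA uses class-proportional priors
  and standardizes features by default (the published analysis does not
  state whether features were standardized; the choice is recorded here),
  and is validated by leave-one-out refitting, excluding the terminal-shape
  PC because it is nearly collinear with the terminal length:width ratio.

## Pipeline seeds and determinism

All randomness flows from a single master seed; each stage derives its own
seed by a fixed integer mixing function, so stages can be toggled without
perturbing one another and a fixed configuration yields byte-identical
numeric summaries. Output files are named with a short configuration hash
and the seed.

## Problem sizes used by the test and acceptance suites

Unit tests run on matrices of tens of individuals and tens to hundreds of
loci. The behaviour checks use the sizes the package treats as its
reference conditions: heterozygosity-halving on 1000 simulated individuals
per generation class at 3,928 loci with a 30% fixed-difference fraction;
parameter recovery over 20 generator seeds at 1,000 loci (chosen so the
seed-to-seed spread, not estimator bias, dominates the 3-SE tolerance);
hybrid-classification trials (100 constructed F1/F2/F3/backcross
individuals) against simulated clouds of 1000 per class at 2,000 loci; and
divergence-scan and diagnostic-panel checks at 500–2,000 loci.

## Known limitations

* The coalescent machinery behind mutation-scaled population sizes and
  migration rates is external; only the `Ne m = theta * M / 4` conversion
  is implemented.
* Hybrid-candidate flagging on PCA scores is a stated convention (centroid
  distance ratio plus elevated heterozygosity); published analyses did this
  visually, so there is no ground truth to match.
* The generator draws each RAD locus independently; tests of multilocus
  statistics inherit that independence assumption.
* `assign_samples` labels hybrid-like (heterozygous-panel) samples
  `insufficient` with the heterozygous evidence attached, since a
  two-panel fixed-allele assay cannot place them in a single group.
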