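---
title: "Genomic-feature prediction with gfblupkit: models, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-feature prediction with gfblupkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfblupkit)
```

## The problem

Milk fatty-acid composition and similar dairy traits are moderately
heritable, expensive to phenotype at scale, and — for some traits —
dominated by a handful of large-effect regions (in cattle, the DGAT1 region
on BTA14 and the SCD1 region on BTA26 are classic examples). Two ideas can
compensate for small per-country reference populations: pooling related
populations into a combined reference, and giving marker subsets with known
large effects ("genomic features", here whole chromosomes) their own
variance components so their signal is not shrunk to the genome-wide
average. `gfblupkit` implements both, end to end, with a synthetic-data
generator that stands in for the multi-population half-sib cow data such
studies use.

## Models

The traditional GBLUP model for cow $l$ in parity $i$, herd $j$ at $DIM_k$
days in milk is

$$y_{ijkl} = \mu + parity_i + herd_j + b_1 DIM_k + b_2 e^{-0.05\,DIM_k}
  + g_l + e_{ijkl},$$

with $\mathbf g \sim N(0, \mathbf G\sigma^2_a)$ and
$\mathbf e \sim N(0, \mathbf I\sigma^2_e)$. The exponential covariate is the
Wilmink lactation-curve adjustment; its exponent is fixed at $-0.05$ per
day, while $b_1, b_2$ are estimated. The GFBLUP variant replaces the single
genomic effect by one effect per feature chromosome plus one for the rest
of the genome,

$$g_l = \sum_{f} g_{f,l}, \qquad
  \mathbf g_f \sim N(0, \mathbf G_f \sigma^2_f),$$

and its heritability uses $\sigma^2_{total} = \sum_f \sigma^2_f$. The
proportion of genomic variance on feature $f$ is
$\sigma^2_f / \sigma^2_{total} \times 100$.

All relationship matrices are VanRaden's first method,
$\mathbf G = (\mathbf M - \mathbf P)(\mathbf M - \mathbf P)^\top / s$ with
$s = 2\sum_j p_j(1-p_j)$. Each matrix records its own $s$; because every
subset matrix is centered with the same frequencies, the identity
$\sum_f (s_f/s_{total})\,\mathbf G_f = \mathbf G_{whole}$ holds to
floating-point accuracy and is tested. Centering frequencies are computed
once from the full analysis set of a scenario (combined individuals in
combined scenarios), which keeps all matrices referenced to a single base
population; the alternative (per-population frequencies) would break the
partition identity and imply population-specific bases.

## REML

Variance components are estimated by average-information (AI) REML. Each
iteration forms $\mathbf V = \sum_f \sigma^2_f \mathbf G_f + \sigma^2_e
\mathbf I$, its Cholesky inverse, and the projection matrix implicitly
through products with $\mathbf P\mathbf y$; traces use the identity
$\mathrm{tr}(\mathbf A\mathbf B) = \sum_{ij} A_{ij}B_{ij}$ for symmetric
matrices, so the per-iteration cost is one Cholesky plus $O(n^2)$ work per
component. The AI step is taken when it keeps the restricted log-likelihood
non-decreasing (with up to six step-halvings); components proposed negative
are clamped to a floor of $10^{-8}\,\mathrm{var}(y)$ and flagged as
boundary estimates; if no damped AI step improves the likelihood an EM step
is used instead. Convergence requires the log-likelihood change below
$10^{-6}$ and the maximum relative parameter change below $10^{-5}$ within
200 iterations; non-convergence is an error carrying the iteration trace,
not a silent result.

Starting values split $\mathrm{var}(y)/2$ equally across the genetic
components, with $\mathrm{var}(y)/2$ residual. These are conventional
choices; the reference software used in this literature (DMU) does not
publish its internals, so the tests pin the estimator to its *definition*
instead: translation invariance, $c^2$ scale equivariance, recovery of
known simulated components, boundary behaviour on pure noise, and the
likelihood equivalence of duplicated kernels.

## Prediction and reliability

Variance components are estimated once on the full analysis set; validation
animals then have their phenotypes removed from the data vector while their
rows remain in every relationship matrix, and breeding values come from

$$\hat{\mathbf g}_f = \sigma^2_f \mathbf G_f[\cdot, obs]\,
  \mathbf V_{obs}^{-1}(\mathbf y_{obs} - \mathbf X_{obs}\hat\beta),$$

the direct solution of the mixed-model equations that never inverts a
(possibly singular) $\mathbf G_f$. The single-kernel solution is
algebraically identical to ridge-regression SNP-BLUP with
$\lambda = \sigma^2_e s / \sigma^2_a$, and the multi-kernel solution with
components fixed at $\sigma^2_a s_f / s_{total}$ collapses to GBLUP; both
identities are acceptance-tested at relative $10^{-6}$.

Reliability follows the corrected-phenotype convention: corrected
phenotypes are $y$ minus the fixed-effect part of a single-population
traditional GBLUP fitted on all of the cow's population (random effects are
*not* subtracted), and reliability is $\mathrm{cor}(\hat g, y_{corr})^2 /
\hat h^2$ with $\hat h^2$ from the same scenario's full-data fit. Scaled
reliabilities can exceed 1; they are flagged, never truncated. Replicate
summaries report the mean reliability, the mean absolute deviation of the
per-replicate correlations, and the regression slope of corrected
phenotypes on predicted values (1 = dispersion-unbiased).

Cross-validation honours kinship: the `unrelated_subset` strategy samples
validation cows that have no sibling in the dataset (sharing a sire *or* a
dam — the stricter reading, since the source design does not define
"sibling") and whose dam is absent; the `sire_group_holdout` strategy
validates within one half-sib group and excludes the group's remaining
cows from the reference entirely. Validation sets may recur across
replicates (set-level resampling); within a replicate sampling is without
replacement.

## The synthetic world

The generator emulates a three-population Holstein-style design at desk
scale: by default 3 populations of 250/200/500 cows in 5 half-sib sire
groups each, 5 chromosomes of 600 SNPs and 100 Mbp, and features on three
chromosomes carrying 30/20/10% of a unit genetic variance. Founder allele
frequencies are Beta(2, 2) truncated to [0.05, 0.95]; populations perturb
them on the logit scale with variance 0.01 (closely related populations,
nonzero cross-population relationships). Linkage disequilibrium arises
from copying gametes in exponential blocks (mean 2 Mbp) out of a finite
founder-haplotype pool of 30; paternal gametes are recombinants of the
sire's two haplotypes (about one crossover per 100 Mbp), which makes
within-sire-group genomic relationships average near 0.25. QTL counts are
allocated to chromosome groups proportionally to SNP counts, and each
group's effects are rescaled after sampling so the realized partial
variances match the configured fractions — concentrating variance on a
SNP-poor feature therefore means fewer, larger effects, which is exactly
the regime where GFBLUP should help.

Values the source design leaves unreported were fixed once: overall mean 10
(a desaturation-index-like percent scale), parity and herd effect SDs of
0.5 trait units, $b_1 = 0.01$/day and $b_2 = -2$ (a typical early-lactation
dip), DIM uniform on [5, 305]. The optional multiplicative-residual mode
multiplies the deterministic mean by log-normal noise with a configured CV,
producing the right-skewed, variance-grows-with-mean pattern that the
residual diagnostic (Spearman correlation of |residual| vs fitted > 0.2 at
p < 0.01) flags for log transformation; it is a device for exercising that
rule, not a full log-scale phenotype model, and heritability bookkeeping
applies only to the additive mode. Traits are modeled on the log scale
throughout when transformed; no back-transformation is applied.

What the generator does **not** emulate: coalescent-realistic LD and MAF
spectra, selection, genotyping error, imputation artifacts, or
genotype-by-environment structure. A green directional test (GFBLUP ≥
GBLUP under enrichment; combined ≥ single-population references under
shared effects) therefore establishes that the estimators order scenarios
correctly when the assumed mechanism is the only mechanism — not that real
cattle data will show gains of any particular size.

## Numerical and design notes

* QC thresholds are inclusive: MAF exactly 0.05 and a minimum genotype
  class of exactly 10 survive, since the rule removes values *below* the
  thresholds. QC runs within one population; combined sets are the
  intersection of per-population post-QC SNPs, matched on id and position.
* Missing genotypes are mean-imputed per SNP before any GRM; a SNP missing
  in every individual is an error, not a silent zero.
* LD $r^2$ is the squared Pearson correlation of allele counts (composite,
  phase-free LD). This can differ slightly from haplotype-based $r^2$; it
  is deterministic and needs no phasing. Distance bins are half-open.
* The chi-square check that zero drift equalizes population frequencies is
  run under a configuration with one sire per cow and a founder pool much
  larger than the sample, because the binomial-sampling oracle it relies on
  is invalid under strong family structure — a deliberate test-design
  choice, not a generator default.
* All pipeline randomness derives from one seed through a stage-keyed
  derivation (`derive_seed`), so stages never share an RNG stream and runs
  are bit-reproducible.
* Where the acceptance experiments needed population sizes the source
  design does not pin (the directional GFBLUP and combined-reference
  checks), sizes were chosen once for acceptable Monte-Carlo noise within
  the stated runtime budgets (600 cows / 8 holdout replicates for the
  feature-enrichment check; 500 + 400 + 1000 cows / 5 replicates of 50
  validation cows for the combined-reference check — below roughly 300
  records, single-population h^2 estimates hit the REML boundary and the
  h^2-scaled reliability becomes unstable) and then frozen.

## Known limitations

Dense-matrix REML limits analyses to a few thousand individuals; the
simulator's block-copy LD model has no mutation or deep pedigree; the VCF
reader handles biallelic GT-only records; VanRaden method 2, pedigree
relationship matrices, Bayesian alternatives and multi-trait models are out
of scope.
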