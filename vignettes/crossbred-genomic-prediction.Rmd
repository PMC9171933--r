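---
title: "Genomic prediction of crossbred pig performance: models, machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of crossbred pig performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In commercial pork production, selection happens in purebred nucleus lines
while the animals that generate revenue are crossbreds, typically from a
three-way cross: purebred terminal-line boars (here Duroc) mated to F1
Landrace x Yorkshire sows.  The traits that matter most for product value —
intramuscular fat, slice shear force, color, primal-cut weights — are
measured post-mortem, often with wet-lab chemistry, and are therefore far
too expensive to record routinely.  Two mitigation strategies exist:

1. **Multi-trait (indirect) selection** — record cheaper indicator traits
   (purebred growth and ultrasound traits, or crossbred live and carcass
   probe traits) and exploit their genetic correlations with the expensive
   objective.
2. **Genomic selection** — genotype some combination of sires, dams,
   crossbred and purebred offspring and replace pedigree relationships with
   marker-informed ones.

`crossblup` implements the full machinery needed to study these strategies
jointly: relationship matrices (pedigree **A**, genomic **G**, blended
single-step **H**), single- and multi-trait animal models solved by dense
mixed-model equations, Bayesian variance-component estimation with a
compiled Gibbs sampler, a pedigree-clustered cross-validation engine over
phenotyping scenarios crossed with genotyping stages, and a synthetic
population generator that emulates the paternal half-sib, three-way cross
structure so that every analysis can be exercised and tested without
proprietary data.

## Models

For a crossbred-measured trait the animal model is

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}_l \mathbf{l}
 + \mathbf{Z}_p \mathbf{p} + \mathbf{Z}_a \mathbf{a} + \mathbf{e},$$

with fixed dam line (cross direction of the F1 sow), sex and contemporary
group; random litter $\mathbf{l}\sim N(\mathbf{0}, \mathbf{I}\sigma^2_l)$,
pen $\mathbf{p}\sim N(\mathbf{0}, \mathbf{I}\sigma^2_p)$ and additive
genetic effects $\mathbf{a}\sim N(\mathbf{0}, \mathbf{K}\sigma^2_a)$, where
$\mathbf{K}$ is **A** (pedigree only) or **H** (single-step).  For a
purebred-measured trait the pen term is dropped and the fixed part uses
contemporary group, parity of the birth sow and a centered age-at-recording
covariate.  Base-population animals are treated as unrelated; unknown-parent
groups are not used.

In multi-trait form each random term carries a full trait x trait
covariance matrix.  Purebred and crossbred expressions of one biological
character are modelled as *distinct traits*, so the purebred-crossbred
genetic correlation can be below one.  Traits measured on different
populations are never observed on the same animal, so their residual
covariance is structurally zero: the residual covariance matrix is
block-diagonal over the crossbred-trait and purebred-trait blocks, and is
sampled that way.

Heritability is reported as
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_l + \sigma^2_p + \sigma^2_e)$:
all non-residual random terms count toward the phenotypic variance.

## Relationship matrices

* **A** is built by the tabular method over the whole pedigree
  ($a_{ii} = 1 + F_i$).  Matrices here are desk-scale, so inverses are
  direct dense solves; no sparse-inverse machinery is used.
* **G** is a VanRaden-type matrix $\mathbf{ZZ}'/k$.  Because a three-way
  cross mixes populations with different allele frequencies, the default
  centers each animal's dosages by twice the allele frequency of *its own*
  population (crossbreds; their F1 dams; the purebred line including the
  sires), with the common denominator $k = \sum_j 2\bar p_j \bar q_j$
  computed from the across-population *average* frequencies so one scale
  applies to all blocks.  Missing dosages are imputed to the centering
  value.  A second mode centers everyone by the average frequencies; this
  is the matrix used for population-structure eigen-analysis, because
  per-population centering removes the between-population divergence by
  construction.  Which frequency set enters each formula is configurable,
  since several defensible conventions exist.
* **H** replaces the genotyped block of **A** with the blended matrix
  $\mathbf{G}^* = (1-\alpha)\mathbf{G} + \alpha\mathbf{A}_{22}$ and
  propagates the update to non-genotyped relatives via the standard block
  formula.  The blending weight defaults to $\alpha = 0.05$, the
  conventional single-step value; no mean-tuning of **G** to
  $\mathbf{A}_{22}$ is applied by default.  Both choices are arguments, so
  experiments are reproducible under other conventions.

## Variance components by Gibbs sampling

The sampler (compiled C++ core) draws location effects from their normal
full conditionals — scalar updates for fixed effects, small per-level
blocks for litter and pen, and per-animal trait-vectors for additive
effects with the $\mathbf{K}^{-1}$ coupling maintained incrementally — and
covariance matrices from inverted-Wishart full conditionals (scaled
inverted chi-square in the single-trait case).  Chains are deterministic
given a seed.  Retained samples number `(n_iter - burn_in) / thin`; the
package's defaults (100,000 / 20,000 / 20 for single-trait and
600,000 / 200,000 / 20 for multi-trait chains) retain 4,000 and 20,000
samples respectively.

**Priors.** The default prior on every covariance matrix is flat
($p(\boldsymbol\Sigma) \propto 1$), giving the full conditional
$IW(m - d - 1,\, \mathbf{U}'\mathbf{U})$ for $m$ levels and dimension $d$.
This matters: an inverse-Wishart prior with small degrees of freedom and a
tiny scale looks vague but concentrates enormous density at zero variance.
For components that the data identify only weakly — litter variance is
nearly confounded with dam breeding values when each dam has a single
litter — such a prior collapses the component to zero and inflates the
additive variance.  With the flat prior the posterior follows the
likelihood ridge and recovery of generating parameters is unbiased to
within Monte-Carlo error.  For terms with very few levels the degrees of
freedom are floored at the dimension so draws remain proper; informative
inverse-Wishart priors can be supplied explicitly.

**Missing records.** Within a population's trait block, missing cells are
handled by augmenting their residuals from the conditional normal given
the animal's observed residuals — the classic multi-trait sampler scheme.
Residual covariance across population blocks is fixed at zero exactly, by
sampling each block separately.  The deterministic BLUP solver, by
contrast, never imputes: it assembles Henderson's equations with
pattern-specific residual inverses per animal.

**Diagnostics.** `summarize_chain()` reports posterior means, 95% highest
posterior density intervals (shortest interval), effective sample sizes
(initial-positive-sequence estimator) and a split-chain potential scale
reduction factor.  These are reported, not enforced; heritabilities and
genetic correlations mix noticeably slower than the location effects, and
chain lengths should be judged against the reported effective sizes.

## Cross-validation engine

Validation follows the phenotype-prediction design: dissimilarities among
the sires are computed from the pedigree relationship matrix as
$d_{ij} = \sqrt{a_{ii} + a_{jj} - 2a_{ij}}$ — a proper metric, monotone in
the relationship — and clustered into four folds by k-means.  Because
k-means needs coordinates, the dissimilarity matrix is embedded by
classical multidimensional scaling, keeping components explaining at least
99% of the positive-eigenvalue variance; the best of many random
initializations (default 50) by within-cluster sum of squares is kept, all
under a fixed seed.  Whether the original analyses clustered an embedding,
the raw dissimilarities or relationships directly is not recoverable; the
MDS choice is recorded here as this package's convention.  All paternal
half-sibs inherit their sire's fold, so whole families are held out
together.

For each grid cell (objective trait x phenotyping scenario x genotyping
stage x fold) the engine masks the objective-trait records of the
validation fold's crossbreds, keeps all predictor-trait records, fits the
multi-trait model, and scores the Pearson correlation between the
estimated breeding values and the masked phenotypes adjusted for fixed
effects, with the fixed-effect solutions taken from a full-data fit.
Accuracies are reported raw (not divided by $\sqrt{h^2}$).  Validation
animals without an objective record (never phenotyped under the subset
design) are excluded from scoring.

Variance components for prediction are, by default, estimated once per
phenotyping scenario on the full unmasked data and then fixed across folds
and stages, mirroring the separation between component estimation and
cross-validation; per-fold re-estimation and fully fixed (user-supplied)
components are both available.

The genotyping stages follow the three-way cross structure: `Stage-1` =
sires + F1 dams, `Stage-2` = crossbreds + sires, `Stage-3` = all three;
purebred offspring genotypes are added to whichever stage is active
whenever purebred phenotypes are in the model.

## The synthetic population

`simulate_population()` emulates the data structure the analyses assume:
28 Duroc sires (default), 914 F1 dams in both cross directions, ~5,300
crossbred and ~3,100 purebred offspring of the same sires.  Founder
haplotypes are drawn per lineage from Balding-Nichols differentiated
frequencies (ancestral frequencies uniform on [0.05, 0.95]; default
differentiation $F_{ST} = 0.15$, typical of divergent pig breeds);
descendants are produced by gene dropping.  Loci are in linkage
equilibrium by default — adequate for relationship-based machinery — with
an optional whole-chromosome block mode as a coarse linkage model; no
mutation, selection, or dominance/heterosis is simulated, since the
analysis machinery is strictly additive.  Litter sizes are split as evenly
as possible to hit the requested totals.

Husbandry structure mirrors a finishing barn: single-sex pens filled
family-wise (a pen holds one or two paternal half-sib groups), so the
grouping "same sire, same sex, same pen" used for subset phenotyping is
non-trivial; litters are split across the sexes, which keeps litter and
pen variances separable.  Contemporary groups pool pens across the sexes,
so they are never confounded with the sex effect.  Contemporary-group
effects are drawn normal (default SD 0.3 phenotypic SD); sex, dam line and
parity effects and the age slope have configurable magnitudes.

Phenotypes come from `simulate_traits()` in two genetic modes: `"pedigree"`
(breeding values by Mendelian-sampling recursion; exact for variance
component studies) and `"markers"` (breeding values are sums of marker
effects on centered dosages, so genomic machinery has marker-linked signal
to find; realized variances match the target covariances under
Hardy-Weinberg/linkage equilibrium).  The trait catalogue ships the 24
traits of the study system with their descriptive statistics and
single-trait heritabilities, and the reported genetic correlations among
them; unlisted correlations default to zero and the assembled correlation
matrix is projected to the nearest positive semidefinite correlation
matrix (Higham's algorithm), with the adjustment magnitude reported.
Because many strong correlations coexist with zero-filled unknowns, that
projection can be substantial for the full panel; models built on small
feasible subsets pass through unchanged, and every entry is overridable.

The within-group phenotyping subset rule selects, per group, the
individuals closest to the group mean of the anchor trait (carcass growth)
and to +1, +2, -1 and -2 within-group standard deviations, in that order,
greedily matched to distinct individuals with ties broken by lowest id;
groups at or below the target size contribute all members.

## Numerical choices and test scale

* Dense symmetric solves (Cholesky) throughout; a singular coefficient
  matrix raises an error naming the likely confounding.  Single-level
  fixed factors fold into the intercept automatically.
* Covariance draws that fail positive-definiteness are retried with a
  small diagonal jitter and counted; the count is reported on the chain
  object.
* The additive Gibbs update keeps `K^{-1} a` current via the stored
  non-negligible entries of each `K^{-1}` column (a pedigree inverse is
  sparse between non-relatives) and refreshes the product densely every
  1,000 iterations to bound drift.
* SNP QC applies its rules in order (non-autosomal, call rate < 0.90,
  pooled MAF < 0.05, strict inequalities), counting each marker against
  the first rule that removes it.

The shipped tests and the acceptance script run everything at reduced
scale chosen to keep the full suite comfortably reproducible on a laptop:
variance-component recovery uses 100 sire families and 2,000 phenotyped
crossbreds with scaled chains (20,000 iterations), the cross-validation
experiment uses 28 sires, 560 crossbreds, 336 purebreds and 2,000 markers,
and the stratification check runs the full default design.  Recovery
checks pass at these scales; posterior means of ratios (heritability,
genetic correlation) still carry Monte-Carlo and design-level noise of a
few hundredths, which is why those checks average over replicate
simulations.

## Limitations

* Breed-of-origin-of-allele models are out of scope; dosages are used
  as-is regardless of which parental line contributed the allele.
* No REML estimator is provided; the Gibbs sampler is the package's
  variance-component engine.
* All solvers are dense and intended for up to roughly ten thousand
  equations; chip-scale marker counts are supported for relationship
  construction, but population sizes far beyond the default design call
  for sparse single-step implementations outside this package's scope.
* Passing tests on synthetic data show the machinery is correct under the
  generator's assumptions (additivity, linkage equilibrium, known model
  structure); they cannot certify behavior on real data with selection
  history, genotyping error, or model misspecification.
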