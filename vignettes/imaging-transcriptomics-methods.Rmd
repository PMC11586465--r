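---
title: "Methods: linking regional atrophy maps to gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking regional atrophy maps to gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagetx)
```

# The analysis and its assumptions

`imagetx` connects two regional maps defined on one parcellation: a
case–control map of gray-matter volume (GMV) alteration, and a regions ×
genes expression matrix. The chain is: covariate-adjusted regional linear
models → a t-map → first-component partial least squares (PLS1) against
expression → bootstrap-z gene lists → enrichment-ratio statistics over gene
sets and cell classes → receptor-map context. Every map-versus-map inference
is protected against spatial autocorrelation by a spherical spin null.

## Regional case–control models

Each region is fit independently by ordinary least squares,

$$\mathrm{GMV}_i = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} +
\beta_3\,\mathrm{TIV} + \beta_4\,\mathrm{group} + \varepsilon,$$

and the group coefficient's t statistic forms the regional map. The
covariates enter **additively**: an age × sex interaction without main
effects would not be a meaningful adjustment model, and age, sex and total
intracranial volume (TIV) are treated as covariates throughout. Assumptions
are those of OLS — independent subjects, homoscedastic residuals within a
region, and a full-rank design (collinearity raises an error rather than a
silent drop). The t statistic is invariant to positive affine rescaling of
the response, so whether GMV is pre-standardized per region cannot change
the map; the test suite asserts this directly.

The FDR family is all regions within one contrast. The default significance
threshold is q < 0.05; post-hoc subgroup contrasts can be run at a stricter
configurable α (e.g. 0.017) without changing the family. The remote/current
FBTCS+ split uses a strict "more than 2 years since the last bilateral
seizure" rule; exactly 2 years is *current*, and the two rules partition the
FBTCS+ group exhaustively.

## Expression processing

Real-mode inputs are taken **after** probe reannotation, probe selection,
sample-to-region matching and donor aggregation; the package implements the
two steps that operate on the aggregated matrix:

* **Intensity filtering** keeps a gene iff it is detected in at least a
  fraction `threshold` (default 0.5) of regions; the comparison is `>=`, so
  detection in exactly half the regions keeps the gene.
* **Scaled robust sigmoid (SRS)**:
  $\tilde x = \bigl(1 + \exp(-(x - \mathrm{median})/(\mathrm{IQR}/1.35))\bigr)^{-1}$,
  min–max rescaled to [0, 1]. The IQR/1.35 factor makes the scale consistent
  with the standard deviation under normality. SRS is monotone, bounded, and
  invariant to positive affine transforms of its input. A zero-IQR gene is
  degenerate for the sigmoid; it falls back to min–max scaling with a
  warning rather than failing a whole matrix.

Normalization order: per gene across regions first (this yields the
invariant that every gene column spans [0, 1] exactly), with an optional
second pass per region across genes for users who want within-region
comparability; the passes are individually testable and the per-gene pass is
the default. Analysis is restricted to the left hemisphere, where donor
coverage is adequate; with the default atlas this leaves 159 regions.

## PLS1 and gene statistics

PLS is fit by NIPALS on the z-normalized matrix and response. For a single
response the first weight vector has the closed form $w \propto X^\top y$
(normalized to unit length) — the test suite uses this closed form, and an
independent PLS implementation, as oracles. Explained variance is defined as
$\mathrm{cor}(Xw, y)^2$ and its significance comes from refitting under
permutations of $y$: spatial spins by default, free shuffles for
non-spatial responses and for calibration tests. Only the first component is
interpreted; further components are computed lazily for diagnostics.

Gene-level inference bootstraps regions with replacement and refits PLS1.
Because a PLS component's sign is arbitrary, each bootstrap weight vector is
**sign-aligned** to the original fit (flipped when its inner product with
the original weights is negative) before the standard error is taken;
without alignment the SEs are inflated by sign indeterminacy rather than by
sampling variability. Bootstrap resamples reuse the already-standardized
matrix without re-standardizing within each resample, following the usual
practice of PLS bootstrap code in this field. `z = w / SE`, two-sided normal
p, BH-FDR across **all** modeled genes, and the significant genes split into
PLS+ (z > 0) and PLS− (z < 0) lists ranked by |z| descending with a
deterministic lexicographic tie-break on the gene identifier.

The sign convention (scores correlate non-negatively with the response)
means genes whose expression tracks the t-map positively get positive
weights and z-scores.

## Spin null

A spin draws a uniformly random 3-D rotation (QR orthonormalization of a
Gaussian matrix, determinant forced to +1), applies it to the left
hemisphere's unit-sphere centroids and the x-mirrored rotation to the
right, and reassigns each region the value of the region whose rotated
centroid lands nearest, using greedy one-to-one matching in random
processing order. Greedy matching (rather than optimal transport) guarantees
a bijection cheaply and matches the spirit of the rotate-parcellation
approach; bijectivity and hemisphere closure are asserted for every row on
construction. The p-value is two-sided on |r| with the +1 smoothing
`p = (1 + #{|null| ≥ |obs|}) / (n_perm + 1)`, so p = 0 is impossible; the
default is 1000 spins.

Subcortical regions have no spherical coordinates, so rotation cannot apply
to them: they are shuffled uniformly among themselves, and a cortex-only
scope is available. The receptor correlation defaults to the full 322-region
scope with this hybrid null; users wanting a strictly rotational null should
use the cortex scope.

The spin p permutes only the first map argument; p is therefore not exactly
symmetric in (x, y). This asymmetry is documented rather than hidden.

## Enrichment ratio

For a weighted PLS list L and gene set S with intersection size k, the
observed statistic is the **median** weight of L ∩ S. The null redraws k
genes **without replacement from the full universe of modeled genes** —
not from within the already-thresholded PLS list, where the restricted
weight range could not produce enrichment scores of meaningful magnitude;
the pool is switchable for sensitivity analyses. ER standardizes the
observed median against the null medians; p is one-sided upper-tail
(enrichment only — depletion is not scored as significant). The default is
10 000 permutations. ER is invariant under positive affine transforms of
the weights, and on small universes the permutation estimate converges to
exhaustive enumeration over all $\binom{n}{k}$ subsets; both properties are
asserted in the tests. An empty intersection returns a flagged empty result
rather than an error, so batteries over many sets degrade gracefully.

Cell-type enrichment consumes a provided gene → class table over the seven
canonical cortical classes (astrocytes, endothelial, excitatory neurons,
inhibitory neurons, microglia, oligodendrocytes, OPCs); re-deriving that
mapping from source single-cell studies is out of scope.

# The synthetic data module

The generators produce inputs with exactly the structure the analysis
assumes, so planted effects are recoverable and null calibrations are
meaningful:

* **Atlas** — deterministic golden-angle lattices on each hemisphere's
  half-sphere. The default is 152 left + 156 right cortical regions plus 7
  subcortical per hemisphere (322 regions, 159 left), emulating a
  backtracking subdivision of an anatomical atlas, which need not be
  hemispherically symmetric. Network labels form contiguous polar bands and
  cytoarchitectonic labels contiguous azimuthal sectors, so label schemes
  are spatially coherent.
* **Cohort** — GMV = lognormal regional baseline + covariate effects +
  planted atrophy + spatially correlated Gaussian noise (exponential kernel
  on inter-centroid angle, default scale 0.5 rad; subcortical noise
  independent). Age is uniform on 18–40 years, sex Bernoulli(½) coded 0/1,
  TIV lognormal around 1500 cm³ — the analysis uses them only as covariates,
  so only their presence and rough scale matter; the cohort tables the
  analysis targets report medians/IQRs but not full distributions, so these
  defaults are plausible rather than calibrated. Default covariate effects:
  −0.004 cm³/year age, +0.05 cm³ sex, +0.0008 cm³/cm³ TIV on a 0.15 cm³
  noise SD.
* **Expression** — each gene a spatially smooth field; the first `n_aligned`
  genes mix the standardized target map at weight `alignment_strength` with
  their own field.
* **Gene sets** — each member drawn from the planted pool independently with
  probability `planted_fraction`, so the planted intersection is binomial.
* **Receptor map** — Gaussian rank-mixture at the Pearson level
  $\rho_P = 2\sin(\pi \rho_S / 6)$, the bivariate-normal value whose implied
  Spearman correlation equals the target, exact at ±1.

The default scale — 322 regions, 2000 genes, 186 subjects (60/37/89),
atrophy of 2 noise-SD in 10 left-cortical regions, 100 aligned genes at
strength 0.6, one planted gene set at fraction 0.5 among null sets, receptor
target ρ = 0.24 — keeps a full pipeline run well under a minute while
leaving all planted effects comfortably recoverable.

**What the generator does not emulate.** Real morphometry has site and
scanner effects, non-Gaussian and spatially non-stationary noise, and
atrophy that is graded rather than a constant shift; real expression has
donor-specific effects, missing right-hemisphere coverage handled upstream,
and gene–gene correlation structure beyond shared spatial smoothness; gene
identifiers are synthetic (`G000001`, …). Passing the recovery tests
therefore shows the *pipeline* is correct and calibrated under its own
assumptions — it does not validate those assumptions against real MRI or
donor microarray data, and the synthetic explained-variance figures (which
approach 90% at the default planted strength) are not comparable to the
much lower values typical of real cohorts.

# Numerical choices

* BH q-values are computed step-up with `m/j * p` ordering and clamped with
  `pmax(q, p)` to keep the `q ≥ p` invariant against 1-ulp rounding.
* Spearman uses average ranks for ties; its analytic p uses the t
  approximation (matching `cor.test(exact = FALSE)`), and is superseded by
  the spin p wherever a spatial null applies.
* Chi-square is the uncorrected Pearson statistic: demographic tables in the
  targeted literature are reported without continuity correction, and the
  package reproduces printed table p-values only without it.
* Permutation p-values all use the +1 smoothing; the minimal attainable p is
  `1/(n_perm + 1)`.
* Degenerate inputs fail loudly: constant vectors for correlation or
  z-normalization, rank-deficient designs, empty groups and empty expression
  matrices raise errors; the two deliberate soft cases are zero-IQR SRS
  (min–max fallback with a warning) and empty ER intersections (flagged
  result).
* Per-stage seeds are derived from the master seed by a stable polynomial
  hash of the stage name, so adding a stage never perturbs the random
  stream of existing stages; all derived seeds stay below 2³¹.
* Tabular outputs use 6 significant digits and fixed column order for
  diffability.

# Test scale

The suite exercises: closed-form PLS oracles on 1000 random matrices;
exhaustive ER enumeration on a 10-gene universe; type-I-error calibration of
the spin test, ER, PLS permutation test and BH-FDR at α = 0.05 over 500
null replicates each (checked against the 95% binomial band); and 50
end-to-end pipeline runs at the default study scale with reduced
permutation counts (100 spins, 150 bootstraps, 499 ER permutations —
recovery of planted effects is insensitive to these counts, which only set
the p-value floor). These sizes were chosen to keep the default test run
fast while leaving each check statistically informative.

# Known limitations

* The spin null is defined on sphere-projected centroids; parcels are
  treated as points, so parcel area and shape do not enter the null.
* The hybrid subcortical shuffle preserves no subcortical spatial structure.
* Bootstrap z assumes approximate normality of weight estimates; for very
  small region counts the normal p-values are only indicative.
* ER significance is enrichment-only; depletion is reported via the ER sign
  but not tested.
* Real-mode inputs must arrive pre-aggregated (one expression value per
  region per gene); donor-level processing belongs to upstream tooling.
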