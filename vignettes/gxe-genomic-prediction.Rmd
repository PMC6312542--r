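---
title: "Multi-environment genomic prediction with factor-analytic G×E models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment genomic prediction with factor-analytic G×E models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgblup)
```

## The problem

Perennial fruit crops are bred and evaluated in localized programs with
little clonal replication across sites: each program phenotypes its own
cultivars, selections and seedlings in its own environment. Genome-wide
SNP panels change the picture — individuals that were never co-tested can
still be connected through realized genomic relationships, so phenotypic
records scattered over locations and seasons can enter a single
multivariate analysis. That analysis answers two questions at once: how
stable are genetic effects across environments (genotype-by-environment
interaction, G×E), and what is each individual's genetic merit in an
environment where it was never grown?

`metgblup` implements the full workflow — data curation, relatedness, the
multivariate mixed model, accuracy evaluation, and a synthetic-data
generator with known truth — so that every stage is testable against
independent oracles.

## Model

For `N` observations on `n_G` individuals across `n_E` location-by-season
environments,

$$ y = Xb + Zu + r, \qquad \mathrm{var}(y) = ZGZ^{\mathsf T} + R, \qquad
   G = G_{A\times E} \otimes G_A . $$

* `b`: fixed environment means plus, at a single designated location, a
  planting-year effect (the only location where trees were established in
  different years).
* `u`: the `n_G × n_E` genomic breeding values. Their covariance
  factorizes into the genomic relationship matrix `G_A` (VanRaden method
  1: centered dosages, scale `2Σp(1−p)`, observed allele frequencies) and
  the environment covariance `G_{A×E}`.
* `r`: residuals, independent between experimental units; within a unit,
  seasons at the same location may covary (`R_Sj` blocks). By default the
  blocks are diagonal — one residual variance per environment — because
  per-environment variances are what single-tree trials support; the
  within-unit season covariance is estimable via `resid_cov = TRUE`.

Three nested parameterisations of `G_{A×E}` are fitted:

| kind | form | parameters | interpretation |
|------|------|------------|----------------|
| `uniform` | $\sigma^2_A J$ | 1 | no G×E, correlation 1 |
| `cs` | $\sigma^2_A J + \sigma^2_{A\times E} I$ | 2 | main effect + homogeneous interaction |
| `fa1` | $\Lambda\Lambda^{\mathsf T} + \Psi$ | $2n_E$ | heterogeneous variances and correlations |

The cs decomposition gives the average cross-environment correlation
$\bar r_{A\times E} = \sigma^2_A/(\sigma^2_A+\sigma^2_{A\times E})$; the
fa1 fit gives per-environment additive variances (its implied diagonal)
and the full correlation matrix. Per environment,
$h^2 = \sigma^2_{A}/(\sigma^2_{A}+\sigma^2_{R})$.

### Estimation

Parameters are estimated by restricted maximum likelihood with the
average-information algorithm. The phenotypic covariance is assembled
without forming `Z` or the Kronecker product:
`V[r,s] = G_AxE[env(r),env(s)] · G_A[id(r),id(s)] + R[r,s]`, a few
hundred to a few thousand rows — dense linear algebra is simplest and
fast at this scale. Each iteration solves the damped AI system with
step-halving (up to 10 halvings, then escalating Levenberg damping); if
no AI step improves the likelihood, an EM-type multiplicative update
`θ ← θ·√(y'P(dV)Py / tr(P dV))` of the variance parameters is tried
before convergence is declared. Constraints: variances ≥ 0 (pinned at the
boundary when the score pushes outward), residual variances floored at
`10⁻⁶·var(y)` to keep `V` positive definite, and the factor-analytic sign
fixed by `Λ₁ ≥ 0` (a single factor needs no rotation). Convergence
requires `|ΔlogL| < 10⁻⁶` and a relative parameter change `< 10⁻⁴`
(defaults, overridable). `G_A` is bent by `+10⁻⁶·I` before any
inversion-heavy step, since panels with fewer markers than individuals or
with clonal duplicates are singular.

The restricted likelihood uses the standard criterion
$-\tfrac12[(N-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]$. The test
suite verifies it against an error-contrast oracle (an orthonormal basis
`K` of the complement of `col(X)`, with the density of `K'y` normalized
by `|X'X|^{-1/2}` so the two conventions coincide identically), and the
whole fitter against `lme4` on a one-environment design, where both agree
to six decimals in variance components and log-likelihood.

BLUEs and BLUPs come from Henderson's mixed model equations, computed
through the equivalent variance-form identities
$\hat b = (X'V^{-1}X)^{-1}X'V^{-1}y$ and
$\hat u = GZ'V^{-1}(y-X\hat b)$ — algebraically the MME solution for the
same bent `G` (verified numerically against an explicitly assembled MME),
but usable also for the `uniform` structure whose `G_{A\times E}` is
singular. Every individual is predicted in every environment, including
cells with no records.

### Model comparison and environment means

Nested structures are compared by likelihood-ratio tests with naive
chi-square references (`df` = difference in parameter count; the
boundary-mixture refinement for variance parameters is noted but not
applied, matching common practice in MET analysis). Environment
least-square means re-expand the treatment-coded fixed effects to cell
means, averaging over planting-year levels at the location where that
factor applies; the compact letter display is computed from the maximal
cliques of the non-significance graph, which makes it invariant to
environment ordering.

## Curation choices

* **Names.** Diacritics fold to their ASCII base letter; whitespace maps
  to a single underscore; all other specials (apostrophes, punctuation)
  are deleted without a separator — so "Precoce d'Isigny" becomes
  `precoce_disigny`. The mapping is idempotent. Partial matching combines
  substring containment with a normalized Levenshtein distance ≤ 0.2,
  ranked by distance.
* **Merging.** Calls that agree across sources are kept, single-source
  calls fill gaps, any disagreement is set to missing and logged. The
  merge runs over the sorted union of individuals and loci, so source
  order cannot matter.
* **Duplicates.** Pairs with concordance ≥ 0.99 over ≥ 100 jointly-called
  loci are linked and closed transitively; the first member of each group
  (panel order) is the representative.
* **Imputation.** A deliberately simple, documented stand-in for
  haplotype-model imputation: the modal dosage among individuals sharing
  the nearest non-missing flanking dosage pair (ties toward the smaller
  dosage), falling back to a seeded Hardy–Weinberg draw at the observed
  allele frequency. This is a fidelity gap relative to HMM imputation —
  adequate at the few-percent missingness typical after merging, but not
  for sparse panels.

## The synthetic study

The generator emulates the structure of the motivating dataset — it is
the package's test bed, not a model of any particular orchard:

* **Genotypes.** Founder haplotypes follow a Gaussian-copula chain along
  each chromosome: a latent AR(1) process with correlation
  `exp(−d/decay)` (default decay 250 kb) thresholded at each locus's
  allele frequency. Defaults: 1273 loci on 8 chromosomes of 30 Mb,
  MAF ≥ 0.05.
* **Relatedness.** Every study individual descends from a pool of 16
  ancestors (two generations with recombination), plus `0.178·n_G`
  full-sib families of 3 whose offspring sit in the block of the largest
  location — reproducing both the reported dispersion of realized
  relationships (off-diagonal GRM variance of order 0.016) and the
  family-heavy composition of the largest trial. Recombination uses
  Haldane's map function at 465 kb/cM, no interference.
* **Design.** Four locations × two seasons with Venn-style overlap (only
  5 individuals present everywhere at the default size of 550),
  per-environment observation probabilities matching the reported
  per-season counts, environment means in Julian days (144–186), and a
  two-level planting-year effect at the first location.
* **Genetics.** Per-environment additive variances 26.5–111.3 and
  residual variances 8.1–20.0 (squared Julian days), giving h² between
  0.60 and 0.91; a single-factor covariance with loadings
  `λ_e = √(c_e·vG_e)` where the common fraction `c_e` is 0.995 for the
  three European-like locations and 0.80 for the Prosser-like one —
  implied correlations ≈ 0.995 within Europe, 0.89 Europe–Prosser, 0.80
  between the Prosser seasons.
* **Truth scaling.** Marker effects are drawn per locus with the
  structure's covariance and scaled so the *model* additive variance (the
  quantity REML estimates, referenced to the relationship-matrix scale)
  equals the target. Scaling to the realized sample variance of breeding
  values is available as an option but not the default: in a panel with
  family structure the sample variance conflates relatedness with scale,
  and forcing it to the target systematically inflates the truth for the
  unrelated subpanel (we observed h² biases of +0.1 that vanish under
  model scaling).
* **Reconstruction.** Every phenotype record stores its mean, planting
  year, breeding value and residual parts, so `y` reconstructs exactly
  and generators are pure functions of `(config, seed)`.

What passing tests on these simulations do **not** show: robustness to
genotyping error, non-additive genetic effects, selection, spatial field
trends, or real LD patterns (the copula chain has no coalescent
structure). Those are outside the model being fitted as well.

## Cross-validation

Adjusted phenotypes remove the full-data fixed-effect estimates (no
shrinkage). Within-location 5-fold CV assigns individuals to folds
stratified by location only — deliberately ignoring family structure, so
accuracy at the family-heavy location is flattered exactly as it is in
practice. PA is computed per location-by-set-by-season and averaged over
sets to season level (the aggregation most tables report); PACC divides
by √h² from the *full-data* fit (training-fold heritabilities would be
the alternative; the full-data convention is used because independent
estimates are generally unavailable), and `se = 1/√n` uses the
season-level validation count, which is the convention the published
standard errors reproduce. Training folds warm-start from the full-data
parameters; a fold that fails to converge falls back to those parameters
with a warning rather than being dropped. Leave-one-location-out CV drops
a location wholesale, refits, averages each dropped individual's
predictions over the preserved environments and correlates with the
dropped location's adjusted phenotypes per season.

## Problem sizes used in the checks

The test suite fits the model at `n_G = 160–400` and `m = 500–2000`; the
parameter-recovery check uses five seeded studies at `n_G = 400`,
`m = 2000` with the default design. The acceptance script runs the whole
pipeline at `n_G = 300`, `m = 1000`. These sizes were chosen so the full
suite runs in minutes on a single CPU while keeping every environment's
record count in the regime of the motivating study. One known limitation
follows directly from that regime: with ~40 records in the smallest
environments and three environment-specific parameters each, REML h²
estimates retain a finite-sample bias of up to ~0.06 even averaged over
seeds (the implied correlations recover within ±0.05). The likelihood
itself is oracle-verified, so this is a property of the estimator under
the design's unbalancedness, not of the implementation.

## Degenerate inputs and tie-breaks

Monomorphic loci are rejected by the GRM (filter first); all-missing loci
make imputation fail loudly; empty-panel filtering warns rather than
errors; duplicate (chromosome, position, name) map rows are rejected;
pedigree cycles are reported with the offending loop; a negative LRT
statistic (possible under non-convergence) is reported with `p = 1` and a
warning; imputation ties take the smaller dosage; the eigen-ordination
"variation explained" denominator is the sum of positive eigenvalues
(configurable to the trace).
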