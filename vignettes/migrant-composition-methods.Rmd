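---
title: "Methods: beta diversity, ordination and wing-shape analysis of island stopover data"
author: "migcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta diversity, ordination and wing-shape analysis of island stopover data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migcomp)
```

## The scientific setting

Small Mediterranean islands act as stopover sites for trans-Saharan
passerines crossing the sea in spring. Standardized ringing (constant
mist-net effort, fixed 16 April - 15 May window) on a set of nine western
Mediterranean islands yields, after eligibility filtering, a matrix of
island-year samples by species counts. The questions this package
addresses on such data are:

1. Is the composition of migrants at stopovers driven by how abundant
   each species is on the European continent?
2. How variable is migrant composition *between* islands versus *between
   years within* islands (beta diversity and its partition)?
3. Which island characteristics (geographic position and distances to
   land, versus area, altitude, vegetation) structure composition
   (constrained ordination), and how does each species respond (count
   models)?
4. Do species that respond to island area versus distance-to-southern-land
   differ in wing shape, once phylogeny is accounted for (PGLS)?

The study's ringing database is not public, so the package ships a
synthetic-data generator that reproduces the study's *design* (the real
nine-island descriptor table, the published number of used years per
island, 35 species spanning three orders of magnitude of continental
abundance) with a known generative model, and every analysis stage is
validated against it and against independent brute-force oracles.

## Eligibility filters and the chord transformation

Two filters mirror standard practice for this kind of ringing data: an
island-year is used only if nets ran on at least 7 distinct days in *each*
fortnight of the window (we read "at least one week of ringing in the
fortnight of each month" as >= 7 days per fortnight, both required — the
strictest consistent interpretation, configurable via `min_days`); and a
species is kept only if it was ringed in at least 5 separate years *or* on
at least 5 islands (a disjunction: regular-but-local and
widespread-but-sporadic species both stay; accidental captures drop).

Counts are then row-normalized to unit Euclidean norm (chord
transformation), \(y'_{rj} = y_{rj} / \sqrt{\sum_j y_{rj}^2}\), which
makes Euclidean distances equal chord distances (bounded by
\(\sqrt 2\)) and removes differences in total captures between samples —
the analyses concern *relative* composition. All-zero island-years are
removed (with a log entry) rather than erroring: the transform is
undefined for them and a season with zero captures of the study group
carries no compositional information.

## Beta diversity as total variance, and its partition

Total beta diversity is the total variance of the transformed matrix:
\(SS_{Total} = \sum_{ijk} (y_{ijk} - \bar y_j)^2\),
\(BD_{I,T} = SS_{Total}/(N-1)\), bounded by 1 under the chord transform.
Row and column shares of \(SS_{Total}\) give local (LCBD) and species
(SCBD) contributions, each summing to 1.

The partition replaces \(y_{ijk}\) by island means \(\bar y_{ij}\):

* between islands: \(SS_I = \sum_{ij} (\bar y_{ij} - \bar y_j)^2\),
  \(BD_I = SS_I/(n-1)\);
* within islands (temporal): \(SS_{Temp} = \sum_{ijk} (y_{ijk} - \bar
  y_{ij})^2\), \(BD_T = SS_{Temp}/(Y-n)\);
* per island: \(BD_{Ti} = SS_{Temp,i}/(Y_i - 1)\).

The exact ANOVA-type identity
\(SS_{Total} = SS_{Temp} + \sum_i Y_i \sum_j (\bar y_{ij} - \bar y_j)^2\)
is computed and returned (`identity_gap`); note the weighted
between-island term equals \(SS_I\) only under balanced designs — with
5-16 years per island the divisors genuinely differ, which is why the
generator defaults to the published unbalanced design. Degenerate inputs
are handled conservatively: identical samples give uniform LCBD/SCBD with
a warning (keeping the totals meaningful), islands with a single year are
excluded from \(BD_{Ti}\) but stay in the totals.

Per-island temporal variability is compared by ANOVA on log-transformed
yearly LCBD (log because LCBD is right-skewed), with Tukey HSD post-hoc.
The per-island summary reports both the raw mean LCBD (what a summary
table prints) and the mean log LCBD (what the ANOVA uses).

## Permutation tests of composition

`permanova()` implements one-way PERMANOVA directly in chord coordinates
(the chord space is Euclidean, so coordinate sums of squares equal the
Gower-centered distance formulation — asserted against both a naive
MANOVA-trace oracle and a double-centering oracle in the tests).
Permutations are unrestricted row-label permutations with the observed
statistic included in the reference set, \(p = (1 + \#\{F^* \ge
F\})/(n_{perm}+1)\); the repeated yearly samples are treated as
exchangeable replicates. `dispersion_test()` compares within-group scatter
via distances to group centroids (chord space is Euclidean, so centroids
rather than spatial medians), with the small-sample bias adjustment
\(\sqrt{m_g/(m_g-1)}\); its permutation scheme re-assigns raw rows to
groups and recomputes centroids. Pairwise island contrasts use
Benjamini-Hochberg FDR across all pairs. Default `n_perm` is 999 and a
seed is mandatory — permutation p-values are part of the reproducible
output.

## Constrained ordination

Descriptors are natural-log transformed (values below 0.1 km floored
first: the westernmost island has longitudinal coordinate 0 by
construction). Collinearity within each block (geographic; habitat) is
screened by iteratively removing the highest-VIF variable until all VIFs
are below 10. On the packaged nine-island table this removes minimum
distance to Africa and latitude, leaving a maximum VIF near 2.1.

`rda_fit()` regresses the centered chord matrix on the standardized
predictors and takes the PCA of the fitted values; \(R^2 =
SS_{fit}/SS_{total}\) with the Ezekiel adjustment \(R^2_{adj} = 1 -
(1-R^2)(N-1)/(N-m-1)\). Axis significance is sequential: axis \(k\) is
tested after residualizing response and predictors on the previous
canonical axes and permuting the residualized response rows. Axis signs
are fixed by orienting each axis so its dominant species loads positively
(eigenvectors are sign-arbitrary; this makes runs comparable).
`varpart2()` partitions \(R^2_{adj}\) between the geographic and habitat
blocks into unique fractions (testable) and the shared fraction (not
testable, as it is a difference of \(R^2_{adj}\) values, not a fit).

Two design points deserve emphasis:

* **Axis-descriptor significance.** Descriptors are constant within
  islands while axis scores vary between years; treating the 74 samples
  as independent would pseudo-replicate. Instead of a mixed model with an
  island random effect, significance comes from regressing island-mean
  axis scores on the island-level descriptor (n = islands): a
  fixed-effect approximation with the same exchangeability unit. The
  tests demonstrate that the naive per-sample test is anticonservative in
  exactly this situation while the aggregated test holds its size.
* **Forward selection** stops on the permutation p-value of the best
  candidate (greedy, so mildly anticonservative under pure noise — a
  property the tests document rather than hide). The optional adjusted-R²
  guard is off by default: with few informative and several noise
  predictors the full-set \(R^2_{adj}\) is diluted below that of a good
  subset, and the guard would veto clearly significant variables.

## Species response models

For each species, counts per island-year are modeled with a log link and
an offset that defines the response scale: the log of total captures of
the study group per island-year ("percentage of captures" mode) or the
log of net-length (hundreds of metres) times ringing days ("capture
rate" mode; stations flagged non-comparable — e.g. nets concentrated on an
attracting feature — are excluded there). Three families are considered:
Poisson, nbinom1 (variance \(\mu(1+\alpha)\), fitted by direct ML) and
nbinom2 (variance \(\mu + \mu^2/\theta\)); the family is chosen by AICc
on the null model, AICc counting \(k = p\) for Poisson and \(p+1\) for
the negative binomials.

The original mixed-model formulation (island and year random effects) is
replaced by a fixed-effect approximation: year enters as a fixed factor;
island identity is omitted from descriptor models because an island
factor is perfectly collinear with any island-level descriptor — the only
estimable fixed-effect analogue. Island-year passage fluctuations act as
observation-level overdispersion for a single species' regression and are
absorbed by the negative-binomial families.

Descriptors are z-scored (log scale) before adding quadratic terms.
A descriptor model is retained only if its AICc beats the null's; the
quadratic is kept over the linear only if the likelihood-ratio test
rejects at 0.05; effects are classified +/− from the linear term, or
"intermediate" when a retained quadratic has an interior extremum within
the observed range. Because descriptors are correlated across the nine
islands (log area and log distance-to-southern-land correlate at ~0.27),
a species' true response to one descriptor can leak into another tested
alone; the summary therefore also reports the *plausible set* (models
within 2 AICc of the species' best), which attributes each species to the
descriptor that actually carries its signal. On synthetic worlds with the
default planted pattern, plausible-set attribution recovers the planted
responders with zero to two spurious species per descriptor, while the
raw retained counts include the leakage.

## Wing shape and phylogeny

The Kipp index (100 × primary projection / wing length) measures wing
pointedness; wing aspect ratio is generated as a strongly correlated
companion trait. Group comparisons (e.g. area-responders versus the rest)
use GLS with residual covariance \(\sigma^2 V(\lambda)\), where \(V\) is
the Brownian phylogenetic covariance (MRCA depths) and \(V(\lambda)\)
scales its off-diagonals. Bivariate models include the interaction first
and drop it when non-significant; the \(\lambda\)-estimated and
\(\lambda = 0\) fits are compared by likelihood ratio and the simpler
model kept when the test is not significant. Coefficient t-tests use
\(n - p\) residual degrees of freedom.

\(\lambda\) is profiled by ML over the standard Pagel interval
\([0, 1]\) (grid of 41 points plus local refinement). The interval is a
deliberate choice: the admissible region extends below zero, but as
\(V(\lambda)\) approaches its positive-definiteness boundary the profiled
likelihood develops spurious spikes — the near-singular model asserts an
almost exact linear constraint on the tip values, and whenever the data
happen to lie close to orthogonal to the collapsing eigendirection the
profiled likelihood grows without bound. Unconstrained profiling
therefore pins \(\hat\lambda\) to the boundary and rejects the no-signal
hypothesis almost always even when the truth is \(\lambda = 0\).
Restricting to \([0, 1]\) removes the pathology; at the \(\lambda = 0\)
boundary the LRT null becomes the \(\tfrac12\chi^2_0 +
\tfrac12\chi^2_1\) mixture, so the \(\chi^2_1\)-referenced test is
conservative (size below nominal), which the acceptance checks assert as
size control. Analyses that require negative \(\lambda\) can widen
`lambda_range`; the lower end is then clamped where the smallest
eigenvalue of \(V(\lambda)\) falls under 1% of the mean tip depth.

## The synthetic-data generator

`simulate_ringing()` draws counts from
\[
\log \mu_{ijk} = \log(C_j s) + \beta_{0j} + b_i
  + \beta_{area,j}\,\widetilde{\log A_i}
  + \beta_{dsouth,j}\,\widetilde{\log D_i}
  + u_{ik} + \log E_{ik}
\]
with \(C_j\) continental abundance (log-uniform over \(10^{4.5}\) to
\(10^{7.5}\) pairs), \(s = 10^{-7}\) a global capture-rate scaling chosen
so that a median-abundance species yields counts of order ten per
island-year at the default effort, \(b_i \sim N(0, 0.2^2)\) an island
baseline, \(u_{ik} \sim N(0, 0.3^2)\) a year-passage effect,
\(E_{ik}\) the effort (300 net-metres × 30 days by default) and tildes
denoting centered natural logs (centering keeps \(s\) interpretable;
between-island count ratios are unchanged). Counts are nbinom2 with
\(\theta = 2\) by default — standardized ringing totals are overdispersed
relative to Poisson. The island covariates are the real nine-island
descriptor rows and the years per island are the published used-year
counts (5-16, 74 island-years in total), so synthetic data live on the
real design space, including its genuine collinearity among distance
variables.

The default planted pattern gives 10 of 35 species a strong positive
area response (\(\beta = 0.5\) per log-unit) and the next 20 a positive
southern-distance response (\(\beta = 0.4\)), mirroring the structure of
the study system's results; trait linkage makes area-responders more
pointed-winged and distance-responders rounder-winged
(`kipp = 25 + 10 β_area − 10 β_dsouth + noise`), with wing aspect ratio
an affine function of Kipp plus noise (correlation above 0.8). Trees are
pure-birth with unit depth.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: within-season daily dynamics (weather,
passage waves), recaptures and stopover duration, species-specific
phenology inside the window, spatial autocorrelation of year effects
across nearby islands, and any phylogenetic signal in the response
coefficients themselves. Recovery results on synthetic worlds validate
the estimators under the stated model, not the ecological conclusions.

## Problem sizes and numerical choices

The test-suite simulations use the sizes the analyses were designed
around: the full 74-island-year design for count-model recovery (300
replicates), 35-tip trees for \(\lambda\) recovery (300 replicates), 500
exchangeable-null datasets × 199 permutations for the size of the
permutation tests, and 100 random unbalanced matrices for the exact
partition identity (tolerance 1e-10 against a naive triple-loop oracle).
Permutation counts default to 999 in analyses. Ties in AICc selection
resolve to the simpler model (linear before quadratic, null before
either); eigenvector signs follow the dominant-species convention;
Cholesky factorization failures mark a \(\lambda\) value inadmissible
rather than erroring a whole profile.

## Known limitations

* The fixed-effect approximations (island-mean axis regressions; year
  factors in count models) are deliberate simplifications of the original
  mixed models; with 9 islands the island-level tests have little power,
  which is the honest price of respecting the exchangeability unit.
* nbinom1 ML uses direct numerical optimization with a Poisson start; for
  very sparse species (many zero island-years) the Hessian-based standard
  errors can be unstable, and family selection then typically prefers
  Poisson or nbinom2 anyway.
* The sequential axis permutation test conditions on the *observed*
  leading axes, a common but approximate scheme.
* LCBD comparisons between islands inherit the usual caveat that LCBD is
  a relative quantity: values depend on the island set analyzed.
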