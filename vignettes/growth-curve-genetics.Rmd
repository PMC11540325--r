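---
title: "Growth-curve genetics from repeated canopy measurements: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve genetics from repeated canopy measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageRR)
```

## The problem

Perennial forage trials measure the trait that matters — harvested
biomass — only a handful of times per season, at each cutting.  Drone
multispectral imaging measures the canopy weekly at plot level, for the
cost of a flight.  If vegetation indices (NDVI, GNDVI, NDRE, the raw NIR
band, and the simple ratio NIR/Red) are heritable and genetically
correlated with yield, breeders can rank cultivars from images instead
of harvest weights, and — because the images are longitudinal — study
*when* during regrowth cultivars diverge and how consistent each
cultivar's growth pattern is across cuttings and years.

forageRR implements that analysis chain: index computation, thermal-time
bookkeeping, per-flight variance components, random-regression growth
curves, indirect-selection efficiency, and two stability views (a GGE
biplot of the genotype-by-environment yield table, and a growth-curve
stability statistic).  Because plot-level data of this kind are rarely
public, the package ships a synthetic-trial generator whose ground truth
is fully recorded; every estimator is validated by parameter recovery
against it.

## Models

### Per-flight variance components

For one flight (time point) within one harvest cycle the plot model is

$$y = Xb + Zg + e, \qquad
  g \sim N(0, I\sigma^2_g),\; e \sim N(0, I\sigma^2_e),$$

with fixed replicate effects (cell-mean coding; the intercept is
absorbed into the replicate cells) and i.i.d. genotype effects.
Plot-level broad-sense heritability is the ratio
$H^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$.  Entries are cultivars
(synthetic populations), so no pedigree or marker decomposition is
attempted; $H^2$ is the repeatability-style quantity a plot trial
identifies.

A bivariate version with unstructured $2\times 2$ genetic and residual
covariance matrices, sharing the design across traits, yields the
genetic correlation $r_g$ between an index at the flight nearest harvest
and the harvested yield.

### Random-regression growth curves

All flights of a harvest cycle enter one longitudinal model,

$$\mathrm{VI}(t, j, r) = \beta_r(t) + \phi(t)^\top u_j +
  \phi(t)^\top p_{jr} + \varepsilon(t),$$

where $\phi(t)$ is the normalized (orthonormal) Legendre basis of degree
3 evaluated on standardized time
$t^* = 2(t - t_{\min})/(t_{\max} - t_{\min}) - 1$, $u_j \sim N(0, K_g)$
are genotype coefficient vectors, $p_{jr} \sim N(0, K_p)$ are
permanent-environment coefficients of the plot (the repeated unit), and
$\beta_r(t)$ is a replicate-within-time-point fixed cell.  The time axis
is cumulative growing degree days, $\max(0, (T_{max}+T_{min})/2 - 4)$
summed daily and reset the day after each harvest.

The fitted $K_g$ implies a covariance *function*
$\mathrm{Cov}_g(t, s) = \phi(t)^\top K_g \phi(s)$, from which the
package derives time-resolved heritability
$H^2(t) = v_g(t) / (v_g(t) + v_p(t) + \sigma^2_e(t))$, genetic
correlation curves $r(t, T)$ against a reference time, and per-genotype
breeding-value trajectories $\phi(t)^\top \hat u_j$.

Harvested yield can be appended as the final "time point" of the cycle
at the harvest-date GDD: it is first rescaled so its sample variance
matches that of the last flight (a pure scaling — plot ranking and all
correlations are unchanged), and the basis domain is re-standardized to
include the harvest time.  The genetic correlation curve against that
terminal record is the longitudinal analogue of the bivariate $r_g$.

### Selection efficiency and stability

Relative selection efficiency of indirect selection on an index is

$$\mathrm{RSE} = \frac{h_{VI}}{h_{FY}}\, r_g
             = \sqrt{H^2_{VI}/H^2_{FY}}\; r_g,$$

which depends on the heritabilities only through their ratio.

The GGE biplot environment-centers the genotype-by-environment mean
yield table, takes its SVD, and absorbs the singular values into the
genotype scores ("genotype-focused" scaling, $f = 1$ in the usual GGE
nomenclature — the source analyses name this scaling without defining
it, so the standard convention is adopted).  The average-environment
axis (AEA) is the direction of the mean environment score; projection on
it ranks mean performance, and the perpendicular projection measures
instability.  Sign conventions are fixed so results are reproducible:
PC1 is oriented so the mean environment score is positive (the AEA
arrow points toward higher yield) and PC2 so the first genotype's score
is non-negative.

The growth-curve stability statistic asks, per genotype, how much its
estimated genetic growth effect varies across cuttings.  At each
selected standardized time point the genetic effects are z-scored across
genotypes within each cutting, each genotype's deviations from its own
cross-cutting mean are taken, and their standard deviation is reported;
the same construction applied to per-cutting yield BLUPs gives a
comparable yield-stability SD.  Full z-scoring (center and scale, rather
than scaling alone) is used deliberately: it makes the statistic
invariant to affine rescaling of the raw index units *and* prevents a
cutting-level shift from leaking into every genotype's SD.

## Estimation

All three model classes are fitted by REML.  The driver is a monotone
EM algorithm on the mixed-model equations; each E-step uses the
conditional moments from the inverse coefficient matrix (fixed-effect
rows included, which is what makes the sequence maximize the
*restricted* likelihood), and each M-step updates
$K = m^{-1}\sum_j (\hat u_j \hat u_j^\top + C_{jj})$ and the residual
from expected squared residuals.  Three implementation points matter:

* **Plot-effect absorption.**  In the random-regression model the plot
  coefficient blocks are block-diagonal, so they are absorbed by a Schur
  complement each iteration.  The system actually factorized has
  dimension (replicate-time cells + genotypes x coefficients), e.g. 184
  for 36 genotypes at degree 3, instead of ~900; one EM step costs a few
  milliseconds.
* **Guarded acceleration.**  EM's reliable but slow tail is cut with a
  squared-extrapolation step (two EM steps, extrapolate, project back to
  the PSD cone, accept only if the restricted likelihood does not
  decrease).  With `accelerate = FALSE` the fit is a textbook EM
  sequence; the test suite asserts monotonicity of the trace in both
  modes.
* **Refinement.**  Where tight tolerances are needed (oracle-equivalence
  tests, boundary diagnosis) `refine = TRUE` finishes with a direct
  quasi-Newton maximization of the restricted log-likelihood over
  Cholesky factors — and, for the single-ratio single-trait model, an
  exact 1-D profiled-likelihood search.  This refinement stage was
  chosen over average-information steps inside the EM loop: it reaches
  the same optimum, keeps the EM iterates pure (so monotonicity is a
  testable invariant), and is considerably simpler to make robust near
  variance boundaries.

Numerical policies: covariance matrices are kept positive semidefinite
by eigenvalue clipping at a relative floor of 1e-8 ("bending"); clip
events are counted in the fit object.  Convergence is declared at a
relative restricted-log-likelihood change below 1e-8 (1e-10 for the
small single-trait fits); non-convergence is flagged, never silently
accepted.  A genetic variance driven to zero is reported as an explicit
boundary fit, and a genetic correlation whose denominator sits on that
boundary is `NA` with a warning rather than a number.  Degenerate
inputs (constant response, zero denominators in indices, missing
weather days, duplicated plot-flight rows, fewer distinct time points
than basis coefficients) are rejected or marked before any fitting.

## The synthetic generator: what it emulates, and what it does not

`simulate_trial()` draws data from exactly the random-regression model
above, for an RCBD trial of configurable size, with a saturating mean
curve plus small replicate offsets as the fixed effects, and one master
seed spawning independent per-component streams (genetic,
permanent-environment, residual, fixed, yield) so toggling one component
never changes another's draws.  `simulate_yield_from_curve()` appends
plot yield equal to the genotype's curve value at the harvest GDD plus
noise, so the true index-yield genetic correlation at any time is a
closed form in $K_g$ and the basis.  Cross-cutting instability is
generated by per-genotype coefficient deviations around a stable mean
vector, with a per-genotype scale.

Defaults mirror the emulated field studies: 24-36 cultivars, 4-5
complete blocks, 5-8 flights per cycle on a GDD axis of roughly 150-600
degree-days, residual standard deviation about half the genetic
standard deviation at mid-season, yield at plot-level heritability 0.5,
and a harvest GDD just beyond the last flight (the emulated trials flew
within days of harvest).  The permanent-environment effect is drawn per
plot — the genotype-by-replicate unit that is actually repeated across
flights — which is the identifiable choice in a single-trial fit.  The
residual is homoscedastic across flights by default, with a
per-time-point option; neither choice is asserted to be "the" structure
of any real trial.

What the generator does **not** emulate: raw imagery and its processing
chain (orthomosaics, plot polygons, pixel summaries), spatial field
trend, saturation nonlinearity of indices at canopy closure,
heteroscedasticity induced by weather at specific flights, or selection
among cultivars.  Passing parameter-recovery tests therefore shows the
estimators are correct for the stated model at realistic sizes — not
that the model captures every feature of field data.

## Design decisions on genuinely open points

* "Third order" Legendre is read as polynomial degree 3, i.e. four
  coefficients per random effect, matching the cubic shapes such models
  produce; genetic and permanent-environment terms share the order by
  default but are independently configurable.
* The orthonormal basis scaling is the default so coefficient
  covariances are comparable across orders; the plain polynomials are
  available (`normalized = FALSE`).
* Daily GDD increments are clamped at zero (standard agronomic
  practice); the unclamped variant is a flag, since the defining formula
  permits negative values on cold days.
* The terminal yield record is placed at the harvest-date GDD and the
  basis domain re-standardized to include it; the time coordinate of an
  appended yield record is otherwise arbitrary.
* Genetic correlation curves condition on the genetic surface only
  (permanent-environment effects excluded); whether to include them is
  ambiguous in this literature, and the genetic-only surface is the
  quantity with a selection interpretation.
* A fixed smooth time trajectory is *not* fitted alongside the
  replicate-within-time cells: the cells already saturate the
  time-mean structure, so a fixed regression on the basis would be
  aliased with them.
* Stability labels ("high/low yielding" x "stable/unstable") use median
  splits by default, with the thresholds exposed, because the verbal
  classifications they mirror have no published cutoffs.  The default
  time grid for the growth-stability statistic is five evenly spaced
  standardized points.
* The NIR band mean is carried as an index in its own right, unscaled.

## Problem sizes used by the validation suite

The test suite fits, among others: 6x2 and 36x5 single-trait instances
(the latter over 200 Monte-Carlo seeds for three generating
heritabilities), 200-seed bivariate recovery of $r_g = 0.8$, 100-seed
random-regression recovery of a known $K_g$ at 36 genotypes x 5
replicates x 8 flights with a 20-point genetic-correlation curve, and a
100-seed stability study at 24 genotypes x 5 cuttings with graded
instability.  These sizes were chosen to match the emulated trial
designs while keeping a full run of the suite in the minutes range on a
single core.  Oracles are independent implementations: explicit-V
restricted likelihoods with generic optimizers, balanced-design ANOVA
expected mean squares, `lme4` for the single-trait model, direct SVD
identities for the biplot, and Gauss-Legendre quadrature for basis
orthonormality.

## Known limitations

* Each harvest cycle is fitted separately; cross-harvest genetic
  covariance is summarized only through the stability statistics, not
  modeled jointly.
* No spatial correction, no genomic or pedigree relationship matrices,
  no spline bases, and no multi-trait random regression across different
  indices.
* The bivariate fitter requires both traits on the same plots (paired
  design), which is the situation it is used for here.
* EM near a variance boundary converges slowly; the refinement stage
  mitigates this, but boundary reports should be read as "the REML
  optimum is at or numerically indistinguishable from zero", not as a
  significance statement.
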