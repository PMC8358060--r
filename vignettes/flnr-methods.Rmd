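---
title: "Deriving and attributing the fraction of leaf nitrogen in RuBisCO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and attributing the fraction of leaf nitrogen in RuBisCO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Leaves couple photosynthetic capacity to nitrogen through RuBisCO. The
package is built around the allocation identity

$$V_{cmax}^{25} = \alpha^{25} \cdot LNC \cdot f_{NR} \cdot fLNR,$$

with $V_{cmax}^{25}$ the maximum carboxylation rate standardized to 25 °C
(µmol CO₂ m⁻² s⁻¹), $LNC$ area-based leaf nitrogen (g m⁻²),
$\alpha^{25} = 47.34$ µmol CO₂ g⁻¹ RuBisCO s⁻¹ the specific activity of
RuBisCO, $f_{NR} = 6.25$ g RuBisCO g⁻¹ N, and $fLNR$ the fraction of leaf
nitrogen allocated to RuBisCO, reported in percent throughout. Given a
gridded $V_{cmax}^{25}$ product and a gridded $LNC$, inverting the identity
yields an fLNR map; `invert_flnr()` is that inversion and
`forward_vcmax25()` its exact inverse (tested to machine precision, along
with the homogeneity of fLNR: degree +1 in $V_{cmax}^{25}$, −1 in each of
$\alpha^{25}$, $f_{NR}$, $LNC$).

Site Vcmax observations arrive at leaf temperature and are standardized
with a peaked Arrhenius response,

$$V_{cmax} = V_{cmax}^{25}\,
  \exp\!\left[\frac{H_a (T_l - T_{ref})}{T_{ref} R T_l}\right]
  \frac{1 + \exp\!\left(\frac{T_{ref}\Delta S - H_d}{T_{ref} R}\right)}
       {1 + \exp\!\left(\frac{T_l \Delta S - H_d}{T_l R}\right)},$$

with $H_a = 71513$ J mol⁻¹, $H_d = 200000$ J mol⁻¹,
$\Delta S = 649.12$ J mol⁻¹ K⁻¹, $R = 8.314$ J mol⁻¹ K⁻¹ and
$T_{ref} = 298.15$ K. The function equals 1 exactly at 25 °C and is peaked:
a single interior optimum, verified numerically on a 0.1 °C lattice over
0–60 °C. Interfaces take °C and convert to Kelvin internally. Temperature
acclimation of the parameters is deliberately not modelled, and the 0.08
floor on the correction factor is opt-in (`apply_floor`), since it belongs
to projecting model output at extreme temperatures, not to standardizing
field observations.

## Upscaling site observations

`fit_rf()` trains 200 bagged regression trees (the `randomForest`
ensemble; `mtry` and node size are library defaults, recorded in the model
bundle) on the site table, without species-abundance weighting. Predictor
choice is data-driven: `rank_importance()` scores all 20 candidates
(19 gridded layers plus the PFT class) by unscaled permutation importance
from one all-predictor ensemble, and `select_predictors()` feeds them
forward in ranking order, refitting the full ensemble at each step, until
the out-of-bag r² no longer increases *and* the out-of-bag MSE no longer
decreases (both read strictly, with an epsilon of 1e−6 absorbing float
jitter); the set before the failed step is kept. Categorical predictors
(PFT, Köppen) enter the trees natively as factors, so they are single
predictor units in ranking and selection — the same accounting as summing
one-hot importances, without the encoding.

Two validation modes are provided. Conventional cross-validation holds out
a random 20% per repetition. Spatial cross-validation additionally removes
every holdout row within 150 km great-circle distance (haversine on a
6371 km sphere — kilometres rather than degrees, because a degree of
longitude shrinks poleward) of *any* training row, applied per repetition;
repetitions left without validation rows are skipped with a warning. The
exclusion is verifiable post hoc: with `return_splits = TRUE` the report
carries the indices, and the tests brute-force all pairwise distances.
`predict_grid()` maps the ensemble over the vegetated cells and reports
the per-tree standard deviation as the map's uncertainty layer.

## Uncertainty propagation

The fLNR map's uncertainty has four sources: the $V_{cmax}^{25}$ map sd,
the $LNC$ uncertainty (itself propagated from LNCm and SLA draws in
`compute_lnc()`), and the literature ranges of $\alpha^{25}$
([47.34, 60.0]) and $f_{NR}$ ([6.11, 7.16]). `bootstrap_flnr()` draws, per
iteration, one $\alpha^{25}$ and one $f_{NR}$ uniformly over their ranges
(shared across cells — a constant is a single physical quantity), and
per-cell Gaussian draws of the map quantities, truncated positive by
redrawing (redraws are counted). Uniform distributions are used where only
ranges are published and Gaussians where sds are published; per-cell map
draws are independent across cells (whether spatially coherent
perturbation would be more faithful is unknowable from the published sds;
the choice is documented here and only affects spatial statistics of the
uncertainty field, not per-cell sds).

The single-source decomposition varies one source and holds the other
three at their *means* — range midpoints for the constants, map means
otherwise. Holding the constants at their published defaults instead would
bias the decomposition: the ranges are one-sided above the defaults, so
every "fixed" denominator would sit ~12% low and the single-source sds
~16% high in quadrature relative to the total. With midpoints the
quadrature sum matches the total sd within a few percent (tested at 15%
tolerance), while the map *mean* itself is still the deterministic
inversion at the published defaults, as in the source derivation.

## Attribution

Drivers are grouped as leaf traits (LPC, LMA — LNC is excluded because it
sits in fLNR's denominator), climate (Tair, PP, PAR, VPD, SWC) and soil
(soilC, soilN, CN, pH, sand, silt, bulkD, CEC). Each group is z-scored and
eigendecomposed (`group_pca()`; deterministic sign convention: the
largest-magnitude loading of each component is positive; zero-variance
variables are dropped with a warning). `fit_attribution_gam()` fits

$$fLNR \sim PFT + \textstyle\sum_{g}\sum_{k\le 3} s(PC_{g,k}),$$

with penalized cubic regression splines of basis dimension 10 and
smoothness by GCV — none of this is prescribed by the science, so the
defaults are ordinary `mgcv` practice; a linear truth is recovered with
negligible smoothing bias because linear functions sit in the spline's
unpenalized null space. Per cell, a group's total effect is the sum of its
smooth terms; dominance is the argmax of $|effect_g| / \sum_g |effect_g|$;
area fractions report the share of cells where a group's share exceeds its
threshold (0.50 / 0.30 / 0.15 for leaf traits / climate / soil; cells
unweighted by default, cosine-latitude weighting would be a one-line
extension). Group effects are invariant under rotations of a group's PCs
since only their sum enters.

Per-variable sensitivities come from ordinary least squares of each
group's total effect on that group's *raw* variables, merged into one
equation per scope; the intercept is assembled as
$\overline{\widehat{fLNR}} - \sum_v a_v \bar{x}_v$ so the equation is
centered on the fitted model. Per-PFT equations refit the group OLS on
that PFT's cells (minimum 200, else skipped). `fit_flnr_equation()` is the
*direct* path — one multivariate OLS of fLNR on the six equation variables
— used for coefficient-recovery experiments because it is free of the
PCA+GAM route's smoothing and subspace bias.

### Identifiability of the PCA+GAM route

Only the top three PCs of each group enter the model. If a group's
variables were mutually independent, its sample covariance would be
near-isotropic, the leading eigenvectors would be arbitrary rotations, and
a 3-component bottleneck on a 5- or 8-variable group could not represent
an arbitrary coefficient direction: per-variable recovery through the
PCA+GAM route would be impossible in principle, not merely noisy. Real
climate and soil stacks are nothing like isotropic — their variables are
strongly mutually correlated and the leading component carries most of the
group variance — and that structure is exactly what makes a truncated PC
basis adequate. The generator therefore exposes `correlate_groups`: the
climate variables other than VPD/PAR and the soil variables other than
pH/sand load on one latent field per group (variance share 0.6), so the
informative directions are leading eigendirections and coefficient
recovery through the full route succeeds (within 5% in the tests; exact up
to numerical tolerance through the direct path). The flag defaults to off
for generic use; the pipeline configuration and the recovery experiments
turn it on.

## The synthetic globe

The generator emulates the *shape* of the study inputs, not Earth:
masked half-degree grids (cell centres at half-degree offsets, latitude
index south to north — stated in the NetCDF metadata), smoothed Gaussian
random fields affinely rescaled into documented ranges (LMA 20–250 g m⁻²,
LPC 0.05–0.25 g m⁻², VPD 0.2–3 kPa, pH 4–8.5, PAR 200–1200 µmol m⁻² s⁻¹,
sand 10–90%, …), PFTs and Köppen classes as latitudinal bands with 15%
categorical noise (every class is guaranteed cells, which the per-PFT fits
need). Traits are coherent with the covariates: SLA = 1000/LMA exactly,
and LNCm (5–18 mg g⁻¹) is anticorrelated with LMA (variance share 0.5),
the leaf-economics trade-off that keeps LNC = LNCm/SLA and hence Vcmax25
in realistic ranges.

The ground truth is fLNR = −0.19 LMA + 42.2 LPC + 4.76 VPD + 0.25 pH +
0.0026 PAR + 0.032 sand + 2.4 (percent), plus per-PFT offsets and Gaussian
noise (default sd 2%). The offsets (forests ~19, non-forests ~25) are a
generator condition chosen once so the synthetic globe has a global mean
fLNR near the observed ~18% with forests below non-forests; they are
needed because the equation's published intercept absorbs real-world
covariance between predictors and goes negative when evaluated over
independent mid-range covariates. Degenerate draws are floored at 1%
(conservative against the ~5% minimum seen in real maps) with a warning
and a count; recovery experiments disable both the offsets and the floor,
since flooring censors a linear target. Observations are drawn in uniform
discs around cluster centres, with an optional scattered fraction
(`p_scatter`; the pipeline uses 0.25) — isolated sites are realistic for
trait compilations and are the only ones that can survive a 150 km
exclusion buffer on a window a few thousand kilometres across. Observed
Vcmax is the true Vcmax25 projected to a uniform random leaf temperature
(10–35 °C) plus Gaussian noise (sd 5 µmol m⁻² s⁻¹, non-positive draws
redrawn).

What the generator does **not** emulate: true geography and spatial
covariance of real climate/soil products, seasonal or within-canopy
variation, observation biases of trait databases (species composition,
campaign clustering by road access), and any covariance between predictor
*groups*. Passing tests therefore demonstrate the correctness and
statistical behaviour of the machinery under controlled conditions, not
the real-data values of the derived quantities — the published real-data
headline numbers depend on proprietary inputs and are documented as
context only, never asserted.

## Numerical choices and problem sizes

Seeds: one global seed expands deterministically into per-stage seeds
(`expand_seeds`), all below 2³¹; every stochastic routine takes an explicit
seed and is bitwise reproducible. Truncated Gaussian draws redraw rather
than clip (counted). The OOB stopping rule uses epsilon 1e−6. OLS condition
numbers above 1e8 are logged, not fatal. JSON reports round to 10 decimal
places so identical runs are byte-identical.

The shipped experiments are sized for a desk machine: the pipeline world
is 40 × 80 cells with 600 sites, 200 trees, 10 CV repetitions and 1000
bootstrap draws (~10 s); the recovery experiments use n = 2000 uniform
cells (direct path) and a 60 × 80 noiseless world (PCA+GAM path); the test
suite uses smaller worlds throughout. These sizes are the package's own
choices — estimates sharpen with n in the usual √n way.

## Known limitations

- EM1/EM2/EM5 require externally published per-PFT coefficients; the
  shipped YAML is a labelled synthetic placeholder, so those models'
  outputs index code behaviour, not the published models. EM3/EM4 carry
  their printed constants and accept no overrides.
- Optimality models (EO, LUNA) are supported only as external maps fed to
  `compare_maps()`; their internals are out of scope.
- The attribution is associative, not causal: additive group structure, no
  interactions, chlorophyll excluded from the leaf-trait group (it is an
  upscaling predictor, not an attribution variable).
- k25 variability (the kinetic constant inside alpha25) is not modelled;
  alpha25 and fNR are treated as global constants with uncertainty ranges.
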