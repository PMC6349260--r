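---
title: "Ensemble-weight calibration and satellite retrieval of crop state: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-weight calibration and satellite retrieval of crop state: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Regional crop growth modelling faces a chicken-and-egg problem: mechanistic
simulators need field-level agromanagement inputs (planting date and
density, cultivar maturity, fertilisation) that are unknown at county scale,
while satellite reflectance observes every field but does not directly
reveal the crop state variables a simulator works with. `simcal` implements
a two-stage answer for rainfed maize:

1. **Ensemble-weight calibration.** For every county-year, a daily crop
   simulator is run over a factorial grid of agromanagement combinations
   (by default 3 planting densities x 2 seed brands x 8 relative maturities
   x 2 nitrogen rates x 3 planting-date percentiles = 288 combinations).
   A single simplex-constrained weight vector `w` — interpretable as the
   share of fields grown under each combination — is fitted so that the
   weighted ensemble reproduces observed county yields and growing-season
   lengths.
2. **Retrieval networks.** The calibrated weighted ensemble supplies, for
   every county-year, continuous state-variable trajectories (LAI, leaf and
   aboveground biomass, leaf nitrogen, harvested organ biomass, layered
   soil moisture), a yield, and per-day phenological stage fractions. Three
   bidirectional LSTM networks are then trained to predict those targets
   from 29-step, 7-band surface reflectance series alone, under
   county-blocked 10-fold cross-validation.

Because the real inputs (satellite reflectance, gridded weather and soil,
county yield surveys, crop-progress reports) are not redistributable, the
package ships a first-class synthetic-data generator that emulates their
statistical structure, with the hidden truth retained so that every stage
of the pipeline can be tested for parameter and prediction recovery.

# The calibration model

With `X_i` a quantity simulated under combination `i` and `w` on the
probability simplex, the calibrated prediction of any continuous quantity
is the mixture `X_c = sum_i w_i X_i`. For the discrete phenological stage,
the weights are read as field fractions: the predicted fraction of fields
in stage `m` on day `d` is the summed weight of combinations whose stage
sequence sits in `m` that day.

The weights are fitted by minimising, over the county-years `k` of a
calibration unit,

    sum_k [ (Y_k - sum_i w_i Y_ik)^2 / sigma_Y^2
          + (P_k - sum_i w_i P_ik)^2 / sigma_P^2 ]
    s.t.  w_i >= 0,  sum_i w_i = 1,

where `Y` are yields (simulated attainable yields first reduced by the
yield-gap factor, default 15%), `P` are growing-season lengths (maturity
minus emergence, days), and `sigma_Y`, `sigma_P` are the standard
deviations of the observed series, which put the two terms on a common
scale. The objective is a sum over all county-years in the unit; a single
printed county-year would not identify a shared weight vector. The sigmas
are computed over the current calibration subset; when a subset is too
small to carry its own standard deviation (a corner reachable under the
leave-one-out scheme below), the full-dataset sigmas are used instead, so
that small training subsets still produce predictions rather than being
dropped.

**Solver.** The problem is a convex quadratic program over the simplex. No
QP routine being part of the package's dependency set, `fit_weights()`
implements a primal active-set method: starting from the best single
combination, it alternates equality-constrained least-squares solves on the
working support with Karush-Kuhn-Tucker screening of excluded
combinations, stepping to the boundary and dropping a blocking weight when
a subproblem solution leaves the feasible set. A ridge of `1e-12` times the
mean Gram diagonal keeps the subproblems well posed when ensemble columns
are collinear (common: combinations differing only in an inert factor). The
contract is optimality, not the algorithm: the tests compare the attained
objective against a brute-force minimum over a 0.01-resolution simplex grid
on small instances and require agreement within `1e-6`.

**Validation.** Skill is measured by leave-one-out cross-validation with a
deliberately strict exclusion rule: the weights used to predict a
county-year are fitted on records that share *neither its county nor its
year*. Headline metrics are the LOO R-squared (squared Pearson correlation;
`1 - SSE/SST` is also reported), the LOO RMSE, and the explained standard
deviation `ESTD = 100 (1 - RMSE_county / sigma_overall)` which compares a
county's LOO error with the overall yield variability.

**Clustering.** Counties can be grouped either by weather climatology
(k-means on 36 standardised features: per-calendar-month means of daily
minimum temperature, maximum temperature and precipitation over the study
years) or by geographic proximity (k-means on centroid coordinates), with
one weight vector per cluster; clusters are then screened by keeping those
with LOO yield R-squared strictly above 0.40. Features are standardised
before k-means because the units are mixed (degrees C vs mm); k-means uses
10 restarts with the best inertia kept. Both choices were open in the
method description; they are fixed here and recorded in the configuration.

# The retrieval networks

All three networks share the same trunk: 7 reflectance bands enter a stack
of 3 bidirectional LSTM layers of 30 units per direction (a sequence of 29
8-day steps, Julian days 109-333), each step's representation carrying
both past and future context. All trainable layers have bias inputs, with
biases initialised to 1. The heads differ by target type:

- **physical**: one linear channel per state variable per step; squared
  error on targets z-scored per variable *using training folds only* (the
  scaler is part of the model; recomputing it with test data included is a
  leakage bug, and a dedicated test trips on it).
- **yield**: one channel whose 29 per-step outputs are averaged into a
  single scalar; squared error on the z-scored yield. The average runs over
  all 29 steps, taken literally from the design it follows.
- **phenology**: one channel per merged stage with a per-step softmax and
  cross-entropy against stage fractions (fractions are probabilities that a
  field is in a stage, so a probabilistic head is the natural choice).

**Stage merging.** Six merged stages are used: pre-emergence,
emergence-juvenile, floral initiation-pre-silking, silking/flowering,
grain fill, and maturity/post-harvest. The five transitions between
consecutive stages (emergence, floral initiation, silking, start of grain
fill, maturity) are the dates evaluated downstream. The original
finer-grained stage catalogue and its merging table are not available;
this six-stage mapping is consistent with those five transitions and is
fixed in the configuration.

**Training.** The BLSTM core (forward pass, backpropagation through time,
and the three heads) is implemented in C++ via RcppArmadillo with a flat
parameter vector; the R side runs minibatch Adam (default learning rate
3e-3, batch 32 — chosen once for single-CPU desk scale and recorded in the
configuration; the contract is the property suite, not the hyperparameters).
Training stops when the validation loss has not improved for 30 consecutive
epochs, and the best-validation parameters are returned. Training is
deterministic given the seed.

**Cross-validation.** Counties (not county-years) are randomly assigned to
10 folds of near-equal size. For each evaluated fold, the remaining nine
folds split into six training folds and three validation folds (the three
folds cyclically following the test fold — a fixed, documented rule); the
held-out fold receives out-of-fold predictions from a network that never
saw its counties in either role.

# Evaluation surface

- **Per-timestep metrics**: for each step and variable, the R-squared of
  out-of-fold predictions across county-years, and the percentage
  uncertainty reduced `PRU = 100 (1 - CVRMSE_pred / CVRMSE_mean)`, where
  the baseline predictor for a county-year is the target mean over the
  *other* folds at that step — the baseline never sees the evaluated fold.
- **Derived ratios**: specific leaf area `SLA = LAI * 1e4 / leaf biomass`
  (m^2 kg^-1; the LAI is converted to leaf area per hectare so the ratio
  has conventional units) masked where LAI <= 0.1 or leaf biomass <= 1 kg
  ha^-1; leaf nitrogen percentage `LNP = leaf N / leaf biomass` masked
  where leaf biomass <= 1 kg ha^-1 or leaf N <= 0.001 kg ha^-1. Thresholds
  are strict inequalities.
- **Transition dates**: from a stage-probability matrix, the cumulative
  fraction of fields at or past the post-transition stage is made monotone
  by a running maximum (network outputs need not be monotone), treated as
  piecewise linear between grid days, and summarised by the *mean* of the
  implied distribution ("average date" is ambiguous between mean and
  median; the mean is implemented as the headline and the median is also
  exposed). A curve that never exceeds 0.5 yields a missing date.
- **Stage confusion**: argmax stage per step pooled over county-years and
  steps into a confusion matrix; Cohen's kappa summarises agreement.
- **Aggregation**: unweighted county-to-region means (weights optional).

# The synthetic-data generator

The generator emulates, per county-year, everything the analysis consumes.
It is the package's definition of the study conditions, not a tuning knob.

**Counties.** 50 counties on a 6 x 10 degree domain with a north-south
temperature gradient (-0.45 degrees C July maximum per degree latitude) and
an east-west precipitation gradient (-2.5 mm/month per degree longitude),
plus county-level deviations (sd 0.4 degrees C, 6 mm/month), lognormal
soil water-capacity factors (log-sd 0.22) and soil brightness factors
(sd 0.08). Years are 2008-2011 and 2013-2016 — eight years, with the
extreme-drought year 2012 left out — giving 400 county-years at default
scale.

**Weather.** Daily series from monthly climatologies: interannual
temperature anomalies (sd 0.9 degrees C) and lognormal precipitation
factors (log-sd 0.22); AR(1) daily temperature noise (sd 2.2, lag-0.6);
Bernoulli-gamma wet-day precipitation (wet fraction 0.33); seasonal solar
radiation (7-24 MJ m^-2 d^-1) damped on wet days. Maximum temperature
dominates the diurnal range by construction, so `tmax >= tmin` always.
Setting the precipitation noise scale to zero reproduces the monthly
climatology exactly — the noise-free limits of the generator are exact, a
property the tests lean on throughout. Planting-date percentiles are read
off a synthetic planting-progress curve centred where the 10-day running
mean temperature first reaches 12 degrees C (clamped to days 105-140,
spread 6 days).

**Surrogate crop simulator.** A deliberately compact daily model with the
qualitative structure of a mechanistic maize simulator, vectorised across
the combination grid:

- *Phenology*: growing degree days, base 10 with a 30/10 cap/floor;
  emergence at 105 GDD after planting; later thresholds scale linearly
  with relative maturity (floral initiation at `105 + 3.3 RM`, silking at
  `105 + 6.6 RM` for brand A and `105 + 6.2 RM` for brand B — same
  maturity total, different flowering, mirroring how seed brands differ —
  grain fill `1.5 RM` after silking, maturity at `105 + 11.5 RM`). A crop
  that has not matured by day 365 is censored there; one that never
  emerges stays at stage 1 with zero trajectories.
- *Canopy*: logistic LAI expansion in normalised emergence-to-silking
  thermal time with amplitude `0.72 x planting density`, growth damped by
  stress, then power-law senescence to zero at maturity.
- *Biomass*: intercepted radiation (extinction 0.65) times a radiation-use
  efficiency of 1.85 g MJ^-1 (brand B 3% lower), reduced by the minimum of
  the water- and nitrogen-stress factors; leaves take 45% of aboveground
  biomass until silking; grain fills along a harvest-index ramp to 0.50.
- *Soil water*: a cascading four-layer bucket (one surface + three
  subsurface layers; the layer count was an open choice and four keeps a
  surface signal distinct from a root zone), layer capacities 25/45/60/70
  mm scaled by the county factor; root access opens with thermal time;
  water stress is supply over demand.
- *Leaf nitrogen*: a dilution curve (3.5% of leaf mass at low biomass
  declining with a -0.25 power, floor 1.2%) scaled by the applied-nitrogen
  factor, and senescing faster than leaf biomass.

Units follow reporting conventions: yields Mg ha^-1, biomass kg ha^-1,
LAI dimensionless, volumetric soil moisture between a lower limit of 0.12
and a drained upper limit of 0.30.

**Forward reflectance.** A two-flux mixing model per band:
`rho = rho_soil exp(-k LAI) + rho_veg (1 - exp(-k LAI))`, on the MODIS-like
band set (red, NIR, blue, green, 1240 nm, 1640 nm, 2130 nm). The soil term
darkens with surface moisture (soil background dominates at low LAI); the
vegetation asymptote greens with leaf nitrogen percentage in the visible
and brightens in the SWIR as the root zone dries. NIR is monotonically
increasing, and red decreasing, in LAI by construction. Additive Gaussian
noise (default sd 0.01, low-noise preset 0.004) is clipped to [0, 1].
Optionally a small fraction of county-years (10%) loses up to two interior
steps, refilled by linear interpolation in time — mirroring how sparse
gaps are handled in the real 8-day composites.

**Observations.** Hidden "true" weights (12 active combinations with
Dirichlet weights, shared globally by default so that a single fitted
vector can in principle reproduce all observations) mix the ensemble:
observed yield is `(1 - 0.15) x` the weighted attainable yield plus noise
(default sd 0.55 Mg ha^-1, low-noise 0.15), observed season length the
weighted maturity-minus-emergence plus noise (sd 4 days, low-noise 1.5),
and the stage-fraction curves are the weighted stage indicators. Additive
Gaussian noise is the simplest model whose zero-noise limit makes the
recovery tests exact. The true weights are retained in the records for
parameter-recovery tests only; nothing downstream reads them.

# What the synthetic data does and does not show

The generator reproduces the *structure* the method relies on: a shared
agromanagement mixture, weather- and soil-driven spatial and interannual
yield variability, reflectance that is a noisy nonlinear function of the
weighted state trajectory, and surveys that are noisy mixtures of the same
ensemble. Passing the recovery tests therefore shows the pipeline is
internally correct and statistically well posed at this scale.

It does not show performance on real data: the forward reflectance model
is far simpler than a canopy radiative-transfer model, the surrogate has
none of a real simulator's process detail (no nitrogen cycling, pests,
heat-stress physiology, or cultivar-specific responses), the true mixture
really is shared across counties (only approximately true of real
agromanagement), and the observation noise is Gaussian and independent.
Headline numbers from the real study are consequently not reproduction
targets here; the package's acceptance checks are structural (exact
counts, solver optimality, metric identities) and property-based
(recovery at reduced scale, negative controls).

# Numerical choices and degenerate inputs

- Active-set tolerances: KKT screening at `1e-8` relative to the gradient
  scale; weights clipped at `-1e-12` and renormalised; iteration cap 2000.
- Z-scaling guards: zero-variance variables scale by 1 instead of 0.
- R-squared via Pearson correlation returns 0 (not NA) when either side is
  constant; per-step metrics skip steps with fewer than two finite pairs.
- Transition curves: running-maximum monotonisation, mass at the first
  grid day attributed to that day, renormalisation when the curve tops out
  below 1, missing when it never exceeds 0.5.
- Degenerate calibration sets (zero observed variance) are an error unless
  fallback sigmas are supplied; LOO supplies the full-dataset sigmas.
- County-years whose LOO exclusion empties the training set are omitted
  with a warning rather than silently dropped.
- The 29-step grid is fixed (days 109, 117, ..., 333); trajectories must
  cover it and are sampled exactly on it.

# Problem sizes used by the tests and the acceptance script

Unit tests run on a reduced 8-combination grid over 6 counties x 3 years.
The end-to-end checks use the full 288-combination grid at the default
domain size (50 counties x 8 years = 400 county-years) under the low-noise
preset, with an epoch cap of 200 and two evaluated folds of the 10-fold
cross-validation per seed, repeated over three seeds with a majority rule;
the negative control retrains on reflectance shuffled across county-years
and requires the skill to vanish. The acceptance script runs the
calibration stage (including the full leave-one-out sweep) on a
default-noise dataset and the retrieval stage on a low-noise dataset at
the same scale. These sizes are the package's documented reduced-scale
study conditions.

# Known limitations

- The surrogate's phenology is purely thermal; photoperiod and frost are
  ignored, and very long maturities in cool synthetic counties censor at
  day 365 rather than failing.
- One weight vector per calibration unit cannot express within-county
  mixture differences; this is inherent to the method, not the artifact.
- The yield head averages all 29 steps, including pre-planting ones.
- Network results are reproducible only up to compiler/BLAS determinism;
  acceptance-style checks use tolerance bands, never exact floats.
- State-to-county survey interpolation is out of scope; synthetic season
  lengths are generated directly at county level.
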