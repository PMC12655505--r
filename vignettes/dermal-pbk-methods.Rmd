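---
title: "Methods: bottom-up dermal PBK modelling with dermalpbk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up dermal PBK modelling with dermalpbk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermalpbk)
```

`dermalpbk` implements a bottom-up workflow for predicting systemic
exposure to a topically applied compound from in vitro and in silico data
alone, with clinical data reserved for external validation. The worked
example throughout is the UV filter oxybenzone applied in sunscreen
formulations under maximal-use conditions. This vignette documents the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data machinery does and does not establish.

## The dermal model

The in vitro simulator (`simulate_franz()`) represents a static diffusion
cell: a finite, evaporating vehicle film on top of three skin layers -
stratum corneum (SC), viable epidermis (VE), dermis (DE) - over a stirred
receptor chamber. Transport in each layer is 1-D Fickian diffusion with a
layer diffusivity $D_x$ (cm^2/s) and a water-referenced partition
coefficient $K_{x/w}$. Interfaces impose flux continuity and continuity of
the water-referenced activity $C_a/K_{a/w} = C_b/K_{b/w}$, which makes the
parameter set exactly the one the refinement machinery works with
($K_{VH/w}$, $D_{SC}$, $K_{SC/w}$, $D_{VE}$, $K_{VE/w}$, $D_{DE}$,
$K_{DE/w}$) and lets layer-to-layer coefficients be derived as ratios.

Model assumptions, all deliberate simplifications:

* **Well-mixed vehicle.** The film is thin (about 20 um at 2 mg/cm^2), so
  no spatial grid is used for it; the vehicle diffusivity only matters
  through an optional donor boundary-layer resistance that is off by
  default (it is reported to be an insensitive parameter).
* **Evaporation and exposure.** The vehicle volume shrinks linearly at the
  measured evaporation rate down to its residual fraction. Dissolved
  concentration rises as volume is lost, capped at the vehicle solubility
  with the excess held as an undissolved depot. At the application
  (exposure) time - by default the evaporation time
  $t_{evap} = V_{dose}(1 - f_{res})/r_{evap}$ - the vehicle-skin flux is
  switched off and remaining solute is stranded: once the film has dried,
  penetration stops. Both the "exposure = evaporation time" rule and a
  user-set exposure are supported; neither is privileged, because a dried
  film ending exposure is an assumption, not an observation.
* **Finite, sampled receptor.** The 3 mL receptor is a well-mixed
  compartment, not a perfect sink; each of the 15 samplings replaces
  300 uL with fresh buffer and the simulator applies the matching
  dilution. `receptor_bookkeeping()` reconstructs cumulative permeation
  from sampled concentrations exactly as a laboratory would.
* **No skin metabolism, no appendageal pathway.** The measured skin S9
  clearance of the example compound is negligible; a clearance hook exists
  in the chemical record but the dermal model does not consume it.
  Follicular/sebum transport is out of scope.
* **Wash arms.** Termination arms at 4/16/24 h carry no feedback into the
  running cell, so layer amounts at wash times are read from one
  continuous simulation rather than separate truncated runs.

Numerically, each layer is discretized by a finite-volume method of lines
(20 cells/layer for reporting, 10 for fitting; the SC is thin and stiff
against the dermis, which is why cells are allocated per layer).
Cell-to-cell fluxes use two half-cell resistances in the activity
variable, so the same expression covers intra-layer edges and partition
jumps at interfaces. Time integration is `deSolve::lsoda` with a banded
Jacobian, relative tolerance 1e-8 for reporting and 1e-6 inside
optimization loops. The engine reproduces the analytic membrane series to
about 0.01% at 40 cells and the solution changes by well under 0.5% when
the grid is doubled; mass balance is enforced to 0.5% and a violation is
an error, not a warning.

## Closed-form parameter estimation

The isolated-dermis experiment is fitted with the classical lag-time
solution of Fick's second law for a membrane between a constant donor and
a sink,

$$Q(t) = m_1\left(m_2 t - \tfrac16 - \tfrac{2}{\pi^2}\sum_{n=1}^{N}
\frac{(-1)^n}{n^2} e^{-m_2 n^2 \pi^2 t}\right),$$

with $m_2 = D/L^2$ and $m_1 = C_d K L$. Under this convention the
late-time slope $m_1 m_2 = C_d K D / L$ is the steady-state flux and the
intercept gives the lag time $L^2/6D$; the alternative reading
$m_1 = C_d K D/L$ is dimensionally inconsistent with $Q$ being an amount
per area, which is why the package adopts the classical form and recovers
$K_{DE/veh} = m_1/(C_d L)$ and $D_{DE} = m_2 L^2$. The series is truncated
at $N = 200$ with an explicit alternating-series tail bound (warning above
`1e-9 * m1`); at $t = 0$ the sum equals $-\pi^2/12$ exactly and the
function returns exactly zero. Starting values for the nonlinear fit come
from a straight line through the late points (slope $m_1 m_2$, intercept
$-m_1/6$), and the fit runs on log-parameters to enforce positivity.

Evaporation curves are reduced to a residual fraction (plateau over
initial mass) and a rate taken as a robust Theil-Sen slope over the first
25% of the mass loss - the early, linear part of the dry-down; no fitting
rule is standard for these curves, so a robust slope on the linear phase
was chosen and is exercised against exponential-decay generators as well.

Systemic constants follow standard IVIVE practice: hepatic plasma
clearance uses the non-restrictive well-stirred equation
$CL_{liver} = Q_{liver}\, CL_{int}\, R_{bp}/(Q_{liver} + CL_{int})$
(appropriate for a highly bound solute whose extraction is not limited by
plasma binding), renal clearance is $f_{up} \times GFR$, and in vitro
intrinsic clearance scales by mg protein per g liver (default 100) times
liver mass (default 1650 g at 70 kg). The in vitro clearance value and the
scaling constants for the example compound are not published, so the
defaults were chosen to put hepatic elimination in the flow-limited
regime, which is the reported behaviour; the resulting systemic clearance
is validated for order of magnitude, not equality.

## First-tier (in silico only) dermal parameters

`l1_insilico_dermal()` fills the parameter set from published
correlations when no skin data exist: the Potts-Guy permeability
correlation split into its lipophilicity (partition,
$K_{SC/w} = 10^{0.71\,\log P}$) and size (diffusion,
$D_{SC}/L_{SC} = 10^{-2.7 - 0.0061\,MW}$ cm/h) terms; a molecular-weight
correlation for free aqueous diffusivity; fixed hindrance factors for the
viable tissue layers; and two-phase water/lipid partition coefficients
with small effective lipid fractions. These are first-tier estimates whose
job is to let the whole chain run and to sit in the right order of
magnitude - the refined (second-tier) parameters are what the validation
rests on.

## The whole-body model

`simulate_plasma()` couples the dermal grid to a 13-compartment
perfusion-limited body (adipose, bone, brain, gut, heart, kidney, liver,
lung, muscle, skin, spleen, reproductive, rest) with arterial/venous blood
pools, gut and spleen draining through the liver, elimination in liver
(well-stirred) and kidney (filtration). The physiology table (volumes,
flows, tissue composition for a 70-kg reference adult, from standard
compilations) ships as CSV; volumes scale with body weight, flows with
body weight to the 3/4 power. Tissue/plasma partition coefficients come
from a documented tissue-composition method
($Kp = f_{up}\,(f_w + P f_{nl} + (0.3P + 0.7) f_{ph} + B)$ with
$P = 10^{\log P}$), which for the example compound yields a steady-state
volume in the hundreds of litres, consistent in magnitude with the
reported value. Model states are blood amounts; plasma concentration is
venous blood concentration divided by the measured blood/plasma ratio,
because that ratio is a printed, sensitive input and keeping the
conversion explicit keeps its sensitivity visible.

Two dermal couplings are provided. The default couples the basal boundary
of the dermis grid directly into venous blood as a diffusive sink -
capillary blood concentration (order 0.1 ug/mL) is negligible against
skin-tissue concentrations (order 10^3 ug/mL). The alternative first-order
mode transfers solute at `ksys` per hour from the dermis amount; the
default rate is the leading diffusion eigenmode of a slab with a sealed
top and absorbing base, $k_{sys} = (\pi^2/4) D_{DE}/L_{DE}^2$, a declared
approximation to integrated dermis-uptake models. The two modes agree on
cumulative absorption at 24 h to within 20% on the worked example, and the
first-order mode is retained because that rate constant is reported to be
a dominant driver in this model family.

One structural parameter deserves emphasis: the in vivo dermis depth to
the absorbing boundary. Capillary uptake in real skin is distributed
through the vascular plexuses; a boundary-sink model needs an effective
depth. The package default is 500 um (mid-dermis). With the packaged
ground truth this reproduces single-dose absorption kinetics peaking
around 5 h; a papillary-plexus-only depth (250 um) makes absorption
markedly faster and an end-of-dermis depth proportionally slower. The
choice is documented here precisely because predictions are sensitive to
it; it is a fixed default, not a fitted quantity.

Repeated applications reset the vehicle film (amount, volume, evaporation
clock) without clearing the skin depots, and stranded residue stays in the
mass balance. Simulations can be extended day-by-day until the daily
maximum changes by less than 1% when steady state is requested.

## Two-stage refinement

Stage 1 (`stage1_chemical_fit()`) fits the chemical-specific parameters
($D_{VE}$, $K_{VE/w}$, $K_{DE/w}$, optionally $D_{DE}$ when it has not
been measured directly) jointly across all formulations' kinetics - one
shared value per parameter, each formulation keeping its own
formulation-specific values. Stage 2 (`stage2_formulation_fit()`) then
fits $K_{VH/w}$, $D_{SC}$, $K_{SC/w}$ and the application time per
formulation with the stage-1 values frozen, inside finite bounds that
should come from the extremes reported in the literature (the shipped
defaults span a factor of 30 around the start). Three relative weightings
of the squared-error objective are available ($1/Y^2$, $1/\hat Y^2$,
$1/(Y+\hat Y)^2$); stage 2 tries all three and selects the lowest
objective, breaking ties by receptor-curve RMSE, mirroring the dual
criterion of "lowest objective and a receptor-consistent profile".

Numerics: fits run in log10 parameter space under box constraints with
`minpack.lm::nls.lm`. The forward-difference Jacobian step is set well
above the inner ODE tolerance (`epsfcn = 1e-6`, i.e. steps of about 0.1%
of a log-parameter) - with the default machine-epsilon step the Jacobian
measures solver noise and the optimizer stalls; this was the single most
important numerical choice in the package. A Latin-hypercube multistart is
available (`n_starts`); the default is a single start because the
log-space objective proved smooth enough that multistarts never changed
the optimum in the closure tests, and start values are taken from
first-tier estimates or bound midpoints. Observation and prediction grids
are matched (fitting simulations use the same 10-cell grid as the
generators) so that closure tests measure estimation error, not
discretization mismatch; with matched grids, noiseless recovery is exact
to optimizer precision and recovery at 5% noise is within a few percent
for stage 1 and within 20% for the less identifiable stage-2 set (the
exposure time and $D_{SC}$ trade off against each other through the
delivered amount, which is the expected degeneracy of finite-dose data).

## Model performance machinery

* `pk_metrics()`: Cmax/Tmax at the sampled maximum; AUC by linear-up/
  log-down trapezoid (standard NCA practice; the source workflow does not
  state its rule); AUC to infinity via log-linear terminal regression,
  reported as undefined with a reason when the profile is still rising at
  the cutoff or the terminal fit is unconvincing (R^2 < 0.9 or
  non-negative slope).
* `fold_validation()`: predicted/observed ratio and fold deviation
  $\max(r, 1/r)$ per metric, pass at 2-fold; the pass decision is
  symmetric under swapping the roles.
* `sensitivity_scan()`: normalized local coefficients
  $S = (\Delta y/\Delta x)(x/y)$ from central +/-5% perturbations
  (one-sided values also reported). Classes: high >= 0.5, medium >= 0.2,
  low >= 0.1 - and an explicit fourth class, negligible, below 0.1,
  because the three-band rule leaves that interval unassigned and silently
  extending "low" would hide it. Values sitting exactly on 0.2 (which two
  bands claim) classify by first match from the top, i.e. medium.
* `uncertainty_eval()`: Monte-Carlo sampling with log-normal parameter
  distributions, median at baseline ($\sigma^2 = \ln(1+CV^2)$), type-7
  quantiles, metric $(p_{97.5}-p_{2.5})/p_{50}$, classes high >= 2,
  medium >= 0.3, low below. For a log-normal passthrough the metric is
  analytically $2\sinh(1.96\sigma)$, which anchors the tests.
* `reliability_matrix()`: low iff (high sensitivity, high uncertainty);
  high iff sensitivity low/negligible and uncertainty low; medium
  otherwise; the mapping is replaceable.
* `population_simulate()`: uniform demographics (default 18-70 years,
  50-90 kg, half male), allometric physiology scaling, log-normal
  parameter variability, and a summary carrying arithmetic/geometric
  means, CV%, extremes, a 90% CI of the mean and the 5th-95th population
  interval - both intervals, because either reading of a "90% interval"
  exists in published tables. Population size is a parameter (published
  analyses in this family report 100, 500 and 2500 in different places).

## Synthetic data: what it emulates and what it does not

No raw measurements from the source study are available, so every dataset
shape the pipeline consumes has a generator with known ground truth:
replicate Franz-cell studies (donor thickness jitter 907 +/- 246 um
truncated at 2 SD, multiplicative log-normal noise, the 15-point receptor
schedule and 4/16/24 h wash arms), isolated-dermis curves on the 10-point
schedule, evaporation weight-loss curves, and clinical-like profile sets
with heavy-tailed inter-subject variability. Noise is multiplicative
log-normal because amounts are positive and dispersion is reported as CV.

The packaged ground truth uses every printed value where one exists
($D_{DE}$ = 1.27e-7 cm^2/s, $D_{VH}$ = 7.5e-6 cm^2/s, the chemical's
properties, doses, areas, demographics). The unpublished
formulation-specific values were fixed once to make the simulated study
reproduce the reported magnitudes - a strongly solute-retaining vehicle,
SC as the dominant depot, receptor recovery of a few percent at 24 h,
systemic absorption of a few percent of the applied dose, and
dose-normalized absorption comparable between formulations (the reported
in vitro comparison found no significant formulation difference after
dose normalization). Passing the closure and validation tests therefore
shows that the pipeline recovers what generated its data and that the
full chain reproduces clinical-scale exposure from in vitro-scale inputs;
it does not show that these parameter values are the true properties of
any real formulation.

## Problem sizes and determinism

Default problem sizes were picked so the whole chain stays comfortable on
a single core: 10-20 finite-volume cells per layer, 8 donors per
formulation, 4 formulations in stage 1, hundreds of subjects in
population analyses, and Monte-Carlo sizes of 100-20,000 depending on the
quantity. Every stochastic entry point takes a mandatory seed and is
bit-reproducible given it; the deterministic chain is reproducible
byte-for-byte under identical configuration.

## Known limitations

* The vehicle is a single well-mixed phase; drying films that form crusts
  or phase-separate are outside the model.
* Partition and diffusion coefficients are constants, while in a drying
  film they drift with composition; refined values are therefore
  effective averages over the exposure.
* The boundary-sink dermis coupling compresses distributed capillary
  uptake into one effective depth (see above).
* The physiology is a documented simplification: 13 lumped compartments,
  weight-only allometry, no age- or sex-specific organ composition.
* First-tier correlations are used outside the hydration state they were
  derived for; partial hydration is approximated, not modelled.
* Local +/-5% sensitivity only; no global (variance-based) analysis.
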