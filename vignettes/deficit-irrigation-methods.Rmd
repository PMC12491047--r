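---
title: "Methods: water-driven maize simulation and deficit-irrigation optimization"
author: "aquadeficit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-driven maize simulation and deficit-irrigation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices made where the
design was open, and what the shipped tests do and do not demonstrate.

## The problem

Drip-irrigated maize in an arid continental climate (roughly 100 mm of annual
rain against 3,500 mm of potential evaporation) receives essentially all of
its water through twelve scheduled drip events. Deficit irrigation supplies a
stated fraction (60/80/100%) of crop evapotranspiration (ETc) in selected
growth stages, trading yield against water savings. The package asks the
follow-on question: given a *fixed seasonal quota*, how should the twelve
event depths be distributed across growth stages to maximize yield and
water-use efficiency (WUE = yield / seasonal evapotranspiration)?

The toolchain has four layers:

1. a daily **water-driven crop simulator** (AquaCrop-style);
2. **EFAST** global sensitivity screening of its parameters;
3. a **dual physics-informed neural surrogate** trained on designed simulator
   runs under a soil-water-balance residual and a multiplicative crop water
   production function, with **dynamic reconstruction** (low-rank trajectory
   features plus a stall-triggered adaptive mechanism);
4. a **bilevel CMA-ES/GA optimizer**: the evolution strategy fits the
   surrogate parameters, the genetic algorithm searches quota allocations,
   and every winning schedule is re-simulated for verification.

## The crop simulator

The simulator is water-driven in the classical sense: biomass is proportional
to transpiration, not to intercepted light. State advances daily.

**Phenology.** Thermal time `GDD = max(0, min(Tavg, 30) - 8)` (base 8 °C —
the standard maize value, configurable; upper threshold 30 °C from the
calibrated profile). The shipped profile places emergence at 151, flowering
at 1607, senescence onset at 1822 and maturity at 2521 GDD. Four stages are
delimited at 0.35 × flowering GDD (a jointing proxy), flowering, senescence
onset and maturity; the paper-style stage names (initial, rapid, mid, late)
carry 2/4/3/3 of the twelve drip events.

**Canopy cover.** Cover starts at `den × ccs` (plant density times seedling
cover, 0.00376 for the shipped profile), grows exponentially at `cgc` per
GDD below half the maximum cover, relaxes exponentially toward the maximum
`mcc` above it, and decays at `cdc` per GDD after senescence onset. Water
stress scales the growth exponent (expansion stress) and can start early
decay (senescence stress). Field LAI measurements can be converted to cover
with the shipped allometric relation `CC = 1.005 (1 - e^{-0.6 LAI})^{1.2}`,
clipped at 1 — the raw asymptote 1.005 is an artifact of the fitted
coefficients, so clipping is the physically safe choice.

**Water stress.** All stresses are driven by the root-zone depletion
fraction `p` of total available water (TAW, field capacity minus wilting
point over the rooted depth). Each stress has an upper threshold (onset), a
lower threshold (complete) and a convex response
`Ks = 1 - (e^{s·Drel} - 1)/(e^s - 1)`. The shipped thresholds: canopy
expansion 0.20–0.65, stomatal closure 0.65–1, early senescence 0.50–1,
pollination 0.80–1.

**Soil water.** A single bucket over the monitored 1.0-m profile. Daily
order: add irrigation and rain, remove actual evapotranspiration, spill the
excess above saturation as runoff, drain a `tau` fraction (default 1,
instantaneous) of the excess above field capacity. The daily balance closes
to machine precision — the test suite requires < 1e-9 mm on every day of
every run — which is why the bucket depth is fixed: a bucket that grows with
the roots would either leak mass or require an explicit "new soil water"
source term. Root growth instead enters through the depletion fraction and
the extraction cap, both computed over the currently rooted depth (linear in
thermal time from 0.3 m to the 2.05-m potential, truncated at the bucket).
Water-table contributions are ignored (the site water table sits at 2–4 m).

Soil hydraulic values: field capacity 0.3607 m³ m⁻³ is the site measurement;
wilting point 0.17 and saturation 0.45 m³ m⁻³ were chosen once as values
consistent with a loam of bulk density 1.47 g cm⁻³ and are configurable. The
initial profile is 30% TAW depleted, an arid pre-season condition.

**Evapotranspiration partition.** Transpiration
`Tr = Ks_sto · kcb · CC · ET0` with `kcb = 1.1` at full cover, reduced under
senescence in proportion to canopy loss (`kcdcl`). Soil evaporation
`E = 1.1 (1 - CC) ET0`, suppressed late in the season (`evladc`) and —
important under drip — limited by the evaporable water in the top 0.10 m:
drip events wet only a `wetted_frac` (default 0.3) of the surface, rain wets
all of it. Without this supply limit a daily-irrigated season evaporates
unrealistically (seasonal ET near the ET0 total and WUE a third of observed
values); with it, seasonal ET and WUE land in the observed range for this
system. This is a single-stage scheme; the two-stage drying cycle of more
detailed models is intentionally out of scope.

**Biomass and yield.** `ΔB = wp · Tr/ET0` grams per m² per day (normalized
water productivity `wp = 39.7 g m⁻²` for the shipped profile) once 12 GDD
have accumulated. Yield is biomass times an adjusted harvest index: the
reference HI (0.49) builds linearly over 900 GDD after flowering; mild
pre-flowering stress raises it by at most `hipsflo = 3%`, damped by
`1/(1 + hinsveg · stress)` so severe vegetative limitation cancels the
bonus; depletion beyond the pollination threshold during flowering reduces
it multiplicatively. The adjusted HI never exceeds `hi (1 + hinc) = 0.5635`.
Temperature-driven pollination failure and salinity effects are implemented
as simple switches and are inactive by default; the salinity thresholds are
stored but inert.

**Reference (unstressed) runs.** Maximum evapotranspiration `ETm,i` per
stage and maximum yield `Ym` come from a companion run with the profile
refilled to field capacity every evening; the refill is booked as irrigation
so even the reference run closes its balance exactly. An unstressed run has
`ETa,i = ETm,i` identically.

## Weather generation and reference evapotranspiration

The generator emulates the target site statistically: an annual temperature
sinusoid (mean 12 °C as fitted over the warm season, amplitude 17 °C, peak
mid-July, Gaussian daily noise, ~13 °C diurnal range), a compound
Bernoulli–exponential rain process (wet-day probability 0.08, mean event
4 mm, giving a growing-season expectation near 58 mm — the warm-season share
of the ~100 mm annual normal), truncated-normal sunshine reduced on wet days,
and normal wind and humidity with a wet-day humidity shift. The 180-day
default series always covers the 2521 GDD to maturity. What it does *not*
emulate: multi-day synoptic persistence, heat waves, within-season trends,
or inter-annual variability structure — so passing tests demonstrate model
behavior under plausible arid forcing, not skill against observed weather.

ET0 follows the standard daily Penman–Monteith computation for the grass
reference, with sunshine converted to solar radiation through the Angström
relation (a = 0.25, b = 0.50 — the standard defaults; the site dataset
records sunshine hours, not radiation) and zero soil heat flux at the daily
step. The implementation is pinned against an independent step-by-step hand
calculation in the test suite.

## EFAST sensitivity screening

The extended FAST estimator assigns each parameter in turn the maximum
interference-free frequency `ω = ⌊(Ns-1)/(2M)⌋` along a search curve
`x = 0.5 + (1/π) asin(sin(ω s + φ))`, with the complementary parameters on
low frequencies and seeded random phases (M = 4 harmonics, the standard
choice). First-order indices are the spectral variance share at the driving
frequency and its harmonics; total-order indices are one minus the share of
the low-frequency complementary band. The sample-size rule `Ns ≥ 65 k` is
enforced; Ns need not be odd. Screening keeps parameters with Si > 0.05 *or*
STi > 0.10 (strict inequalities, union rule), ordered by STi.

The estimator is validated on the Ishigami benchmark at Ns = 3500 per curve
against the analytic decomposition (S1 = 0.3139, S2 = 0.4424, S3 = 0); the
total-order estimate for the interaction-only parameter is biased slightly
low (≈0.21 against the analytic 0.24 at this budget), a known property of
band-counting FAST estimators, and well inside what the screening rule
needs. Default parameter ranges for crop-parameter screening are ±25% of the
calibrated values, truncated where ordering invariants (e.g. depletion
thresholds below 1) would break; published ranges do not exist for this
profile.

## The dual physics-informed surrogate

Two small tanh networks share one architecture (2 hidden layers × 17
neurons, linear heads — the calibrated network size):

- the **soil-water net** maps `(z, t, d₁..d₄)` to volumetric water content,
  where `d_i` are the per-stage irrigation depths of the schedule (divided
  by 100 to be O(1));
- the **crop net** maps `(t, d₁..d₄)` to canopy cover and cumulative
  biomass; predicted yield is the season-end biomass through the reference
  harvest index.

Inputs are standardized against the training design. Training data are
Latin-hypercube-designed simulator runs (per-stage ETc fractions in
[0.4, 1.1], trajectories subsampled every 10 days).

**The physics terms.** The loss is `L = w_d L_d + w_f l_h` with the
calibrated weights `w_d = 1/500`, `w_f = 1`. `L_d` is the mean squared
mismatch of standardized soil moisture, cover, biomass and final yield.
`l_h` adds two residuals:

1. *Water balance.* The conservation form `∂θ/∂t + ∂q/∂z − S = 0` evaluated
   at Latin-hypercube collocation points (default 8000; scaled runs use
   fewer) with derivatives taken **analytically through the network** (a
   fused forward pass propagates value, ∂z, ∂²z and ∂t in one sweep — no
   finite differences). The flux law is the package's central modelling
   choice, since none is prescribed for this term:
   `q = −D_w ∂θ/∂z + K_drain max(0, θ − θ_fc)`, a diffusive term plus a
   drainage term that switches on above field capacity (defaults
   `D_w = 1e-4 m² d⁻¹`, `K_drain = 0.5 d⁻¹`). The source `S(z, t)` is the
   training run's own bucket forcing, `(I + P − ETa − D − R)/depth`,
   interpolated in time — so a surrogate that reproduces the simulator
   exactly has zero residual.
2. *Production function.* The multiplicative (Jensen-type) crop water
   production function `Ya/Ym = Π_i (ETa_i/ETm_i)^{λ_i}` ties the predicted
   relative yield to the run's stage-ET ratios. The stage sensitivity
   exponents λ are never published for this system; the defaults
   (0.25, 1.0, 0.8, 0.3) encode the rapid/mid stages as most sensitive, and
   `fit_lambda()` estimates them from simulator runs by log-linear least
   squares polished with a bounded linear-scale refinement (the linear scale
   is what the loss penalizes). No shipped check depends on the default λ
   values. Groundwater recharge is fixed at zero (deep water table).

Manufactured-solution tests (constant, linear-in-time, and separable
`sin(z)·t` fields with analytically constructed sources) drive the residual
evaluator to zero, and the loss decomposition is exact by construction:
`L_d = 500, l_h = 0` gives `L = 1`.

**Training.** The full loss is not differentiable end to end (the flux
switch, the season-end readout, the clipped ratios), so training is
evolutionary: separable (diagonal-covariance) CMA-ES over the ~900 stacked
network parameters — the standard CMA-ES variant for dimensions this large;
the full-covariance implementation is used for low-dimensional problems and
is validated separately. The initial step size 0.208 is the calibrated
learning-rate scale × 100. The paper-scale budget (17,600 inner iterations)
is the default; scaled runs (2,000 generations) are used throughout testing
and reduce the loss by two orders of magnitude from random initialization.

## Dynamic reconstruction

Two mechanisms:

- **Low-rank trajectory features.** Column-centered SVD of the stacked
  simulator trajectories (θ, CC, scaled biomass); the retained rank is the
  smallest reaching 99% cumulative energy. The reconstruction map is the
  additive form `u = f_NN + D(z)` with `D` the linear map through the
  retained orthonormal modes — the simplest structure satisfying the
  additive decomposition; an autoencoder alternative is out of scope. The
  identities tested: exact additivity, orthonormality, and the
  rank-r error equal to the discarded singular value energy.
- **Adaptive adjustment.** Each generation, the trainer inspects the
  best-loss history. If no relative improvement above 1e-3 occurred over the
  patience window (200 generations in scaled runs, 2,000 at full budget)
  *and* a physics residual exceeds its tolerance (1e-4), the corresponding
  residual weight doubles (never decreases; capped at 32) and zero-mean
  Gaussian noise is added to the output-layer and second-hidden-layer
  parameters only — never the input layer — with scale 0.05 × parameter RMS
  decaying ×0.7 per trigger. All trigger values are configuration, as the
  mechanism is described only qualitatively in its source; events are
  logged (epoch, term, new weight, noise scale).

## Bilevel optimization

The outer loop is a real-coded GA on the 12-event allocation simplex:
tournament selection (size 3), blend crossover (α = 0.5), Gaussian mutation,
and clip-renormalize repair with a per-event depth bound (default 60 mm, a
drip-feasibility choice exposed in configuration). The ETc-proportional
equal-split schedule at the same quota is seeded into generation zero, and
elitism makes the best fitness non-decreasing — together with final
simulator verification this *guarantees* the reported optimized yield is at
least the baseline yield in direct-simulator mode. In surrogate mode the
surrogate ranks candidates, only the winner is re-simulated, and the
baseline is reported if verification contradicts the surrogate's ranking.
The default objective is yield (with WUE reported alongside); a scalarized
`0.7·yield/ȳ + 0.3·WUE/w̄` option exists because both quantities are said to
improve without a stated trade-off rule. The inner (surrogate) loop trains
once per outer run; a per-generation co-evolution mode is deliberately not
implemented (a single stabilized inner network reused by the outer search
matches the published workflow).

Paper-scale budgets (18,000 outer iterations) are defaults in
configuration; every entry point takes a scale factor, and the shipped
checks run the scaled budget (population 24, 60 generations), at which the
optimizer typically finds 5–11% verified yield gains over the
ETc-proportional baseline at a 472-mm quota, with the reallocation favoring
the rapid and mid stages at generous quotas.

## Problem sizes and determinism

Scaled study sizes used by the shipped tests and the reproduction script:
180-day seasons; 50 seasons for conservation checks; 20 seeds × 3 supply
levels for monotonicity; Ns = 3500 × 3 curves for the Ishigami benchmark;
2,000 collocation points for manufactured-solution checks; 50 designed runs
× 2,000 generations for surrogate smoke training; GA 24 × 60 for
optimization. These sizes were chosen so the whole battery runs on a single
CPU in minutes while every qualitative claim stays testable at full budget
through configuration. Every stochastic component takes an explicit seed;
one global seed fans out to per-module seeds through a documented integer
hash, so modules are independently reproducible.

## Known limitations

- The simulator is a single-bucket, single-crop, daily model: no layered
  Richards dynamics, no CO₂ or fertility response, no curve-number runoff,
  no two-stage soil evaporation. It is a transparent stand-in for a
  full-featured water-driven model, not a re-implementation of one.
- Absolute yields (~11 t ha⁻¹ full-supply) and WUE (~18 kg hm⁻² mm⁻¹) under
  the synthetic climate sit below the best field values for this system;
  all shipped checks therefore assert *relative* quantities (gains,
  orderings, closures), never absolute field numbers.
- The deficit-yield response is smooth by construction; real multi-stage
  compounded deficits show threshold behavior the production-function layer
  only approximates.
- EFAST total-order estimates carry a small negative bias at moderate
  sample sizes; screening thresholds absorb this.
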