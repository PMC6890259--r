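---
title: "Modelling postprandial adipose tissue lipid fluxes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postprandial adipose tissue lipid fluxes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoflux)
```

## The problem

During a mixed meal challenge, the abdominal subcutaneous adipose tissue
takes up circulating triglyceride (TG) and glucose and releases (or, at
times, takes up) non-esterified fatty acids (NEFA) and glycerol.
Arteriovenous sampling — simultaneous blood draws from an arterialised
hand vein and the vein draining the tissue — combined with tissue blood
flow measurement turns concentration differences into tissue fluxes:

  flux = (arterial − venous) × ATBF,

in µmol per 100 ml tissue per minute, with uptake positive and release
negative. A [U-13C]palmitate meal tracer additionally quantifies the
*fractional spill-over*: the fraction of NEFA liberated by lipoprotein
lipase (LPL) at the endothelium that escapes into plasma instead of
entering the adipocyte.

`adipoflux` implements a two-compartment kinetic model (plasma + lumped
interstitial adipose space) of these fluxes under delayed insulin
control, together with the estimation, identifiability and
model-selection machinery needed to parameterise it from 7-point meal
challenge data, and a synthetic cohort generator that emulates the
sampling design end to end.

## The model

Arterial concentrations of insulin, glucose, TG, glycerol and NEFA are
*forcings*: sampled at −30, 0, 60, 120, 180, 240, 300 min, interpolated
piecewise-linearly, and extrapolated as constants outside the sampled
range. The model never feeds back on them.

**Insulin delays.** Insulin acts through transcription, translocation
and secretion steps that take minutes to hours. Two damped insulin
signals are produced by three-compartment linear cascades
(`delay_chain_rhs`), each with a single time constant: a long delay
`tau_lpl` gating LPL lipolysis and a shorter delay `tau_at` gating the
intracellular effects (GLUT4 transport, lipolysis inhibition,
re-esterification). For a step input the final compartment follows the
Erlang(3) response `1 − e^(−t/τ)(1 + t/τ + t²/2τ²)`, which the tests use
as an analytic oracle.

**The five modelled flux series** (uptake-positive convention):

* TG: `tg_flux = k_ad · [TG_art] · I_LPL` — linear LPL kinetics,
  stimulated by the delayed insulin signal.
* Spill-over fraction: `f = (d_spill/100) · I_B / [I_art]`, clamped to
  [0, 1] — inversely proportional to arterial insulin, equal to
  `d_spill`% at basal insulin `I_B`.
* Glucose: `glut1·[G_art] + glut4·[G_art]·I_AT`.
* Glycerol: LPL releases one glycerol per TG hydrolysed; plasma and
  adipose glycerol exchange along the gradient at rate `p_gly`, with the
  local plasma concentration elevated by the LPL release; stored-TG
  lipolysis (`atl_rate = b_atl + atl_max/(1 + I_AT/k_atl)`) feeds the
  adipose pool.
* NEFA: three fatty acids per TG hydrolysed, split exactly into spill
  (`3f·LPL`) and adipose influx (`3(1−f)·LPL`); gradient exchange at
  rate `p_nefa` against the spill-elevated local plasma concentration;
  the adipose pool gains `3·atl_rate` and loses NEFA to insulin-
  stimulated re-esterification `3·k_reester·I_AT·[NEFA_AT]·[G3P_AT]`.

**Glycerol-3-phosphate supply.** A fraction `frac_use` of glucose uptake
is routed to G-6-P and on to G-3-P (two trioses per glucose), through a
two-compartment delay with constant `tau_g3p`; the adipose G-3-P pool is
consumed stoichiometrically by re-esterification.

This gives 11 states (two 3-state insulin chains, adipose glycerol,
NEFA, G-6-P, G-3-P production, adipose G-3-P) and 14 estimable
parameters; basal insulin `I_B` comes from the forcing (mean of the two
fasting samples), not from estimation.

### Sign conventions

Published statements of models in this family are not mutually
consistent in sign: glucose-uptake terms are sometimes written negative
while glucose is taken up, and glycerol/NEFA equations are written
release-positive while measured fluxes are uptake-positive. The package
fixes *one* convention — measured flux = (arterial − venous) × ATBF,
uptake positive — and maps every model flux onto it: TG and glucose
uptake are positive; the model glycerol flux is
`−(LPL release + adipose→plasma diffusion)` and the model NEFA flux is
`plasma→adipose diffusion − spill`, so fasting glycerol/NEFA release is
negative, matching the measured series.

### Numerical choices

* Integration: `deSolve::lsoda` (adaptive, stiff-capable) with a
  compiled C right-hand side, rtol 1e−8 / atol 1e−10. The meal at t = 0
  is implicit in the forcing data; there is no discrete event. Halving
  the tolerances changes the flux curves by < 1e−6 relative (tested).
* Initial state: the simulation starts at t = −30 at the *fasting fixed
  point*, solved algebraically (delay chains at `I_B`; adipose glycerol
  `= GLY_art + LPL + atl/p_gly`; steady re-esterification equals G-3-P
  production, which fixes adipose NEFA and G-3-P). Parameter regions
  where no non-negative fixed point exists (e.g. G-3-P production with
  zero re-esterification capacity) raise an initialisation error; the
  fitting layer converts this into an infinite cost so optimisers simply
  avoid the region.
* Delays of exactly zero are rejected rather than divided by: the
  undelayed model variants used in term comparison are separate
  algebraic terms (`lpl_term_variants()`), never a τ → 0 limit.
* The spill fraction is clamped to [0, 1]: the raw expression is
  unbounded as arterial insulin approaches zero, and a fraction must
  stay physical.
* An optional first-order adipose glycerol sink (`k_sink`, default 0)
  reproduces the variant of the glycerol balance with unexplained
  glycerol disappearance; its functional form (first-order decay) is a
  documented placeholder, as no mechanistic form is established.
* Units: time min; insulin µU/ml (1 µU/ml = 6.0 pmol/l, converted only
  at the I/O boundary); metabolites mmol/l; ATBF ml/(100 ml tissue·min);
  fluxes µmol/(100 ml tissue·min). The adipose pool equations treat
  µmol/100 ml/min and mmol/l/min as numerically interchangeable — the
  tissue-volume factor is absorbed into the exchange-rate parameters.
  Units of `k_reester` and the G-3-P pools are fixed by this internal
  convention; they are not anchored to an external standard.

## Estimation

The fitting target is, per flux series, the cross-subject mean µ_i and
standard deviation σ_i at the 7 sampling times. The cost is

  C(p) = Σ_series Σ_i ((M(p, t_i) − µ_i)/σ_i)²,

with equal weight across series (the σ-normalisation is the only
weighting; SEM is used in plots only, never as a weight). Points with
zero or undefined dispersion are excluded with a warning, as are
tracer spill-over points before the meal (no label present). Late
(> 180 min) spill-over points stay in the fit — label recycling inflates
their σ, which down-weights them naturally; there is no hard cutoff.

`fit_global` runs a Price-style Controlled Random Search over the bound
box (population max(10·dim, 250), seeded with 250 uniform draws,
stopping at 1e−8 relative spread or the evaluation cap), refines the
best population points with bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`), adds one *divide-and-conquer* start — each flux
series' dominant parameters fitted separately in low dimension from
moment-based heuristics (fasting flux levels fix the rate-constant
scales), then assembled into a joint start — and finishes with a short
basin-hopping polish:
lognormal perturbations of the incumbent, re-refined locally, with
parameters pinned at a bound resampled log-uniformly across the box.
The polish matters: the glycerol and NEFA exchange rates relax the
adipose pools within minutes, so on an hourly sampling grid there is a
broad quasi-equilibrium valley (large `p_gly` behaves almost like any
other large `p_gly`) that traps purely local refinement started from
the CRS population. Everything is reproducible from one integer seed.

Levenberg-Marquardt finite-difference steps are set well above the ODE
solver's error floor (`epsfcn = 1e−8`, i.e. relative steps ~1e−4);
with machine-scale steps the numerical gradients are dominated by
integration noise and the refinement stalls far from the optimum.

Bounds: all parameters are bounded below by zero, except the three
delay constants which keep a 1-minute floor (delays below a minute are
indistinguishable on an hourly grid, and τ → 0 makes the cascade
arbitrarily stiff). Upper bounds default to ten times the default
values, with fraction-valued parameters capped at one.

95% confidence intervals are linearised: covariance `s²(JᵀJ)⁻¹` with
`s² = cost/(n_obs − k)` and the Jacobian of the weighted residuals
taken by central differences; intervals are `estimate ± 1.96·SE`
(normal quantile — the reference workflow does not state a quantile, so
the simplest convention is used and documented). Because the
linearisation ignores the bounds, intervals for weakly constrained
delays may extend below zero and are reported as-is. Whether the final
fit should be joint across all five series or sequential per series is
left open by the reference workflow; both modes are available (`free` +
per-series datasets), with the joint fit as the default.

## Identifiability and term selection

`profile_likelihood` fixes one parameter on a log-spaced grid around its
optimum (default 21 points per side spanning a factor 100 each way;
`frac_use` uses a linear grid on [0, 1]) and re-fits the remaining
parameters, warm-starting each grid point from its neighbour. A
parameter is *identifiable* if the profile rises by more than 3.84 (χ²,
1 d.o.f., 95%) on both sides, *bounded above/below* if on one side
only, and *non-identifiable* otherwise. The threshold and grid are
standard conventions for the method, not values taken from a reference.
`profile_all_parameters` uses a coarser default (6 points per side)
sized for whole-model classification runs.

Two structural non-identifiabilities are expected by construction:
`k_reester` only ever appears in the product with the adipose G-3-P
concentration, whose scale it itself sets (any change is absorbed by a
compensating change in G-3-P), and `k_atl` trades off against
`b_atl`/`atl_max` when the insulin excursion does not probe the
saturation of lipolysis inhibition.

`select_term` compares candidate rate expressions for one flux series —
e.g. insulin-only vs basal+insulin vs constant spill-over, or delayed
vs undelayed vs Michaelis-Menten LPL lipolysis — by fitting each with
multi-start bounded Levenberg-Marquardt and ranking by AICc,
`n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)`, with n the 7 per-series
observations for single-series comparisons (n = 35 would apply to
whole-model comparisons). Ties are broken by name so rankings are
deterministic.

`local_sensitivities` differentiates the flux curves with respect to
log-parameters (central differences, relative step 1e−4), because the
parameters span four orders of magnitude; parameters at zero cannot be
perturbed multiplicatively and are flagged instead.

## The synthetic cohort generator

No public arteriovenous meal-challenge dataset with this design exists,
so the generator is first-class, tested code, and every downstream
module is validated against it.

* **Arterial curves**: fasting plateau plus a log-normal-shaped
  postprandial bump per analyte (insulin and glucose peak at 60 min, TG
  at 210 min, glycerol modestly at 120 min); NEFA is plateau − dip +
  late rebound. The family is smooth, non-negative, and exactly flat
  over the fasting samples. Shape values are synthetic but
  physiological for an overweight cohort consuming a high-fat meal.
* **Between-subject variability**: every shape parameter and ATBF is
  multiplied by a unit-mean lognormal factor with CV 0.15 — a modest,
  realistic biological spread.
* **Fluxes**: each subject's model fluxes at the true parameters, plus
  additive Gaussian noise with SD = 15% of that subject's series
  dynamic range. Venous concentrations are *back-computed* as
  `arterial − flux/ATBF` (with the flux capped so venous stays
  non-negative), which makes the arteriovenous reconstruction exact by
  construction — the generator/analysis round trip is the package's
  primary integration test.
* **Tracer**: labelled TG hydrolysis is the LPL rate times a meal
  appearance envelope (zero before the meal, peaking at 120 min);
  labelled NEFA efflux is the spill fraction times the labelled
  fatty-acid hydrolysis, with noise inflated 3-fold after 180 min to
  emulate label recycling. Spill-over is therefore undefined at the
  fasting samples, exactly as with a real meal tracer.
* **Default truth**: the five parameters with published baseline
  estimates (`k_ad` 0.0096, `tau_lpl` 156.92, `tau_at` 21.19, `p_gly`
  0.249, `p_nefa` 0.0444) use those values; the other nine are
  *synthetic placeholders* chosen once for physiological flux
  magnitudes (fasting stored-TG lipolysis ≈ 0.22 µmol/100 ml/min,
  spill-over ≈ 35% at basal insulin) and must not be read as published
  estimates.

What the generator does *not* emulate: demographics and diet-arm
structure, arterial measurement error (forcings are treated as exact),
postprandial ATBF dynamics (constant per subject), non-Gaussian noise,
or missing samples. Passing tests therefore demonstrate correctness of
the machinery under the stated statistical assumptions, not performance
on real cohorts.

### A note on validation experiment design

Three validation experiments deserve explanation of their conditions,
all fixed before the experiments were run:

* **Known-truth recovery** uses a noiseless, homogeneous cohort. Zero
  noise makes every cross-subject σ zero, which the weighted cost would
  exclude; the recovery experiment therefore supplies unit σ
  (unweighted least squares). Recovery of the six well-determined
  parameters to < 1% is then a pure test of simulator + optimiser.
* **Confidence-interval coverage** uses replicates with measurement
  noise only (common forcing across subjects). With heterogeneous
  forcings, fitting the cohort-mean flux against the cohort-mean
  forcing incurs a Jensen-type aggregation bias (e.g. the mean of
  `I_B/I_art` across subjects exceeds the ratio of the means), which is
  a model-misspecification effect that linearised CIs make no claim to
  cover. Calibration of the CI machinery is meaningful only under a
  correctly specified model; the aggregation bias is visible separately
  by switching the CV back on.
* **Identifiability classification** runs on one cohort at the full
  default spec (n = 16, CV 0.15, 15% noise) with the coarse profile
  grid — the configuration intended to emulate the real study design.

Problem sizes used throughout (7 time points, 16 subjects, 20 coverage
replicates, 6-point-per-side classification grids, CRS evaluation caps
of a few thousand) were chosen as the smallest sizes at which the
respective statistical statements are stable.

## Known limitations

* The model inherits the structural non-identifiability of
  `k_reester`/G-3-P scale; fixing `k_reester` from external data would
  be required to interpret the G-3-P pool quantitatively.
* Cohort-mean fitting is the supported mode (as in the reference
  workflow); there is no hierarchical per-subject estimation.
* VLDL and chylomicron TG are lumped; a single generic NEFA species is
  modelled.
* Arterial inputs are exogenous — the model cannot close the loop
  through whole-body glucose-insulin regulation.
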