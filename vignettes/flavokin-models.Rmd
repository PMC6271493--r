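---
title: "Kinetic and thermodynamic models of flavylium pigment chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and thermodynamic models of flavylium pigment chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavokin)
```

flavokin models the solution chemistry of flavylium
(3-deoxyanthocyanidin) pigments — the synthetic analogues of anthocyanin
colorants — in four experimental settings: multistate acid–base/hydration
speciation, iron binding followed by UV–visible kinetics and titrations,
binding to human serum albumin (HSA) followed by fluorescence quenching,
and inhibition of heme-induced lipid peroxidation followed as
conjugated-diene accumulation at 234 nm. Every model comes with a
nonlinear least-squares fitter and a synthetic-data generator, so each
fitter can be validated end-to-end by parameter recovery.

## Speciation

A flavylium cation AH⁺ loses a proton to the neutral quinonoid base A
(pKa1) and, at higher pH, to the anionic base A⁻ (pKa2). In parallel,
water addition converts AH⁺ through the hemiketal and the (Z)-chalcone —
both kinetically transient for 3-deoxy pigments — into the stable
(E)-chalcone C~E~, described by a single apparent constant pK'~h~. The
state vector therefore contains only the four accumulating species; the
lumping is a modelling decision justified by the very unfavourable
(Z)-chalcone equilibrium of these pigments. The chalcone-to-base ratio
K~i~ = (C~E~)/(A) = 10^(pKa1 − pK'~h~)^ is pH-independent, and
`eq_constants()` enforces consistency (within 5%) if a user supplies an
independent K~i~.

pH is treated as exact (buffered measurements) and no activity
corrections are applied: the constants are mixed concentration constants,
as is conventional for this kind of spectrophotometric work.

```{r speciation}
k <- eq_constants(pKa1 = 4.44, pKa2 = 7.12, pKh_app = 3.45)
round(mole_fractions(k, pH = 7.4), 3)
```

The pH titration of the quinonoid bases is modelled as a two-state
Henderson–Hasselbalch sigmoid in absorbance with the absorption ratio
r~A~ (anionic/neutral) as amplitude parameter. Only the
instantaneous (pre-equilibration) two-state model is implemented: after
long equilibration the chalcone re-enters the picture and the published
analyses do not state a functional form for that case. When r~A~ ≈ 1 the
curve is flat and pKa2 is undefined; `fit_pka2()` flags this (singular
covariance or a pKa2 standard error above half a pH unit) instead of
returning an arbitrary number.

## Iron binding

Three models cover the iron work, mirroring how the chemistry was probed:

* **Two-step Fe(III) binding** (`simulate_two_step()`,
  `fit_two_step()`): irreversible second-order binding of Fe(III) to the
  pooled colored forms L (rate constant k~b~), followed by first-order
  rearrangement of the kinetic complex into a thermodynamic complex
  (k~r~). All colored forms in fast acid–base equilibrium are pooled into
  a single species L — no internal protonation states. The fit is a
  simultaneous least-squares problem over the 470 and 620 nm traces,
  estimating k~b~, k~r~ and the complex absorption coefficients per
  wavelength (the published fits do not state whether these were shared,
  so they are fitted freely). The free-pigment absorption ε~L~ is fixed
  from the t = 0 absorbance (A₀/L₀) rather than fitted.
* **Reversible 1:1 isotherm** (`isotherm_deltaA()`, `fit_isotherm()`):
  for the glucoside, whose binding is too fast for conventional kinetics
  but reversible, the absorbance change at equilibrium vs total metal is
  fitted for K~b~ and Δε. The bound-metal concentration comes from the
  quadratic implied by the mass balance, written in a cancellation-free
  form (the discriminant expands to a sum of positive terms), so the
  solver agrees with a bisection oracle to better than 10⁻¹² even at
  extreme K~b~.
* **Fe(II) autoxidation → binding** (`simulate_autox()`, `fit_autox()`):
  Fe(II) itself binds negligibly; an apparent first-order autoxidation
  (k~autox~) feeds Fe(III), which then binds (k~b~), while the free
  pigment can still hydrate to the chalcone (k~h~^obs^; set to 0 where
  chalcone formation is negligible). At iron/pigment ratios ≤ 1 the
  Fe(III) intermediate never accumulates and k~b~ drops out; mode
  `"steady_state_FeIII"` implements that reduced model (binding flux =
  autoxidation flux while free pigment remains, with a smooth cutoff at
  L = 1 nM to keep the ODE differentiable).

Binding irreversibility in the two-step model and reversibility in the
isotherm are not contradictory: they reflect the split treatment of the
aglycone (kinetics, quasi-irreversible on the 2-min scale) versus the
glucoside (equilibrium), and the package keeps that split. Path length is
1 cm throughout; nominal concentrations are used as exact.

Both ODE systems conserve total iron and total pigment to the integrator
tolerance (lsoda, rtol 10⁻¹⁰, atol 10⁻¹⁶ in simulations; fitters relax to
10⁻⁸/10⁻¹³ for speed, which is far below the instrument noise).

## HSA binding by fluorescence quenching

Ligand binding near the single Trp residue quenches the intrinsic protein
fluorescence. Because the ligands absorb at the excitation and emission
wavelengths, the intensity follows
I~F~ = f~P~·[P]·exp(−ε~L~·l·L~t~), where ε~L~ is the *sum* of the ligand
molar absorptions at both wavelengths (determined independently by a
Beer's-law plot, fixed in the fit), l the mean excitation path at the
detection point (0.65 cm for the instrument modelled) and [P] the free
protein from the 1:1 mass-action equations. The total ligand
concentration drives the inner-filter exponential, exactly as the model
is defined. `fit_quench()` estimates (K~b~, f~P~) per titration — f~P~ is
an instrument-dependent scale and the published tables list distinct
values per ligand, so it is not shared across titrations.

Titrations on equilibrated solutions measure an apparent constant over
the chalcone/colored mixture. `deconvolve_chalcone_Kb()` inverts the
linear mole-fraction mixture
K~b,app~ = f·K~b,chalcone~ + (1−f)·K~b,colored~; at the 3:1
chalcone-to-colored ratio of the aglycone at pH 7.4 this reproduces the
published corrected value (368 × 10³ M⁻¹) exactly, which is why the
linear weighting was adopted.

```{r quench}
deconvolve_chalcone_Kb(344e3, 273e3, chalcone_fraction = 0.75)
```

## Heme-induced lipid peroxidation

Metmyoglobin (MbFe(III)) cleaves trace lipid hydroperoxides LOOH (rate
constant k~i1~), generating the hypervalent MbFe(IV) species that
oxidises linoleic acid LH (k~i2~, constrained equal to k~i1~ to limit the
parameter count). Radicals are not explicit states: a quasi-steady-state
closure for the chain carriers gives a propagation flux r₂·[LH]·√R~i~,
with r₂ = k~p~/√(2k~t~) the lipid oxidizability and R~i~ the initiation
rate counting one chain-carrying radical from each heme event,
R~i~ = k~i1~[MbIII][LOOH] + k~i2~[MbIV][LH]. MbFe(IV) is *not* assumed
stationary — keeping it dynamic reproduces the short lag phase — and the
antioxidant is modelled as n independent one-electron sub-units, each
reducing MbFe(IV) back to MbFe(III) with rate constant k~a~ = AE·k~i2~.
The antioxidant only cycles heme; no heme bleaching, micelle
partitioning, or co-oxidation of the pigment by peroxyl radicals is
modelled, and O₂ is assumed saturating (open-air assay). Hydroperoxides
are identified with conjugated dienes, A₂₃₄ = 24 000·[LOOH] (1 cm).

Useful consequences of this closure, verified in the test suite:

* With MbFe(IV) at quasi-steady state the two initiation channels run at
  the same rate, so early on R~i~ ≈ 2k~i1~[MbIII][LOOH] and √[LOOH]
  follows the linear ODE d√y/dt = c − a√y with
  c = ½r₂[LH]₀√(2k~i1~[MbIII]₀) and a = k~i1~[MbIII]₀/2. The integrator
  matches this closed form to better than 2% over the first 30 s (the
  window where LH and MbIII are constant to < 1%).
* Inhibition under this closure is a *competition* for MbFe(IV) between
  the antioxidant (k~a~·[AHu]) and the lipid (k~i2~·[LH]); at
  micromolar antioxidant against 0.7 mM lipid the intercepted fraction
  is modest, so (AE, n) shape the curve subtly. The fitted surface has a
  flat AE → 0 plateau, and `fit_inhibited()` therefore seeds the local
  optimizer from a coarse log-spaced (r₂, AE, n) grid and refines from
  the three best grid points, keeping the lowest-residual fit.

Fitting follows the two-stage published protocol: `fit_uninhibited()`
estimates k~i1~ and r₂ from antioxidant-free curves; k~i1~ is then frozen
(default 3 × 10³ M⁻¹s⁻¹) and `fit_inhibited()` estimates (r₂, AE, n).
The hydroperoxide seed LOOH₀ is not printed in the source work beyond
"trace contamination"; the default is 1 µM, exposed as a condition and
optionally fitted in the uninhibited stage.

## Shared fitting engine

All fitters call `least_squares_fit()`, a Levenberg–Marquardt wrapper
(minpack.lm) that pools residuals across simultaneously fitted curves
with equal per-point weights, matching the homoscedastic single-instrument
data the models are meant for (weights are exposed for other uses).
Positivity is enforced by fitting such parameters in log space rather
than with hard bounds. Standard errors are linearised Gauss–Newton
standard deviations — residual variance times the inverse approximate
Hessian, delta-method-mapped to the natural scale. They should be read as
local curvature estimates, not bootstrap intervals; the original analyses
report "standard deviations" without stating an estimator, so exact
agreement of uncertainties is not promised, only point-estimate recovery.
Identifiability problems surface as a large condition number of the
parameter correlation matrix (threshold 10⁸), NA standard errors from a
singular covariance, or model-specific checks (|ρ| > 0.999 between K~b~
and Δε in the isotherm; pKa2 SE > 0.5). If the first optimizer start
fails, three deterministically jittered restarts are tried and the best
kept; determinism is preserved because the jitters are fixed offsets, not
random draws.

## Synthetic data and recovery studies

`make_kinetic_traces()`, `make_isotherm()`, `make_titration()` and
`make_quench_series()` forward-simulate each assay and add instrument
noise: additive Gaussian for absorbance (σ = 0.002 AU for kinetic traces,
0.005 AU for equilibrium series) and 1% multiplicative Gaussian
(shot-noise-like) for fluorescence. The sources report no noise figures,
so these are chosen once as plausible diode-array / fluorimeter levels
and are stated in each scenario. Generators are seeded and byte-identical
given identical inputs.

What the generator emulates: the published assay designs — 50 µM pigment
with iron/pigment ratios 0.5–5 in pH 4 acetate buffer sampled every 0.5 s
over 2 min (binding) or 15 s over 15 min (slow processes); pH 6–8
titrations in steps of 0.2; 2 µM HSA with 0–20 µM ligand; 0.7 mM linoleic
acid + 0.5 µM metmyoglobin + 0.5–7.5 µM pigment at pH 5.8 sampled every
10 s over 30 min. What it does not emulate: baseline drift, stray-light
nonlinearity, dilution during titrant addition, heme bleaching, or
model-mismatch error — so passing recovery studies demonstrate estimator
correctness and identifiability under the stated model, not robustness to
instrument artefacts.

`recovery_study()` wraps the generate–fit loop (replicate i uses seed +
i − 1), reports per-parameter mean, sd, bias and rmse, and counts
non-converged replicates rather than hiding them. `flavokin_scenarios()`
ships the published parameter sets (rate constants, binding constants,
Table-style peroxidation rows) as named ground-truth scenarios; the
free-pigment absorptions, which the published tables omit, are set to
plausible values consistent with the reported t = 0 absorbances and
recorded per scenario.

Problem sizes used by the shipped recovery checks — 25 replicates for the
ODE-embedded fits (two-step binding, inhibited peroxidation), 50 for
titration and quenching fits, 100 for the isotherm — balance Monte-Carlo
error against desk-scale runtimes; they are the sizes at which the
replicate-mean standard error is well below the published uncertainty of
each parameter.

## Numerical choices and limitations

* ODEs are integrated with lsoda; trial parameter points where the
  integrator fails (extreme rate constants proposed by the optimizer) are
  penalized rather than aborting the fit.
* The 1:1 binding quadratics (free metal, free protein/ligand) use
  cancellation-free root forms; each species is computed from its own
  root so conservation and the mass law hold to ~10⁻¹³ relative.
* Initial values are heuristic (half-rise times for k~b~, endpoint
  absorbances for ε) and deliberately *asymmetric* between complex-1 and
  complex-2 absorptions, because symmetric starts make the objective
  locally flat in k~r~.
* Known limitations: no hemiketal/(Z)-chalcone kinetics, no
  copigmentation or self-association, no multi-site protein binding or
  spectral-shift modelling, no 2:1/1:2 metal stoichiometries, no
  antioxidant–metmyoglobin binding (the drift of AE with antioxidant
  concentration in the source data suggests such a term; it is out of
  model here).
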