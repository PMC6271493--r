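# flavokin

Kinetic and thermodynamic models of flavylium (3-deoxyanthocyanidin)
pigment chemistry, with nonlinear least-squares fitters and a
synthetic-data generator for end-to-end validation by parameter
recovery.

Flavylium ions such as 3',4',7-trihydroxyflavylium (P1) and its
7-*O*-glucoside (P2) are readily synthesized models of anthocyanins,
the red-to-blue pigments of fruit and flowers. Their chemistry in
solution — and hence their value as colorants and antioxidants — is
governed by a handful of coupled equilibria and rate processes that are
measured spectroscopically and extracted by curve fitting. flavokin
implements those models for anyone analyzing such data or studying the
estimators themselves:

* **Speciation** — the flavylium cation AH⁺, quinonoid bases A/A⁻ and
  (E)-chalcone C_E connected by pKa1, pKa2 and the apparent hydration
  constant pK'h (hemiketal and (Z)-chalcone lumped as transient);
  mole-fraction diagrams, the chalcone/base ratio
  K_i = 10^(pKa1 − pK'h), two-state pH titrations, first-order color
  decay A(t) = A∞ + (A₀ − A∞)e^(−k_h t).
* **Iron binding** — two-step Fe(III) binding kinetics
  (d[L]/dt = −k_b[Fe][L], kinetic → thermodynamic complex at k_r) fitted
  simultaneously at two wavelengths; the reversible 1:1 isotherm
  ΔA = Δε(M_t − [Fe]) with a cancellation-free quadratic solver; the
  Fe(II) autoxidation → Fe(III) binding → hydration ODE system, with a
  steady-state-Fe(III) variant for substoichiometric iron.
* **Serum-albumin binding** — 1:1 binding observed by Trp fluorescence
  quenching with inner-filter correction,
  I_F = f_P[P]exp(−ε_L·l·L_t), plus deconvolution of apparent mixture
  constants into the intrinsic chalcone value.
* **Lipid peroxidation** — metmyoglobin-induced oxidation of linoleic
  acid followed as conjugated dienes at 234 nm, under a radical
  quasi-steady-state closure parameterized by the oxidizability
  r₂ = k_p/√(2k_t), the antioxidant efficiency AE = k_a/k_i2 and the
  stoichiometry n; two-stage fitting (k_i1 from uninhibited curves,
  then (r₂, AE, n) with k_i1 frozen).

Everything is plain R built on `deSolve` (stiff ODE integration) and
`minpack.lm` (Levenberg–Marquardt), with S3 objects for parameters and
fit results.

## Worked example

Simulate a noisy Fe(III)-binding experiment (50 µM pigment, equimolar
iron, 0.5 s sampling over 2 min at 470/620 nm) from a published
parameter set and refit it:

```r
library(flavokin)
sc <- flavokin_scenarios()
s  <- sc$table1_ratio1          # kb = 17890 M^-1 s^-1, kr = 4e-3 s^-1

traces <- make_kinetic_traces("two_step", s$params,
                              list(L0 = s$L0, M0 = s$M0), s$times,
                              noise_spec("additive", 0.002, seed = 7))
fit <- fit_two_step(traces, s$L0, s$M0)
fit
#> Nonlinear least-squares fit (6 parameters, 482 observations)
#>           estimate std_error
#> kb       1.796e+04 1.043e+02
#> kr       3.429e-03 6.218e-04
#> eps1_470 1.034e+04 8.728e+00
#> eps1_620 1.226e+04 9.402e+00
#> eps2_470 7.579e+03 4.106e+02
#> eps2_620 1.063e+04 2.422e+02
#> r = 0.9994   residual norm = 0.04392   converged: TRUE
```

The second-order binding rate constant is recovered within a few
standard errors (truth 17 890 M⁻¹s⁻¹), the rearrangement constant k_r
within ~15% (it is only weakly constrained by a 2-min trace), and the
complex molar absorptions to a few percent. A recovery study repeats
this over many noise realizations:

```r
print(recovery_study(s, n_replicates = 25)[1:2, 1:6], digits = 4)
#>   parameter     truth      mean        sd       bias      rmse
#> 1        kb 17890.000 1.783e+04 1.588e+02 -5.502e+01 1.651e+02
#> 2        kr     0.004 4.006e-03 6.066e-04  6.370e-06 5.943e-04
```

Equilibrium and titration models work the same way from data frames
(`fit_isotherm`, `fit_pka2`, `fit_quench`, `fit_inhibited`), and CSV
readers (`read_trace_csv`, `read_titration_csv`, `read_quench_csv`)
accept the simple dialects documented on their help pages. A one-line
worked value from the albumin module:

```r
deconvolve_chalcone_Kb(344e3, 273e3, chalcone_fraction = 0.75)
#> [1] 367666.7     # intrinsic chalcone constant, ~368e3 M^-1
```

## Package layout

```
R/                  models, fitters, synthetic-data generators, IO
tests/testthat/     unit, property and recovery tests
vignettes/          methods vignette (model derivations and choices)
scripts/            acceptance.R
```
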