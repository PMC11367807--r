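---
title: "Multi-parameter viscoelastic modelling of denture adhesives"
author: "rheoprony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter viscoelastic modelling of denture adhesives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoprony)
```

## The problem

Denture adhesives are soft, paste-like polymeric materials that operate in
the oral cavity, where temperature, saliva uptake (swelling) and pH all
vary. Finite-element simulations of denture-mucosa mechanics need a
material law for the adhesive that captures its viscoelasticity under those
physiological conditions. This package builds such a law from oscillatory
frequency-sweep rheometry: storage modulus $G'$ and loss modulus $G''$
measured over 0.01-10 Hz at a grid of temperatures, swelling ratios and pH
levels.

## The model

The relaxation modulus is a Prony series (generalized Maxwell model) with
an Arrhenius horizontal shift:

$$G(t, \theta) = G_0 + \sum_{i=1}^{n} g_i
  \exp\!\left(-\frac{a_\theta(\theta)\, t}{\tau_i}\right), \qquad
a_\theta(\theta) = \exp\!\left[\frac{E_a}{R}\left(\frac{1}{T_{\mathrm{ref}}}
  - \frac{1}{\theta}\right)\right].$$

$G_0$ (Pa) is the equilibrium modulus, $g_i$ (Pa) and $\tau_i$ (s) the
branch amplitudes and relaxation times, $E_a$ (J/mol) the activation
energy, and $T_{\mathrm{ref}} = 305.15$ K (32 °C) the reference
temperature at which master curves are assembled. The single-branch form
$G(t) = G_0 \exp(-t/\tau_\theta)$, in which $G_0$ multiplies the
exponential rather than adding to it, is retained as a separate operation
(`maxwell_relaxation()`); the two conventions for $G_0$ coexist in the
denture-adhesive modelling lineage and are deliberately not merged.

The multi-parameter extension lets the branch parameters depend on the
swelling ratio $SR \in [0, 1]$ and optionally pH:

$$G(t, \theta, SR, pH) = G_0 + \sum_{i=1}^{n}
  \left(g^{SR,pH}\right)_i
  \exp\!\left(-\frac{a_\theta(\theta)\, t}{\left(\tau^{SR,pH}\right)_i}\right),$$

with the pH-free simplification used when the statistical screen finds pH
uninfluential. The $(SR[, pH])$ dependence is represented as a grid of
fitted nodes with piecewise-linear interpolation in $\log g_i$ and $\log
\tau_i$ (bilinear when both covariates are retained), which preserves
positivity; the equilibrium modulus is interpolated linearly because $G_0 =
0$ is a legitimate value that the log rule cannot represent. No functional
form in $SR$ or pH is assumed, and evaluation outside the node hull is a
hard error rather than an extrapolation.

### Sign conventions

$a_\theta$ multiplies *time*, so $a_\theta > 1$ above the reference
temperature and relaxation accelerates when warm. In the frequency domain
the effective relaxation times are $\tau_i / a_\theta$, and a sweep
measured at $\theta$ equals the reference curve evaluated at $\omega /
a_\theta$. Master curves therefore use the reduced frequency $\omega /
a_\theta(\theta)$: data measured above the reference temperature move
toward *lower* reduced frequency. `estimate_pairwise_shift()` reports
`log10_shift` $= \log_{10} a_\theta$, which is positive above the
reference; the frequency multiplier that superposes the target is
$10^{-\mathrm{log10\_shift}}$. Rheometers report Hz; all internal
mathematics uses $\omega = 2\pi f$ rad/s, converted exactly once at the
I/O boundary. Temperatures are Kelvin internally and Celsius in every file.

## Frequency-domain interconversion

Storage and loss moduli of the generalized Maxwell model are evaluated in
closed form:

$$G'(\omega) = G_0 + \sum_i g_i
  \frac{(\omega\tau_i^{\mathrm{eff}})^2}{1 + (\omega\tau_i^{\mathrm{eff}})^2},
\qquad
G''(\omega) = \sum_i g_i
  \frac{\omega\tau_i^{\mathrm{eff}}}{1 + (\omega\tau_i^{\mathrm{eff}})^2}.$$

The test suite checks these against an independent numerical oracle: the
Fourier sine/cosine transforms of $G(t) - G_0$, integrated by quadrature
with the trigonometric factor reduced to a single period and the
exponential tail summed as an exact geometric series. Agreement is better
than $10^{-6}$ relative over the full sweep grid.

## Stages of the analysis

**Synthetic data.** Raw adhesive sweeps of this design are not publicly
deposited, so the generator (`generate_dataset()`) emulates the test design with known
ground truth: 31 frequencies (0.01-10 Hz, 10 points/decade, both endpoints
included), temperatures 17-52 °C in 5 °C steps, pH in $\{2, 7, 10\}$,
swelling in 20% steps to saturation ($SR = 1$). Branch parameters follow a
log-linear covariate law, $\log g_i = \log g_i^0 + \beta_{g,i} SR +
\gamma_{g,i}(pH - 7)$, and likewise for $\tau_i$. Defaults are the study
conditions: baseline $G_0 = 400$ Pa, $g = (3000, 1500, 800)$ Pa, $\tau =
(0.05, 0.8, 12)$ s (decade-separated, centred on the sweep window;
paste-like kPa moduli), $E_a = 50$ kJ/mol, $\beta_g = -0.35$, $\beta_\tau
= -0.25$ per unit $SR$, $\gamma_g = 0.005$, $\gamma_\tau = 0.002$ per pH
unit. The orderings $|$temperature effect$|$ > $|SR|$ > $|$pH$|$ reflect the
relative influence these covariates exert on adhesives of this class. Noise is multiplicative
lognormal with CV 2% (1% for shift-recovery experiments), parameterized
mean-unbiased, applied independently per cell. The generator emulates only
$(f, G', G'')$ records: no stress waveforms, instrument inertia or
strain-control dynamics, so passing tests say nothing about raw-signal
artefacts in real rheometry, only about the modelling chain downstream of a
well-conditioned sweep table.

**Time-temperature superposition.** Shifts are estimated in two stages:
free pairwise log-shifts of each isothermal sweep against the 32 °C
reference (coarse grid over $\pm 6$ decades at 0.05 steps, then local
refinement; ties resolve toward the smaller $|$shift$|$; objective is the
mean squared $\log_{10} G'$ plus $\log_{10} G''$ residual over the
overlap), then a through-origin regression of $\ln a_\theta$ on $(1/T_{\mathrm{ref}}
- 1/\theta)$ whose slope is $E_a / R$. Two-stage estimation is simpler to
diagnose than a one-shot constrained fit and mirrors the usual rheometry
workflow of computing shift factors first and superposing after. Only
horizontal shifts are applied — these materials shift horizontally with
temperature — and vertical (modulus) shifts are a non-goal.

**Spectrum fitting.** `fit_prony()` places $n$ relaxation times log-spaced
across the reciprocal reduced-frequency window by the midpoint rule ($n$
equal log-cells, one $\tau$ per cell centre, so the $n = 1$ time sits at
the window centre and residuals decrease as $n$ grows), solves $G_0, g_i
\ge 0$ by non-negative least squares on relatively weighted stacked $G'$
and $G''$ residuals, then optionally refines all parameters by bounded
Levenberg-Marquardt. The refinement works in $\log_{10} g_i$ and
$\log_{10} \tau_i$ — with raw amplitudes the mixed Pa/decade parameter
scales stall the optimizer far from the optimum — with each $\tau_i$
confined to one decade around its grid position; refinements that cross or
tie relaxation times, or that worsen the residual, fall back to the
stage-1 fit. There are no random starts: fits are bit-reproducible on
fixed input. $n = 3$ is the default branch count, the value at which the
fit residual for this material class stops improving materially;
non-negativity is the only regularization by default, with an optional
ridge parameter for ill-conditioned spectra.

**Covariate screen.** `fit_mlr()` regresses a modulus on temperature, $SR$
and pH with intercept, flagging predictors at $p < 0.02$ (98% confidence);
`pearson_matrix()` computes all pairwise correlations; and
`screen_covariates()` retains a covariate only if it is significant in at
least one regression *and* its strongest $|r|$ against either modulus
reaches 0.3. Temperature is always retained because it parameterizes the
shift function, not the node table. By default the screen stage evaluates
at a single representative frequency (1 Hz): with a purely horizontal
temperature effect, pooling three decades of sweep variation into the
response bounds every condition correlation near 0.3 regardless of effect
size, so pooled correlations measure the frequency window, not the
covariates. Pooling (optionally with $\log_{10} f$ as a nuisance
covariate) remains available in `fit_mlr()` itself. Moduli are regressed
on the raw scale by default, with a log-response option matched to the
generator's multiplicative noise; an outlier-exclusion refit is
deliberately not automated. No multiple-testing correction is applied
across the three predictors: each coefficient is tested on its own at
0.02, and that choice is stated rather than hidden.

**Calibration of the screen.** The acceptance suite measures the size of
the 0.02-level pH test on a configuration where the regression's null
model is exactly true — activation energy zero, all covariate slopes zero,
a single test frequency — so the flag rate estimates the test's size
(expected within [1%, 3.5%] over 2000 replicates). With the default
temperature and swelling effects active, the exponential temperature
response makes the linear mean misspecified; the lack-of-fit inflates the
residual variance and the pH test becomes conservative, so a nominal-rate
check there would measure misspecification, not calibration.

**Model assembly.** `fit_condition_table()` fits one Prony series per
$(SR, pH)$ node with the shared global shift (one TTS treatment for the
material, not per-node shifts), and `build_multiparam_model()` assembles
the final model. When the screen drops pH but the data are pH-resolved,
node parameters are collapsed at each $SR$ by the geometric mean over pH
levels — the log-average is the natural reduction for log-linearly
varying, strictly positive parameters and treats the levels symmetrically.

**Export.** `export_fem_card()` writes a solver-neutral text card with
relative amplitudes $\alpha_i = g_i / (G_0 + \sum g_j)$, relaxation times,
the instantaneous modulus and the Arrhenius parameters, the quantities a
commercial FEM package's Prony-plus-shift-function viscoelastic model
requires. $\sum \alpha_i \le 1$ with equality exactly when $G_0 = 0$; no
vendor-specific deck syntax is emitted.

## Worked example

```{r example, eval = FALSE}
out <- run_pipeline(list(
  seed = 7, outdir = tempfile("demo"),
  generator = list(design = "factorial", noise_cv = 0.02)),
  stages = "all")

out$shift          # fitted activation energy
out$screen         # covariate retention decision
out$model          # final multi-parameter model

# relaxation modulus at 37 degC, 40% swelling
evaluate_multiparam(out$model, c(0.01, 0.1, 1, 10),
                    condition(celsius_to_kelvin(37), 0.4, 7))
```

## Numerical choices and degenerate inputs

* Shift search window $\pm 6$ decades, coarse step 0.05, local tolerance
  $10^{-9}$; sweeps need at least 4 points and 2 overlapping points after
  shifting, otherwise a no-overlap error.
* `fit_prony()` requires $\ge 2n + 1$ points spanning $\ge 1$ decade;
  purely elastic input ($G'' = 0$) recovers $G_0$ with silent branches;
  all-zero moduli are a fit error.
* Exact collinearity in the regression design is a hard error; a
  numerically perfect linear fit returns coefficients with p-values
  flagged undefined rather than fabricating inference.
* Zero-variance screen variables are refused by name (a pH-constant
  dataset cannot rank pH).
* Node-grid evaluation is exact at nodes (interpolation weights hit 0/1
  exactly) and refuses extrapolation outside the hull.
* Model JSON and sweep CSV round-trips preserve doubles to at least
  $10^{-12}$ and $10^{-9}$ relative, respectively; serialized models carry
  a format version that is checked on read.

## Problem sizes used in the checks

The packaged tests and the acceptance script run, per invocation: 100
random spectra for the interconversion oracle; 100 replicates of the
8-temperature shift-recovery experiment at 1% noise; 50 replicates of
noisy spectrum recovery at 2% noise; 2000 replicates of the null
calibration at one frequency; 200 replicates of the screen-pattern
experiment; and one full factorial pipeline run (8 temperatures × 6
swelling levels × 3 pH levels × 31 frequencies) compared against noiseless
truth over the grid hull. These sizes give Monte-Carlo standard errors
comfortably inside the tolerances they are tested against.

## Known limitations

* Linear viscoelasticity only: no large-strain behavior, no vertical
  shift factors, no WLF shift (Arrhenius only), no bulk/Poisson behavior
  needed for a full 3-D law.
* The $(SR, pH)$ surface is a grid with log-linear interpolation, not a
  smooth response surface, and carries no uncertainty propagation.
* The branch count $n$ is user-chosen; the package reports residuals for
  the chosen $n$ but performs no automatic model selection.
* Whether real pH/swelling series are measured at one temperature or all
  temperatures is design-dependent; both designs are supported
  (`one_factor`, `factorial`) rather than guessed.
* The screen's per-frequency default is a methodological choice; analysts
  pooling across frequencies should use the log-frequency nuisance option
  and interpret correlations accordingly.
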