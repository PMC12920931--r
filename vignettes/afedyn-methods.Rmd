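---
title: "Modeling AFE-to-lung-progenitor differentiation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling AFE-to-lung-progenitor differentiation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afedyn)
```

## The biological problem

Directed differentiation of induced pluripotent stem cells passes through
anterior foregut endoderm (AFE) on the way to NKX2-1+ lung progenitors
(LPs). In the culture window this package models (protocol days 11-15,
model time 0-4 d), AFE cells proliferate, die, and differentiate into LPs
while consuming glucose and producing lactate. Protocol levers — the
day-10 split ratio and whether the medium is replaced daily — act through
seeding density and the biochemical environment. `afedyn` implements the
full model-development loop for this system: a candidate family of ODE
models, heteroscedastic maximum-likelihood calibration, BIC selection,
identifiability analyses, global sensitivity analysis, sampling-schedule
design, and in silico protocol predictions, together with a synthetic-data
generator that reproduces the experiment's statistical design.

## The candidate model family

A candidate (`model_spec()`) crosses four axes:

* **Lineage.** `M0` tracks only the total live density $n_q$;
  `M1` resolves AFE ($n_a$) and LP ($n_p$) populations, with
  $n_q = n_a + n_p$. In M1, an AFE division yields two AFE daughters with
  renewal probability $p_{ap}$ or two LP daughters otherwise, so the
  differentiation flux is $2(1-p_{ap})\,b_a n_a$ with
  $b_a = \beta_a f(n_a, c_g, c_l)$. Death rates are constant per capita.
* **Growth law** $f_n(n)$: exponential ($1$), logistic ($1 - n/n_{max}$),
  or Gompertz ($\log(n_{max}/n)$, with $n$ floored at $10^{-9}$ — the
  divergence at $n = 0$ is an artifact of the functional form, not
  biology).
* **Environmental effect** $F_{env}(c_g, c_l)$: none, glucose promotion
  $c_g/(K_g + c_g)$, lactate inhibition $K_l/(K_l + c_l)$, or both
  multiplied.
* **Error model** for observations $z = g + \epsilon\eta$,
  $\eta \sim N(0,1)$: additive ($\epsilon = a$), proportional
  ($\epsilon = b\,g$), or combined ($a + b\,g$), with separate parameters
  for densities ($a_n, b_n$) and concentrations ($a_c, b_c$) because the
  two measurement processes have different units and error sources.

Metabolites follow Michaelis-Menten kinetics driven by the total
population: $\dot c_g = -V_g n\, c_g/(c_g + \bar c_g)$ and
$\dot c_l = +V_l n\, c_l/(c_l + \bar c_l)$. Two consequences worth
noting. First, crowding uses the *own-population* density exactly as the
model family is written (`growth_multiplier()` receives $n_j$), not the
total; whether crowding should act through the total is an open modeling
question we resolve by fidelity to the written equations. Second, the
lactate production term is Michaelis-Menten *in lactate itself*, so
$c_l(0) = 0$ freezes lactate at zero forever; the generator therefore
defaults to a small positive fresh-medium lactate (1 mmol/L).

Units are fixed project-wide: days, cells mm^-2, mmol/L. $V_g, V_l$ are
stored as positive magnitudes with signs applied in the right-hand side.
The right-hand sides are compiled (C, via deSolve's compiled-model
interface), with a stacked variant that integrates all experimental
conditions in one solver call — the calibration loop evaluates the
likelihood thousands of times and this is the dominant cost. States are
floored at zero inside the rate computations so transient undershoots with
loose tolerances cannot propagate.

## Likelihood, calibration, selection

The loss is $-2\ell = \sum \epsilon^{-2}(Z - g)^2 + \sum 2\log\epsilon +
m\log 2\pi$, with one stacked ODE solve per evaluation (`neg2loglik()`).
Calibration (`fit()`) is multistart: maximin Latin-hypercube starts over
the packaged search box (`default_bounds()`; the study fidelity is 100
starts, desk-scale defaults are smaller), each start running a bounded
differential-evolution phase (rand/1/bin, CR = 0.9, dithered F in
[0.4, 1], population 10x dimension) followed by Nelder-Mead refinement to
relative tolerance $10^{-6}$. Optimization is in the natural parameter
space with box constraints, matching how the starts are drawn; proposals
outside the box score `Inf`.

An optional `lm_polish` control finishes each start with an iteratively
reweighted Levenberg-Marquardt pass on the weighted residual vector
(bounded pass, then a free interior pass accepted only when the clamped
result lowers the loss). We added it after observing that the noiseless
recovery problem has a likelihood valley with curvature ratios around
$10^{10}$ — the growth-rate combinations are violently steep while the
$(V_g, \bar c_g)$ and $(\beta_a, K_g)$ compensation directions are nearly
flat — and that bounded LM alone stagnates on active box corners. The
default path remains DE + Nelder-Mead.

Model selection computes `bic()` $= k\log m_s - 2\ell$ on a held-out
selection split, where $k$ counts *all* inferred parameters (structural
plus error — both are estimated, so both are counted; the alternative of
counting only structural parameters would not change rankings within an
error-model class). Because M0 and M1 consume different observables their
likelihoods are not comparable, so `select_models()` ranks within lineage
only, breaking BIC ties by fewer parameters and then by the spec string
for determinism.

## Identifiability

`structural_screen()` is a two-part numerical screen on dense noiseless
multi-condition trajectories. (a) A symmetry witness: for exponential
growth with no environmental coupling, a rate translation leaves every
observable unchanged — $(\beta_q + c, \delta_q + c)$ for M0, and
$(\beta_p + c, \delta_p + c)$ for M1, where the LP pair carries the
symmetry because the differentiation flux makes the AFE pair observable.
(b) A local rank test: the Gram matrix of output sensitivities to
log-parameters (central differences, outputs scaled per observable); a
singular value below $10^{-4}$ of the largest marks a rank deficiency.
The threshold sits in a wide empirical gap: exact symmetries produce
relative singular values near $10^{-6}$-$10^{-7}$ (finite-difference and
integrator noise), while the smallest genuine singular values are above
$10^{-3}$.

The screen agrees with the discard rule used for enumeration (the six
exponential/no-environment candidates) and additionally reports an exact
one-dimensional degeneracy for M0 with logistic or Gompertz crowding and
no environmental coupling: the output depends only on
$(\beta_q - \delta_q,\ \beta_q/n_{max})$ (logistic) or
$(\beta_q\log n_{max} - \delta_q,\ \beta_q)$ (Gompertz), which the rank
test finds as deficiency 1. The corresponding M1 candidates are
identifiable because the differentiation cross-term breaks the symmetry.
This is a deliberate deviation from treating all non-exponential/none
candidates as globally identifiable: the algebra is checkable by hand and
the rank test confirms it; enumeration and the 72/66 bookkeeping are
unaffected.

Practical identifiability uses profile likelihoods (`profile_fit()`,
`profile_curve()`): step a parameter outward from the MLE, re-optimize
the nuisances warm-started from the previous step, double the step while
the profile moves by less than 0.1, stop at the threshold crossing
(refined by bisection and interpolation) or at a bound (that side is
reported open). The threshold is $\Delta = \chi^2_{0.95}(1)/2 \approx
1.92$ on the log-likelihood scale — the chi-square quantile needs the
one-half factor on the $\ell$ scale, and we adopt that standard
convention. `practical_filter()` removes shortlisted specs with any open
or flat profile, flags (without removing) parameters whose interval spans
zero, and picks the best-BIC survivor.

## Global sensitivity analysis

`sobol_saltelli()` implements Saltelli's A/B/AB design with the
Saltelli-2010 first-order and Jansen total-order estimators and bootstrap
intervals; base matrices are Latin-hypercube samples for variance
reduction. `sobol_indices()` applies it to model outputs at 96 h under
the 1:2/MCH0 condition, sampling structural parameters uniformly over
$[\theta^*/l,\ \theta^* l]$ with $l = 1.1$ (the printed bracket is linear
and we sample linearly; a log-uniform reading differs by under 1% at this
span). The 40,000-sample budget is read as total model evaluations: the
base size is the largest power of two with $n(d+2) \le 40{,}000$, i.e.
$n = 2048$ for the 10-parameter selected model. Initial conditions are
held fixed — the analysis asks about parameters, and co-varying initial
states would mix design uncertainty into parameter rankings.
`sobol_timecourse()` evaluates the instantaneous LP accumulation rate
$\dot n_p$ along the nominal trajectory via the R-level right-hand side.

## Sampling-period design

`mbdep_curve()` scores a candidate population sampling period by
generating a synthetic four-condition experiment (concentrations stay at
24 h), refitting the assumed model, and measuring the relative parameter
distance $e = \|\hat\theta - \theta^*\| / \|\hat\theta\|$ over structural
parameters only (the error measure is written in $\Theta$). The assumed
model is two-population Gompertz growth with glucose promotion and 30%
proportional noise. The assumed parameter values shipped in
`mbdep_assumed_params()` are **synthetic stand-ins** chosen once to give
realistic culture dynamics (populations of a few hundred cells mm^-2,
glucose drawn down over days without replacement); the original study
drew them from prior experimental experience. The recommended period is
the largest one whose mean error stays within the budget (the cheapest
acceptable design), with the per-repeat error table returned for
inspection.

A caution about interpreting the curve under the stand-in values: the
Euclidean error is dominated by the largest parameter, the carrying
density (about 3000 of the roughly 3000-magnitude parameter norm), and
that parameter is practically unidentifiable from a 4-day window — its
estimate frequently lands on a search bound, in a direction that differs
between sampling periods. Under the packaged stand-ins the resulting mean
error does *not* decrease monotonically with sampling frequency; the
non-carrying-density components are comparable between daily and
alternate-day sampling. Which period wins is therefore a property of the
assumed parameter values (not available for the reference design study), not
of the machinery, and the curve should be read with the per-parameter
breakdown in hand.

## Synthetic data: what it does and does not emulate

`study_design()` reproduces the experiment's statistical skeleton: 4
conditions (split ratios 1:2 and 1:5, with and without daily media
change), N = 4 replicates, populations every 48 h and concentrations
every 24 h over 4 days — 48 records per replicate — with day-11 initial
densities from the split-ratio mapping and Gaussian noise from the error
models. Defaults that the study leaves unstated and we fixed once:
fresh-medium glucose 17.5 mmol/L (a 50:50 IMDM/Ham's F-12 basal mix),
fresh lactate 1 mmol/L (positive so the lactate term can act), and full
daily media replacement under MCH1, applied immediately *after* the
day's measurement instant (measurements at a reset time read the
pre-reset state). Negative sampled values are retained — the likelihood
assumes untruncated Gaussian residuals, and truncation would bias
inference; a display-only clipping flag exists.

What passing tests on these data do *not* show: the generator draws from
the model family itself, so it cannot reveal structural misspecification
(no passaging crash between days 10 and 11, no depletion of growth
factors, no Allee effects, no spatial structure). Role splitting
(`split_dataset()`, 2:1:1 by whole replicates) mirrors the study's
calibration/selection/validation discipline.

## In silico applications

The split-ratio mapping $n_{a0} = \kappa_1 SR + \kappa_{01}$,
$n_{p0} = \kappa_2 SR + \kappa_{02}$ is packaged with the reference
robust-regression coefficients (407.845, 140.941, -13.2916, -2.04044
cells mm^-2; `fit_split_mapping()` refits with a Huber M-estimator,
k = 1.345, falling back to least squares). Its slopes imply that about a
quarter of day-11 cells are already LPs. Outside the calibrated interval
[1:5, 1:2] the mapping warns (extrapolation), and negative mapped
densities are errors.

`simulate_protocol()`, `response_variables()` and `sweep_and_compare()`
evaluate day-4 LP density, yield per input cell ($n_p(4)/n_q(0)$) and LP
ratio ($n_p(4)/n_q(4)$) across split ratios and media regimes. Because
the initial medium concentrations are stand-ins, the headline *percent*
improvements are not pinned down; the package asserts the directional
structure instead: regimes coincide at day 1 (the first reset follows the
day-1 measurement), nutrient-limited cultures peak and decline within 4
days, daily media change never reduces day-4 LP density, and yield per
input cell falls as the seeded fraction rises.

## Validation metrics

`error_metrics()` (RMSE, range-normalized NRMSE, MAE, ME) pools within
observable class — mixed units forbid pooling ranges across densities and
concentrations. `coverage()` compares per-timepoint replicate *means*
against the model band $g \pm k\,\epsilon$ (default $k = 1$, matching how
inferred-standard-deviation bands are drawn); with N = 4 additive-noise
replicates, normal theory puts about 95% of replicate means inside a
1-model-SD band, which the tests verify over seeds. `loocv()` holds out
one entire condition per fold, recalibrates on the rest, and scores
population predictions. `correlation_from_error_params()` inverts the
variance identity $a_{M0} = \sqrt{2(1+\rho)}\,a_{M1}$ that ties the two
lineages' additive density errors through the correlation of the two
population measurements; values outside [-1, 1] warn that the equal-noise
assumption is inconsistent.

## Numerical choices and problem sizes

lsoda with rtol = atol = $10^{-8}$ for user-facing simulation and
$10^{-7}$ inside the calibration loop; media resets by piecewise
integration (no event detection needed at known reset times); the
structural screen uses $10^{-10}$ tolerances, central differences with
relative step $10^{-3}$, and two seeding densities over a 26-point grid.
The test-suite and example configurations deliberately run at desk scale
— a handful of multistarts, DE budgets of a few hundred evaluations,
Sobol base sizes of 256-4096, and 2 repeats per design point; each can be
raised to study fidelity (100 starts, $2\times10^4$ DE evaluations,
$n = 2048$ Sobol base, more repeats) through the same arguments.

A caution from the recovery experiments: at the sparse 48-point study
schedule, the noiseless likelihood of the selected model has, besides the
zero-residual optimum at the generating parameters, a second local
optimum on the boundary of a wide search box in which $\beta_p$,
$V_g/\bar c_g$ and $K_g$ compensate one another at near-zero residuals.
Parameter-recovery demonstrations therefore use a dense (6-hourly)
noiseless schedule and warm bounds; this mirrors the study's own finding
that $\beta_p$ is statistically indistinguishable from zero and that the
glucose-reaction constants carry wide confidence intervals.

## Known limitations

* The packaged reference estimates for the selected models place two
  estimates outside the packaged search box (the AFE proliferation rate
  at 10.58 d^-1 against a 10 d^-1 bound; the glucose half-saturation at
  398.5 against 50 mmol/L). `fit()` accepts caller-supplied bounds, and
  the packaged presets (`selected_m1_params()`) are usable regardless; the
  lactate reaction constants of the presets are synthetic stand-ins (the
  reference fit does not constrain them and they do not feed back on growth
  under glucose-only coupling).
* No Bayesian posterior, no second-order Sobol indices, no vAFE
  intermediate state, no Allee effects, no spatial/PDE extension — all
  outside the model family by design.
* The pipeline's absolute MBDEP percentages and application percentages
  depend on unavailable inputs (assumed design parameters, initial medium
  composition) and are reported as synthetic-conditioned numbers, not
  reproductions.
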