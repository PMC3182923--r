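---
title: "Cost-benefit optimality and evolution of lac regulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-benefit optimality and evolution of lac regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacoptim)
```

This vignette is the package's account of the science it implements: the
growth model and its assumptions, the calibration of the default parameter
set, the fitting and simulation machinery, the numerical choices, and the
limits of what the synthetic-data tests can show.

## The decoupled cost-benefit growth model

The *lac* operon couples sensing to metabolism: lactose induces the operon
*and* is its substrate. Replacing it by the pair (IPTG, Pgal) — a gratuitous
inducer and a non-inducing substrate — breaks that coupling, so expression
and metabolic demand become independent experimental axes. Growth rate is
modeled as

$$ g(I, P) = g_0 - \eta(Z_{\mathrm{reg}}(I, P)) + B(Z_{\mathrm{reg}}(I, P), P), $$

where $Z$ is operon expression normalized to the wild-type fully induced
level. The three pieces, and the assumptions behind them:

* **Regulatory response.** A Hill function of IPTG whose effective
  half-point is shifted by Pgal, $K_{\mathrm{eff}} = k_{1/2}(1 + P/k_a)$.
  The shift is the simplest competitive-binding treatment of
  *anti-induction*: Pgal binds the repressor's inducer site without
  relieving repression. The ~1000-fold affinity ratio between IPTG and Pgal
  motivates the default $k_a = 1000$ μM, which makes anti-induction
  negligible below a few hundred μM Pgal.
* **Cost.** The saturating protein-burden form
  $\eta(Z) = \eta_0 (Z - z_b)/(1 - Z/m_s)$, which rises steeply as
  expression approaches the level $m_s$ at which burden stalls growth. A
  linear form is retained for sensitivity analyses. Cost is referenced to
  basal expression: $\eta(z_b) = 0$, and correspondingly
  $g(0,0) = g_0$ exactly — $g_0$ is *defined* as the measured growth rate
  in plain medium, basal-expression burden included. Genotypes derived from
  the wild type (e.g. a constitutive lacI-null mutant) keep the wild-type
  reference, so raising uninduced expression is paid for in full
  (`z_cost_ref` in `lac_growth_params()`).
* **Benefit.** $B(Z, P) = \delta Z^{a} f(P)$ with Hill saturation
  $f(P) = P^{h}/(k_p^{h} + P^{h})$ in the substrate. Benefit vanishes
  without enzyme or substrate and saturates in both. The exponent $a$ on
  expression is discussed under calibration below; the Hill exponent $h$ in
  $P$ is allowed above 1 because a pure Michaelis–Menten dependence cannot
  reproduce both the balance point (0.2 doublings/hr of benefit at 120 μM)
  and the maximal net increase (1.6 doublings/hr by 500 μM) simultaneously.

Repressor production cost is ignored throughout: 10–20 repressor molecules
against ~10^4 LacZ make it unobservable at growth-rate resolution.

### Derived quantities

* `optimal_expression(P)`: $Z_{\mathrm{opt}}(P)$ maximizes $B - \eta$ over
  $[z_b, z_{\max}]$. For concave benefit ($a \le 1$) the interior optimum
  solves the marginal condition $\partial B/\partial Z = \eta'(Z)$, a
  monotone 1-D root polished to $10^{-12}$; a 512-point grid plus golden
  section is the fallback for convex benefit. A brute-force dense-grid
  argmax serves as the independent oracle in the tests.
* `optimal_inducer(P)`: 1-D optimization of $g$ on $\log I$ with an explicit
  $I = 0$ check. When the unconstrained argmax exceeds 220 μM with less
  than 0.1% further improvement available the optimum is reported as
  `Inf` — the "saturating" marker: beyond full induction the exact inducer
  level no longer matters.
* `balance_concentration(I)`: the root of $B = \eta$ in $P$ by bracketing
  and `uniroot` at tolerance $10^{-9}$; anti-induction makes $Z$ itself
  $P$-dependent, so the composed model is solved, and the round trip
  $g(I, P_{\mathrm{bal}}) = g_0$ holds to $10^{-6}$ doublings/hr.
* `optimality_curve(p_grid)`: tabulates $Z_{\mathrm{opt}}$ and
  $I_{\mathrm{opt}}$ and locates the steepest point of
  $Z_{\mathrm{opt}}(P)$ on a dense Hyman monotone spline; an argmax within
  2% of either grid edge raises a diagnostic error (the grid does not
  bracket the inflection). The spline estimate is cross-checked in the
  tests against direct dense finite differencing of the closed-form curve.

## Calibration of the default parameters

`calibrate_ground_truth()` minimizes the sum of squared *relative*
mismatches between the model's derived quantities and the printed anchor
values (`lac_anchors()`), over
$\{\eta_0, m_s, \delta, k_p, h, k_{1/2}, n, z_b, a\}$ with $g_0$ and $k_a$
fixed, using Nelder–Mead from a seeded Latin-hypercube multistart in log
space. Two calibration choices deserve explanation:

* **Sublinear benefit in expression ($a \approx 0.3$).** With benefit
  linear in $Z$ and a saturating cost, the slope of
  $Z_{\mathrm{opt}}(P)$ is proportional to $f'(P) f(P)^{-3/2}$, which is
  strictly decreasing in $P$ for a Hill $f$ of any exponent. The steepest
  point of the optimality curve then always sits at its takeoff from basal
  expression — and the takeoff must lie below 100 μM Pgal for the optimal
  inducer at 100 μM to be nonzero. An inflection near 150 μM is therefore
  unreachable in the linear-benefit family, whatever the Hill exponents. A
  sublinear exponent (diminishing returns of enzyme level, as expected when
  uptake rather than hydrolysis limits the flux) makes
  $Z_{\mathrm{opt}}(P)$ a smooth sigmoid with an interior steepest point;
  $a$ is therefore calibrated rather than fixed at 1. The calibrated set
  reproduces all seven anchors to better than 0.2% (see
  `tidy(read_ground_truth(...))`).
* **Ridge toward the starting point.** Six scalar anchors cannot pin nine
  free parameters, so a small penalty ($10^{-3}$ in squared log-space
  distance) keeps the optimum unique and seed-stable. The result is frozen
  in `extdata/ground_truth.json` and shipped as `lac_default_params()`.

Residuals are recomputed with the public operations before being reported;
any anchor off by more than 15% is a named calibration failure.

## Fitting growth grids

`fit_growth_model()` is weighted least squares on replicate condition means
via Levenberg–Marquardt (16 seeded Latin-hypercube multistarts in log
space; non-convergence is flagged, never silent). Weights use a *pooled*
relative error — the RMS of per-condition replicate CVs, scaled by each
condition's mean and $\sqrt{n}$ — rather than raw per-condition SEMs: with
three replicates an individual SEM carries ~50% sampling error, and
weighting by it measurably biases the recovered full-induction cost
downward. Without replicates the global 4.3% error model is used. Only
$z_{\max}$ is frozen by default; from growth data alone only products like
$\delta z_{\max}^a$ are identifiable, which mirrors the practice of fixing
the expression scale from independent assays. Per-parameter 95% half-widths
come from the curvature of the fit (pseudo-inverse when a parameter escapes
to a flat direction, e.g. $m_s \to \infty$, the linear-cost limit).

`interpolate_landscape()` is a thin-plate smooth (mgcv) on
$(\log(1+I), \log(1+P))$ — the coordinates in which the condition grids are
roughly regular — with the smoothing parameter chosen by generalized
cross-validation by default; `smoothing = 0` reproduces the condition means
exactly (interpolation). Evaluation outside the convex hull of measured
conditions errors unless explicitly allowed.

## Serial-transfer evolution

The simulator implements grow-and-dilute cycles: each genotype grows
exponentially at its own model growth rate for the cycle's duration, and a
cycle lasts $\log_2(\text{dilution factor})$ generations of the first
(reference) genotype, which defines the generation clock. The selection
coefficient convention follows from this clock:

$$ \frac{\text{odds}(t+1)}{\text{odds}(t)} = 1 + s, \qquad
   1 + s = 2^{(g_{\mathrm{mut}} - g_{\mathrm{wt}})/g_{\mathrm{wt}}}, $$

per wild-type generation. Whether published coefficients are per generation
or per hour is not stated in this literature; this convention is documented
rather than asserted, and for small $s$ it reduces to
$\ln 2 \cdot \Delta g/g_{\mathrm{wt}}$. The deterministic mode tracks
frequencies exactly (and is invariant to splitting cycles into sub-cycles);
the binomial mode resamples multinomially at each bottleneck
(~$10^7$ cells at the default protocol: $10^9$ cells/ml × 10 ml ÷ 400) and
injects wild-type→mutant conversions as a Poisson draw on the cycle's
wild-type divisions. Population-mean expression is emitted under the two
assay conditions, uninduced $(I, P) = (0, 0)$ and induced $(220, 0)$ μM.

`fit_selection_coefficient()` fits the single-sweep competition model
$\bar{z}(t) = x(t) z_{\mathrm{mut}} + (1 - x(t)) z_{\mathrm{wt}}$ with
logistic $x(t)$, jointly over both assay channels, for $(s, x_0)$ by
Nelder–Mead from a 12-point start grid. One sweeping mutant class is
assumed — multi-mutant dynamics exist only in the simulator. A trajectory
whose range does not clear five times its own noise floor (estimated from
first differences, robust to the sweep trend) is rejected as
non-identifiable rather than fitted. The confidence half-width on $s$ is
profile-based: $x_0$ is re-optimized at each trial $s$ and the 95%
sum-of-squares threshold inverted. Since no initial mutant frequencies are
published, synthetic recovery experiments fix $x_0 = 10^{-7}$ by
convention.

`neutral_fixation_time()` is the $1/\mu$ drift timescale: at the lacI-null
mutation rate of $10^{-6}$ per cell per generation, $10^6$ generations —
the reason a fully induced environment shows no repressor loss within an
~800-generation experiment.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed:

* `generate_growth_grid()`: model growth × multiplicative Gaussian noise
  with CV 4.3% — the pooled error margin reported for 96 replicate wells.
  The published value is a single pooled margin; the Gaussian family is a
  documented choice, not a measurement. Default condition grid: IPTG
  {0, 2, 5, 15, 30, 50, 220} μM × Pgal {0, 39, 100, 240, 350, 500} μM,
  the concentrations named in the study.
* `generate_od_curve()`: exponential OD600 growth from 5×10⁻⁴ sampled every
  4 minutes, capped at a stationary plateau.
* `generate_fdg_curve()`: sigmoidal fluorescence accumulation whose maximum
  slope is proportional to LacZ activity, so the assay reduction is exactly
  linear in activity over arbitrarily many decades.
* `generate_trajectory()`: a deterministic logistic sweep mixed into
  population-mean expression with multiplicative observation noise (5%
  default).

Deliberately *not* emulated: evaporation compensation during plate reads,
stationary-phase "superinduction" of LacZ, bistability of induction at
intermediate IPTG, clonal interference, and the identity of the underlying
mutations. Passing the recovery tests therefore shows that the estimators
are unbiased and correctly scaled *within this model family under its
stated noise*, not that the model captures every feature of real
plate-reader or evolution data.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script use the study-scale designs: a
7 × 6 condition grid with 3 replicates for landscape recovery (averaged
over 8 Monte-Carlo grid+refit rounds in the acceptance script), 96 wells
for the noise-margin check, 800-generation trajectories sampled every 25
generations with 15–25 Monte-Carlo replicates per selection-coefficient
recovery, and 20–30 seeds for binomial-versus-deterministic simulator
comparisons. Root and optimization tolerances are $10^{-9}$–$10^{-12}$ on
the relevant scales; ties in `empirical_optima()` break toward lower IPTG
(expression is costly); the convex hull used by the interpolator is
inflated by $10^{-6}$ so boundary nodes evaluate cleanly.

## Known limitations

* The calibrated model family underestimates how steeply cost and benefit
  rise at low inducer concentrations — a discrepancy the original fits
  share. One visible consequence: the 50/50 time-averaged optimum constant
  inducer for the 39/500 μM environment pair falls near 90 μM here,
  whereas the measured growth data place it in the 5–30 μM range. The
  structural conclusions (concave front, small regulation advantage) are
  unaffected.
* Selection coefficients computed *from the growth model* for a
  constitutive mutant in high-Pgal environments are substantially larger
  than the published trajectory fits; the evolution recovery tests
  therefore use the published coefficients directly as ground truth for the
  trajectory generator, and the simulator's model-derived dynamics are
  checked qualitatively (who fixes, who persists) rather than by
  coefficient magnitude.
* Confidence half-widths from the fit curvature are first-order
  (delta-method through the log transforms) and degrade gracefully but
  approximately in flat directions.
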