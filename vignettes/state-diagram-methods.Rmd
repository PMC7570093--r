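---
title: "Modeling thermal transitions and state diagrams of sugar/maltodextrin systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling thermal transitions and state diagrams of sugar/maltodextrin systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statediagram)
```

## The problem

A state diagram maps the physical states of a food system — glassy,
rubbery, frozen, liquid — over the full plane of solids mass fraction
`ws` and temperature. For sugar-rich systems such as fruit juices it is
built from three ingredients:

* the **glass-transition curve** Tg(ws), strongly depressed by water
  (plasticization);
* the **freezing curve** Tm(ws), depressed by dissolved solutes; and
* the **maximal-freeze-concentration condition** (MFCC): the glass
  transition Tg′ and onset-of-ice-melting temperature Tm′ of the
  maximally freeze-concentrated unfrozen phase, and the solids fraction
  ws′ at which maximum ice formation occurs.

Frozen-storage stability lives between Tg′ and Tm′; spray-drying and
powder-storage stability is governed by Tg(ws) in the low-moisture
domain. Because fruit juices have very low Tg′/Tm′, high-molecular-weight
carriers such as maltodextrin are blended in to raise them; this package
implements the complete computational chain for quantifying that effect.

## Models

**Glass-transition curve (Gordon–Taylor).** For a solids–water binary,

$$T_g(w_s) = \frac{w_s T_{gs} + K (1 - w_s) T_{gw}}{w_s + K (1 - w_s)},$$

with `tgs` the anhydrous-solids glass transition (°C), `tgw` the
amorphous-water value fixed at −135 °C (never fitted), and `K > 0` the
water–solids interaction constant. The expression is a weighted mean of
two temperatures, hence affine-invariant: computing in °C is exact, and
the package carries all temperatures in °C (this matches every value the
models are compared against). Tg(ws) is non-decreasing in `ws` whenever
`tgs > tgw`.

**Freezing curve (Chen).** Freezing-point depression is modeled as

$$T_m(w_s) = T_w + \frac{\beta}{\lambda_w}
  \ln\!\frac{1 - w_s - B w_s}{1 - w_s - B w_s + E w_s},$$

with `tw` the pure-water freezing point (fixed 0 °C; it is a physical
constant here, not a fitted parameter), `beta` = 1860 kg·K/kgmol the
molar freezing-point constant of water, `lambda_w` = 18.015 kg/kgmol the
molecular mass of water, `E` the water-to-solids molecular mass ratio
and `B` the ratio of unfreezable water to total solids. The curve is
strictly decreasing, equals `tw` at `ws = 0`, and diverges to −∞ at the
domain boundary `ws_max = 1/(1+B)` where the unfrozen-water term
vanishes. `lambda_w` is not printed alongside the model in the source
tables; fixing it at 18.015 reproduces the tabulated ws′ values to their
printed precision, which is the package's validation of that constant.
The solids-side molecular mass never appears on its own: `E` is fitted
directly and λs is not reconstructed.

## Curve fitting

`fit_gordon_taylor()` estimates (tgs, K) from (ws, Tg) pairs and
`fit_chen()` estimates (E, B) from (ws, Tm) pairs, both by unweighted
least squares in °C (no error model beyond homoscedastic residuals is
assumed). Numerical choices:

* Levenberg–Marquardt with box bounds (`minpack.lm`), relative
  sum-of-squares tolerance 1e-10, 500-iteration cap.
* Starts: `tgs` ← max observed Tg, `K` ← 4; `E` ← 0.05, `B` ← 0.15 —
  central values of the ranges observed across 25 real systems.
* Bounds: `tgs` ∈ (−50, 250) °C, `K` ∈ (0.1, 50), `E` ∈ (1e-4, 1),
  `B` ∈ [0, 0.99]; additionally `B` is capped below
  `(1 − max ws)/max ws` so the log argument stays positive at every data
  point throughout the search.
* On non-convergence the fit is retried from five deterministically
  jittered starts before being returned flagged (`converged = FALSE`);
  fitting never consumes the user's RNG stream.
* At least 3 points per curve are required (2 parameters + 1 residual
  df), and a design with a single distinct `ws` is rejected.

Goodness of fit is the coefficient of determination
R² = 1 − SSE/SST, SST about the observation mean.

## The MFCC by curve intersection

Tg′ and Tm′ vary little across moisture levels in annealed scans, so a
sample's values are unweighted means of the replicate observations
(`average_transition()`; no replicate- or moisture-weighting is applied,
as none is defined for these data). `solve_ws_prime()` intersects the
averaged Tm′ with the fitted freezing curve: since the curve is strictly
monotone from `tw` to −∞, the root is unique and a bracketed Brent
search on (0, ws_max) converges unconditionally; tolerance is 1e-12 on
`ws` and the root is verified to reproduce Tm′ within 1e-6 °C. ws′ is
strictly decreasing in Tm′.

Two deliberate non-enforcements:

* Tg′ is carried as the measured average and is *not* recomputed from
  the glass-transition curve at ws′ — measured Tg′ and the Gordon–Taylor
  value at ws′ genuinely disagree (by ~7 °C for pure fructose), so
  consistency must not be imposed.
* When Tg′ is undetected (it can overlap the melting onset in
  high-maltodextrin systems), it is `NA`, or equal to Tm′ only if the
  input says so.

`tabulate_curves()` exports both curves on an even grid over [0, 1],
blanking the freezing curve beyond `ws_max`.

### Reliability of the intersection

The error in ws′ is roughly the Tm′-plus-curve error divided by the
curve slope at the intersection. For steep curves (high `E`, e.g. pure
fructose, |dTm/dws| ≈ 340 °C near ws′) the method is precise; for flat
curves (low `E`, high-maltodextrin systems) it degrades sharply — the
simulation study in `analysis/04_simulation_study.R` quantifies this
(99% of runs within 0.01 at 1 °C noise for the steep curve, ~27% for the
flat one). This is a property of the method itself, not of the
implementation, and is why an independent experimental determination of
ws′ is preferable for high-polymer systems.

## Mixture models over the composition design

The effect of solute composition (fructose, glucose, sucrose, pectin,
citric acid, maltodextrin; dry-basis fractions summing to 1) on the
seven responses (tgs, K, E, B, Tg′, Tm′, ws′) is modeled with a Scheffé
mixture polynomial: 6 linear blending terms plus 15 pairwise products,
**no intercept** (the simplex constraint makes one redundant), fitted by
ordinary least squares on a 25-run D-optimal design. Coefficients are in
raw mass-fraction units, so a model's value at a pure-component vertex
is that component's linear coefficient exactly.

ANOVA conventions (the originating software's internals are not
published, so these are fixed here once):

* residual SD = sqrt(SSE/(n − p)); CV = 100·SD/|mean response|;
* R² and the regression F-test are computed **about the response mean**
  (df p − 1 and n − p) even though the model has no intercept — this
  choice reproduces the published R², SD and CV of all seven models
  within rounding, which is the package's evidence for it;
* coefficient p-values are two-sided t-tests on the OLS standard errors
  with n − p df.

`prune_model()` performs backward elimination: repeatedly drop the
pairwise term with the largest p-value above `alpha = 0.10` and refit,
until all remaining pairwise terms clear the threshold. The six linear
terms are never dropped (every published model retains them). Two
caveats worth knowing: backward elimination is greedy, and on this
particular design — full rank but with condition number ≈ 2×10⁴ —
selection effects can retain spurious clusters of correlated
interactions under a null generator, and can mask a true interaction
whose partial leverage is small. The pruning tests therefore assert the
invariants of the procedure (retained terms significant, df bounds,
linear terms kept) rather than a fixed count of surviving terms.

`predict_state_diagram()` evaluates the seven models at a blend of a
maltodextrin-free base with fraction `xm` of maltodextrin; the base
fractions are scaled by (1 − xm), the only convention that preserves
their ratios while keeping the simplex constraint. The predicted MFCC
comes from its own response models and is deliberately not forced onto
the predicted freezing curve (the consistency check is disabled for
predicted diagrams).

The bundled E model is transcribed verbatim from its source but carries
two visible typesetting defects (an XF coefficient 10× the measured
pure-fructose value, consistent with a lost leading zero, and a
truncated XM term); it is usable for qualitative trends only and is
excluded from numeric validation.

## Synthetic data

`generator_spec()` / `generate_thermal_dataset()` emulate the
measurement structure of an annealed DSC moisture series: Tg at 6
solids fractions in the unfreezable domain (ws 0.80–1.00), Tm at 6
levels spanning 27–90% water wet-basis (ws 0.10–0.73), and 6 replicate
Tg′/Tm′ observations, all with additive homoscedastic Gaussian noise
(defaults 1.0 °C for curve points, 1.5 °C for the primes, matching the
few-°C scatter seen in real prime transitions across moisture levels).
No error model is published for these measurements; additive Gaussian
noise in °C is the simplest defensible choice. Defaults for the
generating parameters are the pure-fructose set (tgs = 10.4 °C,
K = 2.90, E = 0.0954, B = 0.1668, ws′ = 0.739, Tg′ = −55.9 °C); the
true Tm′ is the generating freezing curve at ws′, so the generated MFCC
is self-consistent, while the true Tg′ is free, as in real data. One
integer seed fixes the entire realization. `generate_design_study()`
does the same for a full 25-run design-response table given seven
generating mixture models.

What the generator does *not* emulate: raw heat-flow thermograms,
annealing kinetics, transition-detection error (transitions are
consumed already annotated), heteroscedastic or moisture-correlated
noise, and composition errors in sample preparation. Passing the
recovery tests therefore shows the estimation chain is correct and
stable under measurement noise — not that the models themselves are
adequate for any particular real system.

## Problem sizes and determinism

The validation suite uses 25-run designs, 6-point moisture series,
100-draw parameter-recovery sweeps and 200-seed Monte-Carlo pipelines —
sizes chosen to estimate coverage proportions to a few percent while
keeping the whole suite interactive (seconds to a couple of minutes).
Every stochastic test fixes its seed; the curve fitters are
deterministic by construction.

## Known limitations

* The intersection-based ws′ inherits the method's flat-curve weakness
  described above.
* The Chen fit extrapolates beyond the highest measured `ws` when the
  intersection lies there; extrapolation error dominates the ws′ error
  budget.
* Backward elimination is greedy; with 25 runs and up to 21 terms,
  inference after selection is descriptive, not confirmatory.
* Published-table transcriptions are only as good as their printing:
  one row's ws′ is internally inconsistent by ~0.004 and the E model is
  defective as printed; both are documented where they are loaded.
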