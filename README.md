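# statediagram

Construction and prediction of **state diagrams** for sugar-rich food
systems (fruit-juice model systems with maltodextrin) from differential
scanning calorimetry (DSC) transition temperatures.

A state diagram maps the physical states of a food — glassy, rubbery,
frozen, liquid — over the solids-fraction × temperature plane. It
combines the glass-transition curve, the freezing curve, and the
maximal-freeze-concentration condition (Tg′, Tm′, ws′) that bounds
frozen-storage stability. This package implements the full computational
chain used to build and model such diagrams:

* **Glass-transition curve** — Gordon–Taylor equation
  `Tg(ws) = (ws·Tgs + K(1−ws)·Tgw) / (ws + K(1−ws))`, with
  `Tgw = −135 °C`, fitted for `(Tgs, K)` by bounded nonlinear least
  squares (`fit_gordon_taylor()`).
* **Freezing curve** — Chen freezing-point-depression equation
  `Tm(ws) = Tw + (β/λw)·ln[(1−ws−B·ws) / (1−ws−B·ws+E·ws)]`, with
  `β = 1860 kg·K/kgmol`, `λw = 18.015 kg/kgmol`, fitted for `(E, B)`
  (`fit_chen()`).
* **MFCC derivation** — the averaged onset-of-melting temperature Tm′ is
  intersected with the fitted freezing curve to obtain ws′
  (`solve_ws_prime()`, `build_state_diagram()`).
* **Composition modeling** — Scheffé mixture polynomials (6 linear + 15
  pairwise terms, no intercept) over a 25-run six-component D-optimal
  design, with ANOVA statistics and backward pruning of nonsignificant
  interactions (`fit_mixture_model()`, `prune_model()`), and prediction
  of complete state diagrams for arbitrary juice/maltodextrin blends
  (`predict_state_diagram()`).
* **Synthetic data** — a seeded generator of moisture-series transition
  data and design-response studies with known ground truth
  (`generator_spec()`, `generate_thermal_dataset()`,
  `generate_design_study()`).

The reference design, fitted-parameter and model tables of a 25-system
maltodextrin study ship as plain-CSV fixtures (`load_fixtures()`).

## Worked example

Derive the state diagram of pure fructose from its fitted curve
parameters and its measured prime transitions:

```r
library(statediagram)

fx <- load_fixtures()
r  <- fixture_row(fx$parameters, 1)     # pure fructose

# solids fraction at maximum ice formation, by curve intersection
solve_ws_prime(r$chen, r$tm_prime)
#> [1] 0.7393598

dg <- state_diagram(r$gt, r$chen,
                    mfcc(r$tg_prime, r$tm_prime,
                         solve_ws_prime(r$chen, r$tm_prime)))
dg
#> State diagram
#> Gordon-Taylor parameters: tgs = 10.4 degC, k = 2.9, tgw = -135 degC
#> Chen parameters: e = 0.0954, b = 0.1668 (ws_max = 0.8570), tw = 0 degC
#> MFCC: Tg' = -55.9 degC, Tm' = -42.8 degC, ws' = 0.7394
```

The solved ws′ = 0.739 means that at maximum ice formation the unfrozen
phase of fructose solution is 73.9% solids; the remaining 26.1% is
unfreezable water. Frozen storage below Tg′ = −55.9 °C keeps that phase
glassy.

Predict how maltodextrin shifts the diagram of a five-solute juice
blend:

```r
base <- composition(0.283, 0.283, 0.283, 0.075, 0.075, 0, tol = 0.002)
d6 <- predict_state_diagram(base, xm = 0.6, fx$models)
d6$mfcc
#> MFCC: Tg' = -46.54 degC, Tm' = -25.07 degC, ws' = 0.7939
```

Adding 60% maltodextrin raises the predicted Tm′ from −38.3 °C (no
maltodextrin) to −25.1 °C: less freezing-point depression, a wider and
warmer stability window — the cryoprotectant effect.

The numbered scripts under `analysis/` run the complete workflow
(diagram reconstruction for all 25 systems, mixture-model refits and
pruning, the maltodextrin prediction sweep, and a simulation study of
ws′ recovery) and write their tables under `results/`.

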