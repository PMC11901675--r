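---
title: "Ion-depletion uptake kinetics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-depletion uptake kinetics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgkinetics)
```

## The measurement and the model

In a solution-depletion (ion-depletion) experiment, seedlings grow in a
pot of hydroponic solution and the concentration of the nutrient of
interest — here Mg²⁺ — is sampled repeatedly as the roots take it up.
The package's reference design is two tea cultivars (Rougui, Shuixian)
× seven culture-solution treatments (`Mg_control`, `Mg_All`, `Mg_N`,
`Mg_P`, `Mg_K`, `Mg_other`, `Mg_Mg`) × three replicate 2 L pots, each
sampled hourly over 0–15 h.

Each pot's record is summarised by an empirical quadratic,

$$C(t) = c + b\,t + a\,t^2,$$

fitted by ordinary least squares. For a depleting pot $a > 0$ and
$b < 0$: concentration falls fastest at the start and levels off as
uptake saturates. Two kinetic parameters condense the curve:

* $I_{\max} = |b| \cdot V / \mathrm{FRW}$ — the maximum uptake rate.
  $|b|$ is the initial depletion rate in mg·L⁻¹·h⁻¹, $V$ the solution
  volume (L), FRW the fresh root weight (g). Since $|b| V$ is mg/h and
  the field reports µg·g⁻¹·h⁻¹, the implementation multiplies by 1000;
  this is the only conversion consistent with the reported magnitudes
  of the treatment effects (hundreds of µg·g⁻¹·h⁻¹ in 2 L pots).
* $C_{\min} = b^2/4a - b^2/2a + c$ — algebraically the vertex value
  $c - b^2/(4a)$, i.e. the solution concentration at which the fitted
  net uptake rate reaches zero. The package evaluates the expanded form
  exactly as written and tests it against a grid-minimisation oracle.

Treatment effects are expressed as differences from the unstarved
control (`Mg_control`) of the same cultivar: $\Delta I_{\max}$ and
$\Delta C_{\min}$, treatment mean minus control mean.

Three aggregation choices matter and are fixed by design:

* **Per-replicate first.** Kinetic parameters are computed per
  replicate fit and then averaged — never by pooling replicates and
  refitting. This is what reproduces the reported $\Delta C_{\min}$
  extremes from the packaged coefficients to two decimals.
* **Extrapolated vertices are kept.** Several reference curves (e.g.
  the Rougui control, vertex ≈ 21.5 h) reach zero uptake only beyond
  the 15 h window. $C_{\min}$ is still computed, and the fit carries
  `extrapolated = TRUE` so users can see which values rest on
  extrapolation.
* **Non-depletion shapes are flagged, not fatal.** A noisy shallow pot
  can fit with $a \le 0$ or $b \ge 0$. Such fits yield NA kinetic
  parameters and a warning collected in the pipeline report; they are
  excluded from treatment means rather than silently dropped or allowed
  to crash a 42-pot run.

Reported tables round half away from zero to 2 decimals (the source
tables' convention — base R's `round()` rounds half to even); JSON
output keeps full precision.

## Inference layer

Treatment comparisons use one-way ANOVA with **Duncan's multiple range
test** at $\alpha = 0.05$, the method behind the letter annotations of
the reference figures. Means are sorted descending; a pair $p$ ranks
apart is compared against the shortest significant range
$R_p = q_{1-\alpha_p}(p, \mathrm{df}_e)\sqrt{\mathrm{MSE}/n_h}$ with
the protection level $\alpha_p = 1-(1-\alpha)^{p-1}$, $n_h$ the
harmonic mean group size (Kramer adjustment; the reference design is
balanced at $n = 3$ anyway). Critical points come from numerical
evaluation of the studentized range distribution
(`stats::ptukey`/`qtukey`), not from tables, so any error df and
protection level are supported; the test suite checks them against an
independent double-quadrature oracle. Letters are assigned to maximal
non-significant stretches with the usual insert-and-absorb rule, so
letter displays are always order-consistent. With two groups the
procedure reduces exactly to the pooled-variance *t*-test.

**PCA** of the kinetic parameters standardises variables by default:
$I_{\max}$ (hundreds of µg·g⁻¹·h⁻¹) and $C_{\min}$ (tens of mg/L) are
on incommensurable scales, so a covariance PCA would be dominated by
$I_{\max}$. Whether the original analysis used correlation or
covariance is not stated; standardisation is this package's documented
default and can be turned off.

**RDA** regresses the (standardised) response block on the explanatory
block and ordinates the fitted values (via `vegan`), reporting the
constrained variance fraction. The variable assignment is not fixed by
the reference analysis, so the pipeline's default — response =
{$I_{\max}$, $C_{\min}$, root Mg content}, explanatory = {relative
*CsMGT5* expression} — is a configurable choice.

**Path model.** The causal chain

$$\text{expression} \rightarrow I_{\max} \rightarrow C_{\min}
  \rightarrow \text{Mg content}$$

is estimated as a PLS path model with one indicator per construct.
In that degenerate case the outer-weight iteration of general PLS-PM
is a no-op: each standardized path coefficient is exactly the OLS slope
(= Pearson correlation) of consecutive standardized columns. The
implementation says so and fits the sequential regressions directly
rather than emulating the iteration. Significance comes from a row
bootstrap (999 replicates by default, seeded through the public
interface): percentile two-sided p-values with `**` for p < 0.01 and
`*` for p < 0.05.

## What the synthetic generator emulates

`generate_experiment()` draws complete experiments with the reference
design's statistical structure so every stage is testable without any
external data:

* **Design**: 2 cultivars × 7 treatments × 3 pots, $t = 0,1,\dots,15$ h
  (16 samples; the grid includes $t=0$ to anchor the intercept),
  $V = 2$ L.
* **Treatment structure**: per-treatment mean relative expression
  taken from the reported fold changes (control = 1, `Mg_Mg` highest,
  `Mg_All` lowest), plus pot-level Gaussian variation (sd 0.4 fold).
* **Structural chain**: pot-level latent expression propagates through
  standardized coefficients (0.94, −0.94, −0.95) — the reported path
  values — with disturbances drawn orthogonal to the predictor in-sample
  and rescaled so the *sample* standardized coefficient equals the
  configured value exactly (the same "empirical" calibration as
  `MASS::mvrnorm(empirical = TRUE)`). Consequently, with all
  measurement noise at zero the full pipeline recovers the configured
  coefficients to within discretisation error, a sharp test of the
  whole chain.
* **Physical mapping**: standardized $I_{\max}$, $C_{\min}$ and content
  map linearly onto means (400 µg·g⁻¹·h⁻¹, 28 mg/L, 90 µg/g) and sds
  (120, 4.5, 35) back-calculated from the packaged coefficient table
  and the reported content means; the depletion quadratic is then
  reconstructed per pot ($b = -I_{\max}\mathrm{FRW}/(1000 V)$, $a$ from
  $C_{\min}$, $c \approx 40$ mg/L). Parameter draws that are physically
  impossible (e.g. $C_{\min}$ at or above the starting concentration)
  abort generation with an error naming the pot — they are not clipped,
  since clipping would silently distort the configured correlation
  structure.
* **Measurement noise**: additive Gaussian on each concentration
  reading (sd 0.6 mg/L, truncated at 0), approximately homoscedastic as
  expected for AAS readings in this range. Digest readings and qPCR Ct
  values are emitted so that the assay arithmetic back-calculates the
  intended contents and folds exactly.
* **Fresh root weight** is never reported for the reference experiment,
  so pots draw FRW from a lognormal (mean 8 g, CV 0.2 — a plausible
  mass for six one-year seedlings per pot). This is a modelling choice,
  recorded in the generated manifest; absolute $I_{\max}$ values are
  therefore only internally consistent, not comparable to the reported
  ones.

What the generator does **not** emulate: mechanistic uptake
(Michaelis–Menten influx, compartments), heteroscedastic or
proportional measurement error, the tiny dilution from hourly 1 mL
sample withdrawals (available behind a flag, off by default because the
quadratic model ignores it), and day-to-day drift. One consequence is
worth stating plainly: under homoscedastic noise of realistic size, the
very shallow pots (total depletion of a few mg/L, as in the Shuixian
control cells) cannot reach the reference table's $R^2 \ge 0.92$ — the
printed uniformly high $R^2$ values imply error roughly proportional
to each curve's depth. Passing tests therefore demonstrate correct
arithmetic and faithful recovery under the stated noise model, not that
the noise model reproduces every feature of the real instrument series.

## Numerical choices

* Least squares via QR of the Vandermonde design (conditioning is mild
  at $t \le 15$, but stability costs nothing); $R^2 = 1$ by convention
  when SS_tot = 0.
* Coefficient recovery checks use design-based standard errors
  ($\sigma\sqrt{[(X^\top X)^{-1}]_{jj}}$ with the known generating
  $\sigma$), the natural yardstick when the noise level is part of the
  simulation design.
* Zero within- and between-group variance in ANOVA → $F = 0$, $p = 1$;
  detection uses a relative tolerance because `lm` residuals of a
  constant response are not exactly zero in floating point.
* Bootstrap p-values use the add-one percentile form
  $2\min(\cdot)/(B+1)$, so 999 replicates can report p as small as
  0.002 but never 0.

## Problem sizes in the test suite

The stochastic properties are checked at the scale of the reference
design: 200 seeded simulations over all 42 packaged curves for
coefficient/$C_{\min}$ recovery, 200 seeded synthetic experiments
(n = 42 pots each) for path-sign recovery, and 500 two-group
simulations for the Duncan/*t* equivalence. The whole suite runs in
well under a minute on a single core.

## Known limitations

* Absolute $I_{\max}$ (and $\Delta I_{\max}$) cannot be validated
  against the reported ranges because FRW values were never published;
  only $C_{\min}$-based quantities are exactly checkable from the
  packaged coefficients.
* The reference report's finer within-group ordering of the Shuixian
  N/P/K $C_{\min}$ means is not reproducible from the packaged
  coefficients (they give N > K > P); assertions are made only at the
  significance-group level, where the two sources agree.
* Only the single-indicator chain path model is implemented — no
  multi-indicator PLS-PM modes, and no alternative post-hoc tests
  (Duncan is what the reference analysis specifies).
* Concentration units follow the source's mg/L labelling throughout,
  although a 100 µmol/L MgSO₄ stock corresponds to ≈ 2.4 mg/L Mg; the
  package does not attempt to resolve that inconsistency.
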