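---
title: "Methods: surrogate-based indoor heat-stress projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-based indoor heat-stress projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(indoorheat)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic world
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The projection workflow

The package projects indoor thermal conditions at a single workplace in
five stages: (i) obtain a training era of paired outdoor weather and
indoor observations; (ii) compute the indoor physiologically equivalent
temperature PET$_i$ from the indoor channels; (iii) train one neural
surrogate per target ($T_i$, PET$_i$) mapping outdoor weather to the
indoor observable; (iv) bias-correct each climate-scenario member against
the historical outdoor reference by quantile delta mapping; (v) drive the
surrogates with the historical reference and each corrected member, and
reduce the predictions to exposure statistics on a noleap calendar.

The central assumption is stationarity of the *building*: the learned
outdoor→indoor transfer is held fixed across periods, so projected indoor
changes reflect only the changing outdoor forcing — no renovations, no
added cooling, no behavioural adaptation. The surrogate is also an
interpolator asked to mildly extrapolate: a future that is a few kelvin
warmer than anything in the training era is predicted from the smooth
continuation of the learned response (the sigmoid hidden layer saturates,
so extreme extrapolations are conservative rather than explosive).

## 2. The indoor comfort model (MEMI / PET)

PET$_i$ is computed with a two-node steady-state heat-balance model of the
Munich Energy Balance Model for Individuals family. Three nodes — core,
skin, clothing — satisfy

* core: $m - q_\mathrm{resp} - q_{cr \to sk} = 0$
* skin: $q_{cr \to sk} - E_{sk} - q_\mathrm{bare} - q_{sk \to cl} = 0$
* clothing: $q_{sk \to cl} - q_{cl \to env} = 0$

per unit DuBois area. The body surface splits into a bare fraction
(emissivity 0.99) exchanging directly at skin temperature and a clothed
fraction (covered-area polynomial in clo; emissivity 0.95; clothing
resistance $0.155\,I_{cl}$ m²K/W; outer-area factor $1 + 0.31\,I_{cl}$).
Core and skin are coupled by Gagge-type skin blood flow
$\dot m_{bl} = (6.3 + 75\,\Delta T_{cr}^+)/(1 + 0.5\,\Delta T_{sk}^+)$
clipped to [0.5, 90] L m⁻² h⁻¹; regulatory sweating is driven by the mean
body temperature above 36.6 °C (304.94 g m⁻² h⁻¹ K⁻¹, capped at
500 g m⁻² h⁻¹) and bounded by the evaporative maximum from the Lewis
relation (1.65 K/hPa), with a 6 % diffusion-wetness floor. Convection uses
$h_c = 2.67 + 6.5 v^{0.67}$ with $v$ floored at 0.1 m s⁻¹; respiration
follows the standard expired-air parameterisation.

**PET definition.** The actual-environment system is solved for
$(T_{cr}, T_{sk}, T_{cl})$; PET is then the air temperature of the
reference environment ($T_{mrt} = T_a$, $v = 0.1$ m s⁻¹, VP $= 12$ hPa,
same person) at which the body with that same core/skin state and the
same *regulatory sweat heat flux* is again in balance. Holding the sweat
flux (not the wetness fraction) fixed is what makes strongly radiant
environments map to high PET; the passive diffusion term is re-evaluated
in the reference environment. When the actual environment *is* the
reference environment, all fluxes coincide and PET $= T_a$ identically —
the defining identity, tested to 0.1 K on [10, 35] °C.

**Numerics.** The actual state is found by nested bisection (inner: core
temperature from the core balance, strictly monotone in $T_{cr}$; outer:
skin temperature on [0, 43] °C; clothing temperature from its own monotone
balance), and the reference search by bisection on $[-50, 80]$ °C to
0.01 K in ≤ 100 iterations — robustness over cleverness. Failure to
bracket a root raises an error carrying the offending inputs; the model
never returns a silent `NaN`.

**Standardized person.** 35-year-old male, 1.75 m, 75 kg, 0.9 clo, 80 W
work above basal metabolism (classic basal-rate formula). All constants
are exposed through `person_parameters()` and `globe_spec()`.

**Cross-validation.** No third-party PET implementation is installable in
the build environment, so the reference oracle is an independently coded
transcription of the same published formulation (Python/scipy, simultaneous
`fsolve` + `brentq`; `tools/pet_reference.py`), frozen as a 100-point grid.
Agreement is ~0.002 K, which validates the numerics; it cannot detect an
error shared by both transcriptions of the formulation. As a formulation
sanity check, classic published example scenarios (e.g. $T_a = 30$,
$T_{mrt} = 60$, VP $= 21$, $v = 1$) land within ~3 K of the classic
code's integer-rounded values — the level at which PET implementations
with different clothing geometries legitimately differ.

**Mean radiant temperature** uses the ISO 7726 forced-convection globe
relation with a standard globe (0.15 m, emissivity 0.95) — exact for
$v = 0$ and $T_g = T_a$ by construction. The globe spec of the emulated
low-cost sensor is unknown, so the standard constants are a documented,
configurable assumption.

**Stress classes** partition the PET axis at 18/23/29/35/41 °C. The
comfortable band is the open interval (18, 23): heat thresholds are
inclusive at the lower edge (PET = 29 is moderate heat stress), PET = 18
falls to cold stress. Cold sub-classes are lumped into a single cold
class, matching how aggregated frequency figures are usually presented.

## 3. The surrogate

Architecture is fixed at 18–16–1: sigmoid hidden layer, linear output.
The 18 inputs are the six outdoor variables at $t$ plus $T_a$, $G$, $A_G$
at $t-3,6,12,24$ h; the lags are how a memoryless network represents
thermal inertia. Training minimises mean squared error with Adam
(learning rate $10^{-4}$, batch size 8) on a random 80/10/10 split.

Decisions taken where the protocol was open:

* **Standardization**: features and target are z-scored with
  training-split statistics (sigmoid units effectively require it; the
  scalers are part of the model and inverted at prediction).
* **Early stopping**: patience 20 epochs on validation MSE, max 500
  epochs, best-validation weights restored.
* **Seeding**: one seed drives Glorot initialisation, the split and batch
  shuffling; identical seed ⇒ bit-identical model.

The linear output head makes the model exactly equivariant to constant
target shifts (tested), and on a linear synthetic building the network
must reach ≤ 2× the MAE of an ordinary-least-squares oracle fitted to the
same features — the irreducible-noise baseline.

## 4. Quantile delta mapping

For a future value $x$ with non-exceedance probability
$\tau = F_{mf}(x)$ estimated from the future sample itself (plotting
positions $(r - 0.5)/n$), the corrected value is
$\hat x = F_{oh}^{-1}(\tau) + [x - F_{mh}^{-1}(\tau)]$ (additive) or
$\hat x = F_{oh}^{-1}(\tau)\, x / F_{mh}^{-1}(\tau)$ (multiplicative),
with empirical quantile functions interpolated linearly between order
statistics. This removes the historical bias while preserving the
projected change at every quantile — the defining property, tested
against a brute-force quantile oracle at $n = 10^4$.

Choices: additive mode for $T_a$, $T_d$, $p$, $A_G$; multiplicative with
trace threshold 0.05 for the zero-bounded $G$ and $v$ (zeros map to
zeros; denominators never blow up). Pooled 30-year distributions by
default, calendar-month grouping available (the grouping used by the
original study is unstated; pooling is the weaker assumption). Beyond the
historical support the edge delta is extrapolated constantly. After
correction, physical invariants are re-imposed ($T_d$ clipped to $T_a$,
$G, v$ floored at 0) with every repair counted and logged — corrections
are audit-able, never silent.

## 5. Exposure metrics

All metrics run on a noleap calendar (every Feb 29 removed; 2920 3-h
steps per year). Exceedance hours multiply the count of steps at or above
the threshold by the step width ("≥" exactly as the thresholds are
defined; 26/30/35 °C for $T_i$ per occupational guidance, 23/29/35/41 °C
for PET$_i$ per the physiological stress scale). A heat day is a day
whose daily maximum meets the threshold; partial first/last days are
excluded and counted. Mean consecutive-run length averages maximal runs
within each year, then across years; years without runs contribute 0
(configurable to exclusion, and a pooled-runs variant exists, since the
averaging convention of published run statistics is ambiguous). Working
hours are the closed interval 09:00–18:00 UTC — at 3-h resolution the 09,
12, 15 and 18 steps, a deliberate boundary decision (the 18:00 step is
counted). Seasons are calendar months; December belongs to the following
winter for bookkeeping. Every metric is verified against brute-force
enumeration on randomized series.

## 6. The synthetic world

The generator emulates the *statistical structure* the pipeline needs,
with known ground truth:

* outdoor variables = annual mean + seasonal cosine + diurnal cosine +
  AR(1) noise; dew point as $T_a$ minus a non-negative depression;
  irradiance as a cosine hump inside a seasonally varying daylight window
  (nighttime zeros by construction); long-wave radiation coupled to the
  $T_a$ anomaly. Defaults approximate a temperate mid-latitude valley
  climate (annual mean 10.5 °C, seasonal amplitude 9 K, diurnal 4 K,
  AR(1) 0.8 with 1 K innovations at 3 h, peak irradiance 800 W m⁻²),
  chosen once as realistic and not tuned thereafter.
* scenarios add a static bias (what QDM must remove), a realised uniform
  offset and a linear in-window ramp (the climate signal), with optional
  extra summer warming; multiplicatively for $G$ and $v$ to preserve
  zeros. The imposed change is exactly recoverable, which is what the
  end-to-end null and +3 K recovery experiments exploit.
* the building is a single thermal node,
  $\dot T_i = (T_a - T_i)/\tau + aG + q(t) + \max(0, k(T_{set} - T_i))$,
  integrated by explicit Euler with internal sub-stepping (sub-step
  $\le \tfrac12 \min(\tau, (1/\tau + k)^{-1})$, forcing held constant
  within an outer step), so small $\tau$ remains stable at a 3-h series
  step; disabling sub-stepping restores the strict $\Delta \le \tau$
  rejection. Indoor RH conserves the outdoor vapour pressure re-evaluated
  at $T_i$ (clipped to [5, 100] %); the globe channel reads
  $T_i + c_g G$; indoor air speed defaults to the still-air 0.1 m s⁻¹
  (the assumption also used when no air-speed sensor exists — documented
  and configurable). White noise (0.3 K) on the indoor channels.

What the generator does **not** emulate: weather fronts and synoptic
persistence beyond AR(1), humidity extremes, multi-zone buildings,
occupant behaviour, ventilation dynamics, sensor drift. A green test
therefore establishes that the pipeline recovers known structure from
data with realistic variance and autocorrelation — not that it handles
every pathology of real sensor records.

## 7. Desk-scale defaults and determinism

Period lengths default to 1 training year and 3-year historical/future
periods so that the full experiment (including five seeded heated
replicates of the damping test) runs in minutes on one CPU; the study
design they mirror uses 30-year periods, and all spans are configurable.
Every stochastic stage derives its seed from the master workplace seed;
running the pipeline twice with the same seed yields identical reports,
which the suite asserts.

## 8. Known limitations

* The heat-balance model is steady-state: no transient storage, no
  acclimatisation, and PET inherits the documented spread between
  published implementations (~0.3 K on ordinary indoor ranges, more in
  extreme radiant cases).
* QDM is univariate; inter-variable dependence is repaired a posteriori
  (clipping) rather than corrected jointly.
* The surrogate extrapolates conservatively beyond its training range:
  projected indoor warming in strongly heated/saturated regimes is a
  lower-bound-flavoured estimate, which is the qualitative behaviour the
  damping experiments test for, but its magnitude should not be read as
  calibrated for extremes far outside the training era.
* The ensemble scaffolding treats members as exchangeable; there is no
  model weighting.
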