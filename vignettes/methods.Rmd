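---
title: "Methods: sensor correction, time-series estimators and the time-resolved IC50"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor correction, time-series estimators and the time-resolved IC50}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tric50)
```

This vignette is the package's own account of the statistical procedures it
implements, their assumptions, the tunable parameters, and the design
decisions taken where more than one reasonable choice existed.

## The measurement model

A time-resolved plate assay yields a table with a shared time axis and one
measurement series per well. Two systematic effects separate the recorded
series from the biology of interest:

1. **Per-sensor gain.** Optical sensors (e.g. oxygen-sensing spots read by
   luminescence lifetime) differ slightly in geometry and excitation, so two
   sensors exposed to the same true value report slightly different numbers.
   When the calibration relationship between the measured quantity $y$ and
   the output $x$ is exponential,
   $$x = P + S\,e^{\alpha y},$$
   with plateau $P$ and span $S$, this inter-sensor variability acts
   multiplicatively in the *log domain*
   $$z = \ln\!\frac{x - P}{S},$$
   i.e. sensor $s$ reports $z_s = g_s\,z^{\mathrm{true}}$ for a gain
   $g_s \approx 1$. A naive multiply/divide correction in the original units
   is exact only for a linear calibration curve; for an exponential one it
   leaves level-dependent residual spread.

2. **Ambient drift.** Cell-free control wells track slow environmental
   changes (incubator oxygen, temperature) that affect all wells alike.

The pipeline removes the first effect with the two-step sensor correction
and the second with reference normalization, then estimates derived
quantities (replicate means, local slopes, time-resolved IC50) from the
cleaned series.

## Two-step sensor correction

During a *calibration window* $[t_0, t_1]$ — a period when all sensors see
the same stable true value, chosen by the user after the read-out has
stabilized (ten or more points is a practical minimum; the package enforces
two) — each sensor's log-domain mean $m_s$ and the plate mean
$m_p = \frac1S\sum_s m_s$ are computed. Step 1 (*logarithmic
recalibration*) rescales each series in the log domain by $m_p/m_s$:
$$x'_{t,s} = P + S\,e^{(m_p/m_s)\,z_{t,s}}.$$
Because $m_s = g_s\,z^{\mathrm{true}}_w$, the rescaled log-domain value
$(m_p/m_s)\,g_s z^{\mathrm{true}}(t) = (m_p/z^{\mathrm{true}}_w)
z^{\mathrm{true}}(t)$ no longer depends on $s$: after step 1 all sensors
agree *exactly* (in the absence of noise), at every level, not only in the
window. The exponent factor $\alpha$ cancels throughout and is only needed
if one wants to estimate the calibration curve itself
(`estimate_calibration()`).

Step 2 (*linear normalization*) multiplies each sensor by
$\text{target}/\bar{x}'_{s,w}$, where $\bar{x}'_{s,w}$ is its recalibrated
window mean, pinning every window mean to the target exactly. The steps do
not commute: recalibration must come first, and `correct_sensors()`
composes them in that order.

Step 2 is implemented as *per-sensor* multiplicative scaling. A whole-plate
scaling would preserve residual between-sensor offsets, which is contrary
to the purpose of the step (setting all sensors to their target value), so
the per-sensor form was chosen; after step 1 the two coincide on noiseless
data anyway, since all sensors already agree.

Values at or below the plateau make $z$ undefined. The default is a hard
error enumerating the offending (sensor, time) cells — such values mean the
calibration parameters are wrong for the data — with an opt-in
`clip_epsilon` (e.g. `1e-9`) that floors $(x-P)/S$ for exploratory work.

Gain is modelled as time-invariant: factors are estimated once from the
window and applied to the full series. Slow sensor drift is out of scope.

## Reference normalization, aggregation, smoothing, slope

**Reference normalization** maps every value to $x_{t,c}\,M/m_t$, with
$m_t$ the mean of the designated reference wells at time $t$ and $M$ the
target (e.g. 91.3 % air saturation for dissolved oxygen, or 100 for percent
viability). It is idempotent, and the reference mean equals $M$ exactly at
every time point afterwards. A zero $m_t$ is a hard error naming the time
point.

**Aggregation** computes the per-group mean and *sample* standard deviation
(divisor $n-1$; the convention is stated because singletons and small
groups make the choice visible — a singleton group gets SD 0 and a
warning). Missing values are excluded pairwise; a group entirely missing at
a time point yields missing outputs there.

**Smoothing** is the centred moving average of odd window length $n$:
$(n-1)/2$ points are dropped at each end rather than padded or reflected,
so every reported value is a genuine average of observed data. Even $n$ is
rejected.

**Slope** fits ordinary least squares through each point and $n$ points on
either side ($2n+1$ points), using the actual time stamps so irregular
sampling is handled, and reports the slope together with the residual
standard error $\sqrt{\mathrm{SSE}/(2n-1)}$ of the local fit. The window
parameter is the *half-width*: a slope with $n = 15$ uses a 31-point
window. Windows are computed with centred sums (subtracting the window
means before forming cross-products), which keeps the result within about
$10^{-13}$ of a reference `lm()` fit per window.

## The time-resolved IC50

The log-logistic family
$$f(x) = c + \frac{d - c}{\bigl(1 + (x/e)^b\bigr)^g}$$
is used with 2, 3, 4 or 5 free parameters (LL2: $c=0, d=1$; LL3: $c=0$;
LL4: $g=1$, the default; LL5 frees the asymmetry $g$). $e$ is the
inflection dose — the IC50/EC50. The form $(x/e)^b$ is algebraically equal
to $e^{b(\log x - \log e)}$ but evaluates at $x = 0$ without taking
$\log 0$: the zero dose enters as the one-sided limit ($d$ for $b>0$).
The reduced families follow the standard conventions of dose-response
software; no absolute-vs-relative IC50 conversion is performed — the fitted
$e$ is reported directly.

Fitting is unweighted nonlinear least squares via Levenberg–Marquardt
(`minpack.lm`), with the initialization $c_0 = \min y$, $d_0 = \max y$,
$e_0$ the dose whose response is nearest $(c_0+d_0)/2$, $b_0 = \pm 1$ by
the sign of the dose-response trend; all overridable. $e$ is bounded to
$(0, 10\max x]$, the objective tolerance is $10^{-8}$ with at most 1000
iterations, and standard errors come from the Jacobian at the optimum. A
fit that does not converge (or has too few usable doses after dropping
missing responses) is *flagged*, never thrown: `fit_ic50_over_time()`
records it as a gap so neighbouring time points are unaffected.

By default fits use replicate-group means ("fit to the averaged data");
`use_replicates = TRUE` fits all individual replicate points instead.
Weighting by replicate SD was considered and not adopted: with balanced
technical triplicates the weights are nearly constant, and unweighted
least squares keeps the per-time-point fits comparable along the
trajectory.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions; the defaults describe
the scenario the package is validated against: a 24-well plate, 13 doses
(300, 200, 100, 90, 80, 70, 60, 50, 40, 30, 20, 10, 0 µM) in triplicate
plus 3 medium wells, 10-minute sampling over 5 days, ambient oxygen
91.3 % a.s. drifting up by 0.4 % a.s./day, seeding at 136 min (the
pre-seeding segment is the calibration window), medium change at day 1.09,
treatment at day 2.1, and a drug potency $e(t)$ relaxing exponentially
from 80 µM at day 2.5 to 30 µM at day 4.7 toward a floor of 25 µM.

Sensor miscalibration is a uniform per-sensor gain $g_s \in [0.95, 1.05]$
applied in the log domain of an exponential calibration curve with
$P = 2$, $S = 100$, $\alpha = 0.035$ — the plateau sits below the lowest
simulated oxygen level (4.8 % a.s.) so the log transform is defined
everywhere, and the span is of the order of the full oxygen scale. Reader
noise is additive Gaussian with SD 0.3 % a.s. *after* the calibration map.
Cell biology is purely phenomenological: the untreated oxygen drawdown
follows saturating exponentials (adhesion, then regrowth to confluence),
and the viable fraction at dose $x$ is the log-logistic
$1/(1+(x/e(t))^b)$ with $b = 2$. Everything is a pure function of the
seed.

Because the generator's gain structure is *exactly* the structure the
correction inverts, noiseless closure tests are sharp (recovery to
$10^{-6}$ rather than "approximately"). The corresponding caveat: real
sensors also show drift, non-exponential residual nonlinearity and
non-Gaussian noise, none of which the generator emulates — passing closure
tests demonstrates the algebra and the estimators, not robustness to every
instrument pathology. Note also that gain correction is exact *across*
levels only in the noiseless limit; with a plate-mean gain
$\bar g \ne 1$ the corrected series is a common, slightly warped monotone
function of the truth, identical for all sensors. The warp is second-order
(the full-pipeline IC50 closure recovers the programmed trajectory to
about 0.05 % where 1 % is required) but it is why per-level validation
anchors the calibration window at the level being checked.

## Numerical and interface choices

* Trimming uses a closed time interval; conversions use exact rational
  unit ratios; shifting may produce negative times (pre-treatment
  baseline).
* Multiple input files merge only if their time vectors agree within
  $10^{-9}$ in the input unit.
* CSV output uses shortest round-trip number formatting, so
  write-then-read is the identity; settings files serialize doubles with
  17 significant digits for the same reason.
* Missing values propagate through all arithmetic and are excluded
  pairwise from means, SDs and fits; only an *entirely* missing required
  group errors.
* The pipeline driver refuses a run directory that already exists and
  writes the resolved settings and a log next to every output, so a run is
  reconstructible from its artifacts.

## Problem sizes used in the test suite

Unit tests run on small hand-checkable fixtures (3–50 points). The
end-to-end checks use the full default scenario — 42 wells × 721 time
points, ~300 dose-response fits along the trajectory — which completes in
a few seconds; closure tolerances are 1 % (noiseless) and 3 standard
errors per fit (0.5 % a.s. noise, fixed seed) for the IC50 trajectory, and
$10^{-6}$ for noiseless sensor-correction recovery.

## Known limitations

* No drift (time-varying gain) correction and no Stern–Volmer-type
  calibration model; the correction applies to sensors whose calibration
  is well described by $P + Se^{\alpha y}$.
* No LOESS/Savitzky–Golay smoothing alternatives; the estimators are
  deliberately the plain moving average and moving-window OLS described
  above.
* No model averaging or information-criterion family selection for the
  dose-response fits, and no confidence bands beyond per-fit standard
  errors.
* Plot export is static (PNG/PDF); there is no interactive interface.
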