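---
title: "Robustness of compliance monitors under sensor faults: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness of compliance monitors under sensor faults: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ventrobust)
```

This vignette is the package's account of its science: the forward model of
the simulated breaths, the two compliance estimators and the gold standard
they are scored against, the fault-injection protocols, the statistics, and
the design decisions taken where the problem left genuine choices. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The forward model

A ventilated respiratory system is modelled as one compartment obeying the
first-order equation of motion

$$P_{aw}(t) \;=\; \frac{V(t)}{C_{RS}} \;+\; \dot V(t)\, R_{RS} \;+\; \mathrm{PEEP},$$

with compliance $C_{RS}$ (ml/cmH2O), resistance $R_{RS}$ (cmH2O/(L/s)) and
total PEEP (cmH2O). Canonical internal units are cmH2O, L, L/s and s;
compliance is converted to ml/cmH2O only at reporting boundaries, which
keeps the elastance term in the design matrix free of unit mix-ups.

`simulate_breath()` generates one volume-controlled constant-flow breath:

* **Inspiration** — constant flow $V_T/T_I$ with
  $T_I = 60/\mathrm{RR} \cdot i/(i+e)$; defaults $V_T$ = 0.4 L, RR = 20
  breaths/min, I:E = 1:2, PEEPe = 5 cmH2O, 200 Hz, matching a common
  configuration for a medium-sized anaesthetised pig.
* **Valve closure** — a single half-amplitude sample ends inspiration, so
  that the trapezoidally integrated volume lands exactly on $V_T$ at the
  first post-inspiratory sample. Volume is defined as the cumulative
  trapezoidal integral of flow (that identity is an invariant of the
  data structure, tested to 1e-9 L).
* **Hold (optional)** — zero flow for `hold_duration` seconds; pressure
  relaxes to the static plateau $\mathrm{PEEP} + V_T/C_{RS}$.
* **Expiration** — passive exponential decay with time constant
  $R_{RS} C_{RS}$ (floored at 0.02 s so $R_{RS}=0$ stays representable;
  only the inspiratory limb is load-bearing for the estimators, the
  expiratory limb exists for realism of whole-breath fits).

Pressure is computed *from the integrated volume array*, so the equation of
motion holds sample-exactly and ordinary least squares on a noiseless
breath recovers $(C_{RS}, R_{RS}, \mathrm{PEEP})$ to machine precision.
This forward/inverse exactness is the package's primary oracle: any
deviation the perturbation sweep measures is attributable to the
perturbation, not to discretisation. The price is a one-sample
discretisation of the end-inspiratory pressure (about $V_T/(C_{RS} n_I)$
below the closed form — 0.07 cmH2O at the defaults), asserted at 0.1 cmH2O
in the tests.

### Stress relaxation

Real lungs show stress relaxation and gas redistribution ("pendelluft"):
the dynamic end-inspiratory pressure exceeds the static plateau, so a fit
of dynamic samples underestimates the compliance revealed by a prolonged
hold. The simulator reproduces this with an optional Kelvin-body term of
elastance `viscoelastic_fraction` $\times 1/C_{RS}$ and relaxation time
`viscoelastic_tau`, integrated with the exact per-sample exponential
update:

$$\dot P_{ve} = E_2 \dot V - P_{ve}/\tau.$$

The option defaults **off** so the exact-recovery oracles stay valid;
turning it on is the documented way to give the least-squares monitor its
characteristic negative baseline bias relative to the interrupter
reference (the acceptance suite measures the sign on a pool with the
fraction pinned at 0.15).

### The synthetic pool

`generate_pool()` emulates a pool of experimental recordings: each record
pairs a regular breath with a 2 s end-inspiratory-hold breath generated
from identical, uniformly sampled mechanics. Default ranges — compliance
10–40 ml/cmH2O, resistance 5–25 cmH2O/(L/s), PEEP 4–8 cmH2O, tidal volume
0.25–0.45 L — bracket healthy to mildly injured (oleic-acid-type ARDS)
lungs of a 25–35 kg pig. No per-animal mechanics table exists to calibrate
against, so these are declared assumptions, configurable in
`pool_sampler_config()`. The sampled PEEP is written into the per-record
ventilator settings as the set PEEPe (the one-compartment model has no
intrinsic PEEP), which is where the interrupter reads it.

For the robustness study itself the pools additionally draw
`viscoelastic_fraction` from U(0.10, 0.20) and `viscoelastic_tau` from
U(0.8, 1.2) s: a heterogeneous relaxation term gives the across-breath
baseline scatter that a pool of real recordings has, with 0.15 as the
central fraction. These values were fixed once when the study
configuration was designed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: transducer noise and drift, nonlinear (flow- and
volume-dependent) resistance and elastance, intrinsic PEEP, patient effort,
heterogeneous multi-compartment mechanics beyond the single Kelvin term,
and between-animal correlation structure. The synthetic baselines are
therefore *cleaner* than real ones; consequences for the acceptance
properties are discussed under "Known limitations".

## The gold standard

`interrupter_crs()` implements the interrupter technique:
$C_{RS} = 1000\, V_T / (P_{plat} - \mathrm{PEEPe})$, with $P_{plat}$ the
mean airway pressure over a trailing window of the hold (default 0.2 s — a
declared choice; averaging a window rather than taking the last sample is
robust to residual ringing) and $V_T$ the volume at the end of the hold.
Because flow is zero at the plateau the estimate is independent of
resistance, which the tests assert. PEEPe is taken as the known
ventilator-set value from the tracing metadata, not estimated from the
tracing.

## Estimator 1: multilinear fitting (MLF)

`mlf_fit()` solves the unweighted ordinary-least-squares problem
$P_{aw} \sim V + \dot V + 1$ and reports $C_{RS} = 1000 / \hat a$ where
$\hat a$ is the volume coefficient. Three properties are deliberate
fidelity choices, not conveniences:

* **No outlier rejection.** The fit uses whatever pressure values are
  present, including zeroed (disconnected) samples. This is the mechanism
  of the disconnection catastrophe.
* **Non-physical fits propagate.** A fitted elastance $\le 0$ yields a
  negative or enormous compliance; the fit is flagged, not rejected,
  because a naive monitor would report it and the error tables must
  contain it. Only exactly singular designs raise an error.
* **Plain OLS.** No regularisation or robust loss — the study quantifies
  the fragility of the unmodified method.

The default window is the whole breath (inspiration plus expiration),
which matches the whole-breath averaging of the classical multilinear
procedure. A window argument allows inspiratory-only fitting; note that
under *perfectly* constant inspiratory flow the flow column is collinear
with the intercept, so the pure inspiratory limb is singular —
`run_sweep(mlf_window = "inspiratory")` therefore includes the
valve-closure transition sample.

## Estimator 2: the neural network

### Input pattern

`build_input_pattern()` under-samples the inspiratory limb of the P-V loop
to 50 coordinate pairs at equally spaced sample indices (rounded, first
and last always included; time spacing equals volume spacing under
constant flow and, unlike arc-length spacing, is reproducible under
perturbation). Pressure coordinates are divided by the maximum airway
pressure over the inspiratory limb of the *presented* (possibly perturbed)
curve — what a monitor would see. The pattern layout is 50 pressure values
followed by 50 volume values.

Volume coordinates are by default also divided by the pressure maximum
(`volume_scale = "paw_max"`). This mixed-units scaling is deliberate: it
keeps the ratio $V_T / P_{aw,max}$ — which carries the compliance — in the
pattern. The fully self-normalised alternative (`"own_max"`) makes the
pattern provably scale-blind: scaling $V_T$ and $C_{RS}$ jointly by $k$
(with $R_{RS}/k$) leaves every pattern element unchanged while the target
changes by $k$, so compliance is not identifiable from such patterns. The
switch is exposed for comparison.

### Architecture and training

The network has three weighted layers: 100 log-sigmoid input neurons (one
per pattern element), 25 log-sigmoid intermediate neurons, and one linear
output neuron yielding C_RS in ml/cmH2O directly (the linear output
absorbs the target scale; no target normalisation). Weights initialise
uniformly in [−0.5, 0.5] under a seed.

Training is full-batch iRprop−: per-parameter steps grow by `eta_plus` =
1.2 on stable gradient sign, shrink by `eta_minus` = 0.5 (with the
gradient forgotten) on a flip, clamped to [1e-6, 50], starting at 0.07 —
the standard published Rprop defaults. One numerical point matters: the
sigmoid derivative is computed as $\sigma(z)\sigma(-z)$, because the naive
$a(1-a)$ underflows to an exact zero for $|z| \gtrsim 36$ and a sign-based
optimiser can then never recover a saturated unit (its gradient sign is
lost forever). With the stable form, saturation episodes self-correct.

The protocol mirrors the reference procedure: the pool splits 80:20 by a
seed-deterministic shuffle; within the 80 % training subset, eight rotating
validation folds drive early stopping (patience 100 epochs, cap 1500 —
both our defaults, as only the eightfold scheme itself is prescribed);
`train_ensemble_select_best()` trains `n_restarts` independently
initialised networks (100 in the full protocol) and keeps the one with the
lowest MSE on the 20 % evaluation subset. Everything is bit-reproducible
from the plan seed, and models serialise to JSON with full-precision
decimal strings so a reloaded model predicts bit-identically.

## Fault injection

Both perturbations touch **only the pressure channel**; flow, volume, time
and window indices are never modified.

* **Random noise (RN)** — i.i.d. uniform noise on $[-a, +a]$ added to every
  pressure sample, $a$ = level % of the clean inspiratory $P_{aw,max}$,
  per tracing. Uniform, because bounded extrema are part of the fault
  definition; i.i.d., because that gives the flat (white) spectrum.
* **Transient disconnection (TD)** — pressure switched to absolute 0 cmH2O
  over a contiguous window of round(level % × $n_I$) samples centred on
  the inspiratory midpoint (one sample earlier when exact centring is
  impossible).

The sweep grid is 0, 2, …, 50 %: level 0 is the unperturbed baseline and
the 25 nonzero levels match the graded protocol; output tables label the
nonzero levels.

## The sweep and its statistics

`run_sweep()` applies every kind × level to every regular breath (one
fresh noise realisation per breath per level, sub-seeded by a counter
scheme from the master seed so that extending the grid never reshuffles
existing draws), estimates C_RS with both monitors, and scores against the
precomputed interrupter references. Errors are **estimate − reference**,
so the stress-relaxation bias of MLF is negative. Per level it reports the
Bland–Altman pair — bias (mean) and scatter (SD, n−1) — and a two-sided F
test on the variance ratio (larger variance in the numerator, so F ≥ 1),
significant at α = 0.01. Normality of each error sample is checked with
the Anderson–Darling test (a design choice; no specific test is
prescribed) and reported; failures warn but do not gate the F test.
Evaluation deliberately uses the training pool itself, so that degradation
under perturbation is not confounded with generalisation to unseen
mechanics; pass `errors`/`train_idx` metadata to restrict to held-out
records if wanted. Non-physical MLF estimates enter the statistics at
their numeric values; only non-finite values (singular fits) are excluded,
with their count reported per level.

## Numerical choices and degenerate inputs

* Exactly singular least-squares designs (rank < 3) raise a classed error;
  the sweep logs and excludes them rather than aborting.
* `bland_altman()` and `compare_variances()` require ≥ 2 finite values;
  both-zero variances are an error (undefined ratio).
* Pattern construction requires ≥ 50 inspiratory samples and a positive
  pressure scale; disconnection zeros stay zeros after rescaling.
* Tracing files are CSV at 9 significant digits (relative round-trip error
  ≤ 5e-9) with a JSON sidecar for sampling metadata; model files
  round-trip weights bit-exactly via 17-digit decimal strings.
* Seeds are applied through `withr::with_seed`, so library calls never
  disturb the caller's RNG state.

## Problem sizes

The shipped study configuration uses the full 378-recording pool, the
100-restart training protocol and both complete 26-level sweeps (about
40,000 estimator evaluations); this runs in a few minutes on one CPU. The
parameter-recovery check uses a 300-recording clean pool with 10 restarts.
Unit tests use pools of 10–100 recordings.

## Known limitations

* The synthetic pool is *cleaner* than a real one: interrupter references
  are near-exact, so a well-trained network nearly interpolates its
  training pool and its baseline scatter is a few tenths of an ml/cmH2O,
  an order below what real recordings give. Ratio-based robustness
  summaries (for example "SD at 50 % versus SD at baseline") are therefore
  much harsher here than on real data, and mid-severity comparisons
  between the two monitors can invert relative to a noisy-data setting.
  The absolute degradation patterns — least-squares bias stability under
  noise, network scatter growing with noise amplitude, the least-squares
  scatter explosion under disconnection — are the transferable findings.
* With pressure-only corruption bounded by $P_{aw,max}$ and a
  well-conditioned whole-breath design anchored by hundreds of clean
  samples, OLS coefficient errors are bounded; thousand-fold scatter
  explosions additionally require a near-singular design or corruption of
  the flow/volume channels (as a physical disconnection of a combined
  flow/pressure sensor would cause). The fault model here deliberately
  keeps flow and volume intact.
* The network's behaviour far off the training manifold (large zeroed
  blocks) depends on the training run; the multistart protocol selects by
  evaluation MSE, which does not control extrapolation.
* No conclusions transfer to other ventilation modes, lung sizes or
  spontaneous effort; the generator and the trained network encode
  volume-controlled constant-flow ventilation only.
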