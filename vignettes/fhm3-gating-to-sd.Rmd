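---
title: "From a sodium-channel gating defect to spreading depression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a sodium-channel gating defect to spreading depression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hhsd)
```

This vignette documents the science and the numerical decisions behind
`hhsd`: the three membrane models, the mutant gating modification, the
protocols that stand in for experimental stimulation, the feature
extraction that turns traces into numbers, and the places where a
definition had to be chosen because the underlying phenomenon does not
come with one.

## The three models

All three models are Hodgkin–Huxley-type: the membrane potential $V$
(mV) obeys $C_m\,dV/dt = -\sum_i I_i + I_{app}$ with currents in
µA/cm², conductances in mS/cm², and voltage-gated conductances formed
from gating variables that relax as $dx/dt = (x_\infty(V) - x)/\tau_x(V)$
with $x_\infty = \alpha_x/(\alpha_x+\beta_x)$ and
$\tau_x = 1/(\phi(\alpha_x+\beta_x))$.

**Action-potential (AP) model.** The classical formulation: gates $m$,
$n$, $h$ with the classical rate functions, $\phi = 1$/ms, fixed
reversal potentials ($E_{Na} = 50$, $E_K = -77$, $E_{leak} = -54.402$
mV), $\bar g_{Na} = 120$, $\bar g_K = 36$, $g_l = 0.3$ mS/cm²,
$C_m = 1$ µF/cm².  This model answers millisecond-scale questions:
spike shape, response latency, firing rate, and the two Hopf
bifurcations in $I_{app}$ that delimit the oscillatory regime.

**Spreading depression (SD) model.**  Ion concentrations stop being
constants.  The state is $(V, n, h, K_i, K_e)$; sodium concentrations
follow algebraically from electroneutrality
($Na_i = Na_i^{(0)} - K_i + K_i^{(0)}$,
$Na_e = (\omega_i/\omega_e)(Na_i^{(0)} - Na_i) + Na_e^{(0)}$), and the
reversal potentials are dynamic Nernst potentials
$E = (26.64/z)\ln(c_e/c_i)$ mV.  A Na/K-ATPase pump
$I_p = \rho\,(1+e^{(25-Na_i)/3})^{-1}(1+e^{5.5-K_e})^{-1}$ enters the
sodium current as $+3I_p$ and the potassium current as $-2I_p$; the
extracellular compartment exchanges potassium with a bath at rate
$F_{diff} = 3.75\times10^{-5}$/ms.  The shifted rate-function variant
is used with $\phi = 3$/ms; the fast $m$-gate is adiabatic
($m = m_\infty(V)$), while $h$ stays dynamic — the mutation acts on
$h$, so eliminating it would remove the phenomenon under study.
Membrane currents convert to concentration fluxes through
$\gamma = A_m/F$; see *Numerical choices* for the unit bookkeeping.

**Anoxic depolarization (AD) model.**  The most explicit of the
three: nine state variables, with intra- and extracellular Na⁺, K⁺ and
Cl⁻ all dynamic (no electroneutrality shortcut), a chloride leak
current, glial potassium buffering
$I_g = G\,(1+e^{(18-K_e)/2.5})^{-1}$ and blood diffusion
$I_d = \epsilon(K_e - k_\infty)$.  Its time base is seconds (the
clearance rates are per second); the per-ms membrane and gating
dynamics are bridged with an explicit factor of 1000.  Sodium and
chloride totals $c_i + c_e/\beta$ are conserved exactly; potassium is
conserved exactly once the energy-dependent terms are switched off.

For the chloride concentration equations the package uses
$d\,Cl_i/dt = +\gamma_c I_{Cl}$ (and $-\beta\gamma_c I_{Cl}$ outside):
chloride carries valence $-1$, so a positive outward membrane current
is an inward chloride flux.  The opposite (cation-like) sign
convention makes the chloride subsystem exponentially unstable — the
concentration would run away from its reversal potential — so it
cannot be the intended model.

## The mutant gating defect

Tail-current measurements of the FHM3 Nav1.1 defect show two- to
four-fold slower inactivation and two- to four-fold faster
deinactivation; the models use the intermediate three-fold change.
Both effects are carried by one voltage-dependent rescaling of the
inactivation time constant:

$$\tau_h^*(V) = \tau_h(V)\,\bigl(\kappa_1\tanh(\sigma(V - V_{max})) + \kappa_2\bigr)$$

* $\sigma = 0.1$/mV: steep enough that the factor saturates within a
  few tens of mV of $V_{max}$;
* $V_{max}$ = the argmax of the wild-type $\tau_h(V)$, computed per
  rate-function variant (`locate_vmax()`; ≈ −66.8 mV classical,
  ≈ −45.8 mV shifted — the shifted h-rates are the classical ones
  moved by +21 mV, and the AP model uses the classical variant while
  the SD/AD models use the shifted one, so sharing a single anchor
  would misplace the sigmoid in one family of models);
* $\kappa_1 + \kappa_2 = f$ (depolarized limit: $f$-fold slower
  inactivation) and $\kappa_2 - \kappa_1 = 1/f$ (hyperpolarized limit:
  $f$-fold faster deinactivation).

For the default $f = 3$ the package uses the published coefficients
$\kappa_1 = 1.335$, $\kappa_2 = 1.665$.  These are slightly rounded —
the constraints give exactly $4/3$ and $5/3$, and the published pair
has difference $0.33$ rather than $1/3$ — but they are what the
reference bifurcation values were produced with, so they are kept as
the study configuration.  For any other $f$ the exact constraint
formulas $\kappa_{1,2} = (f \mp 1/f)/2$ are used, which makes $f = 1$
collapse the factor to exactly 1 (a wild-type identity that the test
suite asserts).

The defect is *verified* rather than assumed: `clamp_measure_tau()`
simulates the tail-current protocol (clamp to −120 mV, step to −10 mV
for inactivation; the reverse for deinactivation) by integrating the
scalar $h$-equation at the clamped step potential and reading the time
at which $h$ crosses the $1/e$ point of its relaxation.  Because a
clamped linear relaxation is exactly exponential, the measurement
recovers $\tau_h^*$ at the step potential, and the mutant/wild-type
ratios come out $3.00$ and $0.33$.

## Protocols: what the generator emulates

`stimulus_schedule` objects describe everything time-dependent about
an experiment:

* `make_pulse(3, 3, 10)` — the 3 ms, 3 µA/cm² excitatory pulse used
  for single-AP comparisons;
* `make_constant_current(12)` — tonic drive in the oscillatory regime;
* `make_pump_interruption(hold_s)` — the ischemia surrogate: the
  maximal pump rate is ramped linearly to 20% over 10 s, held there
  for a variable window, and ramped back over 5 s.  The ramp starts at
  t = 20 s by default so traces show the resting state first; since
  the model sits exactly at its fixed point, the threshold results do
  not depend on this choice;
* `make_anoxia_switch(5)` — total energy failure: pump, glial
  buffering and blood diffusion all zeroed from t = 5 s on.

Schedules compose (currents add, at most one pump program), serialize
to YAML, and are evaluated exactly — integration is restarted at every
control breakpoint so the solver never steps across a discontinuity.

These schedules are *idealized* controls: real hypoperfusion is not
piecewise-linear, real anoxia does not zero all clearance
instantaneously, and none of the models has spatial extent.  Passing
tests therefore show that the implementation reproduces the defined
cellular experiments, not that the schedules are faithful replicas of
tissue-level events; in particular nothing here addresses SD *wave
propagation*.

## Feature extraction and the two definitions that had to be chosen

**Spike detection** is upward threshold crossing with linear
interpolation of the crossing time and a refractory merge (1 ms).  The
default threshold is 0 mV, which healthy APs overshoot.

**SD outcome classification** is all-or-none but the exact rule is a
choice.  Two independent readings are computed on every run
(`classify_outcome()`):

* *E_K-based*: SD iff, after the up-ramp completes, $E_K$ stays above
  −60 mV for ≥ 5 contiguous seconds (sustained gradient breakdown);
* *V-return-based*: SD iff $V$ does not come back within 5 mV of rest
  within 15 s of the stimulation end.

The first is the primary label; the second is attached to every
result, and the test suite asserts that they agree on both sides of
the threshold.  Near the threshold the separation is enormous (peak
$K_e$ ≈ 15 mM on tolerated runs vs ≈ 56 mM on SD runs), so the
classification is insensitive to the exact cut values.

**Excitation-block onset** is the time of the last spike of the
terminal burst.  Here the 0 mV convention fails for a systematic
reason: as the ion gradients run down, $E_{Na}$ collapses and the last
spikes of the burst no longer overshoot 0 mV.  `critical_window()`
therefore detects block-onset spikes at −20 mV (configurable), which
keeps the low-amplitude terminal spikes and matches what "spiking
ceases" means when reading a trace by eye.  The critical window is
then the time from the start of the pump-rate recovery to that last
spike.

## Numerical choices

* **Integration**: `deSolve::lsoda` (stiff-capable, adaptive) with
  `rtol = 1e-8`, `atol = 1e-10` defaults; right-hand sides compiled in
  C.  Plain-R reference implementations of all three right-hand sides
  are part of the public API and the test suite integrates both routes
  on identical problems and requires agreement to ~1e-6.  Halving the
  tolerances moves the AP peak time by < 1% and the SD thresholds not
  at all (asserted at 1e-8 vs 1e-10).
* **Removable singularities**: $\alpha_m$ and $\alpha_n$ contain
  $x/(1-e^{-x/10})$, singular at one voltage each (−40/−55 mV
  classical, −30/−34 mV shifted).  Within $10^{-7}$ mV of the point
  the series limit $10 + x/2$ is used.
* **Flux conversion in the SD model**: the definition $\gamma = A_m/F$
  is evaluated with explicit units — $A_m = 922$ µm² $\to$ cm², volumes
  $\omega_i = 2160$, $\omega_e = 720$ µm³ $\to$ litres — giving
  $\gamma/\omega_i = 4.4240\times10^{-5}$ mM ms⁻¹ per µA cm⁻² (and
  three times that for the smaller extracellular compartment).  Both
  conversions are exposed as `conv_i`/`conv_e` in `sd_parameters()`
  for inspection.  A printed catalogue value for $\gamma$ circulates
  with an inconsistent exponent; the package always derives the
  conversion from the definition.
* **Resting states**: no initial conditions are part of the model
  definitions, so rest is computed, not assumed.  The AP model's rest
  is a scalar root of the steady-state I–V relation (residual
  < 1e-10); the SD model is relaxed for 200 s and Newton-polished
  (residual < 1e-8; rest lands exactly on the reference
  concentrations, $K_e = K_{bath}$); the AD model is relaxed for
  5000 s — its chloride pool equilibrates with a ~100 s time constant
  — and ends with $E_{Cl}$ equal to the resting potential and glial
  uptake balancing blood influx.  Chloride starts from the
  conventional 6/130 mM of this model family and its total is
  conserved by the relaxation.
* **Hopf location**: equilibria are continued over $I_{app}$ in 0.5
  µA/cm² steps (the equilibrium itself reduces to a scalar root
  because every gate sits at $x_\infty(V)$, for the mutant too);
  4×4 Jacobians by central finite differences (step $10^{-6}$,
  validated against an independent numerical-differentiation oracle in
  the tests); the real part of the leading complex eigenvalue pair is
  bisected to $10^{-3}$ µA/cm².  Criticality is decided by simulation
  probes — coexistence of a large-amplitude attractor just outside the
  unstable range (subcritical) versus a small oscillation that shrinks
  toward the point (supercritical) — with an explicit `"undetermined"`
  outcome rather than a guess when neither signature is clear.
* **Firing rates** count upward crossings of the midpoint of the
  settled waveform rather than of 0 mV, because toward the
  supercritical block the oscillation rides a depolarized plateau; a
  settled peak-to-peak amplitude under 5 mV counts as quiescence.
  Runs start from the equilibrium nudged by +1 mV (an exactly-balanced
  unstable focus would otherwise never leave the fixed point), or from
  a spiking state to trace the hysteretic branch below the subcritical
  onset.
* **Threshold search**: SD outcomes are monotone in the hold duration
  (all-or-none), so the minimal non-tolerated window on the 0.1 s grid
  is found by bisection in integer grid units (~8 classification runs
  instead of a linear sweep), and monotonicity is re-asserted on the
  grid points directly below the result.

## Problem sizes

The default analysis sizes, used by the test suite and the
reproduction script alike: continuation over $I_{app} \in [0, 200]$
µA/cm² (401 grid points per genotype); SD classification runs of
~60–105 s of model time sampled at 5 ms (threshold searches) and
0.25 ms (threshold runs for spike-level features); AD runs of 120 s at
0.5 ms; firing-rate windows of 1 s after 0.5 s of settling.  The full
reproduction script completes in well under a minute on one core.

## What is reproduced, and what deviates

With the study configuration ($f = 3$, published $\kappa$'s) the
package reproduces the published Hopf currents of both genotypes to
better than 0.01% (9.78/154.53 wild-type, 9.72/175.03 mutant µA/cm²),
the clamp ratios (3.00, 0.33), the ordering and approximate magnitude
of the firing-rate curves, the critical windows (3.75 s wild-type,
2.75 s mutant, against published 3.4/2.5 ± 0.5 s), and the anoxia
spiking-to-block intervals (6.32/2.45 s against published
"approximately" 6.7/2.7 s).

Two quantities deviate beyond their stated tolerances, and both
deviations are reported rather than tuned away:

* **Absolute SD thresholds.**  The faithful implementation of the
  five-variable SD model yields minimal non-tolerated pump
  interruptions of 11.1 s (wild-type) and 5.9 s (mutant) against
  published values of 13.6 and 7.2 s — both ≈ 18% short, while their
  ratio, 53%, matches the published relative vulnerability exactly.
  The thresholds are robust to solver tolerances, and the flux
  conversion cannot be the cause (the alternative printed value is off
  by three orders of magnitude and would admit no SD at all; treating
  the $m$-gate dynamically instead of adiabatically moves the
  thresholds further down, not up).  A uniform ≈ 20% difference in the
  effective ion-loading rate, such as an additional leak pathway
  present in the lineage this model descends from but absent from its
  five-variable formulation, would explain the offset without
  affecting the ratio.  The package implements the model as defined.
* **Anoxia subthreshold rise.**  The published account gives ≈ 30 s
  from energy failure to spiking onset.  From the fully relaxed
  resting state the rise is ≈ 12 s; starting instead from the
  catalogued reference concentrations (which are *not* a fixed point
  of this model — its true rest has $Na_i \approx 20$ mM) gives
  ≈ 41 s.  The genotype-sensitive quantity, the spiking-to-block
  interval, stays within ± 15% of the published values under either
  initialization, and the wild-type and mutant traces are identical
  until spiking starts under both.  The package initializes at the
  computed rest (the only self-consistent choice for a model whose
  experiments begin "from rest") and reports the rise as measured.

## Known limitations

* No spatial extent: these are point models; SD here is a cellular
  event, not a propagating wave.
* The gating defect is a time-constant rescaling within independent
  two-state gates; kinetic-scheme (Markov) channel models that couple
  activation and inactivation are out of scope.
* The AD model's bursting/seizure regimes are untouched; only the
  total-shut-off experiment is analyzed.
* Criticality classification is probe-based; there is no limit-cycle
  continuation or Floquet analysis.
* The bath/glia/blood couplings are first-order caricatures of
  clearance; they are the right level for threshold questions, not
  for quantitative ion time courses over hours.
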