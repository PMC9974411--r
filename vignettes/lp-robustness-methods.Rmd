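---
title: "Methods: a four-compartment LP neuron model and its robustness analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-compartment LP neuron model and its robustness analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpneuro)
```

## The model

`lpneuro` simulates a reduced model of the lateral pyloric (LP) neuron of the
crustacean stomatogastric ganglion. Four compartments approximate the cell:
the axon initial segment (C = 0.039 nF), the soma-primary neurite (0.8 nF),
the secondary neurites (3.74 nF) and the tertiary neurites (5.50 nF), coupled
in a chain by resistors. Only the axon carries the fast Na⁺ current, so
spikes initiate there and appear strongly attenuated at the soma, riding on a
slow wave generated by the soma/neurite conductances — the hallmark division
of labour in these neurons.

Each compartment's membrane equation is

$$C_i \frac{dV_i}{dt} = -\sum_k I_{\text{ion},k,i} - \sum_s I_{\text{syn},s,i}
  + \sum_{j} \frac{V_j - V_i}{R_{ij}},$$

with all currents ohmic, $I = \bar g\, w\, (V - E_\text{rev})$ (where $w =
m^p h^q$), except the calcium current, which uses the
Goldman–Hodgkin–Katz form

$$I_{Ca} = \bar P_{Ca}\, m^3 h\, N_A q_e z
  \left( \mathrm{[Ca]_i} \frac{-\xi}{e^{-\xi}-1}
       - \mathrm{[Ca]_o} \frac{\xi}{e^{\xi}-1} \right),
  \qquad \xi = \frac{z q_e V}{kT}.$$

A model is specified by 14 free parameters ([`conductanceNames()`]): four
axonal conductances (leak, Kd, A, Na), seven soma/neurite densities shared
across the three non-axonal compartments and scaled by membrane area
(proportional to capacitance; leak, MI, Kd, A, KCa, $\bar P_{Ca}$, h), and
three graded inhibitory synaptic conductances (AB, PD, PY).

### Coupling topology and the Ra map

The published compartment diagram does not pin down the resistor placement,
so the package uses a chain — axon –(r1+r2)– soma –(r3)– secondary –(r4)–
tertiary, with r1 = 2.50×10⁵ Ω, r2 = 1.80×10⁷ Ω, r3 = 1.13×10⁶ Ω,
r4 = 2.26×10⁷ Ω — chosen because (a) it leaves the neurite input resistance
untouched when only r2 changes, and (b) at strong coupling the axon becomes
near-isopotential with the soma, as observed. Varying the axonal axial
resistivity Ra rescales r2 linearly, anchored at the control point
(100 Ω·cm ↔ 1.80×10⁷ Ω), so Ra = 2 gives 3.60×10⁵ Ω and Ra = 500 gives
9×10⁷ Ω. The half-cable formula $R_a L / (2\pi (d/2)^2)$ with the stated
axon geometry (354.5 µm × 3.5 µm) gives ≈1.84×10⁷ Ω, 2 % from the tabulated
value; the tabulated value is authoritative and the map is anchored to it.

### Gating kinetics

The source publication defers the gating formulas to earlier work, so the
package ships a declarative kinetics registry (`defaultKinetics()`,
overridable via plain-text files, `readKineticsRegistry()`). Every gate is a
sigmoid steady state with a constant, sigmoid or bell-shaped time constant —
the functional family used throughout stomatogastric modelling. Parameter
values are this package's own calibration within that family, tuned once so
that the reference model (`referenceConductances()`) fires a clean rebound
burst at control coupling *and* keeps bursting across the whole Ra range
2–500 Ω·cm with a biphasic spikes-per-burst profile. They are stand-ins, not
measurements; an externally fitted kinetics set can be dropped in through
the registry without code changes.

Two registry choices deserve mention. The KCa current uses a single voltage
gate multiplied by a calcium occupancy `cai/(cai + Kd)` (Kd ≈ 2 µM); with
the first-order calcium pool (rest 0.05 µM, removal τ ≈ 276 ms) it provides
the burst-terminating adaptation and the inter-burst quiescence. The axonal
Na inactivation is positioned (half-inactivation ≈ −46 mV, peak τ ≈ 3.5 ms)
so that spikes still regenerate when strong coupling (Ra = 2) forces the
whole cell to spike as one unit — with steeper or more hyperpolarized
inactivation the loaded spike fails and the strong-coupling regime dies.

### Synaptic drive

The three inhibitory inputs are graded:
$g_\text{syn} = \bar g_\text{syn} s$ with
$s_\infty = 1/(1+e^{-(V_\text{pre}-V_\text{thresh})/v_\text{scale}})$
(defaults −55 mV, 5 mV). AB and PY act instantaneously; PD relaxes with the
fixed 50 ms time constant, by `τ ds/dt = s_∞ − s`. Reversals are −70 mV
(AB, PY) and −80 mV (PD). Synapses contact the secondary and tertiary
neurites split by membrane area; a switch (`include_soma_targets`) adds the
soma-primary compartment, since the text describing the distribution is
ambiguous about the soma.

The periodic drive (`pyloricDrive()`) uses raised-cosine-edged voltage
pulses (baseline −70 mV, peak −10 mV, period 1 s): the PY window occupies
cycle phases 0.55–0.875 and the PD/AB window 0.85–1.0, overlapping so the
PY→PD hand-off never transiently releases the cell (an un-overlapped seam
produces a spurious mid-cycle rebound spike). Phase 0 is anchored at the
release from PD/AB inhibition, so every drive cycle contains exactly one
rebound window at its start — this anchoring is what makes per-cycle burst
segmentation unambiguous. The true rhythm's period and phase windows are not
printed in the source; these values mimic the triphasic timing qualitatively
and are configurable, and externally recorded waveforms can be supplied
with `sampledDrive()`.

## Numerics

The integrator (compiled, `solverConfig()`) is a fixed-step staggered
scheme: backward Euler on the four coupled voltages with channel open
fractions and the GHK current frozen over the step (the 4×4 linear system is
solved exactly each step), and exact exponential-integrator updates for
gates, calcium pools and the PD synaptic gate. This is unconditionally
stable for the stiff RC network, in the manner of compartmental simulators.
The default step is dt = 0.05 ms; halving it moves axonal spike times by
less than 0.5 ms (tested), and on a passive-decay oracle the global error
falls first-order in dt. Gate rates are evaluated from piecewise-linear
tables on a 0.05 mV grid (storing `exp(−dt/τ)` directly); `use_tables =
FALSE` switches to exact evaluation, used when cross-checking the engine
against an adaptive reference ODE solution. The GHK bracket switches to a
second-order series below |ξ| < 10⁻⁴ to avoid 0/0 at V = 0.

Steady state is declared when the axonal spike pattern of two consecutive
drive cycles matches (equal count, phase-aligned times within 5 ms), after
which four analysis cycles are recorded and the criterion re-verified on
them; integration gives up after 30 cycles and the trace is flagged
unsettled (callers classify it aperiodic). Initial conditions: all
compartments at −60 mV, gates at steady state, calcium at rest.

## Classification

Axonal spikes are upward crossings of 0 mV (axonal spikes overshoot;
somatic ones do not) with 2 ms refractoriness and sub-sample interpolation.
Within each cycle, runs of spikes with inter-spike intervals below 100 ms
form bursts. The five-way taxonomy is applied in a fixed order: no spikes →
`depolarization_block` if the axon sits above −40 mV for most of the window,
else `non_spiking`; unsettled spiking → `aperiodic_spiking`; spikes in ≥80 %
of cycle-phase bins (i.e. firing through the inhibited phases) →
`tonic_spiking`; exactly one burst per cycle, at least two spikes, equal
per-cycle counts → `rebound_bursting`; anything else aperiodic. "Fires
periodically" is operationalized as the settle criterion plus equal
per-cycle counts — the source states no tolerance, so the 5 ms alignment and
the equality requirement are this package's constructions. The tonic
boundary (80 % occupancy) only affects reporting; the robustness ratio
depends solely on the rebound-burster decision.

## The robustness protocol

A perturbation trial shifts every conductance independently:
$g_x \mapsto \max(0,\ g_x + u_x\, r\, (g_{x,\max} - g_{x,\min}))$ with
$u_x \sim U(-1,1)$, range fraction $r$, and channel bounds taken as the
min/max over the parent population. The robustness ratio of a parent is the
fraction of its m children classified as rebound bursters; the parent's own
label is recorded separately and never enters the ratio. Trials are seeded
by a counter scheme keyed on (experiment seed, parent, trial, stream), so
any child is reproducible in isolation, trial order is irrelevant, and a
coupling experiment restricted to Ra = 100 reproduces the noise experiment's
ratios exactly. Fresh perturbation draws are used at every Ra (the
alternative — reusing one set of draws across Ra — is supported by replaying
seeds but is not the default).

## The synthetic population

The deposited model database is not shipped here; instead the package
generates its study population. Candidates are drawn uniformly per channel
from intervals centred on the calibrated reference model (default
[0.65, 1.35]× each reference value) and screened for rebound bursting under
the default drive at control coupling. The default box half-width (0.35) was
calibrated once so the regime matches the emulated study: the screen retains
most candidates (hit rate ≈ 0.85), the ±10 % ratio histogram piles up near
1, and the left shift with growing range is strong. Widening the box makes
bursters progressively rarer (≈ 0.4 at [0, 2]×), but even extreme boxes
retain a few tens of percent — the million-to-thousand rarity of the
original database screen is not reproduced by a box anchored this way, and
the tests assert only the qualitative decline.

Two fixture tables ship under `inst/extdata/` so tests and examples never
depend on screening compute: 24 screened parents
(`fixtureParents()`) and 8 coupling elites (`fixtureElites()`) — models that
keep bursting when Ra is set to 2, 100 and 500 Ω·cm. Both are synthetic,
produced by this package's own screen from recorded seeds; the elite table
is ordered by the strength of its pre-validated robustness-vs-Ra ordering.
Note the two elite notions: `selectElite()` implements the perturbation
elite (child ratio exactly 1 at ±10 % and 3–11 spikes per burst in parent
and children), while the coupling analyses use the triple-Ra elites. In
this synthetic family the perturbation-elite criterion is essentially
unattainable at m = 50 (best cores reach ratios ≈ 0.97–0.99): the bursting
manifold is smaller relative to its population bounds than the emulated
database's.

## What the scaled analyses do and do not show

The test suite re-derives the study's qualitative findings at desk scale,
with sizes chosen as the package's defaults: 20 parents × 50 trials for the
noise experiment (ranges ±10/50/100 %, paired 95 % intervals across
parents); 5 elites × 3 Ra × 50 trials for the robustness-vs-Ra comparison;
8 elites over a 9-point Ra grid for the spikes-per-burst profile. Passing
them shows that the implemented mechanics reproduce the emulated regime on
this synthetic family — not that the numbers match any particular biological
population. Two honest caveats, both measured during calibration: at ±10 %
the robustness-vs-Ra ordering is weak and can genuinely reverse for a
minority of synthetic triple-Ra elites (weak coupling can slightly *help* at
small perturbations here), so the scaled comparison tests ±40 % and ±60 %,
where the true effect (margins ≳ 0.3) dwarfs the m = 50 estimator noise; and
burster persistence along 2–100 Ω·cm admits rare exceptions, which are
counted and reported rather than hidden (as in the emulated study, which
also reports rare exceptions).

## Known limitations

* The gating kinetics and drive waveforms are calibrated stand-ins within
  the standard functional family, not fits to the deposited model code.
* One density parameter per non-axonal channel, scaled by area, is assumed
  shared across soma/secondary/tertiary — required to make 14 free
  parameters, but the deposited models may differ.
* No temperature scaling, stochastic gating, plasticity, or morphology
  beyond four compartments.
* The synthetic population's absolute rates (hit rates, elite prevalence)
  are properties of the calibrated generator, not of the biological system.
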