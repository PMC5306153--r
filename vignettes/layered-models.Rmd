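---
title: "Layered neural-network models: format, simulation and fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered neural-network models: format, simulation and fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineml)
```

## The model format

`spineml` implements a layered declarative description of point-neuron
networks, split into three separable layers, each serialized as its own XML
file:

* **Components** are reusable hybrid dynamical systems: parameters, state
  variables, aliases (derived quantities), typed ports, and regimes holding
  time derivatives and transitions.  A component may describe a neuron body,
  a weight-update rule, a postsynapse, or any generic dynamical process.
* **Networks** bind components into populations and wire them with
  projections.  Every projection carries at least one synapse, and every
  synapse is a triple of connectivity scheme, weight-update component and
  postsynapse component.  Generic inputs connect arbitrary compatible ports
  outside the projection structure.
* **Experiments** describe what is done to the model — duration and
  integration step, stimuli, recordings, and property overrides — without
  touching the model itself, the way an experimental paradigm is described
  separately from the animal.

The separation means a network can be re-parameterised, re-stimulated and
re-recorded by exchanging one small file, and a component can be reused
across models.  Everything tool-specific (display colours, layout
references, connectivity recipes) lives in `<Annotations>` under a dedicated
namespace, so any reader that ignores annotations still sees a plain, valid
model.

### Expressions

All behaviour is written in a deliberately small expression grammar:
`+ - * / ^` (right-associative power), unary minus, parentheses, the
functions `exp, log, sin, cos, sqrt, abs, pow, min, max, floor`, and
comparisons with `&& || !` in boolean contexts.  `min`/`max` are
element-wise so a single expression evaluation covers a whole population.
`rand()` exists only in layout equations, never in component dynamics, so a
component's trajectory is fully determined by its inputs and initial state.
Expressions are parsed once and checked against a whitelist; identifiers are
case-sensitive, unit labels (`mV`, `pA`, ..., `dimensionless`) are compared
by equality only — there is no unit-conversion algebra, matching how the
format uses dimensions purely to prevent mis-wiring of ports.

Two conventions tie ports to dynamics: an analog or impulse *send* port is
named after the component symbol it exposes (a state variable or alias),
and an impulse's payload is the value of that symbol at emission time.  In
an `on_impulse` transition the payload is bound to the receiving port's
name, so `I_post + w_in` reads naturally as "current plus arriving weight".

## The layout engine

Populations can be given 3D coordinates procedurally.  A layout rule is an
ordered set of per-variable update equations evaluated like an animation:
frame 0 is the initial state (all variables 0, micrometre units), and for
each subsequent frame index `p = 1, ..., n-1` the equations are evaluated in
declared order.  Reading a variable yields its previous-frame value unless
it was assigned earlier in the current frame.  We chose the
frame-0-is-initial-state reading because it is the only one under which both
canonical examples hold simultaneously: the accumulator rule
`x <- x + 1` produces `0, 1, 2, 3, ...`, and index formulas such as the grid
rule `x = p mod row_length`, `y = floor(p / row_length)` produce the same
grid either way (both give 0 at `p = 0`).

`rand()` draws uniform [0,1) values from a stream seeded by the rule's
seed (Mersenne–Twister, pinned), so layouts are reproducible across sessions
and platforms.  A minimum pairwise distance is enforced by rejection: a
frame whose point violates the constraint is re-evaluated wholesale — all of
its `rand()` draws refreshed — up to 10,000 retries per point, after which a
packing error is raised.  A deterministic rule (no `rand()`) that violates
the constraint fails immediately, since retrying cannot help.  The
`min_distance` postcondition is verified in the test suite by exhaustive
O(n²) checks up to n = 1000.

## Connectivity generators

Most connectivity must ultimately be stored as an explicit list of
`(source index, destination index, delay)` triplets so that any simulator
can consume it.  Generator scripts bridge the gap between that requirement
and convenient distance-based rules.  A script is a plain-text file whose
entry point takes `srclocs` and `dstlocs` (lists of (x, y, z) tuples) plus
parameters declared by `#PARNAME:`/`#LOC:` comment lines, with `#HASWEIGHT`
and `#HASDELAY` flags announcing what the script produces.  Scripts run in a
whitelist sandbox — pure computation, seeded RNG, no file or network access.

Two builtins ship with the package: `fixed_radius` (connect iff Euclidean
distance ≤ radius; delay = distance/velocity + base, in ms with velocity in
um/ms) and `gaussian_field` (connect with probability
`exp(-d²/2σ²)`, weight `amplitude · exp(-d²/2σ²)`).  Both are tested for
exact agreement with independent brute-force reimplementations.

A generated list is persisted as a fully explicit `<ConnectionList>` plus a
*generation recipe* (script text, parameter values, population sizes, weight
target) inside its annotations.  The file therefore remains plain valid
connectivity for any reader, while this package can skip regeneration
entirely unless the script text (even a whitespace change), the parameter
values, or either population size differs — exact equality, no heuristics.
Regeneration from a recipe is bit-exact.

## The reference simulator

The simulator flattens a resolved network into instance groups: one per
population, plus one weight-update group (one instance per connection) and
one postsynapse group (one instance per destination neuron) for each
projection synapse.  Numerical choices:

* **Fixed-step forward Euler**, `dt` from the experiment (ms, default 0.1).
  Time derivatives are in units of the state variable per second, so
  fixture components with ms-valued time constants carry explicit
  `1000/tau` factors.
* **Synchronous (Jacobi) analog propagation**: every receive port reads the
  sender's previous-step value, making results independent of group
  evaluation order.  Reduce ports sum over all wired senders; unwired
  receive ports read 0.
* **Delay queues**: event/impulse delays are quantised to
  `round(delay/dt)` steps with a minimum of one step, so a spike emitted at
  step *k* on a *d*-step connection acts at step *k + d* exactly.  Analog
  connections carry no delay.
* **Edge-triggered conditions**: an `on_condition` fires only on a
  false→true transition of its trigger, evaluated after the Euler update;
  simultaneous transitions resolve in declaration order.  The baseline is
  the trigger's value at t = 0, so a condition already true at start does
  not fire until it has gone false and true again.
* **Error handling**: any non-finite state aborts the run naming the
  population, neuron, variable and step.

All randomness (property sampling, probabilistic connectivity) derives from
one master seed by stable hashing of the object path (e.g.
`prop/SD1/tau_m`), so a run is reproducible end to end: identical project,
experiment and master seed give bit-identical logs.  Loggers produce one
data file and one XML descriptor each; analog traces have
`floor(duration/dt) + 1` records (the initial state plus one per step).

## Fixtures

### The rate-coded selection network

`build_selection_network()` constructs a channel-based action-selection
circuit of rate-coded leaky integrators
(`tau a' = -a + input`, output `y = clip(m(a - eps), 0, 1)`): cortical input
drives two striatal populations (with D1-type dopamine facilitation
`(1 + da)` and D2-type attenuation `(1 - da)`) and the subthalamic nucleus;
the D1 striatum focally inhibits the output nucleus (SNr), the D2 striatum
focally inhibits the globus pallidus, the subthalamic nucleus diffusely
excites both, and the pallidus feeds back onto the subthalamic nucleus.
Diffuse pathways are all-to-all with fan-in-normalised weights; focused
pathways are channel-wise one-to-one.  Selection shows as disinhibition: a
channel's SNr output falling below threshold (0.1 in normalised rate units)
releases its target from tonic inhibition.

The default weight/gain/threshold table follows the standard published
parameterisation of this model family (Gurney, Prescott & Redgrave 2001).
It is a starting point, not a certified reproduction — reproducing published
output curves requires the exact table from the published model files, which
is why the package's tests assert structural and qualitative properties of
the fixture rather than published trace values.

The suite asserts one behavioural property: driving exactly one channel's
cortical input strictly lowers that channel's SNr output at steady state,
for five seeded weight tables obtained by sign-preserving ±40% perturbation
of the default table.  The perturbation neighbourhood is part of the
property's definition, deliberately: the sign pattern alone does not make
this architecture a selection device.  Per channel, the focused striatal
inhibition (∝ `|w_sd1_snr|·w_cortex_sd1`) competes with the diffuse
subthalamic excitation (∝ `w_stn_snr·w_cortex_stn`), and with unconstrained
magnitudes the excitation can dominate, raising the driven channel's output
instead of lowering it.  Disinhibition is a property of the operating
regime, and the perturbation test probes robustness around it.

### Rate-to-spiking conversion

`convert_rate_to_snn()` turns the rate model into a spiking one by a
mechanical recipe whose knobs live in `snn_conversion_config()`:

| Step | Default | Rationale |
|---|---|---|
| neurons per rate unit | 7 | lower bound for a robust group response |
| channel pathways | one-to-one → within-channel all-to-all | each neuron hears the whole channel |
| weights | ÷ 7 | fan-in grows sevenfold |
| current-valued properties (dimension pA/nA) | × 10 | bridges rate-model levels and spiking currents; the subthalamic intrinsic current is exempt |
| membrane time constants | uniform 20–30 ms, seeded | desynchronises units (originally all 25 ms) |
| synapses | exponential current, τ = 4 ms | standard fast current synapse |
| cortical drive | analog level u → regular spike train at u·100 Hz | consistent with the 0.1 ↔ 10 Hz output correspondence |
| D2 dopamine | × 0.9 | "slightly reduced" influence; the exact factor is not a published constant |

The current-scaling rule is mechanical — it applies to properties whose
declared dimension is a current (pA/nA) — and the exemption list is a set of
(population, property) paths, defaulting to the subthalamic intrinsic
current only.  The neuron model is a leaky integrate-and-fire unit
(`tau_m v' = -v + R(I_syn + I_offset)`) with threshold 1, reset 0 and a 2 ms
refractory period; these defaults are this package's fixture choices, since
the conversion source names the neuron class but not its constants.  The
reduced D2 dopamine level is carried as an attribute of the converted
population because the LIF fixture has no explicit dopamine parameter.
Constant analog inputs convert to spike trains; time-varying inputs are
dropped with a warning rather than silently approximated.

### The striatal-like microcircuit

`build_striatal_like_fixture()` is a *synthetic* stand-in for an
anatomically detailed striatal microcircuit: it reproduces the geometry and
wiring style — two medium-spiny populations and a small fast-spiking
interneuron population placed uniformly in a 300 um cube with a minimum
separation, connected by the `fixed_radius` generator with distance-derived
delays, all using 2-variable quadratic (Izhikevich-style) point neurons —
but none of the published biophysics (dopamine-modulated conductances, gap
junctions).  It exists to exercise layouts, generator recipes and the
event-driven simulator at microcircuit scale.

## Spike-train analysis

`gaussian_rate()` convolves spike trains with unit-area Gaussian kernels,
giving an instantaneous firing-rate estimate in Hz; the default width used
for the spiking selection model is σ = 100 ms, and with unit-area kernels
the estimate of a regular train recovers its rate (a 10 Hz train reads
10 Hz mid-train to within 10⁻⁶ relative, since the periodic ripple at
σ = inter-spike interval is of order e^(−2π²)).  The trace integrates to
the spike count.  `detect_selection()` applies a strict `<` threshold —
0.1 for normalised rate outputs, 10 Hz for kernel estimates — so a channel
sitting exactly at threshold is not selected; two channels below threshold
are both selected (dual selection is representable).  Plot helpers build
line and raster plots whose underlying data frames carry exactly one row
per sample or spike, which is what the tests assert on (pixel output is not
tested).

## What the tests do and do not show

The synthetic fixtures emulate the *structure* of the models they are
patterned on: rosters, connectivity styles, conversion arithmetic, geometry.
They do not reproduce published parameter tables, so passing tests certify
the machinery — serialization identity, generator/oracle agreement, Euler
convergence against closed forms, delay exactness, bit-reproducibility,
conversion factors, qualitative disinhibition — and not any published
figure.  Problem sizes were chosen to keep each check sharp but small:
layouts up to 1000 points for O(n²) distance verification, generator
oracles up to 200×200 pairs, charging-curve runs of 5,000–10,000 Euler
steps, selection-network steady states at dt = 5 ms for 1.2 s, and
microcircuits of tens of neurons for end-to-end determinism.

Known limitations: analog connections cannot carry delays; property
overrides are population-level (no per-synapse overrides from the
experiment layer); the conversion handles constant cortical inputs only;
and the reference integrator is first-order fixed-step — components with
stiff dynamics need a smaller `dt`, not a different method.
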