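---
title: "Models, numerics and design choices in neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

`neurodyn` is a simulator for dynamical-systems models of neurons and
networks. This vignette explains the modeling formalism, the numerical
choices, and the places where the design was genuinely open — and why the
package resolves them the way it does.

## The modeling formalism

A model is a set of plain-text statements: parameters (`gNa = 120`), fixed
variables (expressions evaluated once before integration, e.g. a
connectivity matrix), functions of declared arguments
(`INa(V,m,h) = -gNa*m^3*h*(V-ENa)`), ODEs with initial conditions
(`dV/dt = ...; V(0) = -65`), and conditional updates
(`if(v > vpeak)(v = c; u = u + d)`) that fire after every integration step.
Statements are delimited by newlines or semicolons; `%` and `#` start
comments; `^` is exponentiation. Identifiers are ASCII
letters/digits/underscores; every identifier in every expression must be
declared or belong to the builtin whitelist (`exp`, `log`, `sqrt`,
trigonometric functions, `min`/`max` (elementwise when binary), `abs`,
`heaviside`, `mod`, `rand`, `randn`, `matmul`, `ones`, the time `t` and
step `dt`). This strictness catches typos at parse time rather than as
mysterious `NA`s at run time.

Two object kinds organize larger models. A *population* is a set of
identical units with per-unit state arrays; scalar parameters and initial
conditions broadcast over the population, arrays of the population size
give heterogeneity. A *mechanism* is a reusable equation fragment (an ion
current, a synapse, an input source) inserted into a host population.
Mechanisms export their contribution through *linker* statements: the host
writes a placeholder such as `@current` into its voltage equation, and each
mechanism contributes `@current += INa`. At build time every object's names
receive a namespace prefix (`pop1_Na_m` for state `m` of mechanism `Na` in
population `pop1`, joined with `_`), contributions are folded in
mechanism-list order (`+=` adds, `-=` subtracts, `*=` multiplies, `=`
overwrites and must be unique), and the placeholder disappears: the flat
model contains no `@` token. A placeholder with no contributions becomes
the additive identity 0, so a model "missing" its mechanisms still builds
and integrates. Name collisions between qualified symbols (which can arise
when a population name plus local name happens to equal another path) are
hard errors rather than silent renames: predictability beats convenience.

Connections between populations carry their own mechanisms. Inside a
connection mechanism the reserved symbols are `netcon` (the connectivity
matrix, **target x source**, default all-to-all ones, so synaptic drive is
`matmul(netcon, s)` with `s` the per-source-cell gating vector),
`<name>_pre` / `<name>_post` (elements of the source/target populations),
`Npre`/`Npost` (sizes), and `tspike_pre`/`tspike_post` (ring buffers of the
most recent spike times per cell, newest first, depth set by the
`spike_buffer` solver option). Connection-mechanism ODE states are per
source cell — the natural shape for synaptic gating driven by presynaptic
voltage. Parameter precedence, highest first: population/connection
`parameters` overrides, then inline mechanism definitions in the
specification, then library file defaults. The packaged synapses divide the
summed drive by `Npre`, so their conductances are per-afferent and roughly
size-invariant.

## Numerical integration

Fixed-step Euler, midpoint (RK2) and classical RK4 are generated as
straight-line R programs from the flat model; the in-memory integrator
evaluates exactly the program that `render_solver_source()` writes to disk,
which is why the emitted-solver fidelity checks pass at the level of
floating-point round-off in CSV serialization (~1e-13) rather than at some
looser tolerance. Each step: state update, then conditionals in declaration
order (actions left-to-right, each seeing earlier actions' effects), then
spike detection and recording. Defaults are `dt = 0.01` ms and a 0-100 ms
span — fine enough to resolve Hodgkin-Huxley spike upstrokes — with spike
threshold 0 mV, overridable per population via `monitor V.spikes(level)`.

Spikes are *upward threshold crossings*: a spike at step k iff
`v[k-1] < threshold <= v[k]`, detected at full resolution regardless of the
`downsample_factor` used for recording. Because detection runs after the
conditionals, models that reset the voltage from above (integrate-and-fire
style) should monitor a level *below* the reset trigger — the packaged LIF
cell monitors `V.spikes(-45)` against its -40 mV firing threshold — so the
upstroke is caught before the reset erases it.

Stochastic terms use one engine-owned stream seeded from the solver
options. Random builtins inside right-hand sides are hoisted to one draw
per step, taken before the first stage and reused across Runge-Kutta
stages; per-evaluation draws inside multi-stage methods would make the
effective noise variance depend on the method, which is never what a
modeler means. The packaged `noise` mechanism contributes
`noise_amp*sqrt(dt)*randn(...)` to the current, i.e. a per-step voltage
increment of `noise_amp*dt^{3/2}` standard deviations under Euler; for
stochastic models the Euler method is the natural (Euler-Maruyama) choice
and is what the stochastic fixtures use.

The `adaptive` method delegates to `deSolve::ode` (lsoda) for stiff or
high-accuracy reference solutions. Conditionals are then applied by polling
at the recording grid, so reset timing is grid-quantized — a documented
caveat — and stochastic builtins are rejected outright rather than given
ill-defined semantics. The sparse-connectivity option is a storage hint
only (`Matrix` sparse storage behind the same `matmul`); results must and
do match dense evaluation, which is also the honest reading of "simulation
speed independent of connection density" for a clock-driven synapse scheme
at these model sizes.

Fixed variables are evaluated once, before integration, in dependency
order; referencing a state variable from a fixed variable is a build error
because it would silently freeze a time-varying quantity. Functions are
inlined into closed-form expressions during code generation (a bare
reference to a function stands for a call with its declared arguments —
this is what makes the flat ODE read `pop1_Na_INa + pop1_K_IK` and still
execute).

## The mechanism library

The library ships the objects the worked examples need: Hodgkin-Huxley
`iNa`/`iK` (1952 squid kinetics), fast-spiking `iNaF`/`iKDR`
(Wang-Buzsaki-style, instantaneous sodium activation, rate scale phi = 5),
a slow M-type `iM`, a persistent sodium `iNaP`, first-order
sigmoid-threshold synapses `iAMPA` (reversal 0 mV, decay 2 ms) and
`iGABAa` (reversal -80 mV, decay `tauD = 10` ms — the library default),
ohmic `iGAP`/`iCOM`, input sources `noise`/`poisson`/`stim`, and population
templates `HH`, `Izh`, `LIF` (with a parameterized refractory period via a
conditional and a last-spike-time state). Kinetic constants follow the
cited canonical sources where those sources print them; where they do not,
values are the package's own, chosen for the qualitative behaviors the
tests pin down (rest stability, repetitive firing, bursting, gamma).

Two library choices deserve explanation. First, `iM` uses a simplified
high-threshold activation (half-activation -15 mV, 90 ms time constant) so
that it accumulates across spikes rather than at rest. Second, the
intrinsically-bursting fixture includes `iNaP` alongside
`{iNaF, iKDR, iM}`: a type-1 spiking model with only a slow adaptation
current settles into tonic adapted firing — rhythmic burst-and-pause
requires bistability between rest and spiking, which the persistent sodium
window current provides (and which the cortical IB cell type in fact has).
With the defaults (`Iapp = 0.5`, `gNaP = 0.5`, `gM = 4`) the cell fires
stereotyped spike triplets separated by ~120 ms silent pauses, a strongly
bimodal interspike-interval distribution.

## The weak PING fixture

`weak_ping_fixture()` is the package's canonical network: 20 excitatory and
5 inhibitory fast-spiking cells, all-to-all `iAMPA` E→I and `iGABAa` I→E,
tonic drive `Iapp = 5` to E plus weak Gaussian current noise
(`noise_amp = 10`) and 5 mV uniform jitter on initial voltages. The gamma
mechanism is the classic one: an E volley recruits I within a couple of
milliseconds, the returned inhibition silences E for roughly one GABA-A
decay time (`tauD = 10` ms), and the cycle repeats — a ~25 ms period, i.e.
a ~40 Hz rhythm whose frequency is set chiefly by `tauD` and the E drive.
The conductances and drive were calibrated once, while authoring the
fixture, so that the 1-s, `dt = 0.01` ms Euler simulation
(`weak_ping_options()`) peaks at 40 Hz in the spectrum of the cell-averaged
E voltage; `weak_ping_peak()` packages that measurement (100 ms transient
discarded, periodogram peak excluding DC).

What the fixture emulates is the rhythm-generation mechanism, not cortex:
cells are single-compartment and identical up to initial conditions, the
connectivity is all-to-all, and the drive is stationary. Passing tests
therefore certify the simulator and the model composition machinery — that
this network, as specified, oscillates where its dynamics say it should —
not that the library parameters reproduce any particular biological
dataset.

## Analyses

Firing rates are whole-window spike counts divided by the window length,
with a 50 ms default onset transient excluded (an optional binned view can
be had by windowing). The power spectrum is the rectangular-window
periodogram of each cell's (mean-subtracted) trace averaged over cells,
normalized so total power equals signal variance (Parseval), with the peak
reported off-DC. Coherence is Welch-style: Hann window, 8 segments, 50%
overlap by default; the estimator's small-sample bias for unrelated
signals is ~1/K for K segments, which the null tests use as their
yardstick. Raster extraction returns sorted (cell, time) pairs; plotting is
a thin layer over that.

## Batches and studies

`expand_vary()` turns (object, parameter, values) triplets into the
Cartesian product of modification sets, first triplet slowest-varying; an
explicit list of modification sets ("zipped" sweeps) is accepted as-is.
Modifications address specifiers generally — population `size` included —
not just parameters. Each simulation's seed is derived deterministically
from the master seed and the simulation index, so serial and parallel
execution (a local `mclapply` map) give identical results and any single
simulation can be reproduced in isolation; cluster scheduling is out of
scope, but each study writes a `jobs.manifest` with one command line per
simulation for any external scheduler. A study directory is
self-describing: `index.json` records the plan, seeds and outcomes, and
each simulation's subdirectory holds `states.csv`, `spikes.csv`,
`metadata.json` and one JSON file per analysis hook. Hook errors are
recorded per simulation and the batch continues — in a 1000-simulation
sweep, one analysis bug should cost one result, not the night's compute.
All on-disk formats are plain text by design: diffable, greppable, and
readable from any language without a binary dependency.

## Problem sizes and determinism in the tests

The test suite exercises the full pipeline at deliberately modest sizes:
the 25-cell PING network for 0.2-1 s, single cells for 0.1-1 s, 9-way
sweeps of 3-cell noisy populations for 150 ms. These sizes are where the
scientific content lives (the gamma mechanism, convergence orders,
bit-level reproducibility); larger networks exercise the same generated
code paths with bigger vectors. Solver-order checks fit log-error against
log-dt over a 8x dt range and require slopes within 0.3 of nominal;
trajectory equivalences (mechanism-composed vs. explicitly written models;
emitted vs. in-memory solvers; serial vs. parallel batches) are held to
1e-12-or-exact because the implementation makes them identical by
construction, and a looser tolerance would only mask regressions.

## Known limitations

Synaptic evaluation is clock-driven (every step), not event-driven; there
is no physical-unit management (values are conventionally mV, ms, and
µA/cm² with Cm = 1 µF/cm², but nothing checks this); no explicit spatial
geometry (compartments are populations joined by `iCOM`); the adaptive
delegate quantizes conditional resets to the recording grid; and value
monitors record post-conditional values (the other convention is defensible
— this one matches what the recorded state arrays show at the same
instant). Expression evaluation is vectorized-interpreted R — ample for
tens to hundreds of cells, but no substitute for compiled kernels at
10^5+ cells.
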