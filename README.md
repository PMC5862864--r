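# neurodyn

Equation-based modeling and batch simulation of neural dynamics in R.

`neurodyn` is for computational neuroscientists (and dynamical-systems
modelers generally) who want to go from a model written as plain equations
— or assembled from reusable ion-channel/synapse components — to simulated,
analyzed dynamics without writing integration loops. It covers the full
workflow: a small equation language, modular model composition, fixed-step
numerical integration with spike handling, parameter-sweep batch
management, and built-in spectral/rate analysis.

## The formalism

A model is text. Parameters, functions, ODEs with initial conditions, and
conditional updates:

```
a = 0.03; b = -2; c = -50; d = 100; vr = -60; vpeak = 35
I(t) = Iapp
dv/dt = .01*(.7*(v - vr)*(v + 40) - u + I(t))
du/dt = a*(b*(v - vr) - u)
if(v > vpeak)(v = c; u = u + d)
```

Larger models are composed from *mechanisms* — reusable equation objects
such as the packaged Hodgkin–Huxley currents — inserted into a
population's dynamics through *linker* placeholders. A host equation
`dV/dt = @current` plus mechanism statements `@current += INa` and
`@current += IK` flattens, after namespace qualification, into the single
ODE

```
d(pop1_V)/dt = pop1_Na_INa + pop1_K_IK
```

with every symbol made globally unique by its object path (`pop1_Na_m` for
state `m` of mechanism `Na` in population `pop1`). Networks are
specifications with `populations` (name, size, equations, mechanism list,
parameters) and `connections` (source, target, connection mechanisms, with
a target-by-source connectivity matrix `netcon`). The flattened system is
integrated with Euler/RK2/RK4 (or delegated to `deSolve`), evaluating
conditionals after every step and detecting spikes as upward threshold
crossings. Parameter sweeps are triplets (object, parameter, values)
expanded by Cartesian product into deterministic, reproducible batches.

## Worked example: a 40 Hz gamma network

The packaged weak-PING fixture couples 20 excitatory and 5 inhibitory
Hodgkin–Huxley-type cells: AMPA synapses E→I, GABA-A synapses I→E with a
10 ms decay constant, tonic drive to E. The inhibitory decay time paces a
pyramidal–interneuron gamma rhythm:

```r
library(neurodyn)

model <- build_model(weak_ping_fixture())
model
#> <flat_model: 8 state variable(s), 100 unit(s) total>
#>   population E (n=20, spikes on E_V >= 0)
#>   population I (n=5, spikes on I_V >= 0)
#>   states: E_V, I_V, E_iNaF_hNaF, E_iKDR_nKDR, I_iNaF_hNaF, I_iKDR_nKDR,
#>           E_I_iGABAa_s, I_E_iAMPA_s

d <- integrate_model(model, weak_ping_options(seed = 1, tspan = c(0, 500)))
firing_rate(d, "E")
#> <rate_result 'E': mean 40.00 spikes/s over [50, 500] ms, 20 cell(s)>
firing_rate(d, "I")
#> <rate_result 'I': mean 80.00 spikes/s over [50, 500] ms, 5 cell(s)>

keep <- d$time >= 100  # discard the onset transient
power_spectrum(matrix(rowMeans(d$series$E_V[keep, ]), ncol = 1), 0.01)
#> <spectrum_result: 20001 bins up to 49998.8 Hz, peak at 40.00 Hz>
```

Every E cell fires on every ~25 ms cycle (40 spikes/s), the I cells fire
twice per volley (80 spikes/s), and the cell-averaged E voltage has its
spectral peak at 40 Hz — the gamma rhythm whose period is set chiefly by
the inhibitory decay constant.

Sweeping parameters over a batch:

```r
plan <- expand_vary(list(vary("E", "Iapp", c(4, 5, 6)),
                         vary("I->E", "tauD", c(5, 10, 20))))  # 9 simulations
res <- run_batch(weak_ping_fixture(), plan, weak_ping_options(),
                 hooks = "firing_rate", study_dir = "study")
```

writes one self-describing subdirectory per simulation (plain-text states,
spikes, metadata, hook results) plus an `index.json`; `import_results()`
loads data or hook results back in plan order. A thin command-line front
end (`inst/cli/neurodyn`) exposes `run`, `sweep`, `analyze` and
`list-mechanisms` over JSON specification files.

`render_solver_source(model, opts)` emits the integration program as a
standalone base-R script whose output matches the in-memory integrator to
round-off; the generated solver is saved with each study for examination
and re-use.

## Package layout

- `R/` — equation parsing, specification handling, model flattening,
  solver code generation, batch management, analyses, fixtures
- `inst/library/` — packaged mechanism (`.mech`) and population (`.pop`)
  files with citations in their headers
- `inst/schema/` — JSON schema for specification files
- `vignettes/neurodyn-methods.Rmd` — the models, numerics and design
  choices in detail
- `tests/testthat/` — unit, property and end-to-end tests
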