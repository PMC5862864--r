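# Worked-example model fixtures. These are first-class model generators
# used by the examples, tests and the reproduction script; their defaults
# are the package's canonical study conditions.

#' Lorenz system fixture
#'
#' The classic three-variable chaotic system with s = 10, r = 27, b = 2.666
#' and initial state (1, 1, 1). Time is in the system's own dimensionless
#' units; integrate with a correspondingly small `dt`.
#'
#' @return A `specification` with a single population `pop1` holding the
#'   three ODEs.
#' @export
lorenz_fixture <- function() {
  standardize(paste(
    "s = 10; r = 27; b = 2.666",
    "dx/dt = s*(y - x)",
    "dy/dt = r*x - y - x*z",
    "dz/dt = -b*z + x*y",
    "x(0) = 1; y(0) = 1; z(0) = 1",
    sep = "\n"))
}

#' Izhikevich neuron fixture
#'
#' Two-variable spiking model with the quadratic voltage equation
#' `dv/dt = .01*(.7*(v - vr)*(v + 40) - u + I(t))`, linear recovery
#' `du/dt = a*(b*(v - vr) - u)`, and the conditional reset
#' `if(v > vpeak)(v = c; u = u + d)` (regular-spiking coefficients). The
#' equation text is identical to the packaged `Izh` library population, so
#' both specification routes build the same model.
#'
#' @param Iapp Tonic input amplitude.
#' @param noisy Add a uniformly-jittered input (`I(t)` multiplied by a
#'   per-step random factor) for the stochastic-drive variant.
#' @return A `specification`.
#' @export
izhikevich_fixture <- function(Iapp = 100, noisy = FALSE) {
  itxt <- if (noisy) "I(t) = Iapp*(0.5 + rand(1, Npop))" else "I(t) = Iapp"
  standardize(population("pop1", 1, paste(
    "a = 0.03; b = -2; c = -50; d = 100; vr = -60; vpeak = 35",
    sprintf("Iapp = %g", Iapp),
    itxt,
    "dv/dt = .01*(.7*(v - vr)*(v + 40) - u + I(t))",
    "v(0) = vr",
    "du/dt = a*(b*(v - vr) - u)",
    "u(0) = 0",
    "if(v > vpeak)(v = c; u = u + d)",
    sep = "\n")))
}

#' Intrinsically-bursting neuron fixture
#'
#' A single compartment with fast spike-generating currents (iNaF, iKDR), a
#' persistent sodium window current (iNaP) providing the plateau
#' depolarization that sustains a burst, and the slow M-type potassium
#' current (iM) whose build-up across spikes terminates each burst and
#' whose decay paces the inter-burst pause. Under tonic drive the cell
#' produces stereotyped bursts of spikes separated by long silent
#' intervals, giving a strongly bimodal interspike-interval distribution.
#' Dropping iNaP and iM from the mechanism list yields a regular-spiking
#' cell. (Slow adaptation alone cannot produce rhythmic bursting in this
#' type-1 spiking model; the persistent inward current supplies the
#' required bistability.)
#'
#' @param Iapp Tonic drive (default 0.5).
#' @param gM Peak M-current conductance (default 4).
#' @param gNaP Peak persistent-sodium conductance (default 0.5).
#' @return A `specification` for one cell.
#' @export
ib_neuron_fixture <- function(Iapp = 0.5, gM = 4, gNaP = 0.5) {
  standardize(population(
    "pop1", 1,
    "dV/dt = (Iapp + @current)/Cm; Iapp = 0; Cm = 1; V(0) = -70",
    mechanism_list = c("iNaF", "iKDR", "iNaP", "iM"),
    parameters = list(Iapp = Iapp, gM = gM, gNaP = gNaP)))
}

#' Weak PING network fixture
#'
#' Two reciprocally coupled populations of Hodgkin-Huxley-type cells: an
#' excitatory population E under tonic drive (plus weak Gaussian current
#' noise and jittered initial voltages) and an inhibitory population I
#' driven only by E through AMPA synapses, feeding GABA-A inhibition back
#' onto E. With the inhibitory decay constant `tauD = 10` ms the loop
#' generates a pyramidal-interneuron network gamma rhythm near 40 Hz: each
#' E volley recruits I, whose inhibition silences E for roughly one decay
#' time before the next volley.
#'
#' @param n_e,n_i Population sizes (defaults 20 and 5).
#' @param Iapp Tonic current into E (default 5).
#' @param g_gabaa GABA-A conductance of the I->E synapse (default 1).
#' @param g_ampa AMPA conductance of the E->I synapse (default 0.5).
#' @param tauD GABA-A decay time constant in ms (default 10).
#' @param noise_amp Gaussian current-noise amplitude on E (default 10).
#' @return A `specification`.
#' @export
weak_ping_fixture <- function(n_e = 20L, n_i = 5L, Iapp = 5, g_gabaa = 1,
                              g_ampa = 0.5, tauD = 10, noise_amp = 10) {
  specification(
    populations = list(
      population("E", n_e,
                 "dV/dt = (Iapp + @current)/Cm; Iapp = 0; Cm = 1; V(0) = -65 + 5*rand(1, Npop)",
                 mechanism_list = c("iNaF", "iKDR", "noise"),
                 parameters = list(Iapp = Iapp, noise_amp = noise_amp)),
      population("I", n_i,
                 "dV/dt = (Iapp + @current)/Cm; Iapp = 0; Cm = 1; V(0) = -65 + 5*rand(1, Npop)",
                 mechanism_list = c("iNaF", "iKDR"))),
    connections = list(
      connection("I", "E", mechanism_list = "iGABAa",
                 parameters = list(gGABAa = g_gabaa, tauD = tauD)),
      connection("E", "I", mechanism_list = "iAMPA",
                 parameters = list(gAMPA = g_ampa))))
}

#' Canonical solver options for the weak PING fixture
#'
#' 1 s of simulated time at dt = 0.01 ms with the Euler update (the
#' fixture's drive is stochastic, making this the Euler-Maruyama scheme).
#'
#' @param seed Random seed.
#' @param tspan Simulated interval (ms).
#' @return A `solver_options`.
#' @export
weak_ping_options <- function(seed = 1L, tspan = c(0, 1000)) {
  solver_options(method = "euler", dt = 0.01, tspan = tspan, seed = seed)
}

#' Gamma peak of the weak PING fixture
#'
#' Builds and simulates the weak PING fixture, discards an initial
#' transient, and returns the power-spectrum peak frequency of the
#' cell-averaged E voltage.
#'
#' @param seed Random seed.
#' @param tspan Simulated interval (ms).
#' @param transient Discarded initial interval (ms, default 100).
#' @param spec Fixture specification (default [weak_ping_fixture()]).
#' @return Peak frequency in Hz.
#' @export
weak_ping_peak <- function(seed = 1L, tspan = c(0, 1000), transient = 100,
                           spec = weak_ping_fixture()) {
  d <- integrate_model(build_model(spec), weak_ping_options(seed, tspan))
  keep <- d$time >= d$time[[1]] + transient
  x <- rowMeans(d$series$E_V[keep, , drop = FALSE])
  power_spectrum(matrix(x, ncol = 1), diff(d$time[1:2]))$peak_hz
}

#' Poisson-driven population fixture
#'
#' Cells whose state is kicked above threshold by a homogeneous Poisson
#' event train (rate `lambda0` events/s per cell, per-step thinning) and
#' decays back quickly, so detected spike counts follow the input process.
#' Used to check rate estimation against the Poisson expectation.
#'
#' @param lambda0 Event rate per cell in events/s.
#' @param n Number of cells.
#' @return A `specification`.
#' @export
poisson_rate_fixture <- function(lambda0 = 20, n = 100L) {
  standardize(population(
    "pop1", n,
    "dv/dt = -v/0.5 + @current; v(0) = 0\nmonitor v.spikes(1)",
    mechanism_list = "poisson",
    parameters = list(poisson_rate = lambda0, poisson_amp = 2.2)))
}
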