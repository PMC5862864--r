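# Shared helpers and independent oracles used across the test files.
# Oracles are deliberately plain-R re-derivations (scalar loops, closed
# forms) that never touch the package's code-generation path.

# scalar Euler integrator with a single post-update reset condition;
# mirrors the documented step semantics (update, then conditional)
oracle_euler_reset <- function(slope, v0, dt, nsteps, threshold, reset) {
  v <- v0
  trace <- numeric(nsteps + 1L)
  trace[[1L]] <- v
  resets <- 0L
  for (k in seq_len(nsteps)) {
    v <- v + dt * slope
    if (v > threshold) {
      v <- reset
      resets <- resets + 1L
    }
    trace[[k + 1L]] <- v
  }
  list(trace = trace, resets = resets)
}

# global error of a method on dx/dt = -x, x(0) = 1 over (0, 1)
decay_error <- function(method, dt) {
  d <- integrate_model("dx/dt = -x; x(0) = 1",
                       solver_options(method = method, dt = dt, tspan = c(0, 1)))
  abs(d$series$pop1_x[length(d$time)] - exp(-1))
}

# log-log slope of error vs dt
error_slope <- function(method, dts = c(0.1, 0.05, 0.025, 0.0125)) {
  errs <- vapply(dts, function(dt) decay_error(method, dt), 0)
  unname(stats::coef(stats::lm(log(errs) ~ log(dts)))[[2]])
}

# hand-built sim_data for analysis unit tests
fake_simdata <- function(spikes, t0 = 0, t1 = 1000, dt = 1) {
  time <- seq(t0, t1, by = dt)
  structure(list(
    time = time,
    series = list(),
    spikes = list(pop1 = spikes),
    metadata = list()), class = "sim_data")
}

# small stochastic population used by batch tests: noisy HH cells
noisy_hh_spec <- function(n = 3L, Iapp = 8) {
  standardize(population("pop1", n, "HH", mechanism_list = "noise",
                         parameters = list(Iapp = Iapp, noise_amp = 30)))
}

batch_opts <- function(seed = 42L) {
  solver_options(method = "euler", dt = 0.02, tspan = c(0, 150), seed = seed)
}

# run the standalone emitted solver and return the states matrix (no time col)
run_emitted <- function(model, opts) {
  td <- tempfile("emit")
  dir.create(td)
  script <- file.path(td, "solve.R")
  render_solver_source(model, opts, file = script)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(script, td), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  st <- utils::read.csv(file.path(td, "states.csv"), check.names = FALSE)
  st
}

# one cached short weak-PING run shared by analysis tests
.ping_cache <- new.env(parent = emptyenv())
ping_run <- function() {
  if (is.null(.ping_cache$d)) {
    .ping_cache$d <- integrate_model(
      build_model(weak_ping_fixture()),
      weak_ping_options(seed = 11L, tspan = c(0, 400)))
  }
  .ping_cache$d
}
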