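# Numerical integration front end: solver options, the in-memory fixed-step
# integrator (which evaluates the generated solver program), the adaptive
# delegate (deSolve), spike detection, and post-hoc downsampling.

#' Solver options
#'
#' @param method Integration method: `"rk4"` (default), `"rk2"`, `"euler"`
#'   (fixed-step; for models with stochastic drive the Euler update is the
#'   Euler-Maruyama scheme), or `"adaptive"` which delegates to
#'   [deSolve::ode()] (`lsoda`); with the adaptive delegate conditionals are
#'   applied by polling at the recording grid, so reset timing is
#'   grid-quantized, and stochastic builtins are not allowed.
#' @param dt Integration time step in ms (default 0.01, chosen to resolve
#'   Hodgkin-Huxley-type spikes).
#' @param tspan Length-2 numeric, simulated interval in ms (default 0-100).
#' @param downsample_factor Record every k-th step (default 1). Spikes are
#'   always detected at full resolution.
#' @param seed Integer seed for the engine-owned random stream (initial
#'   conditions and stochastic drive). Identical (model, options, seed)
#'   triplets give bit-identical results.
#' @param record `"all"` or character vector of state/monitor names.
#' @param spike_buffer Number of recent spike times kept per cell in the
#'   `tspike_pre`/`tspike_post` buffers (newest first).
#' @param sparse Store connectivity matrices sparsely (storage hint only;
#'   results are identical to dense evaluation).
#' @param rtol,atol Tolerances for the adaptive delegate.
#' @return A `solver_options` list.
#' @export
solver_options <- function(method = c("rk4", "rk2", "euler", "adaptive"),
                           dt = 0.01, tspan = c(0, 100),
                           downsample_factor = 1L, seed = 1L,
                           record = "all", spike_buffer = 1L,
                           sparse = FALSE, rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  structure(list(method = method, dt = dt, tspan = tspan,
                 downsample_factor = downsample_factor, seed = seed,
                 record = record, spike_buffer = spike_buffer,
                 sparse = sparse, rtol = rtol, atol = atol),
            class = "solver_options")
}

.check_solver_options <- function(opts) {
  if (!inherits(opts, "solver_options")) {
    opts <- do.call(solver_options, as.list(opts))
  }
  if (!(is.numeric(opts$dt) && opts$dt > 0)) stop("dt must be > 0", call. = FALSE)
  if (length(opts$tspan) != 2L || opts$tspan[[2]] <= opts$tspan[[1]]) {
    stop("tspan must be (t0, t1) with t1 > t0", call. = FALSE)
  }
  dsf <- opts$downsample_factor
  if (!isTRUE(all.equal(dsf, round(dsf))) || dsf < 1) {
    stop("downsample_factor must be a positive integer", call. = FALSE)
  }
  opts$downsample_factor <- as.integer(round(dsf))
  opts$seed <- as.integer(opts$seed)
  opts
}

# cheap content hash (md5 of the serialized object) for provenance metadata
.model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model, f)
  unname(tools::md5sum(f))
}

#' Integrate a flat model
#'
#' Runs the numerical integration and returns a `sim_data` object: the
#' shared time axis, one time-by-cells matrix per recorded state variable
#' (and per value monitor), detected spike times per population, and
#' metadata. Fixed variables are evaluated once before the loop; each step
#' applies the state update, then the conditionals in declaration order,
#' then spike detection and recording. Non-finite states abort with the
#' offending variable and step.
#'
#' @param model A `flat_model` (or anything [build_model()] accepts).
#' @param opts [solver_options()].
#' @param mech_paths Extra mechanism search paths when `model` still needs
#'   building.
#' @return A `sim_data` object.
#' @examples
#' d <- integrate_model("dx/dt = -x; x(0) = 1",
#'                      solver_options(method = "rk4", dt = 0.01, tspan = c(0, 1)))
#' tail(d$series$pop1_x, 1)  # ~ exp(-1)
#' @export
integrate_model <- function(model, opts = solver_options(), mech_paths = character(0)) {
  if (!inherits(model, "flat_model")) model <- build_model(model, mech_paths)
  opts <- .check_solver_options(opts)
  if (opts$method == "adaptive") return(.integrate_adaptive(model, opts))
  prog <- .generate_program(model, opts)
  env <- new.env(parent = globalenv())
  eval(parse(text = c(prog$preamble, prog$loop, prog$finish_mem)), envir = env)
  res <- env$.result
  varied <- attr(model, "varied")
  structure(list(time = res$time, series = res$series, spikes = res$spikes,
                 metadata = list(options = opts, model_hash = .model_hash(model),
                                 varied = varied)),
            class = "sim_data")
}

# adaptive delegate: deSolve::lsoda over the recording grid, with
# conditionals polled (and spikes detected) at grid points
.integrate_adaptive <- function(model, opts) {
  all_exprs <- c(unlist(model$odes), unlist(model$ics),
                 vapply(model$functions, `[[`, "", "body"))
  if (any(vapply(all_exprs, function(s) .uses_random(dsl_parse_expr(s)), TRUE))) {
    stop("the adaptive delegate requires deterministic equations (no rand/randn)",
         call. = FALSE)
  }
  states <- names(model$odes)
  layout <- model$state_layout
  sizes <- vapply(states, function(st) layout[[st]]$size, 0L)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- states

  # evaluation environment: parameters, helpers, fixed variables
  fixed_opts <- opts; fixed_opts$method <- "euler"
  prog <- .generate_program(model, fixed_opts)
  env <- new.env(parent = globalenv())
  eval(parse(text = prog$preamble), envir = env)

  dexpr <- lapply(states, function(st) {
    parse(text = .compile_expr(model$odes[[st]], model))[[1]]
  })
  names(dexpr) <- states

  unpack <- function(y) {
    for (st in states) {
      assign(st, y[(offsets[[st]] + 1L):(offsets[[st]] + sizes[[st]])], envir = env)
    }
  }
  rhs <- function(t, y, parms) {
    env$t <- t
    unpack(y)
    list(unlist(lapply(states, function(st) {
      rep_len(eval(dexpr[[st]], env), sizes[[st]])
    }), use.names = FALSE))
  }

  y0 <- unlist(lapply(states, function(st) get(st, envir = env)), use.names = FALSE)
  t0 <- opts$tspan[[1]]; t1 <- opts$tspan[[2]]
  grid <- seq(t0, t1, by = opts$dt * opts$downsample_factor)
  if (grid[[length(grid)]] < t1) grid <- c(grid, t1)

  cond_exprs <- lapply(model$conditionals, function(cd) {
    list(cond = parse(text = .compile_expr(cd$condition, model))[[1]],
         size = cd$size,
         actions = lapply(cd$actions, function(a) {
           list(target = a$target,
                expr = parse(text = .compile_expr(a$expr, model))[[1]])
         }))
  })
  apply_conditionals <- function() {
    for (ce in cond_exprs) {
      cnd <- rep_len(eval(ce$cond, env), ce$size)
      if (any(cnd)) {
        m <- which(cnd)
        for (a in ce$actions) {
          av <- rep_len(eval(a$expr, env), ce$size)
          cur <- get(a$target, envir = env)
          cur[m] <- av[m]
          assign(a$target, cur, envir = env)
        }
      }
    }
  }

  nrec <- length(grid)
  rec <- lapply(states, function(st) matrix(NA_real_, nrec, sizes[[st]]))
  names(rec) <- states
  for (st in states) rec[[st]][1, ] <- get(st, envir = env)
  pops <- model$populations
  prev_v <- lapply(pops, function(p) get(p$voltage, envir = env))
  spk <- lapply(pops, function(p) list(t = numeric(0), i = integer(0)))

  y <- y0
  for (k in seq_len(nrec - 1L)) {
    seg <- deSolve::ode(y = y, times = c(grid[[k]], grid[[k + 1L]]), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = opts$rtol, atol = opts$atol)
    y <- as.numeric(seg[nrow(seg), -1])
    env$t <- grid[[k + 1L]]
    unpack(y)
    apply_conditionals()
    for (pn in names(pops)) {
      p <- pops[[pn]]
      v <- get(p$voltage, envir = env)
      cross <- (prev_v[[pn]] < p$threshold) & (v >= p$threshold)
      if (any(cross)) {
        idx <- which(cross)
        spk[[pn]]$t <- c(spk[[pn]]$t, rep(grid[[k + 1L]], length(idx)))
        spk[[pn]]$i <- c(spk[[pn]]$i, idx)
      }
      prev_v[[pn]] <- v
    }
    y <- unlist(lapply(states, function(st) get(st, envir = env)), use.names = FALSE)
    for (st in states) rec[[st]][k + 1L, ] <- get(st, envir = env)
    if (any(!is.finite(y))) {
      stop(sprintf("non-finite state at t = %g ms (adaptive delegate)", grid[[k + 1L]]),
           call. = FALSE)
    }
  }

  spikes <- lapply(names(pops), function(pn) {
    split(spk[[pn]]$t, factor(spk[[pn]]$i, levels = seq_len(pops[[pn]]$size)))
  })
  names(spikes) <- names(pops)
  record <- if (identical(opts$record, "all")) states else opts$record
  structure(list(time = grid, series = rec[record], spikes = spikes,
                 metadata = list(options = opts, model_hash = .model_hash(model),
                                 varied = attr(model, "varied"))),
            class = "sim_data")
}

#' Detect spikes by upward threshold crossings
#'
#' A spike is registered at sample `k` when `v[k-1] < threshold <= v[k]`.
#'
#' @param trace Numeric vector or time-by-cells matrix.
#' @param threshold Crossing level (same units as the trace).
#' @param times Optional time axis; defaults to sample indices.
#' @return A list with one sorted numeric vector of spike times per cell.
#' @examples
#' detect_spikes(c(-1, 1, -1, 2), threshold = 0)
#' @export
detect_spikes <- function(trace, threshold = 0, times = NULL) {
  if (is.null(dim(trace))) trace <- matrix(trace, ncol = 1L)
  n <- nrow(trace)
  if (is.null(times)) times <- seq_len(n)
  if (n < 2L) return(rep(list(numeric(0)), ncol(trace)))
  lapply(seq_len(ncol(trace)), function(j) {
    v <- trace[, j]
    k <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
    sort(times[k])
  })
}

#' Downsample recorded simulation data
#'
#' Keeps every `factor`-th recorded time point (always including the first).
#' Spike times are unchanged: spikes are detected at full integration
#' resolution, before any decimation.
#'
#' @param data A `sim_data`.
#' @param factor Positive integer decimation factor.
#' @return A `sim_data` with a shortened time axis.
#' @export
downsample <- function(data, factor) {
  stopifnot(inherits(data, "sim_data"))
  if (!isTRUE(all.equal(factor, round(factor))) || factor < 1) {
    stop("downsample factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(data)
  keep <- seq(1L, length(data$time), by = factor)
  data$time <- data$time[keep]
  data$series <- lapply(data$series, function(m) m[keep, , drop = FALSE])
  data
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data: %d time points (%g..%g ms), %d series>\n",
              length(x$time), x$time[[1]], x$time[[length(x$time)]],
              length(x$series)))
  cat(sprintf("  series: %s\n", paste(names(x$series), collapse = ", ")))
  for (pn in names(x$spikes)) {
    cat(sprintf("  spikes[%s]: %d events over %d cell(s)\n", pn,
                sum(lengths(x$spikes[[pn]])), length(x$spikes[[pn]])))
  }
  invisible(x)
}
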