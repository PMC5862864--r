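# Solver code generation. A flat model plus solver options is turned into a
# plain-R program that performs the fixed-step integration loop: parameters,
# fixed variables (evaluated once), initial conditions, the per-step state
# update (Euler/RK2/RK4), post-update conditionals in declaration order,
# spike detection by upward threshold crossings, and recording with optional
# downsampling. The in-memory integrator evaluates this program directly;
# render_solver_source() wraps the same program into a standalone script, so
# the two are equal by construction.
#
# Model functions are inlined into closed-form expressions before emission
# (a bare reference to a function stands for a call with its declared
# arguments). Random builtins in right-hand sides are hoisted to one draw
# per integration step, taken before the first stage and reused across
# Runge-Kutta stages.

# ---- expression rewriting ---------------------------------------------------

.inline_functions <- function(e, funcs, depth = 0L) {
  if (depth > 64L) {
    stop("function inlining exceeded depth limit (cyclic function definitions?)",
         call. = FALSE)
  }
  if (is.symbol(e)) {
    f <- funcs[[as.character(e)]]
    if (!is.null(f)) {
      return(.inline_functions(dsl_parse_expr(f$body), funcs, depth + 1L))
    }
    return(e)
  }
  if (is.call(e)) {
    head <- e[[1]]
    if (is.symbol(head)) {
      f <- funcs[[as.character(head)]]
      if (!is.null(f)) {
        args <- lapply(as.list(e)[-1], .inline_functions, funcs = funcs,
                       depth = depth + 1L)
        if (length(args) != length(f$args)) {
          stop(sprintf("function '%s' expects %d argument(s), got %d",
                       as.character(head), length(f$args), length(args)),
               call. = FALSE)
        }
        body <- dsl_parse_expr(f$body)
        body <- subst_symbols(body, stats::setNames(args, f$args))
        return(.inline_functions(body, funcs, depth + 1L))
      }
    }
    return(as.call(lapply(as.list(e), .inline_functions, funcs = funcs,
                          depth = depth)))
  }
  e
}

# builtin surface forms -> runnable R (except random draws, handled apart)
.rewrite_builtins <- function(e, matrix_syms = character(0)) {
  map_calls(e, function(cl) {
    if (!is.symbol(cl[[1]])) return(cl)
    hn <- as.character(cl[[1]])
    args <- as.list(cl)[-1]
    if (hn == "*" && length(args) == 2L && is.symbol(args[[1]]) &&
        as.character(args[[1]]) %in% matrix_syms) {
      return(as.call(c(as.symbol("matmul"), args)))
    }
    if (hn == "min" && length(args) > 1L) return(as.call(c(as.symbol("pmin"), args)))
    if (hn == "max" && length(args) > 1L) return(as.call(c(as.symbol("pmax"), args)))
    if (hn == "ceil") return(as.call(c(as.symbol("ceiling"), args)))
    cl
  })
}

# replace rand()/randn() calls: hoisted (one draw per step, reused across
# stages) when `draws` is an environment collector, or rewritten in place
.rewrite_random <- function(e, draws = NULL) {
  draw_call <- function(cl) {
    hn <- as.character(cl[[1]])
    fn <- if (hn == "rand") "runif" else "rnorm"
    args <- as.list(cl)[-1]
    n <- if (length(args) == 1L) args[[1]] else call("*", args[[1]], args[[2]])
    as.call(list(as.symbol(fn), n))
  }
  map_calls(e, function(cl) {
    if (!is.symbol(cl[[1]])) return(cl)
    hn <- as.character(cl[[1]])
    if (!(hn %in% c("rand", "randn"))) return(cl)
    rc <- draw_call(cl)
    if (is.null(draws)) return(rc)
    draws$n <- draws$n + 1L
    sym <- as.symbol(sprintf(".rv%d", draws$n))
    draws$stmts <- c(draws$stmts, sprintf("%s <- %s", as.character(sym),
                                          dsl_deparse(rc)))
    sym
  })
}

.uses_random <- function(e) {
  any(expr_symbols(e) %in% c("rand", "randn"))
}

# prepare one runnable R expression string from a model expression
.compile_expr <- function(s, model, draws = NULL) {
  e <- dsl_parse_expr(s)
  e <- .inline_functions(e, model$functions)
  e <- .rewrite_builtins(e, model$matrix_symbols)
  e <- .rewrite_random(e, draws)
  paste(deparse(e, width.cutoff = 500L), collapse = " ")
}

# topological order of fixed variables by mutual dependency
.fixed_order <- function(model) {
  nms <- names(model$fixed)
  if (length(nms) < 2L) return(nms)
  deps <- lapply(nms, function(nm) {
    intersect(expr_vars(dsl_parse_expr(model$fixed[[nm]])), nms)
  })
  names(deps) <- nms
  out <- character(0)
  while (length(out) < length(nms)) {
    ready <- nms[!nms %in% out &
                 vapply(nms, function(n) all(deps[[n]] %in% out), TRUE)]
    if (length(ready) == 0L) {
      stop("circular dependency among fixed variables", call. = FALSE)
    }
    out <- c(out, ready)
  }
  out
}

.fmt_num <- function(x) {
  if (is.integer(x)) return(as.character(x))
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    sprintf("%.17g", v)
  }, "")
}

.emit_value <- function(v) {
  if (is.matrix(v)) {
    sprintf("matrix(c(%s), nrow = %d, ncol = %d)",
            paste(.fmt_num(as.vector(v)), collapse = ", "), nrow(v), ncol(v))
  } else if (length(v) > 1L) {
    sprintf("c(%s)", paste(.fmt_num(v), collapse = ", "))
  } else {
    .fmt_num(v)
  }
}

# ---- program assembly -------------------------------------------------------

# returns list(preamble, loop, finish_mem, finish_standalone, record)
.generate_program <- function(model, opts) {
  states <- names(model$odes)
  layout <- model$state_layout
  pops <- model$populations

  monitors_val <- Filter(function(m) m$kind == "value", model$monitors)
  mon_names <- vapply(monitors_val, `[[`, "", "name")

  record <- opts$record
  recordable <- c(states, mon_names)
  if (identical(record, "all")) record <- recordable
  unknown <- setdiff(record, recordable)
  if (length(unknown)) {
    stop(sprintf("unknown record name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  t0 <- opts$tspan[[1]]; t1 <- opts$tspan[[2]]
  nsteps <- as.integer(round((t1 - t0) / opts$dt))
  ds <- as.integer(opts$downsample_factor)
  nrec <- nsteps %/% ds + 1L

  tspike_refs <- paste0(".tspike_", names(pops))
  all_exprs <- c(unlist(model$odes), unlist(model$fixed), unlist(model$ics),
                 unlist(lapply(model$conditionals, function(cd) {
                   c(cd$condition, vapply(cd$actions, `[[`, "", "expr"))
                 })),
                 vapply(model$functions, `[[`, "", "body"))
  need_buffers <- any(vapply(all_exprs, function(s) {
    any(expr_symbols(dsl_parse_expr(s)) %in% tspike_refs)
  }, TRUE))

  pre <- character(0)
  add <- function(...) pre <<- c(pre, sprintf(...))

  add("## fixed-step solver program (method: %s, dt = %s ms, tspan = [%s, %s] ms)",
      opts$method, .fmt_num(opts$dt), .fmt_num(t0), .fmt_num(t1))
  add("heaviside <- function(x) as.numeric(x > 0)")
  add("step <- heaviside")
  add("mod <- function(a, b) a %%%% b")
  add("matmul <- function(A, x) as.numeric(A %%*%% x)")
  add("ones <- function(n, m) if (missing(m)) rep(1, n) else matrix(1, n, m)")
  add("dt <- %s", .fmt_num(opts$dt))
  add("set.seed(%d)", as.integer(opts$seed))
  add("## parameters")
  for (nm in names(model$parameters)) {
    add("%s <- %s", nm, .emit_value(model$parameters[[nm]]))
  }
  add("## fixed variables (evaluated once before integration)")
  for (nm in .fixed_order(model)) {
    add("%s <- %s", nm, .compile_expr(model$fixed[[nm]], model))
  }
  if (isTRUE(opts$sparse) && length(model$matrix_symbols)) {
    add("## sparse connectivity storage (numerically identical to dense)")
    for (nm in model$matrix_symbols) {
      add("%s <- Matrix::Matrix(%s, sparse = TRUE)", nm, nm)
    }
  }
  add("t <- %s", .fmt_num(t0))
  add("## initial conditions (scalars broadcast over the population)")
  for (st in states) {
    add("%s <- rep_len(%s, %d)", st,
        .compile_expr(model$ics[[st]], model), layout[[st]]$size)
  }
  add(".nsteps <- %dL; .ds <- %dL; .nrec <- %dL", nsteps, ds, nrec)
  add(".rec_t <- numeric(.nrec); .rec_t[1] <- t")

  mon_exprs <- list()
  for (m in monitors_val) mon_exprs[[m$name]] <- .compile_expr(m$name, model)
  for (nm in record) {
    if (nm %in% states) {
      add(".rec_%s <- matrix(NA_real_, .nrec, %d)", nm, layout[[nm]]$size)
      add(".rec_%s[1, ] <- %s", nm, nm)
    } else {
      add(".mon_%s <- %s", nm, mon_exprs[[nm]])
      add(".rec_%s <- matrix(NA_real_, .nrec, length(.mon_%s))", nm, nm)
      add(".rec_%s[1, ] <- .mon_%s", nm, nm)
    }
  }
  add("## spike bookkeeping (upward threshold crossings at full resolution)")
  for (pn in names(pops)) {
    p <- pops[[pn]]
    add(".prev_%s <- %s", pn, p$voltage)
    add(".spk_t_%s <- numeric(0); .spk_i_%s <- integer(0)", pn, pn)
    if (need_buffers) {
      add(".tspike_%s <- matrix(-Inf, %d, %d)", pn, as.integer(opts$spike_buffer),
          p$size)
    }
  }
  add(".check_state <- function(k) {")
  add("  for (nm in c(%s)) {", paste(sprintf("\"%s\"", states), collapse = ", "))
  add("    v <- get(nm)")
  add("    if (any(!is.finite(v))) stop(sprintf(")
  add("      'non-finite state %%s at step %%d (t = %%g ms)', nm, k, t), call. = FALSE)")
  add("  }")
  add("}")

  # ---- per-step body ----
  loop <- character(0)
  ladd <- function(...) loop <<- c(loop, sprintf(...))

  draws <- new.env(parent = emptyenv()); draws$n <- 0L; draws$stmts <- character(0)
  dexpr <- stats::setNames(
    lapply(states, function(st) .compile_expr(model$odes[[st]], model, draws)),
    states)

  ladd("for (.k in seq_len(.nsteps)) {")
  ladd("  .t0k <- t")
  for (s in draws$stmts) ladd("  %s", s)

  emit_derivs <- function(prefix) {
    for (st in states) ladd("  %s%s <- %s", prefix, st, dexpr[[st]])
  }
  emit_set <- function(fmt_rhs) {
    for (st in states) ladd(paste0("  ", st, " <- ", sprintf(fmt_rhs, st, st)))
  }

  if (opts$method == "euler") {
    emit_derivs(".d_")
    emit_set("%s + dt * .d_%s")
  } else if (opts$method == "rk2") {
    for (st in states) ladd("  .y_%s <- %s", st, st)
    emit_derivs(".k1_")
    ladd("  t <- .t0k + dt/2")
    emit_set(".y_%s + (dt/2) * .k1_%s")
    emit_derivs(".k2_")
    emit_set(".y_%s + dt * .k2_%s")
  } else if (opts$method == "rk4") {
    for (st in states) ladd("  .y_%s <- %s", st, st)
    emit_derivs(".k1_")
    ladd("  t <- .t0k + dt/2")
    emit_set(".y_%s + (dt/2) * .k1_%s")
    emit_derivs(".k2_")
    emit_set(".y_%s + (dt/2) * .k2_%s")
    emit_derivs(".k3_")
    ladd("  t <- .t0k + dt")
    emit_set(".y_%s + dt * .k3_%s")
    emit_derivs(".k4_")
    for (st in states) {
      ladd("  %s <- .y_%s + (dt/6) * (.k1_%s + 2*.k2_%s + 2*.k3_%s + .k4_%s)",
           st, st, st, st, st, st)
    }
  } else {
    stop(sprintf("unsupported fixed-step method '%s'", opts$method), call. = FALSE)
  }
  ladd("  t <- .t0k + dt")

  if (length(model$conditionals)) {
    ladd("  ## conditionals, declaration order; actions see earlier actions' effects")
    for (i in seq_along(model$conditionals)) {
      cd <- model$conditionals[[i]]
      ladd("  .cnd <- %s", .compile_expr(cd$condition, model))
      ladd("  if (any(.cnd)) {")
      ladd("    .m <- which(rep_len(.cnd, %d))", cd$size)
      for (a in cd$actions) {
        ladd("    .av <- rep_len(%s, %d)", .compile_expr(a$expr, model), cd$size)
        ladd("    %s[.m] <- .av[.m]", a$target)
      }
      ladd("  }")
    }
  }

  ladd("  ## spike detection")
  for (pn in names(pops)) {
    p <- pops[[pn]]
    ladd("  .cross <- (.prev_%s < %s) & (%s >= %s)", pn, .fmt_num(p$threshold),
         p$voltage, .fmt_num(p$threshold))
    ladd("  if (any(.cross)) {")
    ladd("    .idx <- which(.cross)")
    ladd("    .spk_t_%s <- c(.spk_t_%s, rep(t, length(.idx)))", pn, pn)
    ladd("    .spk_i_%s <- c(.spk_i_%s, .idx)", pn, pn)
    if (need_buffers) {
      K <- as.integer(opts$spike_buffer)
      if (K == 1L) {
        ladd("    .tspike_%s[1, .idx] <- t", pn)
      } else {
        ladd("    .tspike_%s[, .idx] <- rbind(rep(t, length(.idx)), .tspike_%s[1:%d, .idx, drop = FALSE])",
             pn, pn, K - 1L)
      }
    }
    ladd("  }")
    ladd("  .prev_%s <- %s", pn, p$voltage)
  }

  ladd("  if (.k %%%% .ds == 0L) {")
  ladd("    .ri <- .k %%/%% .ds + 1L")
  ladd("    .rec_t[.ri] <- t")
  for (nm in record) {
    if (nm %in% states) {
      ladd("    .rec_%s[.ri, ] <- %s", nm, nm)
    } else {
      ladd("    .rec_%s[.ri, ] <- %s", nm, mon_exprs[[nm]])
    }
  }
  ladd("    .check_state(.k)")
  ladd("  }")
  ladd("}")

  series_items <- paste(sprintf("`%s` = .rec_%s", record, record), collapse = ", ")
  spikes_items <- paste(vapply(names(pops), function(pn) {
    sprintf("`%s` = split(.spk_t_%s, factor(.spk_i_%s, levels = seq_len(%d)))",
            pn, pn, pn, pops[[pn]]$size)
  }, ""), collapse = ", ")
  finish_mem <- c(
    sprintf(".result <- list(time = .rec_t, series = list(%s), spikes = list(%s))",
            series_items, spikes_items))

  finish_standalone <- c(
    ".args <- commandArgs(trailingOnly = TRUE)",
    ".out <- if (length(.args) >= 1) .args[[1]] else \".\"",
    "dir.create(.out, showWarnings = FALSE, recursive = TRUE)",
    sprintf(".cols <- list(%s)",
            paste(sprintf("`%s` = .rec_%s", record, record), collapse = ", ")),
    ".df <- do.call(cbind, lapply(.cols, function(m) m))",
    "colnames(.df) <- unlist(lapply(names(.cols), function(nm) paste(nm, seq_len(ncol(.cols[[nm]])), sep = '.')))",
    "write.csv(cbind(time = .rec_t, .df), file.path(.out, 'states.csv'), row.names = FALSE)",
    sprintf(".spk <- rbind(%s)", paste(vapply(names(pops), function(pn) {
      sprintf("if (length(.spk_t_%s)) data.frame(population = \"%s\", cell = .spk_i_%s, time = .spk_t_%s) else NULL",
              pn, pn, pn, pn)
    }, ""), collapse = ", ")),
    "if (is.null(.spk)) .spk <- data.frame(population = character(0), cell = integer(0), time = numeric(0))",
    "write.csv(.spk, file.path(.out, 'spikes.csv'), row.names = FALSE)")

  list(preamble = pre, loop = loop, finish_mem = finish_mem,
       finish_standalone = finish_standalone, record = record,
       nsteps = nsteps, nrec = nrec)
}

#' Render standalone solver source
#'
#' Emits the complete fixed-step integration program for a model as a
#' self-contained R script (base R only: no package dependencies). Running
#' the script with `Rscript <file> <outdir>` writes `states.csv` (recorded
#' time series) and `spikes.csv` (detected spike times) into `outdir`. The
#' emitted program is the same one the in-memory integrator evaluates, so
#' its output matches [integrate_model()] exactly.
#'
#' @param model A `flat_model`.
#' @param opts [solver_options()]; must use a fixed-step method.
#' @param file Optional path; when given the source is written there.
#' @return The program text as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
render_solver_source <- function(model, opts = solver_options(), file = NULL) {
  opts <- .check_solver_options(opts)
  if (opts$method == "adaptive") {
    stop("source emission requires a fixed-step method (euler, rk2, rk4)",
         call. = FALSE)
  }
  if (isTRUE(opts$sparse)) {
    stop("standalone source is emitted with dense connectivity; disable the sparse option",
         call. = FALSE)
  }
  prog <- .generate_program(model, opts)
  lines <- c("#!/usr/bin/env Rscript",
             "## standalone solver: usage: Rscript <this file> <output dir>",
             prog$preamble, prog$loop, prog$finish_standalone)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
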