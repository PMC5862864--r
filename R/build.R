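# Model building: standardize -> resolve mechanisms -> qualify names with
# object namespaces -> linker substitution -> one flat ODE system.
#
# Every element of every object receives a fully-qualified name formed by
# joining its object path with '_' (population "pop1" -> "pop1_V"; mechanism
# "Na" in "pop1" -> "pop1_Na_m"; connection mechanism "iGABAa" on I->E ->
# "E_I_iGABAa_s", target first). Linker placeholders ("@current") in host
# equations are replaced by the fold of all mechanism contributions in
# mechanism-list order; no '@' token survives into the flat model.

#' Join an object path and a local name into a fully-qualified name
#'
#' @param object_path Character vector of object tokens, outermost first
#'   (e.g. `c("pop1", "Na")`).
#' @param local_name Local element name.
#' @param registry Optional environment used as a namespace table; reusing a
#'   qualified name for a different (path, local) pair is a collision error.
#' @return The fully-qualified name.
#' @examples
#' qualify(c("pop1", "Na"), "m")  # "pop1_Na_m"
#' @export
qualify <- function(object_path, local_name, registry = NULL) {
  tokens <- c(object_path, local_name)
  if (!all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", tokens))) {
    stop("path and name tokens must be identifiers", call. = FALSE)
  }
  q <- paste(tokens, collapse = "_")
  if (!is.null(registry)) {
    key <- paste(c(object_path, "::", local_name), collapse = "\r")
    prev <- registry$tbl[[q]]
    if (!is.null(prev) && !identical(prev, key)) {
      stop(sprintf(
        "namespace collision: qualified name '%s' claimed by two different local symbols", q),
        call. = FALSE)
    }
    registry$tbl[[q]] <- key
    registry$map[[key]] <- q
  }
  q
}

.new_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$tbl <- list()
  e$map <- list()
  e
}

# rewrite all symbols of `e` through resolver(nm) -> lang | NULL(keep)
.rename_expr <- function(e, resolver) {
  if (is.symbol(e)) {
    r <- resolver(as.character(e))
    return(if (is.null(r)) e else r)
  }
  if (is.call(e)) return(as.call(lapply(as.list(e), .rename_expr, resolver = resolver)))
  e
}

# resolver factory. locals: named chr local -> qualified. host: same for the
# host population (mechanism contexts). specials: named list of language
# objects (size literals, netcon, spike buffers). pre/post: locals of source
# and target populations for <name>_pre / <name>_post references.
.make_resolver <- function(locals, host = NULL, specials = list(),
                           pre = NULL, post = NULL, where = "model") {
  keep <- c(dsl_builtins(), .dsl_implicit(), .dsl_operators())
  locals <- as.list(locals)
  host <- as.list(host)
  pre <- if (is.null(pre)) NULL else as.list(pre)
  post <- if (is.null(post)) NULL else as.list(post)
  function(nm) {
    if (startsWith(nm, .AT_PREFIX)) return(NULL)
    if (!is.null(locals[[nm]])) return(as.symbol(locals[[nm]]))
    if (!is.null(specials[[nm]])) return(specials[[nm]])
    if (!is.null(pre) || !is.null(post)) {
      m <- regmatches(nm, regexec("^(.*)_(pre|post)$", nm))[[1]]
      if (length(m) == 3L) {
        tab <- if (m[[3]] == "pre") pre else post
        if (!is.null(tab[[m[[2]]]])) return(as.symbol(tab[[m[[2]]]]))
        stop(sprintf("%s: '%s' does not name a %ssynaptic element", where, nm,
                     if (m[[3]] == "pre") "pre" else "post"), call. = FALSE)
      }
    }
    if (length(host) && !is.null(host[[nm]])) return(as.symbol(host[[nm]]))
    if (nm %in% keep) return(NULL)
    stop(sprintf("%s: unresolved identifier '%s'", where, nm), call. = FALSE)
  }
}

# local name -> qualified map for one equation set at `path`
.locals_map <- function(eq, path, registry) {
  locals <- c(names(eq$parameters), names(eq$fixed), names(eq$functions),
              names(eq$odes))
  stats::setNames(vapply(locals, function(nm) qualify(path, nm, registry), ""),
                  locals)
}

# qualify a full equation set through `resolver`, returning flat-field lists
.qualify_set <- function(eq, locals, resolver, where) {
  locals <- as.list(locals)
  rn <- function(s) dsl_deparse(.rename_expr(dsl_parse_expr(s), resolver))
  out <- list(parameters = list(), fixed = list(), functions = list(),
              odes = list(), ics = list(), conditionals = list(),
              monitors = list())
  for (nm in names(eq$parameters)) out$parameters[[locals[[nm]]]] <- eq$parameters[[nm]]
  for (nm in names(eq$fixed)) out$fixed[[locals[[nm]]]] <- rn(eq$fixed[[nm]])
  for (nm in names(eq$functions)) {
    f <- eq$functions[[nm]]
    # formals resolving to object symbols become those qualified names;
    # others remain genuinely bound local arguments
    qargs <- vapply(f$args, function(a) {
      r <- tryCatch(resolver(a), error = function(...) NULL)
      if (is.null(r)) a else dsl_deparse(r)
    }, "")
    bound <- f$args[f$args == qargs]
    fres <- function(s) {
      if (s %in% bound) return(NULL)
      resolver(s)
    }
    body <- dsl_deparse(.rename_expr(dsl_parse_expr(f$body), fres))
    out$functions[[locals[[nm]]]] <- list(args = unname(qargs), body = body)
  }
  for (nm in names(eq$odes)) out$odes[[locals[[nm]]]] <- rn(eq$odes[[nm]])
  for (nm in names(eq$ics)) out$ics[[locals[[nm]]]] <- rn(eq$ics[[nm]])
  for (cd in eq$conditionals) {
    out$conditionals[[length(out$conditionals) + 1L]] <- list(
      condition = rn(cd$condition),
      actions = lapply(cd$actions, function(a) {
        tq <- locals[[a$target]]
        if (is.null(tq)) {
          stop(sprintf("%s: conditional action target '%s' is not local", where, a$target),
               call. = FALSE)
        }
        list(target = tq, expr = rn(a$expr))
      }))
  }
  for (mn in eq$monitors) {
    out$monitors[[length(out$monitors) + 1L]] <-
      list(kind = mn$kind, name = locals[[mn$name]], threshold = mn$threshold)
  }
  out
}

# resolve the mechanism equation set for `mname`: inline definitions in the
# specification shadow same-named library files
.resolve_mechanism <- function(mname, spec, paths) {
  if (!is.null(spec$mechanisms[[mname]])) return(spec$mechanisms[[mname]])
  f <- find_object(mname, paths)
  if (is.null(f)) {
    stop(sprintf("mechanism '%s' not found (searched inline mechanisms and %d path(s))",
                 mname, length(paths)), call. = FALSE)
  }
  parse_mechanism_file(f)
}

# apply parameter overrides to a mechanism's defaults; returns updated eq
.apply_overrides <- function(eq, overrides) {
  for (nm in intersect(names(overrides), names(eq$parameters))) {
    eq$parameters[[nm]] <- overrides[[nm]]
  }
  eq
}

# fold linker contributions (list of list(op, payload_sym)) into one
# language object; zero contributions -> 0
.link_fold <- function(contribs, linker_name) {
  acc <- NULL
  n_set <- sum(vapply(contribs, function(x) x$op == "=", TRUE))
  if (n_set > 1L) {
    stop(sprintf("linker '@%s': '=' used by more than one mechanism (ambiguous overwrite)",
                 linker_name), call. = FALSE)
  }
  if (n_set == 1L && length(contribs) > 1L) {
    stop(sprintf("linker '@%s': '=' cannot be combined with compound contributions",
                 linker_name), call. = FALSE)
  }
  for (cb in contribs) {
    p <- cb$payload_sym
    acc <- switch(cb$op,
      "+=" = if (is.null(acc)) p else call("+", acc, p),
      "-=" = if (is.null(acc)) call("-", p) else call("-", acc, p),
      "*=" = if (is.null(acc)) p else call("*", acc, p),
      "="  = p,
      stop("unknown linker operator ", cb$op, call. = FALSE))
  }
  if (is.null(acc)) acc <- 0
  acc
}

#' Link mechanism contributions into host equations
#'
#' Performs linker substitution for a single population: each `@name`
#' placeholder in the host equations is replaced by the fold of the
#' mechanisms' linker statements in mechanism order (`+=` adds, `-=`
#' subtracts, `*=` multiplies, `=` overwrites and must be unique), after
#' namespace qualification. A placeholder with no contributions becomes 0; a
#' contribution whose linker never appears in the host equations raises a
#' warning.
#'
#' @param population_eqns Host `equation_set` (or equation text).
#' @param mechanism_sets Named list of mechanism `equation_set`s (or texts),
#'   in insertion order.
#' @param population_name Namespace token for the host (default `"pop1"`).
#' @param size Population size.
#' @return The merged, fully-qualified `equation_set` for this population.
#' @examples
#' merged <- link("dV/dt = @current; V(0) = 0",
#'                list(Na = "gNa = 1\nINa(V) = -gNa*(V - 50)\n@current += INa",
#'                     K  = "gK = 1\nIK(V) = -gK*(V + 77)\n@current += IK"))
#' merged$odes[["pop1_V"]]
#' @export
link <- function(population_eqns, mechanism_sets = list(),
                 population_name = "pop1", size = 1L) {
  mechs <- lapply(mechanism_sets, function(m) {
    if (is.character(m)) parse_equations(m, context = "mechanism") else m
  })
  spec <- specification(
    populations = list(population(population_name, size, equations = population_eqns,
                                  mechanism_list = names(mechs))),
    mechanisms = mechs)
  model <- build_model(spec)
  eq <- new_equation_set(population_name)
  eq$parameters <- model$parameters
  eq$fixed <- model$fixed
  eq$functions <- model$functions
  eq$odes <- model$odes
  eq$ics <- model$ics
  eq$conditionals <- model$conditionals
  eq$monitors <- model$monitors
  eq
}

#' Build a flat model from a specification
#'
#' Standardizes the specification, resolves every mechanism (inline
#' definitions first, then the mechanism search paths, then the packaged
#' library), applies object namespaces, performs linker substitution, and
#' returns a single flat ODE system ready for integration.
#'
#' Parameter precedence, highest first: population/connection `parameters`
#' overrides, then inline mechanism definitions, then library file defaults.
#' Scalar parameters broadcast over the population; arrays must have one
#' element per unit. Connection mechanisms see the reserved symbols
#' `netcon` (connectivity matrix, target x source, default all-to-all
#' ones), `<state>_pre`/`<state>_post` (source/target population elements),
#' `Npre`/`Npost` (sizes), and `tspike_pre`/`tspike_post` (spike-time
#' buffers, newest first). Connection-mechanism ODE states are per source
#' cell.
#'
#' @param spec A `specification` (or anything [standardize()] accepts).
#' @param mech_paths Extra directories searched for mechanism files before
#'   the packaged library.
#' @return A `flat_model` with fields `parameters`, `fixed`, `functions`,
#'   `odes`, `ics`, `conditionals`, `monitors`, `state_layout`,
#'   `namespace_table`, `populations`.
#' @examples
#' m <- build_model("dx/dt = -x; x(0) = 1")
#' names(m$odes)
#' @export
build_model <- function(spec, mech_paths = character(0)) {
  spec <- standardize(spec)
  paths <- library_paths(mech_paths)
  registry <- .new_registry()

  model <- structure(list(
    parameters = list(), fixed = list(), functions = list(),
    odes = list(), ics = list(), conditionals = list(), monitors = list(),
    state_layout = list(), namespace_table = NULL,
    populations = list(), matrix_symbols = character(0),
    buffer_k = 1L
  ), class = "flat_model")

  pop_names <- vapply(spec$populations, `[[`, "", "name")

  # ---- first pass: resolve equation sets and mechanism sets ----------------
  pops <- list()
  for (p in spec$populations) {
    eq <- p$equations
    overrides <- p$parameters
    if (is.character(eq)) {
      token <- length(eq) == 1L && grepl("^[A-Za-z_][A-Za-z0-9_]*$", trimws(eq))
      if (token && !is.null(find_object(trimws(eq), paths))) {
        eq <- instantiate(trimws(eq), p$size, paths = paths)
      } else {
        eq <- parse_equations(eq, name = p$name)
      }
    }
    if (!inherits(eq, "equation_set")) {
      stop(sprintf("population '%s' has no usable equations", p$name), call. = FALSE)
    }
    if (length(eq$odes) == 0L) {
      stop(sprintf("population '%s' declares no ODE states", p$name), call. = FALSE)
    }
    mech_list <- union(eq$mechanism_list, p$mechanism_list)
    mechs <- lapply(stats::setNames(mech_list, mech_list),
                    .resolve_mechanism, spec = spec, paths = paths)
    mechs <- lapply(mechs, .apply_overrides, overrides = overrides)
    eq <- .apply_overrides(eq, overrides)
    # every override must land somewhere
    known <- unique(c(names(eq$parameters),
                      unlist(lapply(mechs, function(m) names(m$parameters)))))
    unknown <- setdiff(names(overrides), known)
    if (length(unknown)) {
      stop(sprintf("population '%s': unknown parameter(s) %s", p$name,
                   paste(sprintf("'%s'", unknown), collapse = ", ")), call. = FALSE)
    }
    # array parameters must match the population size
    for (nm in names(eq$parameters)) {
      v <- eq$parameters[[nm]]
      if (!is.matrix(v) && !(length(v) %in% c(1L, p$size))) {
        stop(sprintf("population '%s': parameter '%s' has length %d (size is %d)",
                     p$name, nm, length(v), p$size), call. = FALSE)
      }
    }
    pops[[p$name]] <- list(spec = p, eq = eq, mechs = mechs)
  }

  cons <- list()
  for (i in seq_along(spec$connections)) {
    cn <- spec$connections[[i]]
    mech_list <- cn$mechanism_list
    if (length(mech_list) == 0L) next
    overrides <- cn$parameters
    mechs <- lapply(stats::setNames(mech_list, mech_list),
                    .resolve_mechanism, spec = spec, paths = paths)
    mechs <- lapply(mechs, .apply_overrides, overrides = overrides)
    known <- unique(c("netcon", unlist(lapply(mechs, function(m) names(m$parameters)))))
    unknown <- setdiff(names(overrides), known)
    if (length(unknown)) {
      stop(sprintf("connection %s->%s: unknown parameter(s) %s", cn$source, cn$target,
                   paste(sprintf("'%s'", unknown), collapse = ", ")), call. = FALSE)
    }
    cons[[length(cons) + 1L]] <- list(spec = cn, mechs = mechs)
  }

  # ---- second pass: qualification ------------------------------------------
  qualified <- list()   # per object, in merge order
  linker_contribs <- list()  # pop name -> linker name -> list of contribs
  pop_locals <- list()

  for (pn in names(pops)) {
    P <- pops[[pn]]
    size <- P$spec$size
    locals <- .locals_map(P$eq, pn, registry)
    pop_locals[[pn]] <- locals
    res <- .make_resolver(locals, specials = list(Npop = size),
                          where = sprintf("population '%s'", pn))
    qualified[[length(qualified) + 1L]] <- list(
      kind = "population", pop = pn, size = size,
      set = .qualify_set(P$eq, locals, res, sprintf("population '%s'", pn)),
      raw = P$eq)
  }

  add_contrib <- function(pop, mech_ns, mech_eq, mech_locals) {
    for (lk in mech_eq$linkers) {
      pq <- mech_locals[[lk$payload]]
      linker_contribs[[pop]][[lk$name]] <<- c(
        linker_contribs[[pop]][[lk$name]] %||% list(),
        list(list(op = lk$op, payload_sym = as.symbol(pq), ns = mech_ns)))
    }
  }

  for (pn in names(pops)) {
    P <- pops[[pn]]
    for (mn in names(P$mechs)) {
      meq <- P$mechs[[mn]]
      path <- c(pn, mn)
      locals <- .locals_map(meq, path, registry)
      res <- .make_resolver(locals, host = pop_locals[[pn]],
                            specials = list(Npop = P$spec$size,
                                            tspike_post = as.symbol(paste0(".tspike_", pn)),
                                            tspike_pre = as.symbol(paste0(".tspike_", pn))),
                            where = sprintf("mechanism '%s' in '%s'", mn, pn))
      qualified[[length(qualified) + 1L]] <- list(
        kind = "intrinsic", pop = pn, size = P$spec$size,
        set = .qualify_set(meq, locals, res, sprintf("mechanism '%s' in '%s'", mn, pn)),
        raw = meq)
      add_contrib(pn, paste(path, collapse = "_"), meq, locals)
    }
  }

  for (C in cons) {
    cn <- C$spec
    src <- cn$source; tgt <- cn$target
    ssize <- pops[[src]]$spec$size
    tsize <- pops[[tgt]]$spec$size
    for (mn in names(C$mechs)) {
      meq <- C$mechs[[mn]]
      path <- c(tgt, src, mn)
      ns <- paste(path, collapse = "_")
      locals <- .locals_map(meq, path, registry)
      # netcon: parameter override or default all-to-all ones
      ncq <- qualify(path, "netcon", registry)
      locals[["netcon"]] <- ncq
      if (!is.null(cn$parameters$netcon)) {
        ncv <- cn$parameters$netcon
        if (!is.matrix(ncv) || !all(dim(ncv) == c(tsize, ssize))) {
          stop(sprintf(
            "connection %s->%s: netcon must be a %d x %d matrix (target x source)",
            src, tgt, tsize, ssize), call. = FALSE)
        }
        model$parameters[[ncq]] <- ncv
      } else {
        model$fixed[[ncq]] <- sprintf("ones(%d, %d)", tsize, ssize)
      }
      model$matrix_symbols <- c(model$matrix_symbols, ncq)
      res <- .make_resolver(
        locals,
        specials = list(Npre = ssize, Npost = tsize,
                        tspike_pre = as.symbol(paste0(".tspike_", src)),
                        tspike_post = as.symbol(paste0(".tspike_", tgt))),
        pre = pop_locals[[src]], post = pop_locals[[tgt]],
        where = sprintf("connection mechanism '%s' on %s->%s", mn, src, tgt))
      qualified[[length(qualified) + 1L]] <- list(
        kind = "connection", pop = tgt, size = ssize,  # conn states are per source cell
        set = .qualify_set(meq, locals, res,
                           sprintf("connection mechanism '%s' on %s->%s", mn, src, tgt)),
        raw = meq)
      add_contrib(tgt, ns, meq, locals)
    }
  }

  # ---- third pass: merge + linker substitution -----------------------------
  for (q in qualified) {
    s <- q$set
    model$parameters <- c(model$parameters, s$parameters)
    model$fixed <- c(model$fixed, s$fixed)
    model$functions <- c(model$functions, s$functions)
    model$odes <- c(model$odes, s$odes)
    model$ics <- c(model$ics, s$ics)
    for (cd in s$conditionals) {
      cd$population <- q$pop
      cd$size <- q$size
      model$conditionals[[length(model$conditionals) + 1L]] <- cd
    }
    for (mn in s$monitors) {
      mn$population <- q$pop
      model$monitors[[length(model$monitors) + 1L]] <- mn
    }
    for (st in names(s$odes)) {
      model$state_layout[[st]] <- list(population = q$pop, size = q$size)
    }
    if (q$kind == "population") {
      states <- names(s$odes)
      model$populations[[q$pop]] <- list(
        size = q$size, voltage = states[[1]], threshold = 0)
    }
  }

  # spike-monitor directives set the population's detection variable/threshold
  for (mn in model$monitors) {
    if (mn$kind == "spikes") {
      pinfo <- model$populations[[mn$population]]
      if (!is.null(pinfo) && mn$name %in% names(model$odes)) {
        model$populations[[mn$population]]$voltage <- mn$name
        model$populations[[mn$population]]$threshold <- mn$threshold
      }
    }
  }

  # linker substitution into host population expressions
  used <- character(0)
  for (pn in names(pops)) {
    contribs <- linker_contribs[[pn]] %||% list()
    subst <- function(s) {
      e <- dsl_parse_expr(s)
      syms <- expr_symbols(e)
      at <- syms[startsWith(syms, .AT_PREFIX)]
      if (length(at) == 0L) return(s)
      map <- list()
      for (a in at) {
        lname <- substring(a, nchar(.AT_PREFIX) + 1L)
        used <<- c(used, paste0(pn, "@", lname))
        map[[a]] <- .link_fold(contribs[[lname]] %||% list(), lname)
      }
      dsl_deparse(subst_symbols(e, map))
    }
    plocals <- pop_locals[[pn]]
    for (nm in unname(plocals)) {
      if (!is.null(model$odes[[nm]])) model$odes[[nm]] <- subst(model$odes[[nm]])
      if (!is.null(model$fixed[[nm]])) model$fixed[[nm]] <- subst(model$fixed[[nm]])
      if (!is.null(model$functions[[nm]])) {
        model$functions[[nm]]$body <- subst(model$functions[[nm]]$body)
      }
      if (!is.null(model$ics[[nm]])) model$ics[[nm]] <- subst(model$ics[[nm]])
    }
    for (lname in names(contribs)) {
      if (!(paste0(pn, "@", lname) %in% used)) {
        warning(sprintf(
          "population '%s': linker '@%s' has contributions but never appears in host equations",
          pn, lname), call. = FALSE)
      }
    }
  }

  model$namespace_table <- registry$map
  .validate_flat_model(model)
}

# final structural validation of a flat model
.validate_flat_model <- function(model) {
  known <- c(names(model$parameters), names(model$fixed),
             names(model$functions), names(model$odes),
             dsl_builtins(), .dsl_implicit(),
             paste0(".tspike_", names(model$populations)))
  dup <- known[duplicated(known)]
  if (length(dup)) {
    stop(sprintf("flat model has duplicate qualified names: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  chk <- function(s, where, extra = character(0)) {
    if (grepl("@", s, fixed = TRUE)) {
      stop(sprintf("%s: linker token survived flattening in \"%s\"", where, s),
           call. = FALSE)
    }
    e <- dsl_parse_expr(s)
    bad <- setdiff(expr_symbols(e), c(known, extra, .dsl_operators()))
    bad <- bad[!startsWith(bad, .AT_PREFIX)]
    if (length(bad)) {
      stop(sprintf("%s: unresolved identifier(s) %s in \"%s\"", where,
                   paste(sprintf("'%s'", bad), collapse = ", "), s), call. = FALSE)
    }
  }
  for (nm in names(model$fixed)) {
    chk(model$fixed[[nm]], sprintf("fixed variable '%s'", nm))
    e <- dsl_parse_expr(model$fixed[[nm]])
    st <- intersect(expr_vars(e), names(model$odes))
    if (length(st)) {
      stop(sprintf(
        "fixed variable '%s' references state(s) %s; fixed variables are evaluated once before integration",
        nm, paste(st, collapse = ", ")), call. = FALSE)
    }
  }
  for (nm in names(model$functions)) {
    chk(model$functions[[nm]]$body, sprintf("function '%s'", nm),
        extra = model$functions[[nm]]$args)
  }
  for (nm in names(model$odes)) chk(model$odes[[nm]], sprintf("ODE '%s'", nm))
  for (nm in names(model$ics)) chk(model$ics[[nm]], sprintf("IC '%s'", nm))
  for (cd in model$conditionals) {
    chk(cd$condition, "conditional")
    for (a in cd$actions) chk(a$expr, "conditional action")
  }
  model
}

#' @export
print.flat_model <- function(x, ...) {
  ns <- sum(vapply(x$state_layout, function(s) s$size, 0))
  cat(sprintf("<flat_model: %d state variable(s), %d unit(s) total>\n",
              length(x$odes), ns))
  for (pn in names(x$populations)) {
    p <- x$populations[[pn]]
    cat(sprintf("  population %s (n=%d, spikes on %s >= %g)\n",
                pn, p$size, p$voltage, p$threshold))
  }
  cat(sprintf("  states: %s\n", paste(names(x$odes), collapse = ", ")))
  if (length(x$conditionals)) cat(sprintf("  conditionals: %d\n", length(x$conditionals)))
  invisible(x)
}
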