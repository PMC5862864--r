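# Equation DSL: parsing of plain-text model equations into structured
# equation sets.
#
# The dialect covers: parameter assignments (numeric scalars or bracketed
# arrays), fixed variables (expressions evaluated once before integration),
# functions of declared arguments, ODEs ("dX/dt = ..." or "X' = ..."),
# initial conditions ("X(0) = ..."), conditional updates
# ("if(cond)(action1; action2)"), linker statements ("@current += INa"),
# and monitor directives ("monitor f", "monitor V.spikes(0)").
# Statements are delimited by newlines or top-level semicolons; '%' and '#'
# start comments.

# internal marker used so '@linker' tokens survive R's parser
.AT_PREFIX <- ".at_"

#' Builtin functions available inside model expressions
#'
#' Whitelisted callables usable in any model expression, alongside the
#' arithmetic, comparison and logical operators. `rand(n)`/`rand(1,n)` and
#' `randn(n)`/`randn(1,n)` draw uniform/normal variates from the solver's
#' seeded stream (population-sized draws; inside right-hand sides they are
#' drawn once per integration step and reused across Runge-Kutta stages).
#' `heaviside(x)` is the unit step (1 for x > 0, else 0), `mod(a,b)` the
#' remainder, `matmul(A, x)` a matrix-vector product (used for connectivity
#' matrices). The time variable `t` (ms) and the step `dt` (ms) are always
#' in scope.
#'
#' @return Character vector of builtin function names.
#' @export
dsl_builtins <- function() {
  c("exp", "log", "log10", "sqrt", "sin", "cos", "tan", "atan", "tanh",
    "abs", "min", "max", "floor", "ceil", "sign", "heaviside", "step",
    "mod", "rand", "randn", "matmul", "ones", "sum", "mean")
}

# symbols that are implicitly in scope everywhere
.dsl_implicit <- function() c("t", "dt", "pi")

# reserved symbols resolved at model-build time (mechanism context)
.dsl_reserved <- function() {
  c("Npop", "Npre", "Npost", "netcon", "tspike_pre", "tspike_post")
}

.dsl_operators <- function() {
  c("+", "-", "*", "/", "^", "(", ">", "<", ">=", "<=", "==", "!=",
    "&", "|", "!")
}

# arity table for builtins: c(min, max)
.dsl_arity <- function() {
  list(exp = c(1, 1), log = c(1, 2), log10 = c(1, 1), sqrt = c(1, 1),
       sin = c(1, 1), cos = c(1, 1), tan = c(1, 1), atan = c(1, 1),
       tanh = c(1, 1), abs = c(1, 1), min = c(1, Inf), max = c(1, Inf),
       floor = c(1, 1), ceil = c(1, 1), sign = c(1, 1),
       heaviside = c(1, 1), step = c(1, 1), mod = c(2, 2),
       rand = c(1, 2), randn = c(1, 2), matmul = c(2, 2), ones = c(1, 2),
       sum = c(1, 1), mean = c(1, 1))
}

dsl_error <- function(msg, line = NULL, stmt = NULL) {
  loc <- if (!is.null(line)) sprintf(" (line %d)", line) else ""
  txt <- if (!is.null(stmt)) sprintf(" in \"%s\"", trimws(stmt)) else ""
  stop(sprintf("equation syntax error%s: %s%s", loc, msg, txt), call. = FALSE)
}

# strip comments, normalize to single string
.strip_comments <- function(text) {
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("[%#].*$", "", lines)
}

# split lines into statements at top-level semicolons, tracking line numbers
.split_statements <- function(lines) {
  out <- list()
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    depth <- 0L
    start <- 1L
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_along(chars)) {
      ch <- chars[[i]]
      if (ch == "(" || ch == "[") depth <- depth + 1L
      else if (ch == ")" || ch == "]") depth <- depth - 1L
      else if (ch == ";" && depth == 0L) {
        out[[length(out) + 1L]] <- list(stmt = substr(s, start, i - 1L), line = ln)
        start <- i + 1L
      }
    }
    out[[length(out) + 1L]] <- list(stmt = substr(s, start, nchar(s)), line = ln)
  }
  out <- Filter(function(x) nzchar(trimws(x$stmt)), out)
  lapply(out, function(x) { x$stmt <- trimws(x$stmt); x })
}

# parse one expression string to an R language object; '@name' tokens are
# rewritten to '.at_name' symbols so R's parser accepts them
dsl_parse_expr <- function(s, line = NULL) {
  s2 <- gsub("@([A-Za-z_][A-Za-z0-9_]*)", paste0(.AT_PREFIX, "\\1"), s)
  e <- tryCatch(str2lang(s2), error = function(err) {
    m <- conditionMessage(err)
    m <- sub("^<text>:", "position ", m)
    dsl_error(sprintf("cannot parse expression: %s", m), line, s)
  })
  if (is.character(e)) dsl_error("string literals are not allowed", line, s)
  e
}

# deparse a language object back to the DSL surface form
dsl_deparse <- function(e) {
  s <- paste(deparse(e, width.cutoff = 500L), collapse = " ")
  gsub(paste0("\\", .AT_PREFIX, "([A-Za-z0-9_]+)"), "@\\1", s)
}

# all symbol names appearing in an expression (as variables or call heads)
expr_symbols <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e), expr_symbols))))
  character(0)
}

# names used as plain variables (not call heads)
expr_vars <- function(e) unique(all.vars(e))

# walk an expression applying `fn` to each call node (bottom-up)
map_calls <- function(e, fn) {
  if (is.call(e)) {
    e <- as.call(lapply(as.list(e), map_calls, fn = fn))
    e <- fn(e)
  }
  e
}

# substitute symbols by a named list of language objects / symbols
subst_symbols <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!is.null(map[[nm]])) return(map[[nm]])
    return(e)
  }
  if (is.call(e)) {
    return(as.call(lapply(as.list(e), subst_symbols, map = map)))
  }
  e
}

# is the rhs a plain numeric value (scalar or bracketed array)?
.parse_numeric_rhs <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[", s)) {
    inner <- sub("^\\[", "", sub("\\]$", "", s))
    parts <- strsplit(inner, "[,[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) && !anyNA(vals)) return(vals)
    return(NULL)
  }
  val <- suppressWarnings(as.numeric(s))
  if (!is.na(val)) return(val)
  # signed scientific etc. already covered by as.numeric; allow simple
  # arithmetic of literals (e.g. "1/3") by safe evaluation
  e <- tryCatch(str2lang(s), error = function(...) NULL)
  if (!is.null(e) && length(all.vars(e)) == 0L &&
      all(expr_symbols(e) %in% c("+", "-", "*", "/", "^", "(", "c"))) {
    v <- tryCatch(eval(e, baseenv()), error = function(...) NULL)
    if (is.numeric(v)) return(v)
  }
  NULL
}

.match_balanced <- function(s, open_at) {
  # returns index of the ')' matching the '(' at position open_at
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq(open_at, length(chars))) {
    if (chars[[i]] == "(") depth <- depth + 1L
    if (chars[[i]] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  NA_integer_
}

#' Construct an empty equation set
#'
#' @param name Optional object name (mechanisms take theirs from the file
#'   stem).
#' @return An object of class `equation_set`.
#' @keywords internal
new_equation_set <- function(name = NULL) {
  structure(list(
    name = name,
    parameters = list(),       # name -> numeric scalar or array
    fixed = list(),            # name -> expression string
    functions = list(),        # name -> list(args = chr, body = chr)
    odes = list(),             # state -> rhs string
    ics = list(),              # state -> expression string
    conditionals = list(),     # list(condition = chr, actions = list(list(target, expr)))
    linkers = list(),          # list(name, op, payload)
    monitors = list(),         # list(kind = "value"|"spikes", name, threshold)
    mechanism_list = character(0)
  ), class = "equation_set")
}

#' Parse model equations
#'
#' Parses equation text (a single string or a character vector of
#' statements) into a structured equation set. Statements may appear in any
#' order; declaration order is preserved within each category (functions,
#' conditionals, linkers) because it is semantically meaningful: functions
#' evaluate in declaration order and conditionals are applied in declaration
#' order after every integration step.
#'
#' @param text Character vector with the model equations. `%` and `#` start
#'   comments; `;` and newlines both delimit statements.
#' @param name Optional object name stored on the result.
#' @param context `"population"` (default) validates strictly;
#'   `"mechanism"` additionally admits the reserved mechanism symbols
#'   (`Npop`, `Npre`, `Npost`, `netcon`, `tspike_pre`, `tspike_post`, and
#'   `<state>_pre`/`<state>_post` references to the source/target
#'   populations, resolved at build time).
#' @return An object of class `equation_set` with fields `parameters`,
#'   `fixed`, `functions`, `odes`, `ics`, `conditionals`, `linkers`,
#'   `monitors`.
#' @examples
#' eqs <- parse_equations("dx/dt = -x; x(0) = 1")
#' names(eqs$odes)
#' @export
parse_equations <- function(text, name = NULL, context = c("population", "mechanism")) {
  context <- match.arg(context)
  lines <- .strip_comments(text)
  stmts <- .split_statements(lines)
  if (length(stmts) == 0L) {
    stop("no statements found after comment stripping", call. = FALSE)
  }
  eq <- new_equation_set(name)

  declare <- function(nm, what, line) {
    kinds <- c(parameter = nm %in% names(eq$parameters),
               `fixed variable` = nm %in% names(eq$fixed),
               `function` = nm %in% names(eq$functions),
               state = nm %in% names(eq$odes))
    if (any(kinds)) {
      dsl_error(sprintf("name '%s' already declared as a %s; cannot redeclare as a %s",
                        nm, names(kinds)[kinds][1], what), line)
    }
  }

  for (st in stmts) {
    s <- st$stmt
    ln <- st$line

    # monitor directive
    if (grepl("^monitor\\s+", s)) {
      body <- trimws(sub("^monitor\\s+", "", s))
      msp <- regmatches(body, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)\\.spikes\\s*\\((.*)\\)$", body))[[1]]
      if (length(msp) == 3L) {
        thr <- .parse_numeric_rhs(msp[[3]])
        if (is.null(thr)) dsl_error("spike monitor threshold must be numeric", ln, s)
        eq$monitors[[length(eq$monitors) + 1L]] <-
          list(kind = "spikes", name = msp[[2]], threshold = thr)
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", body)) {
        eq$monitors[[length(eq$monitors) + 1L]] <-
          list(kind = "value", name = body, threshold = NULL)
      } else {
        dsl_error("malformed monitor directive", ln, s)
      }
      next
    }

    # mechanism list directive (population files)
    if (grepl("^mechanism(_list|s)?\\b", s)) {
      body <- sub("^mechanism(_list|s)?\\s*[:=]?\\s*", "", s)
      body <- gsub("[{}]", "", body)
      mechs <- trimws(strsplit(body, ",")[[1]])
      mechs <- mechs[nzchar(mechs)]
      if (!all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", mechs))) {
        dsl_error("malformed mechanism list", ln, s)
      }
      eq$mechanism_list <- c(eq$mechanism_list, mechs)
      next
    }

    # linker statement: @name op payload
    mlk <- regmatches(s, regexec(
      "^@([A-Za-z_][A-Za-z0-9_]*)\\s*(\\+=|-=|\\*=|=)\\s*([A-Za-z_][A-Za-z0-9_]*)$", s))[[1]]
    if (length(mlk) == 4L) {
      eq$linkers[[length(eq$linkers) + 1L]] <-
        list(name = mlk[[2]], op = mlk[[3]], payload = mlk[[4]])
      next
    }
    if (grepl("^@", s)) dsl_error("malformed linker statement", ln, s)

    # conditional: if(cond)(actions)
    if (grepl("^if\\s*\\(", s)) {
      o1 <- regexpr("\\(", s)
      c1 <- .match_balanced(s, o1)
      if (is.na(c1)) dsl_error("unbalanced parentheses in conditional", ln, s)
      rest <- trimws(substr(s, c1 + 1L, nchar(s)))
      if (!grepl("^\\(", rest)) dsl_error("conditional must be if(condition)(actions)", ln, s)
      c2 <- .match_balanced(rest, 1L)
      if (is.na(c2) || nzchar(trimws(substr(rest, c2 + 1L, nchar(rest))))) {
        dsl_error("unbalanced parentheses in conditional actions", ln, s)
      }
      cond <- substr(s, o1 + 1L, c1 - 1L)
      acts <- substr(rest, 2L, c2 - 1L)
      cond_e <- dsl_parse_expr(cond, ln)
      action_stmts <- .split_statements(acts)
      actions <- lapply(action_stmts, function(a) {
        ma <- regmatches(a$stmt, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", a$stmt))[[1]]
        if (length(ma) != 3L || grepl("^(=|[<>!+*/-]=)", sub("^[A-Za-z_][A-Za-z0-9_]*\\s*", "", a$stmt))) {
          # guard against comparison being mistaken for assignment
        }
        if (length(ma) != 3L) dsl_error("conditional action must be 'name = expr'", ln, a$stmt)
        list(target = ma[[2]], expr = dsl_deparse(dsl_parse_expr(ma[[3]], ln)))
      })
      if (length(actions) == 0L) dsl_error("conditional has no actions", ln, s)
      eq$conditionals[[length(eq$conditionals) + 1L]] <-
        list(condition = dsl_deparse(cond_e), actions = actions)
      next
    }

    # ODE: dX/dt = rhs  |  d(X)/dt = rhs
    mode_ <- regmatches(s, regexec(
      "^d\\(?([A-Za-z_][A-Za-z0-9_]*)\\)?\\s*/\\s*dt\\s*=\\s*(.+)$", s))[[1]]
    if (length(mode_) == 0L) {
      # X' = rhs
      mode_ <- regmatches(s, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)'\\s*=\\s*(.+)$", s))[[1]]
    }
    if (length(mode_) == 3L) {
      nm <- mode_[[2]]
      declare(nm, "state", ln)
      eq$odes[[nm]] <- dsl_deparse(dsl_parse_expr(mode_[[3]], ln))
      next
    }

    # IC: X(0) = rhs
    mic <- regmatches(s, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*\\(\\s*0\\s*\\)\\s*=\\s*(.+)$", s))[[1]]
    if (length(mic) == 3L) {
      eq$ics[[mic[[2]]]] <- dsl_deparse(dsl_parse_expr(mic[[3]], ln))
      next
    }

    # function definition: f(a,b) = rhs
    mfn <- regmatches(s, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*\\(([^)]*)\\)\\s*=\\s*(.+)$", s))[[1]]
    if (length(mfn) == 4L) {
      args <- trimws(strsplit(mfn[[3]], ",")[[1]])
      args <- args[nzchar(args)]
      if (!all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", args))) {
        dsl_error("function arguments must be identifiers", ln, s)
      }
      nm <- mfn[[2]]
      declare(nm, "function", ln)
      eq$functions[[nm]] <- list(args = args,
                                 body = dsl_deparse(dsl_parse_expr(mfn[[4]], ln)))
      next
    }

    # parameter or fixed variable: name = rhs
    masn <- regmatches(s, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", s))[[1]]
    if (length(masn) == 3L) {
      nm <- masn[[2]]
      val <- .parse_numeric_rhs(masn[[3]])
      if (!is.null(val)) {
        declare(nm, "parameter", ln)
        eq$parameters[[nm]] <- val
      } else {
        declare(nm, "fixed variable", ln)
        eq$fixed[[nm]] <- dsl_deparse(dsl_parse_expr(masn[[3]], ln))
      }
      next
    }

    dsl_error("unrecognized statement", ln, s)
  }

  validate_equation_set(eq, context = context)
}

#' Validate an equation set against its invariants
#'
#' Checks that every initial condition names a known state, fills missing
#' initial conditions with 0, verifies that no name is declared in more than
#' one category, and validates every expression against the declared scope
#' plus the builtin whitelist.
#'
#' @param eq An `equation_set`.
#' @param context `"population"` or `"mechanism"` (see [parse_equations()]).
#' @return The validated (and possibly IC-defaulted) `equation_set`.
#' @export
validate_equation_set <- function(eq, context = c("population", "mechanism")) {
  context <- match.arg(context)
  states <- names(eq$odes)

  extra_ics <- setdiff(names(eq$ics), states)
  if (length(extra_ics)) {
    stop(sprintf("initial condition for undeclared state(s): %s",
                 paste(extra_ics, collapse = ", ")), call. = FALSE)
  }
  for (nm in setdiff(states, names(eq$ics))) eq$ics[[nm]] <- "0"
  # keep IC order aligned with state order
  eq$ics <- eq$ics[states]

  # linker payloads must be defined locally
  for (lk in eq$linkers) {
    if (!(lk$payload %in% c(names(eq$functions), names(eq$fixed),
                            names(eq$parameters), states))) {
      stop(sprintf("linker '@%s %s %s': payload '%s' is not defined in this equation set",
                   lk$name, lk$op, lk$payload, lk$payload), call. = FALSE)
    }
  }

  scope <- c(names(eq$parameters), names(eq$fixed), names(eq$functions), states)
  dup <- scope[duplicated(scope)]
  if (length(dup)) {
    stop(sprintf("name declared in more than one category: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }

  allow <- c(scope, .dsl_implicit(), "Npop")
  if (context == "mechanism") allow <- c(allow, .dsl_reserved())

  chk <- function(expr, where, extra = character(0)) {
    .check_expression(dsl_parse_expr(expr), c(allow, extra), eq$functions,
                      context = context, where = where)
  }
  for (nm in names(eq$fixed)) chk(eq$fixed[[nm]], sprintf("fixed variable '%s'", nm))
  for (nm in names(eq$functions)) {
    f <- eq$functions[[nm]]
    chk(f$body, sprintf("function '%s'", nm), extra = f$args)
  }
  for (nm in states) chk(eq$odes[[nm]], sprintf("ODE 'd%s/dt'", nm))
  for (nm in names(eq$ics)) chk(eq$ics[[nm]], sprintf("initial condition '%s(0)'", nm))
  for (i in seq_along(eq$conditionals)) {
    cd <- eq$conditionals[[i]]
    chk(cd$condition, sprintf("conditional %d condition", i))
    for (a in cd$actions) {
      if (!(a$target %in% c(states, names(eq$parameters)))) {
        stop(sprintf("conditional action target '%s' is not a declared state or parameter",
                     a$target), call. = FALSE)
      }
      chk(a$expr, sprintf("conditional %d action '%s='", i, a$target))
    }
  }
  for (mn in eq$monitors) {
    if (!(mn$name %in% c(scope))) {
      stop(sprintf("monitor '%s' does not name a declared element", mn$name),
           call. = FALSE)
    }
  }
  eq
}

# expression scope/arity checker shared by validate_expression and set
# validation; `functions` is the local function table (for arity checks)
.check_expression <- function(e, allow, functions = list(),
                              context = "population", where = "expression") {
  builtins <- dsl_builtins()
  arity <- .dsl_arity()
  fail <- function(msg) stop(sprintf("%s: %s", where, msg), call. = FALSE)

  check_node <- function(node, bound) {
    if (is.symbol(node)) {
      nm <- as.character(node)
      if (startsWith(nm, .AT_PREFIX)) return(invisible())  # linker placeholder
      ok <- nm %in% c(allow, bound, builtins)
      # mechanisms may reference host-population symbols and source/target
      # states (<name>_pre / <name>_post); those resolve at build time
      if (!ok && context == "mechanism") ok <- TRUE
      if (!ok) fail(sprintf("unknown identifier '%s'", nm))
      return(invisible())
    }
    if (is.call(node)) {
      head <- node[[1]]
      args <- as.list(node)[-1]
      if (is.symbol(head)) {
        hn <- as.character(head)
        if (hn %in% .dsl_operators()) {
          # fine
        } else if (hn %in% builtins) {
          a <- arity[[hn]]
          if (!is.null(a) && (length(args) < a[[1]] || length(args) > a[[2]])) {
            fail(sprintf("builtin '%s' called with %d argument(s)", hn, length(args)))
          }
        } else if (hn %in% names(functions)) {
          nf <- length(functions[[hn]]$args)
          if (length(args) != nf) {
            fail(sprintf("function '%s' expects %d argument(s), got %d",
                         hn, nf, length(args)))
          }
        } else if (hn %in% c(allow, bound) || context == "mechanism") {
          # call to a symbol resolved later (e.g. host-population function
          # referenced from a mechanism); arity checked at build time
        } else {
          fail(sprintf("unknown function '%s'", hn))
        }
      } else {
        fail("only named functions may be called")
      }
      for (a in args) check_node(a, bound)
      return(invisible())
    }
    if (is.numeric(node) || is.logical(node)) return(invisible())
    fail(sprintf("unsupported element '%s'", dsl_deparse(node)))
  }
  check_node(e, character(0))
  invisible(TRUE)
}

#' Validate and normalize a single expression
#'
#' Checks an expression against a set of in-scope names plus the builtin
#' whitelist, and returns its canonical (whitespace-normalized) form.
#' `^` denotes exponentiation throughout the dialect.
#'
#' @param expr Expression string.
#' @param scope Character vector of identifiers in scope.
#' @param context `"population"` (strict) or `"mechanism"` (admits reserved
#'   symbols).
#' @return The normalized expression string.
#' @examples
#' validate_expression("s*(y - x)", c("s", "y", "x"))
#' @export
validate_expression <- function(expr, scope = character(0),
                                context = c("population", "mechanism")) {
  context <- match.arg(context)
  e <- dsl_parse_expr(expr)
  .check_expression(e, c(scope, .dsl_implicit()), context = context,
                    where = sprintf("expression \"%s\"", expr))
  dsl_deparse(e)
}

#' Serialize an equation set back to DSL text
#'
#' Produces text that [parse_equations()] parses back to an identical
#' equation set (round-trip identity, field by field).
#'
#' @param eq An `equation_set`.
#' @return A single string of newline-delimited statements.
#' @export
serialize_equations <- function(eq) {
  out <- character(0)
  fmt_num <- function(v) {
    s <- vapply(v, function(x) trimws(formatC(x, format = "g", digits = 17)), "")
    if (length(v) > 1L) paste0("[", paste(s, collapse = ", "), "]") else s
  }
  for (nm in names(eq$parameters)) {
    out <- c(out, sprintf("%s = %s", nm, fmt_num(eq$parameters[[nm]])))
  }
  for (nm in names(eq$fixed)) out <- c(out, sprintf("%s = %s", nm, eq$fixed[[nm]]))
  for (nm in names(eq$functions)) {
    f <- eq$functions[[nm]]
    out <- c(out, sprintf("%s(%s) = %s", nm, paste(f$args, collapse = ","), f$body))
  }
  for (nm in names(eq$odes)) out <- c(out, sprintf("d%s/dt = %s", nm, eq$odes[[nm]]))
  for (nm in names(eq$ics)) out <- c(out, sprintf("%s(0) = %s", nm, eq$ics[[nm]]))
  for (cd in eq$conditionals) {
    acts <- paste(vapply(cd$actions, function(a) sprintf("%s = %s", a$target, a$expr), ""),
                  collapse = "; ")
    out <- c(out, sprintf("if(%s)(%s)", cd$condition, acts))
  }
  for (lk in eq$linkers) out <- c(out, sprintf("@%s %s %s", lk$name, lk$op, lk$payload))
  for (mn in eq$monitors) {
    out <- c(out, if (mn$kind == "spikes") {
      sprintf("monitor %s.spikes(%s)", mn$name, fmt_num(mn$threshold))
    } else sprintf("monitor %s", mn$name))
  }
  if (length(eq$mechanism_list)) {
    out <- c(out, sprintf("mechanism_list: %s", paste(eq$mechanism_list, collapse = ", ")))
  }
  paste(out, collapse = "\n")
}

#' Parse a mechanism file
#'
#' Reads a mechanism definition file (one statement per line in the equation
#' dialect, with linker statements such as `@current += INa`) and returns the
#' parsed equation set. The mechanism name is the filename stem. A file that
#' defines neither a linker statement nor an ODE is rejected as empty.
#'
#' @param path Path to a `.mech` (or `.pop`) file.
#' @return An `equation_set` with `linkers` populated.
#' @export
parse_mechanism_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("mechanism file not found: %s", path), call. = FALSE)
  }
  txt <- readLines(path, warn = FALSE)
  nm <- sub("\\.[A-Za-z]+$", "", basename(path))
  lines <- .strip_comments(txt)
  if (!any(nzchar(trimws(lines)))) {
    stop(sprintf("empty mechanism '%s': file contains only comments", nm), call. = FALSE)
  }
  eq <- parse_equations(lines, name = nm, context = "mechanism")
  if (length(eq$linkers) == 0L && length(eq$odes) == 0L &&
      length(eq$mechanism_list) == 0L) {
    stop(sprintf("empty mechanism '%s': no linker statements and no ODEs", nm),
         call. = FALSE)
  }
  eq
}

#' @export
print.equation_set <- function(x, ...) {
  cat(sprintf("<equation_set%s>\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else ""))
  cat(sprintf("  states: %s\n",
              if (length(x$odes)) paste(names(x$odes), collapse = ", ") else "(none)"))
  if (length(x$parameters)) {
    cat(sprintf("  parameters: %s\n", paste(names(x$parameters), collapse = ", ")))
  }
  if (length(x$functions)) {
    cat(sprintf("  functions: %s\n", paste(names(x$functions), collapse = ", ")))
  }
  if (length(x$conditionals)) cat(sprintf("  conditionals: %d\n", length(x$conditionals)))
  if (length(x$linkers)) {
    cat(sprintf("  linkers: %s\n", paste(vapply(x$linkers, function(l)
      sprintf("@%s %s %s", l$name, l$op, l$payload), ""), collapse = "; ")))
  }
  if (length(x$mechanism_list)) {
    cat(sprintf("  mechanism_list: %s\n", paste(x$mechanism_list, collapse = ", ")))
  }
  invisible(x)
}
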