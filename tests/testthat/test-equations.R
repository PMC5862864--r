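# Equation dialect: parsing, validation, serialization round trips.

test_that("classic three-variable chaotic system parses into ODEs and parameters", {
  eq <- parse_equations(paste(
    "dx/dt=s*(y-x); dy/dt=r*x-y-x*z; dz/dt=-b*z+x*y",
    "s=10; r=27; b=2.666", sep = "\n"))
  expect_setequal(names(eq$odes), c("x", "y", "z"))
  expect_equal(length(eq$parameters), 3L)
  expect_equal(eq$parameters$b, 2.666)
  expect_length(eq$conditionals, 0L)
  # states without explicit ICs get the 0 default
  expect_equal(eq$ics, list(x = "0", y = "0", z = "0"))
})

test_that("conditional reset syntax yields ordered actions", {
  eq <- parse_equations(c(
    "a=.03; b=-2; c=-50; d=100; vr=-60; vpeak=35",
    "dv/dt=.01*(.7*(v-vr)*(v+40)-u+1); v(0)=vr",
    "du/dt=a*(b*(v-vr)-u); u(0)=0",
    "if(v>vpeak)(v=c; u=u+d)"))
  expect_setequal(names(eq$odes), c("v", "u"))
  expect_length(eq$conditionals, 1L)
  acts <- eq$conditionals[[1]]$actions
  expect_length(acts, 2L)
  expect_equal(acts[[1]]$target, "v")
  expect_equal(acts[[2]]$target, "u")
  expect_equal(acts[[2]]$expr, "u + d")
})

test_that("a minimal one-line program parses", {
  eq <- parse_equations("dx/dt=-x; x(0)=1")
  expect_equal(names(eq$odes), "x")
  expect_equal(eq$ics$x, "1")
  expect_length(eq$parameters, 0L)
})

test_that("alternative ODE spelling and comments are handled", {
  eq <- parse_equations("x' = -x  % decay\n# a comment line\nx(0) = 2")
  expect_equal(eq$odes$x, "-x")
  expect_equal(eq$ics$x, "2")
  expect_error(parse_equations("% only a comment"), "no statements")
})

test_that("malformed and conflicting statements raise located errors", {
  expect_error(parse_equations("dx/dt = -x; x = 3"), "already declared")
  expect_error(parse_equations("dx/dt = -x +* 2"), "line 1")
  expect_error(parse_equations("dx/dt = -y"), "unknown identifier 'y'")
  expect_error(parse_equations("@@bad = x"), "linker|unrecognized")
  expect_error(parse_equations("if(x>1)(x=0)\ndx/dt=-x; y=1\nif(x>1)(z=0)"),
               "not a declared state or parameter")
})

test_that("expression validation enforces scope, arity and balance", {
  expect_equal(validate_expression("s*(y-x)", c("s", "y", "x")), "s * (y - x)")
  expect_equal(validate_expression("rand(1, Npop)", "Npop"), "rand(1, Npop)")
  expect_error(validate_expression("foo(x)", "x"), "unknown function 'foo'")
  expect_error(validate_expression("(x + 1", "x"), "parse")
  expect_error(validate_expression("exp(x, 2)", "x"), "argument")
  expect_error(validate_expression("matmul(a)", "a"), "argument")
})

test_that("serialization round-trips field by field", {
  txt <- paste(
    "gmax = [1, 2, 3]",
    "tau = 5",
    "w = ones(2, 3)",
    "f(x) = 1/(1+exp(-x/2))",
    "ds/dt = f(V_pre)*(1-s) - s/tau",
    "s(0) = 0.5",
    "if(s > 1)(s = 1)",
    "@current += f",
    "monitor f",
    sep = "\n")
  eq <- parse_equations(txt, context = "mechanism")
  eq2 <- parse_equations(serialize_equations(eq), context = "mechanism")
  for (fld in c("parameters", "fixed", "functions", "odes", "ics",
                "conditionals", "linkers", "monitors")) {
    expect_identical(eq[[fld]], eq2[[fld]], label = fld)
  }
})

test_that("parsing is pure: identical text gives identical structures", {
  txt <- "k = 2\ndx/dt = -k*x\nx(0) = rand(1, Npop)"
  expect_identical(parse_equations(txt), parse_equations(txt))
})

test_that("declaration order of conditionals changes the result", {
  base <- "dv/dt = 0; v(0) = 5"
  d1 <- integrate_model(paste(base, "if(v>0)(v=1)", "if(v>0)(v=2)", sep = "\n"),
                        solver_options(method = "euler", dt = 0.1, tspan = c(0, 1)))
  d2 <- integrate_model(paste(base, "if(v>0)(v=2)", "if(v>0)(v=1)", sep = "\n"),
                        solver_options(method = "euler", dt = 0.1, tspan = c(0, 1)))
  n <- length(d1$time)
  expect_equal(d1$series$pop1_v[n], 2)  # later conditional wins
  expect_equal(d2$series$pop1_v[n], 1)
})

test_that("mechanism files parse with linkers and reject degenerate input", {
  f <- file.path(system.file("library", "mechanisms", package = "neurodyn"),
                 "iGABAa.mech")
  eq <- parse_mechanism_file(f)
  expect_equal(eq$name, "iGABAa")
  expect_equal(names(eq$odes), "s")
  expect_true("tauD" %in% names(eq$parameters))
  expect_equal(eq$parameters$tauD, 10)
  expect_length(eq$linkers, 1L)
  expect_equal(eq$linkers[[1]],
               list(name = "current", op = "+=", payload = "IGABAa"))
  # round trip through the serializer
  eq2 <- parse_equations(serialize_equations(eq), name = eq$name,
                         context = "mechanism")
  expect_identical(eq$odes, eq2$odes)
  expect_identical(eq$linkers, eq2$linkers)

  empty <- tempfile(fileext = ".mech")
  writeLines(c("% nothing here", "# still nothing"), empty)
  expect_error(parse_mechanism_file(empty), "empty mechanism")
  expect_error(parse_mechanism_file(tempfile(fileext = ".mech")), "not found")
})
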