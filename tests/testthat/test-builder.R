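# Specification standardization, namespace qualification, linker
# substitution, and flat-model assembly.

test_that("bare equations standardize to a default one-cell population", {
  s <- standardize("dx/dt=s*(y-x); dy/dt=r*x-y-x*z; dz/dt=-b*z+x*y; s=10; r=27; b=2.666")
  expect_s3_class(s, "specification")
  expect_length(s$populations, 1L)
  p <- s$populations[[1]]
  expect_equal(p$name, "pop1")
  expect_equal(p$size, 1L)
  expect_length(p$equations$odes, 3L)
})

test_that("a two-population network specification standardizes and is idempotent", {
  s <- standardize(weak_ping_fixture())
  expect_length(s$populations, 2L)
  expect_length(s$connections, 2L)
  expect_equal(vapply(s$populations, `[[`, "", "name"), c("E", "I"))
  expect_identical(standardize(s), s)
  dup <- specification(list(population("A", 1, "dx/dt=-x"),
                            population("A", 1, "dx/dt=-x")))
  expect_error(standardize(dup), "duplicate population")
  bad <- specification(list(population("A", 1, "dx/dt=-x")),
                       list(connection("A", "B")))
  expect_error(standardize(bad), "unknown population 'B'")
})

test_that("qualification joins object paths and flags collisions", {
  expect_equal(qualify(c("pop1", "Na"), "m"), "pop1_Na_m")
  expect_equal(qualify("pop1", "V"), "pop1_V")
  reg <- neurodyn:::.new_registry()
  qualify(c("E", "Na"), "m", reg)
  expect_error(qualify("E", "Na_m", reg), "collision")
  # re-registering the same pair is fine
  expect_equal(qualify(c("E", "Na"), "m", reg), "E_Na_m")
})

test_that("linker substitution reproduces the additive worked example", {
  merged <- link("dV/dt = @current; V(0) = 0",
                 list(Na = "gNa = 1\nINa(V) = -gNa*(V - 50)\n@current += INa",
                      K  = "gK = 1\nIK(V) = -gK*(V + 77)\n@current += IK"))
  expect_identical(merged$odes[["pop1_V"]], "pop1_Na_INa + pop1_K_IK")
  expect_false(any(grepl("@", unlist(merged$odes), fixed = TRUE)))
})

test_that("an unlinked placeholder becomes the additive identity", {
  merged <- link("dV/dt = @current; V(0) = 0", list())
  expect_identical(merged$odes[["pop1_V"]], "0")
})

test_that("contribution order follows the mechanism list", {
  mechs <- list(K = "gK = 1\nIK(V) = -gK*(V + 77)\n@current += IK",
                Na = "gNa = 1\nINa(V) = -gNa*(V - 50)\n@current += INa")
  merged <- link("dV/dt = @current; V(0) = 0", mechs)
  # oracle: hand-concatenated qualified payloads in list order
  oracle <- paste(sprintf("pop1_%s_I%s", names(mechs), names(mechs)),
                  collapse = " + ")
  expect_identical(merged$odes[["pop1_V"]], oracle)
})

test_that("operator semantics: -=, *=, duplicate '=' rejection", {
  merged <- link("dV/dt = @current; V(0) = 0",
                 list(A = "f(V) = V + 1\n@current += f",
                      B = "g(V) = V + 2\n@current -= g"))
  expect_identical(merged$odes[["pop1_V"]], "pop1_A_f - pop1_B_g")
  expect_error(
    link("dV/dt = @current; V(0) = 0",
         list(A = "f(V) = V + 1\n@current = f",
              B = "g(V) = V + 2\n@current = g")),
    "ambiguous overwrite")
})

test_that("a contribution whose linker is absent from the host warns", {
  expect_warning(
    link("dV/dt = -V; V(0) = 0",
         list(A = "f(V) = V + 1\n@missing += f")),
    "never appears")
})

test_that("the mechanism-composed bursting neuron builds with its gating states", {
  m <- build_model(population("pop1", 1,
                              "dV/dt=(Iapp+@current)/Cm; Iapp=2; Cm=1; V(0)=-70",
                              mechanism_list = c("iNaF", "iKDR", "iM")))
  expect_setequal(names(m$odes),
                  c("pop1_V", "pop1_iNaF_hNaF", "pop1_iKDR_nKDR", "pop1_iM_wM"))
  expect_match(m$odes[["pop1_V"]], "pop1_iNaF_INaF \\+ pop1_iKDR_IKDR \\+ pop1_iM_IM")
})

test_that("the two-population gamma network links synapses across populations", {
  m <- build_model(weak_ping_fixture())
  # E voltage sees both intrinsic currents and the inhibitory synapse
  expect_match(m$odes[["E_V"]], "E_iNaF_INaF")
  expect_match(m$odes[["E_V"]], "E_I_iGABAa_IGABAa")
  # synaptic gating is driven by the presynaptic (I) voltage
  expect_match(m$odes[["E_I_iGABAa_s"]], "I_V")
  # gating states are per source cell
  expect_equal(m$state_layout[["E_I_iGABAa_s"]]$size, 5L)
  expect_equal(m$state_layout[["I_E_iAMPA_s"]]$size, 20L)
  # no linker token survives anywhere
  all_txt <- c(unlist(m$odes), unlist(m$fixed), unlist(m$ics),
               vapply(m$functions, `[[`, "", "body"))
  expect_false(any(grepl("@", all_txt, fixed = TRUE)))
})

test_that("scalar initial conditions broadcast over the population", {
  d <- integrate_model(population("pop1", 100, "dx/dt = -x; x(0) = 0"),
                       solver_options(method = "euler", dt = 0.1, tspan = c(0, 1)))
  expect_equal(ncol(d$series$pop1_x), 100L)
  expect_equal(d$series$pop1_x[1, ], rep(0, 100))
})

test_that("build errors: missing mechanism, bad netcon shape, unknown override", {
  expect_error(build_model(population("p", 1, "dV/dt=@current",
                                      mechanism_list = "no_such_mech")),
               "not found")
  s <- weak_ping_fixture()
  s$connections[[1]]$parameters$netcon <- matrix(1, 3, 3)
  expect_error(build_model(s), "20 x 5")
  expect_error(build_model(population("p", 1, "dx/dt=-x",
                                      parameters = list(zz = 1))),
               "unknown parameter")
  expect_error(build_model(population("p", 2, "dx/dt=-x",
                                      parameters = list(x0 = c(1, 2, 3)))),
               "unknown parameter|length")
})

test_that("array parameters must match the population size", {
  ok <- build_model(population("p", 3, "dx/dt=-k*x; k=1",
                               parameters = list(k = c(1, 2, 3))))
  expect_equal(ok$parameters$p_k, c(1, 2, 3))
  expect_error(build_model(population("p", 3, "dx/dt=-k*x; k=1",
                                      parameters = list(k = c(1, 2)))),
               "length 2")
})

test_that("mechanism route and explicit-equation route give identical trajectories", {
  opts <- solver_options(method = "rk4", dt = 0.01, tspan = c(0, 50))
  via_mech <- build_model(specification(
    populations = list(population("pop1", 1,
                                  "dV/dt = (Iapp + @current)/Cm; Iapp = 1; Cm = 1; V(0) = -60",
                                  mechanism_list = "L")),
    mechanisms = list(L = "gl = 0.1\nEl = -65\nIleak(V) = -gl*(V - El)\n@current += Ileak")))
  explicit <- build_model(paste(
    "gl = 0.1; El = -65; Iapp = 1; Cm = 1",
    "Ileak(V) = -gl*(V - El)",
    "dV/dt = (Iapp + Ileak(V))/Cm",
    "V(0) = -60", sep = "\n"))
  a <- integrate_model(via_mech, opts)$series$pop1_V
  b <- integrate_model(explicit, opts)$series$pop1_V
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-12)
})

test_that("building is deterministic", {
  s <- weak_ping_fixture()
  expect_identical(build_model(s), build_model(s))
})

test_that("JSON specifications round-trip through disk", {
  f <- tempfile(fileext = ".json")
  write_specification(weak_ping_fixture(), f)
  s2 <- read_specification(f)
  m1 <- build_model(weak_ping_fixture())
  m2 <- build_model(s2)
  expect_identical(names(m1$odes), names(m2$odes))
  expect_identical(m1$parameters, m2$parameters)
})
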