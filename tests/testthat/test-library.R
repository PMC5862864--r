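# Packaged model-object library: index, instantiation, and the qualitative
# behavior of the shipped cell and synapse models.

test_that("the library index lists the packaged objects by kind", {
  idx <- list_objects()
  expect_true(all(c("iNa", "iK", "iNaF", "iKDR", "iM", "iNaP") %in%
                  idx$name[idx$kind == "intrinsic"]))
  expect_true(all(c("iAMPA", "iGABAa", "iGAP", "iCOM") %in%
                  idx$name[idx$kind == "connection"]))
  expect_true(all(c("noise", "poisson", "stim") %in%
                  idx$name[idx$kind == "input"]))
  expect_true(all(c("HH", "Izh", "LIF") %in%
                  idx$name[idx$kind == "population"]))
  expect_false(is.unsorted(idx$name))
  expect_true(all(nzchar(idx$citation)))
  expect_error(list_objects("sideways"), "unknown object kind")
  expect_equal(nrow(list_objects(paths = tempfile())), 0L)
})

test_that("every packaged object parses cleanly", {
  idx <- list_objects()
  for (i in seq_len(nrow(idx))) {
    expect_s3_class(parse_mechanism_file(idx$file[[i]]), "equation_set")
  }
})

test_that("all packaged ionic mechanisms compose through the additive current linker", {
  idx <- list_objects()
  ionic <- idx[idx$kind %in% c("intrinsic", "connection", "input"), ]
  for (i in seq_len(nrow(ionic))) {
    eq <- parse_mechanism_file(ionic$file[[i]])
    ops <- vapply(eq$linkers, `[[`, "", "op")
    nms <- vapply(eq$linkers, `[[`, "", "name")
    expect_true(any(nms == "current" & ops == "+="), label = ionic$name[[i]])
  }
})

test_that("instantiation applies overrides and validates their names", {
  hh <- instantiate("HH", 100, parameters = list(noise_amp = 1e3),
                    mechanisms = "noise")
  expect_equal(hh$mechanism_list, c("iNa", "iK", "noise"))
  expect_equal(hh$parameters$noise_amp, 1e3)
  expect_error(instantiate("HH", 1, parameters = list(bogus = 1)),
               "nonexistent parameter")
  # overrides are unchecked numerics: no sign/unit policing
  expect_silent(instantiate("HH", 1, parameters = list(gNa = -5)))
  expect_error(instantiate("noSuchThing"), "not found")
})

test_that("the packaged two-variable spiking neuron carries its printed coefficients", {
  iz <- instantiate("Izh")
  expect_match(iz$odes$v, "0\\.01 \\* \\(0\\.7 \\* \\(v - vr\\) \\* \\(v \\+ 40\\)")
  expect_length(iz$conditionals, 1L)
  expect_equal(iz$conditionals[[1]]$condition, "v > vpeak")
})

test_that("the HH cell rests quietly and spikes repetitively under drive", {
  rest <- integrate_model(population("pop1", 1, "HH"),
                          solver_options(method = "rk4", dt = 0.01, tspan = c(0, 100)))
  v <- rest$series$pop1_V
  expect_lt(max(abs(v - v[[1]])), 1)  # stays within 1 mV of rest
  driven <- integrate_model(population("pop1", 1, "HH", parameters = list(Iapp = 10)),
                            solver_options(method = "rk4", dt = 0.01, tspan = c(0, 500)))
  st <- driven$spikes$pop1[[1]]
  expect_gt(length(st), 20)
  isi <- diff(st)
  expect_lt(stats::sd(isi) / mean(isi), 0.1)  # repetitive, near-tonic firing
})

test_that("the bursting fixture shows burst-and-pause interval bimodality", {
  d <- integrate_model(build_model(ib_neuron_fixture()),
                       solver_options(method = "rk4", dt = 0.01, tspan = c(0, 800)))
  isi <- diff(d$spikes$pop1[[1]])
  expect_gt(length(isi), 8)
  expect_gt(max(isi) / min(isi), 5)       # intervals span burst and pause scales
  expect_gt(sum(isi < 30), 4)             # intra-burst intervals
  expect_gt(sum(isi > 60), 2)             # inter-burst pauses
  # bimodality: nothing sits between the two clusters
  expect_equal(sum(isi >= 30 & isi <= 60), 0)
})

test_that("the integrate-and-fire cell honours its refractory period", {
  d <- integrate_model(population("pop1", 1, "LIF",
                                  parameters = list(Iapp = 6, tref = 20)),
                       solver_options(method = "euler", dt = 0.01, tspan = c(0, 500)))
  st <- d$spikes$pop1[[1]]
  expect_gt(length(st), 3)
  expect_true(all(diff(st) > 20))  # no interval shorter than the refractory period
})
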