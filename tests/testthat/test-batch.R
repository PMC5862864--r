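# Sweep expansion, modification application, batch execution and study
# directory import.

test_that("a two-triplet vary expands to the full Cartesian product", {
  plan <- expand_vary(list(vary("E", "Iapp", c(0, 5, 10)),
                           vary("I->E", "tauD", c(5, 10, 20))))
  expect_length(plan$modifications, 9L)
  # first triplet varies slowest
  first_vals <- vapply(plan$modifications, function(m) m[[1]]$value, 0)
  second_vals <- vapply(plan$modifications, function(m) m[[2]]$value, 0)
  expect_equal(first_vals, rep(c(0, 5, 10), each = 3))
  expect_equal(second_vals, rep(c(5, 10, 20), times = 3))
})

test_that("expansion cardinality equals the product of value counts", {
  plan <- expand_vary(list(vary("a", "p", 1:2), vary("a", "q", 1:3),
                           vary("a", "r", 1:4)))
  expect_length(plan$modifications, 24L)
  # brute-force enumeration oracle
  oracle <- nrow(expand.grid(1:2, 1:3, 1:4))
  expect_equal(length(plan$modifications), oracle)
  # every combination appears exactly once
  keys <- vapply(plan$modifications, function(m) {
    paste(vapply(m, function(x) as.character(x$value), ""), collapse = "|")
  }, "")
  expect_false(anyDuplicated(keys) > 0)
  expect_length(expand_vary(list(vary("a", "p", 7)))$modifications, 1L)
  expect_identical(expand_vary(list())$modifications, list(list()))
})

test_that("vary strings parse into triplets", {
  plan <- expand_vary("E.Iapp=0,5,10; I->E.tauD=5,10,20")
  expect_length(plan$modifications, 9L)
  expect_equal(plan$modifications[[1]][[2]]$object, "I->E")
})

test_that("modifications copy the specification and route to the right object", {
  base <- weak_ping_fixture()
  mods <- expand_vary(list(vary("E", "Iapp", 10),
                           vary("I->E", "tauD", 5)))$modifications[[1]]
  sp <- apply_modifications(base, mods)
  expect_equal(sp$populations[[1]]$parameters$Iapp, 10)
  i_e <- Filter(function(cn) cn$source == "I" && cn$target == "E", sp$connections)
  expect_equal(i_e[[1]]$parameters$tauD, 5)
  # base untouched
  expect_equal(standardize(base)$populations[[1]]$parameters$Iapp, 5)
  expect_error(apply_modifications(base, list(list(object = "Z", parameter = "x", value = 1))),
               "unknown object")
  expect_error(apply_modifications(base, list(list(object = "E", parameter = "nope", value = 1))),
               "no parameter")
})

test_that("population size is a modifiable specifier", {
  sp <- apply_modifications(weak_ping_fixture(),
                            list(list(object = "E", parameter = "size", value = 7)))
  m <- build_model(sp)
  expect_equal(m$state_layout[["E_V"]]$size, 7L)
  expect_equal(m$state_layout[["I_E_iAMPA_s"]]$size, 7L)
})

test_that("a batch produces one simulation per modification set with hook results", {
  plan <- expand_vary(list(vary("pop1", "Iapp", c(6, 8, 10))))
  res <- run_batch(noisy_hh_spec(), plan, batch_opts(), hooks = "firing_rate")
  expect_equal(nrow(res$index), length(plan$modifications))
  expect_true(all(res$index$status == "ok"))
  rates <- vapply(res$results, function(r) r$firing_rate$pop1, 0)
  expect_length(rates, 3L)
  expect_true(all(is.finite(rates)))
  # firing rate grows with drive
  expect_true(rates[[3]] >= rates[[1]])
  # varied values travel in the metadata
  expect_equal(res$data[[2]]$metadata$varied[[1]]$value, 8)
})

test_that("an empty plan runs the base model once", {
  res <- run_batch(noisy_hh_spec(), expand_vary(), batch_opts())
  expect_equal(nrow(res$index), 1L)
})

test_that("serial and parallel batch execution are element-wise identical", {
  plan <- expand_vary(list(vary("pop1", "Iapp", c(6, 8, 10)),
                           vary("pop1", "noise_amp", c(10, 30, 50))))
  a <- run_batch(noisy_hh_spec(), plan, batch_opts(seed = 99L), hooks = "firing_rate")
  b <- run_batch(noisy_hh_spec(), plan, batch_opts(seed = 99L), hooks = "firing_rate",
                 parallel = TRUE, cores = 2L)
  expect_equal(nrow(a$index), 9L)
  expect_identical(a$index, b$index)
  expect_identical(a$results, b$results)
  expect_identical(lapply(a$data, `[[`, "series"), lapply(b$data, `[[`, "series"))
})

test_that("per-simulation seeds derive deterministically from the master seed", {
  plan <- expand_vary(list(vary("pop1", "Iapp", c(6, 8))))
  r1 <- run_batch(noisy_hh_spec(), plan, batch_opts(seed = 5L), keep_data = FALSE)
  r2 <- run_batch(noisy_hh_spec(), plan, batch_opts(seed = 5L), keep_data = FALSE)
  expect_identical(r1$index$seed, r2$index$seed)
  expect_false(any(duplicated(r1$index$seed)))
})

test_that("hook exceptions are recorded and the batch continues", {
  plan <- expand_vary(list(vary("pop1", "Iapp", c(6, 8))))
  res <- run_batch(noisy_hh_spec(), plan, batch_opts(),
                   hooks = list(boom = function(d) stop("kaboom"),
                                ok = function(d) list(x = 1)))
  expect_true(all(res$index$status == "ok"))
  expect_s3_class(res$results[[1]]$boom, "hook_error")
  expect_equal(res$results[[2]]$ok$x, 1)
})

test_that("a study directory round-trips data, results and failure flags", {
  td <- file.path(tempfile("study"), "s")
  plan <- expand_vary(list(vary("pop1", "Iapp", c(6, 8, 10))))
  hooks <- list(rate = function(d) list(pop1 = firing_rate(d)$mean),
                boom = function(d) {
                  if (abs(d$metadata$varied[[1]]$value - 8) < 1e-9) stop("no")
                  list(ok = TRUE)
                })
  res <- run_batch(noisy_hh_spec(), plan, batch_opts(), hooks = hooks,
                   study_dir = td)
  expect_true(file.exists(file.path(td, "index.json")))
  expect_true(file.exists(file.path(td, "jobs.manifest")))

  # data mode: entries in plan order, numerically matching in-memory output
  imp <- import_results(td, "data")
  expect_length(imp$items, 3L)
  expect_false(any(imp$missing))
  for (k in 1:3) {
    expect_lt(max(abs(imp$items[[k]]$series$pop1_V - res$data[[k]]$series$pop1_V)),
              1e-10)
    expect_identical(lengths(imp$items[[k]]$spikes$pop1),
                     lengths(res$data[[k]]$spikes$pop1))
  }

  # hook mode: the failing middle simulation is flagged, others load
  imph <- import_results(td, "boom")
  expect_identical(imph$missing, c(FALSE, TRUE, FALSE))
  imprate <- import_results(td, "rate")
  expect_false(any(imprate$missing))
  expect_equal(imprate$items[[1]]$pop1, res$results[[1]]$rate$pop1)

  # overwrite protection
  expect_error(run_batch(noisy_hh_spec(), plan, batch_opts(), study_dir = td),
               "overwrite")
  expect_error(import_results(tempfile()), "not a study directory")
})

test_that("hook results through the batch equal post-hoc analysis of imported data", {
  td <- file.path(tempfile("study"), "s")
  plan <- expand_vary(list(vary("pop1", "Iapp", c(8, 10))))
  res <- run_batch(noisy_hh_spec(), plan, batch_opts(), hooks = "firing_rate",
                   study_dir = td, keep_data = FALSE)
  imp <- import_results(td, "data")
  for (k in seq_along(imp$items)) {
    post_hoc <- builtin_hooks()$firing_rate(imp$items[[k]])
    expect_equal(res$results[[k]]$firing_rate$pop1, post_hoc$pop1)
  }
})
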