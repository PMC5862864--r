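# Batch management: vary descriptions expand by Cartesian product into
# sweep plans; each plan entry is a self-contained modification set applied
# to a deep copy of the base specification; batches run serially or with a
# local parallel map into a self-describing study directory.

#' Define a vary triplet
#'
#' @param object Population name, or `"source->target"` for a connection.
#' @param parameter Parameter name (or `"size"` for a population's size).
#' @param values Vector/list of values to sweep over.
#' @return A `vary_triplet`.
#' @export
vary <- function(object, parameter, values) {
  if (length(values) == 0L) stop("vary values must be non-empty", call. = FALSE)
  structure(list(object = object, parameter = parameter, values = values),
            class = "vary_triplet")
}

# parse "E.Iapp=0,5,10; I->E.tauD=5,10,20" into a list of triplets
parse_vary_string <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(.+)\\.([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", p))[[1]]
    if (length(m) != 4L) stop(sprintf("malformed vary term '%s'", p), call. = FALSE)
    vary(trimws(m[[2]]), m[[3]], as.numeric(strsplit(m[[4]], ",")[[1]]))
  })
}

#' Expand vary triplets into a sweep plan
#'
#' The plan is the Cartesian product of the triplets' value lists, in
#' lexicographic order with the first triplet varying slowest. Each
#' modification set is self-contained: it lists one (object, parameter,
#' value) per triplet. An empty triplet list yields one empty modification
#' set (the unmodified base model). A list of modification sets passed
#' through unchanged ("zipped" form) is also accepted.
#'
#' @param triplets A `vary_triplet`, list of them, or a vary string such as
#'   `"E.Iapp=0,5,10; I->E.tauD=5,10,20"`.
#' @return A `sweep_plan` with `modifications` and `axes`.
#' @examples
#' plan <- expand_vary(list(vary("E", "Iapp", c(0, 5, 10)),
#'                          vary("I->E", "tauD", c(5, 10, 20))))
#' length(plan$modifications)  # 9
#' @export
expand_vary <- function(triplets = list()) {
  if (is.character(triplets)) triplets <- parse_vary_string(triplets)
  if (inherits(triplets, "vary_triplet")) triplets <- list(triplets)
  if (length(triplets) && all(vapply(triplets, function(x)
      is.list(x) && !inherits(x, "vary_triplet") &&
      all(vapply(x, inherits, TRUE, "modification")), TRUE))) {
    # explicit list-of-modification-sets ("zipped") form
    return(structure(list(modifications = triplets, axes = NULL),
                     class = "sweep_plan"))
  }
  if (length(triplets) == 0L) {
    return(structure(list(modifications = list(list()), axes = NULL),
                     class = "sweep_plan"))
  }
  lens <- vapply(triplets, function(tr) length(tr$values), 0L)
  total <- prod(lens)
  mods <- vector("list", total)
  for (k in seq_len(total)) {
    idx <- k - 1L
    sel <- integer(length(lens))
    # first triplet slowest-varying
    for (j in rev(seq_along(lens))) {
      sel[[j]] <- idx %% lens[[j]] + 1L
      idx <- idx %/% lens[[j]]
    }
    mods[[k]] <- lapply(seq_along(triplets), function(j) {
      tr <- triplets[[j]]
      structure(list(object = tr$object, parameter = tr$parameter,
                     value = tr$values[[sel[[j]]]]), class = "modification")
    })
  }
  axes <- lapply(triplets, function(tr) {
    list(object = tr$object, parameter = tr$parameter, values = tr$values)
  })
  structure(list(modifications = mods, axes = axes), class = "sweep_plan")
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("<sweep_plan: %d modification set(s)>\n", length(x$modifications)))
  invisible(x)
}

# names of parameters reachable for an object of the spec (population or
# "source->target" connection), including its mechanisms' parameters
.known_parameters <- function(spec, object, mech_paths = character(0)) {
  paths <- library_paths(mech_paths)
  grab <- function(eq, mech_list) {
    nms <- character(0)
    if (inherits(eq, "equation_set")) nms <- names(eq$parameters)
    else if (is.character(eq) && length(eq) == 1L &&
             grepl("^[A-Za-z_][A-Za-z0-9_]*$", trimws(eq))) {
      f <- find_object(trimws(eq), paths)
      if (!is.null(f)) {
        peq <- parse_mechanism_file(f)
        nms <- names(peq$parameters)
        mech_list <- union(peq$mechanism_list, mech_list)
      }
    } else if (is.character(eq)) {
      nms <- names(parse_equations(eq)$parameters)
    }
    for (mn in mech_list) {
      f <- find_object(mn, paths)
      if (!is.null(f)) nms <- c(nms, names(parse_mechanism_file(f)$parameters))
    }
    unique(nms)
  }
  if (grepl("->", object, fixed = TRUE)) {
    ends <- trimws(strsplit(object, "->", fixed = TRUE)[[1]])
    for (cn in spec$connections) {
      if (cn$source == ends[[1]] && cn$target == ends[[2]]) {
        return(c("netcon", grab(NULL, cn$mechanism_list)))
      }
    }
    stop(sprintf("unknown connection '%s'", object), call. = FALSE)
  }
  for (p in spec$populations) {
    if (p$name == object) {
      return(c("size", grab(p$equations, p$mechanism_list)))
    }
  }
  stop(sprintf("unknown object '%s'", object), call. = FALSE)
}

#' Apply a modification set to a specification
#'
#' Returns a deep-copied specification with each (object, parameter, value)
#' override placed in the right object's parameters. Population `size` may
#' be modified too (modifications address specifiers, not only parameters).
#'
#' @param spec A `specification` (standardized first).
#' @param mods A modification set from a [sweep_plan][expand_vary()], or a
#'   list of `vary()`-style (object, parameter, value) lists.
#' @param mech_paths Extra mechanism search paths used for validation.
#' @return The modified `specification`; the input is untouched.
#' @export
apply_modifications <- function(spec, mods, mech_paths = character(0)) {
  spec <- standardize(spec)
  for (md in mods) {
    known <- .known_parameters(spec, md$object, mech_paths)
    if (!(md$parameter %in% known)) {
      stop(sprintf("object '%s' has no parameter '%s'", md$object, md$parameter),
           call. = FALSE)
    }
    if (grepl("->", md$object, fixed = TRUE)) {
      ends <- trimws(strsplit(md$object, "->", fixed = TRUE)[[1]])
      for (i in seq_along(spec$connections)) {
        cn <- spec$connections[[i]]
        if (cn$source == ends[[1]] && cn$target == ends[[2]]) {
          spec$connections[[i]]$parameters[[md$parameter]] <- md$value
        }
      }
    } else {
      for (i in seq_along(spec$populations)) {
        if (spec$populations[[i]]$name == md$object) {
          if (md$parameter == "size") {
            spec$populations[[i]]$size <- as.integer(md$value)
          } else {
            spec$populations[[i]]$parameters[[md$parameter]] <- md$value
          }
        }
      }
    }
  }
  spec
}

# deterministic per-simulation seed from (master seed, index)
.sim_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647L)
}

.mods_label <- function(mods, index) {
  if (length(mods) == 0L) return(sprintf("sim%03d", index))
  tags <- vapply(mods, function(md) {
    v <- if (is.numeric(md$value) && length(md$value) == 1L)
      .fmt_num(md$value) else "custom"
    gsub("[^A-Za-z0-9_.=-]", "-", sprintf("%s_%s_%s", md$object, md$parameter, v))
  }, "")
  sprintf("sim%03d__%s", index, paste(tags, collapse = "__"))
}

#' Run a simulation batch
#'
#' Applies every modification set of the plan to the base specification,
#' builds and integrates each variant, applies the analysis hooks, and (when
#' `study_dir` is given) lays the results out as one subdirectory per
#' simulation plus an `index.json` making the study self-describing.
#' Per-simulation seeds are derived deterministically from the master seed
#' and the simulation index, so serial and parallel execution produce
#' identical results and any subset can be reproduced in isolation. A hook
#' error is recorded for that simulation and the batch continues.
#'
#' @param spec Base `specification` (or anything [standardize()] accepts).
#' @param plan A `sweep_plan`, vary triplet list, or vary string.
#' @param opts [solver_options()]; its `seed` is the master seed.
#' @param hooks Named list of functions `f(sim_data) -> list`, or names of
#'   [builtin_hooks()].
#' @param study_dir Optional output directory; required for later
#'   [import_results()]. An existing study is only replaced when
#'   `overwrite = TRUE`.
#' @param parallel Run simulations with a local parallel map
#'   ([parallel::mclapply()]).
#' @param cores Worker count when `parallel` (default 2).
#' @param keep_data Keep each simulation's `sim_data` in the returned
#'   object (default TRUE; set FALSE for large batches written to disk).
#' @param overwrite Replace an existing `study_dir`.
#' @param mech_paths Extra mechanism search paths.
#' @return A `study_results` list: `index` (data.frame of simulations),
#'   `results` (per-simulation hook outputs), `data` (per-simulation
#'   `sim_data` when kept), `errors`.
#' @export
run_batch <- function(spec, plan = expand_vary(), opts = solver_options(),
                      hooks = list(), study_dir = NULL, parallel = FALSE,
                      cores = 2L, keep_data = TRUE, overwrite = FALSE,
                      mech_paths = character(0)) {
  spec <- standardize(spec)
  if (!inherits(plan, "sweep_plan")) plan <- expand_vary(plan)
  opts <- .check_solver_options(opts)
  if (is.character(hooks)) {
    hooks <- builtin_hooks()[hooks]
    if (any(vapply(hooks, is.null, TRUE))) {
      stop("unknown builtin hook name", call. = FALSE)
    }
  }
  if (length(hooks) && is.null(names(hooks))) {
    stop("hooks must be a named list", call. = FALSE)
  }
  if (!is.null(study_dir)) {
    if (dir.exists(study_dir) && length(list.files(study_dir))) {
      if (!overwrite) {
        stop(sprintf("study directory '%s' exists; use overwrite = TRUE", study_dir),
             call. = FALSE)
      }
      unlink(study_dir, recursive = TRUE)
    }
    dir.create(study_dir, showWarnings = FALSE, recursive = TRUE)
  }

  n <- length(plan$modifications)
  labels <- vapply(seq_len(n), function(k) .mods_label(plan$modifications[[k]], k), "")
  seeds <- vapply(seq_len(n), function(k) .sim_seed(opts$seed, k), 0L)

  one <- function(k) {
    mods <- plan$modifications[[k]]
    out <- list(index = k, label = labels[[k]], seed = seeds[[k]],
                error = NULL, results = list(), data = NULL)
    res <- tryCatch({
      sp <- apply_modifications(spec, mods, mech_paths)
      model <- build_model(sp, mech_paths)
      attr(model, "varied") <- lapply(mods, function(md) {
        list(object = md$object, parameter = md$parameter, value = md$value)
      })
      o <- opts; o$seed <- seeds[[k]]
      integrate_model(model, o)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      return(out)
    }
    d <- res
    for (hn in names(hooks)) {
      hr <- tryCatch(hooks[[hn]](d), error = function(e) {
        structure(list(message = conditionMessage(e)), class = "hook_error")
      })
      out$results[[hn]] <- hr
    }
    if (!is.null(study_dir)) {
      sdir <- file.path(study_dir, labels[[k]])
      write_simdata(d, sdir)
      for (hn in names(out$results)) {
        hr <- out$results[[hn]]
        payload <- if (inherits(hr, "hook_error")) {
          list(error = hr$message)
        } else hr
        jsonlite::write_json(payload, file.path(sdir, sprintf("result_%s.json", hn)),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             force = TRUE)
      }
    }
    if (keep_data) out$data <- d
    out
  }

  runs <- if (parallel) {
    parallel::mclapply(seq_len(n), one, mc.cores = cores)
  } else {
    lapply(seq_len(n), one)
  }

  index <- data.frame(
    index = seq_len(n), label = labels, seed = seeds,
    status = vapply(runs, function(r) if (is.null(r$error)) "ok" else "error", ""),
    stringsAsFactors = FALSE)

  if (!is.null(study_dir)) {
    jsonlite::write_json(list(
      n = n,
      master_seed = opts$seed,
      options = unclass(opts),
      hooks = as.list(names(hooks)),
      simulations = lapply(seq_len(n), function(k) list(
        index = k, label = labels[[k]], seed = seeds[[k]],
        status = index$status[[k]],
        error = runs[[k]]$error,
        varied = lapply(plan$modifications[[k]], function(md) {
          list(object = md$object, parameter = md$parameter, value = md$value)
        })))),
      file.path(study_dir, "index.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(vapply(seq_len(n), function(k) {
      sprintf("neurodyn-worker --study %s --sim %d --seed %d", study_dir, k, seeds[[k]])
    }, ""), file.path(study_dir, "jobs.manifest"))
  }

  structure(list(
    index = index,
    results = lapply(runs, `[[`, "results"),
    data = if (keep_data) lapply(runs, `[[`, "data") else NULL,
    errors = stats::setNames(lapply(runs, `[[`, "error"), labels),
    plan = plan, study_dir = study_dir), class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  ok <- sum(x$index$status == "ok")
  cat(sprintf("<study_results: %d simulation(s), %d ok%s>\n", nrow(x$index), ok,
              if (!is.null(x$study_dir)) paste0(", at ", x$study_dir) else ""))
  invisible(x)
}

#' Import results from a study directory
#'
#' Loads either the stored analysis results of one hook, or the full
#' simulated data, from a directory written by [run_batch()]. Entries come
#' back in plan order; simulations that failed (or whose files are missing)
#' are flagged in `missing` and returned as `NULL`.
#'
#' @param study_dir Study directory containing `index.json`.
#' @param what A hook name, or `"data"` for the simulated data.
#' @return A list with `items` (per-simulation results or `sim_data`),
#'   `index` (data.frame), `missing` (logical vector).
#' @export
import_results <- function(study_dir, what = "data") {
  idx_file <- file.path(study_dir, "index.json")
  if (!file.exists(idx_file)) {
    stop(sprintf("no index.json in '%s': not a study directory", study_dir),
         call. = FALSE)
  }
  idx <- jsonlite::fromJSON(idx_file, simplifyVector = FALSE)
  sims <- idx$simulations
  items <- vector("list", length(sims))
  missing <- logical(length(sims))
  for (k in seq_along(sims)) {
    s <- sims[[k]]
    sdir <- file.path(study_dir, s$label)
    got <- tryCatch({
      if (identical(what, "data")) {
        read_simdata(sdir)
      } else {
        rf <- file.path(sdir, sprintf("result_%s.json", what))
        if (!file.exists(rf)) stop("missing result file")
        jsonlite::fromJSON(rf, simplifyVector = TRUE)
      }
    }, error = function(e) NULL)
    bad <- is.null(got) || !is.null(s$error) ||
      (is.list(got) && !is.null(got$error))
    items[[k]] <- got
    missing[[k]] <- bad
  }
  list(items = items,
       index = data.frame(
         index = vapply(sims, `[[`, 0L, "index"),
         label = vapply(sims, `[[`, "", "label"),
         seed = vapply(sims, function(s) as.integer(s$seed), 0L),
         status = vapply(sims, `[[`, "", "status"),
         stringsAsFactors = FALSE),
       missing = missing)
}
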