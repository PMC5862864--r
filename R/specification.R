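# High-level model specification: populations, connections, inline
# mechanisms. A bare equation string is standardized into a one-population
# specification named "pop1".

#' Define a population
#'
#' @param name Population name (unique within a specification).
#' @param size Number of identical units (cells/compartments), >= 1.
#' @param equations Equation text, an `equation_set`, or the name of a
#'   library population object (e.g. `"HH"`).
#' @param mechanism_list Character vector of mechanism names inserted into
#'   the population's linker placeholders, in order.
#' @param parameters Named list of parameter overrides; each value a scalar
#'   (broadcast over the population) or an array of length `size`.
#' @return A `population_spec`.
#' @export
population <- function(name, size = 1L, equations = NULL,
                       mechanism_list = character(0), parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    stop(sprintf("invalid population name '%s'", name), call. = FALSE)
  }
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("population size must be >= 1", call. = FALSE)
  structure(list(name = name, size = size, equations = equations,
                 mechanism_list = as.character(mechanism_list),
                 parameters = as.list(parameters)),
            class = "population_spec")
}

#' Define a connection between populations
#'
#' @param source Name of the presynaptic (source) population.
#' @param target Name of the postsynaptic (target) population.
#' @param mechanism_list Connection mechanism names, in order.
#' @param parameters Named list of overrides; may include `netcon`, an
#'   explicit connectivity matrix of shape (target size x source size).
#' @return A `connection_spec`.
#' @export
connection <- function(source, target, mechanism_list = character(0),
                       parameters = list()) {
  stopifnot(is.character(source), is.character(target))
  structure(list(source = source, target = target,
                 mechanism_list = as.character(mechanism_list),
                 parameters = as.list(parameters)),
            class = "connection_spec")
}

#' Assemble a model specification
#'
#' @param populations List of [population()] objects (or a single one).
#' @param connections List of [connection()] objects.
#' @param mechanisms Named list of inline mechanism definitions (equation
#'   text or `equation_set`s); inline definitions override same-named
#'   library files.
#' @return A `specification`.
#' @export
specification <- function(populations = list(), connections = list(),
                          mechanisms = list()) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (inherits(connections, "connection_spec")) connections <- list(connections)
  structure(list(populations = populations, connections = connections,
                 mechanisms = mechanisms),
            class = "specification")
}

#' Standardize a model specification
#'
#' Accepts the full range of user inputs -- a bare equation string (or
#' character vector), an `equation_set`, a `population_spec`, or a
#' `specification` -- and returns a canonical `specification`: bare
#' equations become a single population named `"pop1"` of size 1 (unless the
#' equations carry an explicit size), defaults are filled in, and names are
#' checked. Standardization is idempotent.
#'
#' @param spec_input Model input in any supported form.
#' @return A validated `specification`.
#' @examples
#' s <- standardize("dx/dt = -x; x(0) = 1")
#' s$populations[[1]]$name
#' @export
standardize <- function(spec_input) {
  if (is.character(spec_input)) {
    spec_input <- parse_equations(spec_input)
  }
  if (inherits(spec_input, "equation_set")) {
    spec_input <- population("pop1", size = 1L, equations = spec_input,
                             mechanism_list = spec_input$mechanism_list)
  }
  if (inherits(spec_input, "population_spec")) {
    spec_input <- specification(populations = list(spec_input))
  }
  if (is.list(spec_input) && !inherits(spec_input, "specification")) {
    known <- c("populations", "connections", "mechanisms")
    bad <- setdiff(names(spec_input), known)
    if (length(bad)) {
      stop(sprintf("unknown specification field(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    spec_input <- specification(populations = spec_input$populations %||% list(),
                                connections = spec_input$connections %||% list(),
                                mechanisms = spec_input$mechanisms %||% list())
  }
  if (!inherits(spec_input, "specification")) {
    stop("cannot standardize input of class ",
         paste(class(spec_input), collapse = "/"), call. = FALSE)
  }
  spec <- spec_input
  if (length(spec$populations) == 0L) {
    stop("specification has no populations", call. = FALSE)
  }
  spec$populations <- lapply(spec$populations, function(p) {
    if (is.character(p) || inherits(p, "equation_set")) {
      p <- population("pop1", equations = p)
    }
    if (!inherits(p, "population_spec")) {
      bad <- setdiff(names(p), c("name", "size", "equations", "mechanism_list",
                                 "parameters"))
      if (length(bad)) {
        stop(sprintf("unknown population field(s): %s", paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      p <- population(p$name %||% "pop1", p$size %||% 1L, p$equations,
                      p$mechanism_list %||% character(0), p$parameters %||% list())
    }
    # fold a mechanism list declared inside the equations into the spec
    if (inherits(p$equations, "equation_set") &&
        length(p$equations$mechanism_list)) {
      p$mechanism_list <- union(p$equations$mechanism_list, p$mechanism_list)
    }
    p
  })
  nms <- vapply(spec$populations, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate population name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  spec$connections <- lapply(spec$connections, function(cn) {
    if (!inherits(cn, "connection_spec")) {
      bad <- setdiff(names(cn), c("source", "target", "mechanism_list", "parameters"))
      if (length(bad)) {
        stop(sprintf("unknown connection field(s): %s", paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      cn <- connection(cn$source, cn$target, cn$mechanism_list %||% character(0),
                       cn$parameters %||% list())
    }
    for (endpoint in c(cn$source, cn$target)) {
      if (!(endpoint %in% nms)) {
        stop(sprintf("connection references unknown population '%s'", endpoint),
             call. = FALSE)
      }
    }
    cn
  })
  if (length(spec$mechanisms)) {
    if (is.null(names(spec$mechanisms)) || any(!nzchar(names(spec$mechanisms)))) {
      stop("inline mechanisms must be a named list", call. = FALSE)
    }
    spec$mechanisms <- lapply(stats::setNames(names(spec$mechanisms),
                                              names(spec$mechanisms)),
                              function(nm) {
      m <- spec$mechanisms[[nm]]
      if (is.character(m)) m <- parse_equations(m, name = nm, context = "mechanism")
      if (!inherits(m, "equation_set")) {
        stop(sprintf("inline mechanism '%s' must be equation text or an equation_set", nm),
             call. = FALSE)
      }
      m$name <- nm
      m
    })
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a specification from a JSON file
#'
#' The JSON dialect mirrors the in-memory structure: top-level keys
#' `populations` (list of objects with `name`, `size`, `equations`,
#' `mechanism_list`, `parameters`), `connections` (`source`, `target`,
#' `mechanism_list`, `parameters`) and `mechanisms` (name -> equation text).
#' Equations are given as strings in the equation dialect. A schema ships
#' with the package (`inst/schema/specification.schema.json`).
#'
#' @param path Path to a JSON specification file.
#' @return A standardized `specification`.
#' @export
read_specification <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fix_params <- function(p) {
    lapply(p %||% list(), function(v) {
      if (is.list(v)) {
        if (!is.null(v$matrix)) {
          # {"matrix": [[...],[...]]} row-major connectivity
          do.call(rbind, lapply(v$matrix, function(r) as.numeric(unlist(r))))
        } else as.numeric(unlist(v))
      } else if (is.numeric(v)) as.numeric(v) else v
    })
  }
  pops <- lapply(doc$populations %||% list(), function(p) {
    population(p$name %||% "pop1", p$size %||% 1L,
               paste(unlist(p$equations), collapse = "\n"),
               unlist(p$mechanism_list) %||% character(0),
               fix_params(p$parameters))
  })
  cons <- lapply(doc$connections %||% list(), function(cn) {
    connection(cn$source, cn$target,
               unlist(cn$mechanism_list) %||% character(0),
               fix_params(cn$parameters))
  })
  mechs <- lapply(doc$mechanisms %||% list(), function(m) {
    paste(unlist(m), collapse = "\n")
  })
  standardize(specification(pops, cons, mechs))
}

#' Write a specification to a JSON file
#'
#' @param spec A `specification` (standardized first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specification <- function(spec, path) {
  spec <- standardize(spec)
  as_params <- function(p) {
    lapply(p, function(v) {
      if (is.matrix(v)) list(matrix = lapply(seq_len(nrow(v)), function(i) v[i, ]))
      else v
    })
  }
  doc <- list(
    populations = lapply(spec$populations, function(p) {
      eqs <- p$equations
      if (inherits(eqs, "equation_set")) eqs <- serialize_equations(eqs)
      list(name = p$name, size = p$size, equations = eqs,
           mechanism_list = as.list(p$mechanism_list),
           parameters = as_params(p$parameters))
    }),
    connections = lapply(spec$connections, function(cn) {
      list(source = cn$source, target = cn$target,
           mechanism_list = as.list(cn$mechanism_list),
           parameters = as_params(cn$parameters))
    }),
    mechanisms = lapply(spec$mechanisms, serialize_equations)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.specification <- function(x, ...) {
  cat("<specification>\n")
  for (p in x$populations) {
    cat(sprintf("  population %s (n=%d)%s\n", p$name, p$size,
                if (length(p$mechanism_list))
                  paste0(" {", paste(p$mechanism_list, collapse = ","), "}") else ""))
  }
  for (cn in x$connections) {
    cat(sprintf("  connection %s->%s {%s}\n", cn$source, cn$target,
                paste(cn$mechanism_list, collapse = ",")))
  }
  if (length(x$mechanisms)) {
    cat(sprintf("  inline mechanisms: %s\n", paste(names(x$mechanisms), collapse = ", ")))
  }
  invisible(x)
}
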