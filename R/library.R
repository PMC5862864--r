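# Prepackaged model-object library: ionic mechanisms, synapses, inputs and
# population templates, stored as plain-text files in the equation dialect
# under inst/library/{mechanisms,populations}. The first comment line of a
# file is its description/citation; a "% kind:" line classifies it.

#' Default library search paths
#'
#' Directories searched for mechanism (`.mech`) and population (`.pop`)
#' files. User-supplied paths are searched before the packaged library, so
#' same-named user files shadow packaged ones.
#'
#' @param extra Character vector of additional directories (searched first).
#' @return Character vector of existing directories.
#' @export
library_paths <- function(extra = character(0)) {
  pkg <- system.file("library", package = "neurodyn")
  paths <- c(extra,
             file.path(pkg, "mechanisms"),
             file.path(pkg, "populations"))
  paths[dir.exists(paths)]
}

.scan_header <- function(path) {
  lines <- readLines(path, n = 6L, warn = FALSE)
  cite <- ""
  kind <- NA_character_
  for (l in lines) {
    if (!grepl("^\\s*[%#]", l)) break
    body <- trimws(sub("^\\s*[%#]+\\s*", "", l))
    km <- regmatches(body, regexec("^kind:\\s*(\\w+)$", body))[[1]]
    if (length(km) == 2L) kind <- km[[2]]
    else if (!nzchar(cite)) cite <- body
  }
  list(citation = cite, kind = kind)
}

#' List packaged model objects
#'
#' Builds an index of every model object found on the library search paths,
#' optionally filtered by kind. Kinds follow the library grouping:
#' `"input"` (drive sources), `"intrinsic"` (ion currents depending only on
#' the host population), `"connection"` (synapses/junctions reading a source
#' population), and `"population"` (complete neuron templates).
#'
#' @param kind Optional filter, one of `"input"`, `"intrinsic"`,
#'   `"connection"`, `"population"`.
#' @param paths Library search paths (see [library_paths()]).
#' @return A data.frame with columns `name`, `kind`, `file`, `citation`,
#'   sorted alphabetically by name.
#' @examples
#' \donttest{list_objects("population")}
#' @export
list_objects <- function(kind = NULL, paths = library_paths()) {
  if (!is.null(kind) &&
      !kind %in% c("input", "intrinsic", "connection", "population")) {
    stop(sprintf("unknown object kind '%s'", kind), call. = FALSE)
  }
  rows <- list()
  seen <- character(0)
  for (p in paths) {
    files <- list.files(p, pattern = "\\.(mech|pop)$", full.names = TRUE)
    for (f in files) {
      nm <- sub("\\.[A-Za-z]+$", "", basename(f))
      if (nm %in% seen) next  # earlier path shadows
      seen <- c(seen, nm)
      hdr <- .scan_header(f)
      k <- hdr$kind
      if (is.na(k)) k <- if (grepl("\\.pop$", f)) "population" else "intrinsic"
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, kind = k, file = f, citation = hdr$citation,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), kind = character(0),
                      file = character(0), citation = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- do.call(rbind, rows)
  if (!is.null(kind)) idx <- idx[idx$kind == kind, , drop = FALSE]
  idx <- idx[order(idx$name), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

# find one object file by name; NULL if absent
find_object <- function(name, paths = library_paths()) {
  idx <- list_objects(paths = paths)
  hit <- idx$file[idx$name == name]
  if (length(hit)) hit[[1]] else NULL
}

# declared parameter names of a library object (including, for populations,
# the parameters of its listed mechanisms)
.object_parameter_names <- function(eq, paths = library_paths()) {
  nms <- names(eq$parameters)
  for (m in eq$mechanism_list) {
    f <- find_object(m, paths)
    if (!is.null(f)) {
      nms <- c(nms, names(parse_mechanism_file(f)$parameters))
    }
  }
  unique(nms)
}

#' Instantiate a library object
#'
#' Loads a packaged (or user-path) model object by name and applies
#' parameter overrides. Overrides may target the object's own parameters or
#' parameters of any mechanism in its mechanism list (routed by name at
#' build time); overriding a parameter that exists nowhere is an error.
#' Override values are taken as-is: no unit or sign policing is performed.
#'
#' @param name Object name (e.g. `"HH"`, `"Izh"`, `"iGABAa"`).
#' @param size Population size the object will be instantiated at (stored
#'   for use by [build_model()]; mechanisms ignore it).
#' @param parameters Named list of parameter overrides.
#' @param mechanisms Additional mechanism names appended to the object's
#'   mechanism list (e.g. adding `"noise"` to `"HH"`).
#' @param paths Library search paths.
#' @return An `equation_set` with `mechanism_list` filled in.
#' @examples
#' \donttest{izh <- instantiate("Izh")}
#' @export
instantiate <- function(name, size = 1L, parameters = list(),
                        mechanisms = character(0), paths = library_paths()) {
  f <- find_object(name, paths)
  if (is.null(f)) stop(sprintf("model object '%s' not found in library", name),
                       call. = FALSE)
  eq <- parse_mechanism_file(f)
  eq$mechanism_list <- union(eq$mechanism_list, mechanisms)
  known <- .object_parameter_names(eq, paths)
  for (nm in names(parameters)) {
    if (!(nm %in% known)) {
      stop(sprintf("override of nonexistent parameter '%s' in object '%s'", nm, name),
           call. = FALSE)
    }
    eq$parameters[[nm]] <- parameters[[nm]]
  }
  attr(eq, "size") <- as.integer(size)
  eq
}
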