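# On-disk representation of simulated data: one directory per simulation
# holding plain-text files (states.csv, spikes.csv, metadata.json), the
# same layout the standalone emitted solver writes. Analysis hook results
# are stored beside them as result_<hook>.json.

#' Write simulated data to a directory
#'
#' @param data A `sim_data`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simdata <- function(data, dir) {
  stopifnot(inherits(data, "sim_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- lapply(data$series, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = 1L) else m
  })
  df <- do.call(cbind, unname(cols))
  colnames(df) <- unlist(lapply(names(cols), function(nm) {
    paste(nm, seq_len(ncol(cols[[nm]])), sep = ".")
  }))
  utils::write.csv(cbind(time = data$time, df),
                   file.path(dir, "states.csv"), row.names = FALSE)
  spk <- do.call(rbind, lapply(names(data$spikes), function(pn) {
    s <- data$spikes[[pn]]
    if (!sum(lengths(s))) return(NULL)
    data.frame(population = pn, cell = rep(seq_along(s), lengths(s)),
               time = unlist(s, use.names = FALSE))
  }))
  if (is.null(spk)) {
    spk <- data.frame(population = character(0), cell = integer(0),
                      time = numeric(0))
  }
  utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
  meta <- data$metadata
  meta$pop_sizes <- lapply(data$spikes, length)
  meta$options <- unclass(meta$options)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read simulated data from a directory
#'
#' @param dir Directory previously written by [write_simdata()] (or by an
#'   emitted standalone solver, in which case metadata may be absent).
#' @return A `sim_data`.
#' @export
read_simdata <- function(dir) {
  sf <- file.path(dir, "states.csv")
  if (!file.exists(sf)) stop(sprintf("no states.csv in %s", dir), call. = FALSE)
  st <- utils::read.csv(sf, check.names = FALSE)
  time <- st[["time"]]
  cn <- setdiff(colnames(st), "time")
  base <- sub("\\.[0-9]+$", "", cn)
  series <- lapply(split(cn, factor(base, levels = unique(base))), function(cols) {
    m <- as.matrix(st[, cols, drop = FALSE])
    dimnames(m) <- NULL
    m
  })
  meta <- NULL
  mf <- file.path(dir, "metadata.json")
  if (file.exists(mf)) meta <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  spikes <- list()
  spf <- file.path(dir, "spikes.csv")
  if (file.exists(spf)) {
    spk <- utils::read.csv(spf)
    sizes <- if (!is.null(meta$pop_sizes)) meta$pop_sizes else list()
    pops <- unique(c(names(sizes), unique(spk$population)))
    for (pn in pops) {
      n <- sizes[[pn]]
      sub <- spk[spk$population == pn, , drop = FALSE]
      if (is.null(n)) n <- max(sub$cell, 1L)
      spikes[[pn]] <- split(sub$time, factor(sub$cell, levels = seq_len(n)))
    }
  }
  structure(list(time = time, series = series, spikes = spikes,
                 metadata = meta), class = "sim_data")
}
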