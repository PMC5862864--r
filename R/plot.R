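# Thin base-graphics renderers over sim_data: state traces and spike
# rasters.

#' Plot recorded state traces
#'
#' @param x A `sim_data`.
#' @param name Series to plot (default: the first recorded series).
#' @param cells Which cells to draw (default: up to 10).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sim_data <- function(x, name = NULL, cells = NULL, ...) {
  if (is.null(name)) name <- names(x$series)[[1]]
  m <- x$series[[name]]
  if (is.null(m)) stop(sprintf("series '%s' was not recorded", name), call. = FALSE)
  if (is.null(cells)) cells <- seq_len(min(10L, ncol(m)))
  graphics::matplot(x$time, m[, cells, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = name, ...)
  invisible(x)
}

#' Plot a spike raster
#'
#' One row per cell, one tick per spike, populations stacked and
#' color-coded.
#'
#' @param data A `sim_data`.
#' @param populations Populations to include (default: all).
#' @param ... Passed to [graphics::plot()].
#' @return The combined raster data.frame, invisibly.
#' @export
plot_raster <- function(data, populations = NULL, ...) {
  stopifnot(inherits(data, "sim_data"))
  if (is.null(populations)) populations <- names(data$spikes)
  offset <- 0L
  rows <- list()
  for (pn in populations) {
    r <- raster(data, pn)
    r$row <- r$cell + offset
    r$population <- pn
    offset <- offset + length(data$spikes[[pn]])
    rows[[pn]] <- r
  }
  all <- do.call(rbind, rows)
  graphics::plot(all$time, all$row, pch = "|", cex = 0.6,
                 col = match(all$population, populations),
                 xlab = "time (ms)", ylab = "cell", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(offset), labels = FALSE, tcl = -0.2)
  invisible(all)
}
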