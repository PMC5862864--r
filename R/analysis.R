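# Built-in post-simulation analyses: firing rates, power spectra,
# magnitude-squared coherence, and raster extraction. All are usable
# standalone or as batch hooks (see run_batch()).

#' Mean firing rate over an analysis window
#'
#' Whole-window spike counts divided by the window length. By default the
#' window is the simulated interval minus an initial transient (50 ms),
#' which avoids onset artifacts.
#'
#' @param data A `sim_data`.
#' @param population Population name; defaults to the first.
#' @param window Length-2 numeric (ms); default `c(t0 + transient, t1)`.
#' @param transient Initial transient to discard (ms) when `window` is
#'   NULL; capped at half the simulated span so short runs keep a
#'   non-empty window.
#' @return A `rate_result`: `per_cell` (spikes/s), `mean`, `window`.
#' @examples
#' \donttest{
#' d <- integrate_model(population("pop1", 1, "HH", parameters = list(Iapp = 10)))
#' firing_rate(d)$mean
#' }
#' @export
firing_rate <- function(data, population = NULL, window = NULL, transient = 50) {
  stopifnot(inherits(data, "sim_data"))
  if (is.null(population)) population <- names(data$spikes)[[1]]
  spk <- data$spikes[[population]]
  if (is.null(spk)) {
    stop(sprintf("no spike data for population '%s'", population), call. = FALSE)
  }
  t0 <- data$time[[1]]; t1 <- data$time[[length(data$time)]]
  if (is.null(window)) {
    window <- c(t0 + min(transient, (t1 - t0) / 2), t1)
  }
  if (window[[2]] <= window[[1]]) stop("empty analysis window", call. = FALSE)
  len_s <- (window[[2]] - window[[1]]) / 1000
  per_cell <- vapply(spk, function(ts) {
    sum(ts >= window[[1]] & ts <= window[[2]]) / len_s
  }, 0)
  structure(list(per_cell = per_cell, mean = mean(per_cell), window = window,
                 population = population),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result '%s': mean %.2f spikes/s over [%g, %g] ms, %d cell(s)>\n",
              x$population, x$mean, x$window[[1]], x$window[[2]], length(x$per_cell)))
  invisible(x)
}

# resolve a signal argument to a time-by-cells matrix + sampling step (ms)
.get_signal <- function(data, signal) {
  if (inherits(data, "sim_data")) {
    if (is.null(data$series[[signal]])) {
      stop(sprintf("signal '%s' was not recorded", signal), call. = FALSE)
    }
    list(x = data$series[[signal]], dt = diff(data$time[1:2]))
  } else {
    x <- data
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    list(x = x, dt = signal)  # (matrix, dt) calling form
  }
}

# one-sided periodogram of a mean-subtracted vector; power normalized so
# that sum(power) equals the (population) variance of the input
.periodogram <- function(x, fs, detrend = TRUE) {
  n <- length(x)
  if (detrend) x <- x - mean(x)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  freq <- (0:half) * fs / n
  pow <- p2[1:(half + 1)]
  # fold the negative frequencies in (skip DC; skip Nyquist when n is even)
  idx <- 2:(half + 1)
  fold <- if (n %% 2 == 0) idx[-length(idx)] else idx
  pow[fold] <- 2 * pow[fold]
  list(freq = freq, power = pow)
}

#' Power spectrum of a recorded signal
#'
#' Discrete-Fourier periodogram (rectangular window) of each cell's trace,
#' averaged over cells, with optional mean subtraction (on by default). The
#' normalization satisfies Parseval's identity: the summed periodogram
#' equals the signal variance. The reported peak excludes the DC bin.
#'
#' @param data A `sim_data`, or a numeric vector/matrix (time by cells); in
#'   the latter case pass the sampling step (ms) as `signal`.
#' @param signal Recorded series name (or the sampling step when `data` is
#'   a plain matrix).
#' @param detrend Subtract the mean before transforming (default TRUE).
#' @return A `spectrum_result`: `freq` (Hz), `power` (cell-averaged),
#'   `peak_hz`.
#' @export
power_spectrum <- function(data, signal = NULL, detrend = TRUE) {
  if (inherits(data, "sim_data") && is.null(signal)) {
    signal <- names(data$series)[[1]]
  }
  sg <- .get_signal(data, signal)
  fs <- 1000 / sg$dt  # Hz
  specs <- lapply(seq_len(ncol(sg$x)), function(j) {
    .periodogram(sg$x[, j], fs, detrend)
  })
  pow <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  freq <- specs[[1]]$freq
  peak <- freq[-1][which.max(pow[-1])]
  structure(list(freq = freq, power = pow, peak_hz = peak,
                 n_cells = ncol(sg$x)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result: %d bins up to %.1f Hz, peak at %.2f Hz>\n",
              length(x$freq), max(x$freq), x$peak_hz))
  invisible(x)
}

# Hann window
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Magnitude-squared coherence between two signals
#'
#' Welch-style estimate: the signals are cut into `nseg` segments with
#' `overlap` fractional overlap, windowed (Hann by default), and the
#' averaged cross- and auto-spectra combined into
#' `|Sxy|^2 / (Sxx * Syy)`, which lies in `[0, 1]`. With K independent
#' segments the estimate for unrelated signals is biased upward by
#' approximately 1/K, so prefer more segments for null comparisons.
#'
#' @param x,y Equal-length numeric vectors (cell-averaged signals), or `x`
#'   a `sim_data` with `x_name`/`y_name` naming recorded series.
#' @param dt Sampling step in ms (taken from the `sim_data` when given).
#' @param nseg Number of segments (default 8; at least 2 required).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @param x_name,y_name Series names when `x` is a `sim_data`.
#' @return A `coherence_result`: `freq` (Hz), `coherence`.
#' @export
coherence <- function(x, y = NULL, dt = NULL, nseg = 8L, overlap = 0.5,
                      window = c("hann", "rectangular"),
                      x_name = NULL, y_name = NULL) {
  window <- match.arg(window)
  if (inherits(x, "sim_data")) {
    d <- x
    dt <- diff(d$time[1:2])
    x <- rowMeans(d$series[[x_name]])
    y <- rowMeans(d$series[[y_name]])
  }
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  if (is.null(dt)) stop("sampling step dt (ms) required", call. = FALSE)
  n <- length(x)
  nseg <- as.integer(nseg)
  if (nseg < 2L) stop("coherence requires at least 2 segments", call. = FALSE)
  # segment length L with hop h = L*(1-overlap): n = L + (nseg-1)*h
  L <- floor(n / (1 + (nseg - 1) * (1 - overlap)))
  if (L < 8L) stop("signals too short for the requested segmentation", call. = FALSE)
  h <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, by = h, length.out = nseg)
  starts <- starts[starts + L - 1L <= n]
  w <- if (window == "hann") .hann(L) else rep(1, L)
  half <- floor(L / 2)
  Sxx <- Syy <- numeric(half + 1)
  Sxy <- complex(half + 1)
  for (s0 in starts) {
    xs <- (x[s0:(s0 + L - 1L)] - mean(x[s0:(s0 + L - 1L)])) * w
    ys <- (y[s0:(s0 + L - 1L)] - mean(y[s0:(s0 + L - 1L)])) * w
    X <- stats::fft(xs)[1:(half + 1)]
    Y <- stats::fft(ys)[1:(half + 1)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  fs <- 1000 / dt
  freq <- (0:half) * fs / L
  structure(list(freq = freq, coherence = coh, nseg = length(starts),
                 window = window, overlap = overlap),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result: %d bins, %d segments (%s window, %.0f%%%% overlap)>\n",
              length(x$freq), x$nseg, x$window, 100 * x$overlap))
  invisible(x)
}

#' Raster of spike events
#'
#' @param data A `sim_data`.
#' @param population Population name; defaults to the first.
#' @return A data.frame with columns `cell` (1-based index) and `time`
#'   (ms), sorted by time.
#' @export
raster <- function(data, population = NULL) {
  stopifnot(inherits(data, "sim_data"))
  if (is.null(population)) population <- names(data$spikes)[[1]]
  spk <- data$spikes[[population]]
  if (is.null(spk)) {
    stop(sprintf("no spike data for population '%s'", population), call. = FALSE)
  }
  df <- data.frame(cell = rep(seq_along(spk), lengths(spk)),
                   time = unlist(spk, use.names = FALSE))
  df <- df[order(df$time, df$cell), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Built-in analysis hooks
#'
#' Named hook functions for [run_batch()]: each takes a `sim_data` first and
#' returns a result list. `"firing_rate"` reports the mean rate per
#' population; `"power"` the spectral peak of each population's
#' cell-averaged voltage; `"coherence"` the peak coherence between the
#' first two populations' mean voltages.
#'
#' @return Named list of functions.
#' @export
builtin_hooks <- function() {
  list(
    firing_rate = function(data, transient = 50) {
      rates <- lapply(names(data$spikes), function(pn) {
        firing_rate(data, pn, transient = transient)$mean
      })
      names(rates) <- names(data$spikes)
      rates
    },
    power = function(data, transient = 50) {
      out <- list()
      keep <- data$time >= data$time[[1]] + transient
      for (pn in names(data$spikes)) {
        # population's designated voltage series: first series whose name
        # starts with the population prefix
        cand <- grep(paste0("^", pn, "_"), names(data$series), value = TRUE)
        if (!length(cand)) next
        x <- rowMeans(data$series[[cand[[1]]]][keep, , drop = FALSE])
        sp <- power_spectrum(matrix(x, ncol = 1), diff(data$time[1:2]))
        out[[pn]] <- list(peak_hz = sp$peak_hz)
      }
      out
    },
    coherence = function(data) {
      pops <- names(data$spikes)
      if (length(pops) < 2L) return(list())
      cand <- vapply(pops[1:2], function(pn) {
        grep(paste0("^", pn, "_"), names(data$series), value = TRUE)[[1]]
      }, "")
      ch <- coherence(data, x_name = cand[[1]], y_name = cand[[2]])
      list(peak_coherence = max(ch$coherence[-1]),
           peak_hz = ch$freq[-1][which.max(ch$coherence[-1])])
    })
}
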