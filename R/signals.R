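# Simulated-EEG construction and spectral / stimulus-locked analysis.

#' Extract the simulated EEG trace
#'
#' The simulated EEG is the sum of all excitatory postsynaptic currents
#' arriving at excitatory cells, recorded during the simulation.
#'
#' @param result an \code{sz_simulation}
#' @return numeric trace with attributes \code{fs_hz} (sampling rate)
#' @export
compute_eeg <- function(result) {
  stopifnot(inherits(result, "sz_simulation"))
  if (is.null(result$eeg))
    stop("simulation carries no EPSC recording; rerun with EEG recording enabled")
  structure(result$eeg, fs_hz = 1000 / result$eeg_dt_ms)
}

#' Periodogram power spectrum
#'
#' Plain rectangular-window periodogram of the mean-subtracted trace,
#' one-sided, normalized so the powers sum to the time-domain variance
#' (Parseval-consistent).
#'
#' @param trace numeric signal; sampling rate from attribute \code{fs_hz} or
#'   the \code{fs_hz} argument
#' @param window analysis window \code{c(start_ms, end_ms)}; default the
#'   whole trace. Must span at least 1 s (coarser windows cannot separate
#'   30 from 40 Hz cleanly).
#' @param detrend subtract the window mean before transforming
#' @param fs_hz sampling rate, Hz
#' @return object of class \code{power_spectrum}: data.frame
#'   (\code{freq_hz}, \code{power}) with attributes \code{resolution_hz}
#'   and \code{window_ms}
#' @export
power_spectrum <- function(trace, window = NULL, detrend = TRUE,
                           fs_hz = attr(trace, "fs_hz") %||% 1000) {
  n_total <- length(trace)
  if (is.null(window)) window <- c(0, n_total * 1000 / fs_hz)
  stopifnot(length(window) == 2, window[1] >= 0,
            window[2] <= n_total * 1000 / fs_hz + 1e-9)
  if (diff(window) < 1000)
    stop("analysis window must span at least 1 s")
  i0 <- floor(window[1] * fs_hz / 1000) + 1
  i1 <- floor(window[2] * fs_hz / 1000)
  x <- as.numeric(trace[i0:min(i1, n_total)])
  if (detrend) x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  nk <- floor(n / 2)
  pow <- (Mod(X[2:(nk + 1)])^2) / n^2
  dbl <- rep(2, nk)
  if (n %% 2 == 0) dbl[nk] <- 1      # Nyquist bin is not mirrored
  pow <- pow * dbl
  freq <- (1:nk) * fs_hz / n
  structure(data.frame(freq_hz = freq, power = pow),
            resolution_hz = fs_hz / n, window_ms = window,
            class = c("power_spectrum", "data.frame"))
}

#' Band power around a target frequency
#'
#' Sum of spectral power over bins within \code{halfwidth} of \code{f}. The
#' default 1.5 Hz halfwidth absorbs leakage from finite windows while still
#' separating the 20/30/40 Hz components of interest.
#'
#' @param spectrum a \code{power_spectrum}
#' @param f target frequency, Hz
#' @param halfwidth halfwidth of the band, Hz (must be at least the
#'   spectral resolution)
#' @return summed power (scalar)
#' @export
band_power <- function(spectrum, f, halfwidth = 1.5) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  res <- attr(spectrum, "resolution_hz")
  if (halfwidth < res)
    stop(sprintf("halfwidth %.3f Hz below spectral resolution %.3f Hz",
                 halfwidth, res))
  if (f < min(spectrum$freq_hz) - halfwidth || f > max(spectrum$freq_hz) + halfwidth)
    stop("target frequency outside the spectrum range")
  sum(spectrum$power[abs(spectrum$freq_hz - f) <= halfwidth])
}

#' Band-power triple for one condition pair
#'
#' Convenience constructor of the (P40 at 40 Hz drive, P20 at 40 Hz drive,
#' P30 at 30 Hz drive) triple used by the illness metrics.
#'
#' @param p40_40,p20_40,p30_30 non-negative powers
#' @return object of class \code{band_powers}
#' @export
band_powers <- function(p40_40, p20_40, p30_30) {
  stopifnot(p40_40 >= 0, p20_40 >= 0, p30_30 >= 0)
  structure(list(p40_40 = p40_40, p20_40 = p20_40, p30_30 = p30_30),
            class = "band_powers")
}

#' Extract the band-power triple from a 40 Hz and a 30 Hz run
#'
#' @param result_40,result_30 \code{sz_simulation} results under 40 and
#'   30 Hz drive
#' @param transient_ms onset transient discarded before the spectrum
#' @param halfwidth band halfwidth, Hz
#' @return a \code{band_powers} object
#' @export
extract_band_powers <- function(result_40, result_30,
                                transient_ms = NULL, halfwidth = 1.5) {
  tr40 <- compute_eeg(result_40)
  tr30 <- compute_eeg(result_30)
  t40 <- transient_ms %||% result_40$provenance$sim_config$transient_ms
  t30 <- transient_ms %||% result_30$provenance$sim_config$transient_ms
  fs <- attr(tr40, "fs_hz")
  s40 <- power_spectrum(tr40, window = c(t40, length(tr40) * 1000 / fs))
  s30 <- power_spectrum(tr30, window = c(t30, length(tr30) * 1000 / fs))
  band_powers(band_power(s40, 40, halfwidth),
              band_power(s40, 20, halfwidth),
              band_power(s30, 30, halfwidth))
}

# infer the constant click period of a periodic train; error for irregular
# (poisson) trains where stimulus locking is undefined
.train_period <- function(train) {
  stopifnot(inherits(train, "event_train"))
  d <- diff(train$times)
  if (length(d) < 1) stop("train has too few events for locking")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("stimulus locking is undefined for irregular (poisson) trains")
  mean(d)
}

#' Stimulus-locked EEG average over consecutive drive cycles
#'
#' Segments aligned to every \code{n_cycles}-th click (starting at the first
#' click after the transient, so two-cycle phase is preserved) are averaged
#' pointwise.
#'
#' @param trace EEG trace (attribute \code{fs_hz} or argument)
#' @param train the periodic \code{event_train} that drove the run
#' @param n_cycles segment length in drive cycles (2 reproduces the
#'   two-cycle averages used for beat-skipping analysis)
#' @param transient_ms portion of the trace excluded from averaging
#' @param fs_hz sampling rate, Hz
#' @return object of class \code{stim_locked_avg}: \code{avg} (numeric),
#'   \code{bin_ms}, \code{n_segments}
#' @export
stimulus_locked_average <- function(trace, train, n_cycles = 2,
                                    transient_ms = 0,
                                    fs_hz = attr(trace, "fs_hz") %||% 1000) {
  period <- .train_period(train)
  seg_len <- round(n_cycles * period * fs_hz / 1000)
  clicks <- train$times[train$times >= transient_ms]
  starts <- clicks[seq(1, length(clicks), by = n_cycles)]
  idx0 <- floor(starts * fs_hz / 1000) + 1
  idx0 <- idx0[idx0 + seg_len - 1 <= length(trace)]
  if (length(idx0) < 10)
    stop("need at least 10 segments after the transient")
  segs <- vapply(idx0, function(i) as.numeric(trace[i:(i + seg_len - 1)]),
                 numeric(seg_len))
  structure(list(avg = rowMeans(segs), bin_ms = 1000 / fs_hz,
                 n_segments = length(idx0)),
            class = "stim_locked_avg")
}

#' Stimulus-locked spike histogram
#'
#' Spike counts binned by phase within \code{n_cycles} consecutive drive
#' cycles, aligned exactly as \code{\link{stimulus_locked_average}}.
#'
#' @param spikes numeric spike times (ms) or a data.frame with a
#'   \code{time_ms} column
#' @param train the periodic \code{event_train}
#' @param bin_ms histogram bin width
#' @param n_cycles cycles per segment
#' @param transient_ms spikes before this time are excluded
#' @return object of class \code{spike_histogram}: \code{counts},
#'   \code{bin_centers_ms}, \code{bin_ms}, \code{n_segments}
#' @export
spike_histogram <- function(spikes, train, bin_ms = 1, n_cycles = 2,
                            transient_ms = 0) {
  if (is.data.frame(spikes)) spikes <- spikes$time_ms
  period <- .train_period(train)
  seg_ms <- n_cycles * period
  clicks <- train$times[train$times >= transient_ms]
  starts <- clicks[seq(1, length(clicks), by = n_cycles)]
  starts <- starts[starts + seg_ms <= train$duration_ms + 1e-9]
  nbin <- max(1, round(seg_ms / bin_ms))
  counts <- integer(nbin)
  n_used <- 0
  for (s0 in starts) {
    sel <- spikes[spikes >= s0 & spikes < s0 + seg_ms]
    if (length(sel) > 0) {
      b <- pmin(floor((sel - s0) / bin_ms) + 1, nbin)
      tb <- tabulate(b, nbins = nbin)
      counts <- counts + tb
    }
    n_used <- n_used + 1
  }
  structure(list(counts = counts,
                 bin_centers_ms = (seq_len(nbin) - 0.5) * bin_ms,
                 bin_ms = bin_ms, n_segments = n_used),
            class = "spike_histogram")
}
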