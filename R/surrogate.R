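# Surrogate data generators: band-power tables over the sweep grid from
# specified generative rules, and synthetic EEG traces with prescribed band
# content. These stand in for full network sweeps so the metric, mutual
# information and signal analyses can be validated in seconds against known
# ground truth.

.bp_cols <- c("p40_40", "p20_40", "p30_30")

#' Surrogate generative rule
#'
#' Expected band powers start from a control \code{baseline} triple and are
#' multiplied by effect terms. Each term names one or more parameters, the
#' instance values at which it fires, and per-band multipliers; a term with
#' one parameter is a "linear" (single-factor) effect, terms with several
#' parameters encode interactions. The \code{"xor"} kind instead binarizes
#' its two parameters (baseline instance vs. not) and applies the
#' multipliers when exactly one bit is set, creating a purely multifactorial
#' code: nothing is visible in either parameter alone. Zero-mean Gaussian
#' noise with sd \code{noise_sd * baseline} is added per band; the control
#' ensemble is drawn i.i.d. around baseline with sd
#' \code{control_sd * baseline}.
#'
#' @param kind "linear", "interaction", "xor" or "custom" (descriptive;
#'   the terms drive the behavior except for "xor")
#' @param terms list of terms: each
#'   \code{list(params=, instances=, mult=c(p40_40=, p20_40=, p30_30=))}
#' @param xor_params for kind "xor": the two parameter names
#' @param xor_mult named multipliers applied when the XOR is true
#' @param baseline named control band powers
#' @param noise_sd,control_sd noise fractions of baseline
#' @param n_controls control ensemble size
#' @param seed RNG seed
#' @return object of class \code{surrogate_rule}
#' @export
surrogate_rule <- function(kind = c("linear", "interaction", "xor", "custom"),
                           terms = list(), xor_params = c("tau_ii", "n_ii"),
                           xor_mult = c(p40_40 = 0.5),
                           baseline = c(p40_40 = 100, p20_40 = 10,
                                        p30_30 = 100),
                           noise_sd = 0, control_sd = 0.05, n_controls = 20,
                           seed = 1) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, control_sd >= 0, n_controls >= 2,
            all(.bp_cols %in% names(baseline)), all(baseline >= 0))
  structure(list(kind = kind, terms = terms, xor_params = xor_params,
                 xor_mult = xor_mult, baseline = baseline,
                 noise_sd = noise_sd, control_sd = control_sd,
                 n_controls = n_controls, seed = seed),
            class = "surrogate_rule")
}

# baseline instance of each parameter (the unchanged network)
.pv_baseline <- c(tau_ie = 6, tau_ii = 6, n_ie = 1, n_ii = 1,
                  w_ie = 1, w_ii = 1)

#' Generate a surrogate band-power table over a grid
#'
#' Deterministic given the rule's seed. Where the rule defines ground-truth
#' labels (the XOR rule), they are included as column \code{truth}.
#'
#' @param grid a \code{sweep_grid} (possibly a reduced sub-grid)
#' @param rule a \code{surrogate_rule}
#' @return object of class \code{surrogate_dataset}: \code{table} (pv
#'   columns, band powers, optional truth), \code{controls} (band powers,
#'   one row per control subject), \code{rule}
#' @export
generate_bandpower_table <- function(grid = sweep_grid(), rule) {
  stopifnot(inherits(rule, "surrogate_rule"))
  pvs <- enumerate_grid(grid)
  n <- nrow(pvs)
  mult <- matrix(1, n, 3, dimnames = list(NULL, .bp_cols))
  truth <- NULL
  if (rule$kind == "xor") {
    b1 <- abs(pvs[[rule$xor_params[1]]] -
                .pv_baseline[[rule$xor_params[1]]]) > 1e-9
    b2 <- abs(pvs[[rule$xor_params[2]]] -
                .pv_baseline[[rule$xor_params[2]]]) > 1e-9
    truth <- as.integer(xor(b1, b2))
    for (band in names(rule$xor_mult))
      mult[truth == 1L, band] <- mult[truth == 1L, band] * rule$xor_mult[[band]]
  }
  for (term in rule$terms) {
    hit <- rep(TRUE, n)
    for (j in seq_along(term$params))
      hit <- hit & abs(pvs[[term$params[j]]] - term$instances[j]) < 1e-9
    for (band in names(term$mult))
      mult[hit, band] <- mult[hit, band] * term$mult[[band]]
  }
  with_seed(rule$seed, {
    tab <- pvs
    for (band in .bp_cols) {
      expected <- rule$baseline[[band]] * mult[, band]
      noise <- if (rule$noise_sd > 0)
        rnorm(n, 0, rule$noise_sd * rule$baseline[[band]]) else 0
      tab[[band]] <- pmax(expected + noise, 0)
    }
    if (!is.null(truth)) tab$truth <- truth
    ctrl <- as.data.frame(lapply(setNames(.bp_cols, .bp_cols), function(band)
      pmax(rule$baseline[[band]] *
             (1 + rnorm(rule$n_controls, 0, rule$control_sd)), 0)))
    structure(list(table = tab, controls = ctrl, rule = rule),
              class = "surrogate_dataset")
  })
}

#' Control statistics of a surrogate dataset
#'
#' @param ds a \code{surrogate_dataset}
#' @return \code{control_stats}
#' @export
surrogate_control_stats <- function(ds) {
  stopifnot(inherits(ds, "surrogate_dataset"))
  control_stats(lapply(seq_len(nrow(ds$controls)), function(i)
    band_powers(ds$controls$p40_40[i], ds$controls$p20_40[i],
                ds$controls$p30_30[i])))
}

#' Synthetic EEG with prescribed band content
#'
#' Sum of sinusoids plus optional white noise; band powers of the result
#' recover the squared relative amplitudes.
#'
#' @param bands data.frame or matrix with columns \code{freq_hz},
#'   \code{amplitude}
#' @param noise_sd white-noise standard deviation
#' @param duration_ms trace duration
#' @param fs_hz sampling rate; every frequency must be below fs_hz/2
#' @param seed RNG seed for the noise
#' @return numeric trace with attribute \code{fs_hz}
#' @export
generate_surrogate_eeg <- function(bands, noise_sd = 0, duration_ms = 10000,
                                   fs_hz = 1000, seed = 1) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("freq_hz", "amplitude") %in% names(bands)))
  if (any(bands$freq_hz >= fs_hz / 2))
    stop("band frequency at or above the Nyquist frequency")
  t_s <- (seq_len(round(duration_ms * fs_hz / 1000)) - 1) / fs_hz
  x <- numeric(length(t_s))
  for (i in seq_len(nrow(bands)))
    x <- x + bands$amplitude[i] * sin(2 * pi * bands$freq_hz[i] * t_s)
  if (noise_sd > 0)
    x <- x + with_seed(seed, rnorm(length(x), 0, noise_sd))
  structure(x, fs_hz = fs_hz)
}

#' Synthetic cycle-skipping EEG
#'
#' A periodic train of smooth pulses at the drive frequency in which every
#' \code{skip_every}-th pulse is scaled by \code{suppress_factor} (0 = full
#' suppression, the beat-skipping mechanism that moves 40 Hz power into the
#' 20 Hz band; 1 or \code{skip_every = Inf} = no skipping). \code{amplitude}
#' scales all pulses, dissociating overall amplitude reduction (40 Hz power
#' falls, 20 Hz unchanged) from cycle skipping (power transfer to the
#' subharmonic).
#'
#' @param drive_hz drive frequency
#' @param duration_ms trace duration
#' @param skip_every suppress every skip_every-th pulse (>= 2, or Inf)
#' @param suppress_factor amplitude factor of suppressed pulses
#' @param amplitude global pulse amplitude
#' @param pulse_width_ms Gaussian pulse width (sd)
#' @param fs_hz sampling rate
#' @return numeric trace with attribute \code{fs_hz}
#' @export
generate_cycle_skipping_eeg <- function(drive_hz = 40, duration_ms = 10000,
                                        skip_every = 2, suppress_factor = 0,
                                        amplitude = 1, pulse_width_ms = 3,
                                        fs_hz = 1000) {
  stopifnot(is.infinite(skip_every) || skip_every >= 2)
  n <- round(duration_ms * fs_hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs_hz
  x <- numeric(n)
  period <- 1000 / drive_hz
  k <- 0
  t0 <- 0
  while (t0 < duration_ms) {
    a <- amplitude
    if (is.finite(skip_every) && (k + 1) %% skip_every == 0)
      a <- a * suppress_factor
    if (a != 0)
      x <- x + a * exp(-0.5 * ((t_ms - t0) / pulse_width_ms)^2)
    k <- k + 1
    t0 <- t0 + period
  }
  structure(x, fs_hz = fs_hz)
}
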