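# Click-train drive and background noise event trains.

#' Stimulus specification
#'
#' Click entrainment drive at rate omega. The default for entrainment runs
#' is a periodic train shared by all cells (the standard auditory
#' steady-state paradigm, giving exact stimulus locking); a Poisson-rate
#' train is retained as an option, either shared or drawn independently per
#' cell.
#'
#' @param mode "periodic" or "poisson"
#' @param rate_hz drive rate omega, Hz (>= 0)
#' @param duration_ms train duration, ms
#' @param shared one train for all cells (TRUE) or independent per-cell
#'   trains (FALSE)
#' @param seed RNG seed (poisson mode)
#' @return object of class \code{stimulus_spec}
#' @export
stimulus_spec <- function(mode = c("periodic", "poisson"), rate_hz = 40,
                          duration_ms = 10000, shared = TRUE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(rate_hz >= 0, duration_ms > 0)
  structure(list(mode = mode, rate_hz = rate_hz, duration_ms = duration_ms,
                 shared = shared, seed = seed), class = "stimulus_spec")
}

event_train <- function(times, duration_ms) {
  times <- as.numeric(times)
  stopifnot(all(times >= 0), all(times < duration_ms),
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, duration_ms = duration_ms),
            class = "event_train")
}

#' Generate a click train
#'
#' Periodic mode places events at k/omega for k = 0, 1, ...; Poisson mode
#' draws a homogeneous Poisson process at rate omega. A zero rate yields an
#' empty train.
#'
#' @param spec a \code{stimulus_spec}
#' @return object of class \code{event_train} (fields \code{times} ms,
#'   \code{duration_ms})
#' @export
generate_click_train <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$rate_hz == 0) return(event_train(numeric(0), spec$duration_ms))
  if (spec$mode == "periodic") {
    period <- 1000 / spec$rate_hz
    k <- 0:ceiling(spec$duration_ms / period)
    times <- k * period
    times <- times[times < spec$duration_ms - 1e-9]
  } else {
    times <- with_seed(spec$seed, {
      n_guess <- ceiling(spec$rate_hz * spec$duration_ms / 1000 * 1.5 + 50)
      t <- cumsum(rexp(n_guess, rate = spec$rate_hz / 1000))
      while (t[length(t)] < spec$duration_ms)
        t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate = spec$rate_hz / 1000)))
      t[t < spec$duration_ms]
    })
  }
  event_train(times, spec$duration_ms)
}

#' Generate independent Poisson background trains
#'
#' One train per target excitatory cell (inhibitory cells receive no
#' background drive).
#'
#' @param rate_hz Poisson rate per train, Hz
#' @param n_targets number of trains (one per E cell)
#' @param duration_ms duration, ms
#' @param seed RNG seed
#' @return list of \code{event_train}
#' @export
generate_background <- function(rate_hz, n_targets, duration_ms, seed = 1) {
  stopifnot(rate_hz >= 0, n_targets >= 0)
  if (rate_hz == 0)
    return(replicate(n_targets, event_train(numeric(0), duration_ms),
                     simplify = FALSE))
  with_seed(seed, {
    lapply(seq_len(n_targets), function(i) {
      n <- stats::rpois(1, rate_hz * duration_ms / 1000)
      event_train(sort(runif(n, 0, duration_ms)), duration_ms)
    })
  })
}

#' Attach a drive pathway to a network
#'
#' Thalamic events reach every excitatory cell and a random 65\% subset of
#' inhibitory cells (the Table of synaptic parameters' thalamic row);
#' background events reach excitatory cells only. The drive-to-cell
#' connection draw is reproducible from \code{seed}.
#'
#' @param net an \code{sz_network}
#' @param trains a single \code{event_train} (shared), a list with one train
#'   per connected cell, or a \code{stimulus_spec} from which the train(s)
#'   are generated
#' @param pathway "thalamic" or "background"
#' @param seed seed for the drive connection draw
#' @return the network with the drive recorded in \code{net$drives}
#' @export
attach_drive <- function(net, trains, pathway = c("thalamic", "background"),
                         seed = net$config$seed) {
  stopifnot(inherits(net, "sz_network"))
  pathway <- match.arg(pathway)
  st <- net$synapse_table
  e_ids <- which(net$cells$class == "E")
  i_ids <- which(net$cells$class == "I")
  from_spec <- inherits(trains, "stimulus_spec")
  shared <- if (from_spec) trains$shared else inherits(trains, "event_train")
  if (!shared && !from_spec)
    stopifnot(is.list(trains), all(vapply(trains, inherits,
                                          logical(1), "event_train")))

  if (pathway == "thalamic") {
    rows <- list(E = st[st$pathway == "ThE", ], I = st[st$pathway == "ThI", ])
    if (nrow(rows$E) == 0 || nrow(rows$I) == 0)
      stop("thalamic pathway has no SynapseSpec in the synapse table")
    i_conn <- with_seed(seed + 777, i_ids[runif(length(i_ids)) < rows$I$p])
    e_conn <- with_seed(seed + 778, e_ids[runif(length(e_ids)) < rows$E$p])
    targets <- list(E = e_conn, I = i_conn)
  } else {
    row_bg <- st[st$pathway == "BgE", ]
    if (nrow(row_bg) == 0)
      stop("background pathway has no SynapseSpec in the synapse table")
    targets <- list(E = e_ids, I = integer(0))
    rows <- list(E = row_bg, I = NULL)
  }
  n_conn <- length(targets$E) + length(targets$I)
  if (from_spec) {
    spec <- trains
    trains <- if (shared) generate_click_train(spec) else
      lapply(seq_len(n_conn), function(i)
        generate_click_train(stimulus_spec(spec$mode, spec$rate_hz,
                                           spec$duration_ms, shared = FALSE,
                                           seed = spec$seed + i)))
  }
  if (!shared && length(trains) != n_conn)
    stop(sprintf("need one train per connected cell (%d), got %d",
                 n_conn, length(trains)))
  net$drives[[pathway]] <- list(trains = trains, shared = shared,
                                targets = targets, spec = rows)
  net
}
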