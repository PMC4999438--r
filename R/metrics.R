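# Illness metrics: control-ensemble statistics, M1/M2/M3, the 30 Hz
# validity gate, top-fraction region extraction and per-parameter instance
# distributions.

#' Control-ensemble band-power statistics
#'
#' Arithmetic means of the three band powers over the control subjects plus
#' the sample standard deviation (n-1 denominator) of the 30 Hz response,
#' which defines the validity gate.
#'
#' @param band_powers_list list of \code{band_powers}, one per control
#'   subject (at least two)
#' @return object of class \code{control_stats}: \code{mean_p40},
#'   \code{mean_p30}, \code{mean_p20}, \code{sd_p30}, \code{n_subjects}
#' @export
control_stats <- function(band_powers_list) {
  stopifnot(length(band_powers_list) >= 1,
            all(vapply(band_powers_list, inherits, logical(1), "band_powers")))
  if (length(band_powers_list) < 2)
    stop("control standard deviation is undefined for a single subject")
  p40 <- vapply(band_powers_list, `[[`, numeric(1), "p40_40")
  p20 <- vapply(band_powers_list, `[[`, numeric(1), "p20_40")
  p30 <- vapply(band_powers_list, `[[`, numeric(1), "p30_30")
  structure(list(mean_p40 = mean(p40), mean_p30 = mean(p30),
                 mean_p20 = mean(p20), sd_p30 = sd(p30),
                 n_subjects = length(band_powers_list)),
            class = "control_stats")
}

#' Illness metric M1: relative 40 Hz reduction
#'
#' M1 = 1 - P40_PV / mean(P40_Ctrl). Zero when the parameter vector matches
#' the control mean, 1 when the 40 Hz response is abolished, negative when
#' it exceeds the control mean. Independent of the validity gate.
#'
#' @param bp \code{band_powers} of the parameter vector
#' @param ctrl \code{control_stats}
#' @return the score
#' @export
compute_M1 <- function(bp, ctrl) {
  stopifnot(inherits(bp, "band_powers"), inherits(ctrl, "control_stats"))
  if (ctrl$mean_p40 <= 0)
    stop("metric undefined: control mean 40 Hz power is zero")
  1 - bp$p40_40 / ctrl$mean_p40
}

#' 30 Hz validity gate
#'
#' A parameter vector is valid when its 30 Hz response under 30 Hz drive
#' lies within three standard deviations of the control mean (boundary
#' inclusive).
#'
#' @inheritParams compute_M1
#' @return logical
#' @export
is_valid <- function(bp, ctrl) {
  stopifnot(inherits(bp, "band_powers"), inherits(ctrl, "control_stats"),
            ctrl$sd_p30 >= 0)
  abs(bp$p30_30 - ctrl$mean_p30) <= 3 * ctrl$sd_p30
}

#' Illness metric M2: 40 Hz reduction gated by 30 Hz validity
#'
#' Vectors whose 30 Hz response deviates from the control band are excluded
#' (score 0); all remaining vectors score as M1.
#'
#' @inheritParams compute_M1
#' @return the score
#' @export
compute_M2 <- function(bp, ctrl) {
  if (!is_valid(bp, ctrl)) return(0)
  compute_M1(bp, ctrl)
}

#' Illness metric M3: 40 Hz reduction plus 20 Hz facilitation, gated
#'
#' For valid vectors,
#' M3' = (1/2)(1 - P40_PV/mean P40_Ctrl) - (1/2)(1 - P20_PV/mean P20_Ctrl):
#' positive when the relative 40 Hz loss exceeds the relative 20 Hz loss,
#' i.e. it rewards 40 Hz reduction combined with 20 Hz gain. Invalid vectors
#' score 0.
#'
#' @inheritParams compute_M1
#' @return the score
#' @export
compute_M3 <- function(bp, ctrl) {
  stopifnot(inherits(bp, "band_powers"), inherits(ctrl, "control_stats"))
  if (ctrl$mean_p40 <= 0 || ctrl$mean_p20 <= 0)
    stop("metric undefined: zero control mean power")
  if (!is_valid(bp, ctrl)) return(0)
  0.5 * (1 - bp$p40_40 / ctrl$mean_p40) - 0.5 * (1 - bp$p20_40 / ctrl$mean_p20)
}

#' Score a band-power table with all three metrics
#'
#' @param tab data.frame with columns \code{p40_40}, \code{p20_40},
#'   \code{p30_30} (one row per parameter vector)
#' @param ctrl \code{control_stats}
#' @return \code{tab} with added columns \code{valid}, \code{M1},
#'   \code{M2}, \code{M3}
#' @export
compute_metrics <- function(tab, ctrl) {
  stopifnot(all(c("p40_40", "p20_40", "p30_30") %in% names(tab)))
  bps <- lapply(seq_len(nrow(tab)), function(i)
    band_powers(tab$p40_40[i], tab$p20_40[i], tab$p30_30[i]))
  tab$valid <- vapply(bps, is_valid, logical(1), ctrl = ctrl)
  tab$M1 <- vapply(bps, compute_M1, numeric(1), ctrl = ctrl)
  tab$M2 <- vapply(bps, compute_M2, numeric(1), ctrl = ctrl)
  tab$M3 <- vapply(bps, compute_M3, numeric(1), ctrl = ctrl)
  tab
}

#' Highest-scoring fraction of parameter vectors
#'
#' Returns the indices of the ceiling(q * N) highest scores. Ties are broken
#' deterministically by position (supply scores in grid enumeration order so
#' ties resolve lexicographically).
#'
#' @param scores numeric scores, one per parameter vector
#' @param q fraction in (0, 1)
#' @return integer indices of the selected vectors
#' @export
top_fraction <- function(scores, q = 0.05) {
  if (length(scores) == 0) stop("empty score set")
  stopifnot(q > 0, q < 1)
  n_take <- ceiling(q * length(scores))
  ord <- order(-scores, seq_along(scores))
  sort(ord[seq_len(n_take)])
}

#' Distribution of a parameter's instances within a set of vectors
#'
#' For each instance of the parameter, the percentage of the supplied
#' (e.g. schizophrenia-like) parameter vectors carrying that instance.
#'
#' @param pv_set data.frame of parameter vectors (columns tau_ie, tau_ii,
#'   n_ie, n_ii, w_ie, w_ii)
#' @param parameter one of those column names
#' @param grid the sweep grid giving the full instance lists
#' @return named numeric vector of percentages (sums to 100)
#' @export
instance_distribution <- function(pv_set, parameter, grid = sweep_grid()) {
  if (nrow(pv_set) == 0) stop("empty parameter vector set")
  if (!(parameter %in% names(grid)))
    stop(sprintf("unknown parameter name: '%s'", parameter))
  instances <- grid[[parameter]]
  counts <- vapply(instances, function(v)
    sum(abs(pv_set[[parameter]] - v) < 1e-9), numeric(1))
  pct <- 100 * counts / nrow(pv_set)
  names(pct) <- as.character(instances)
  pct
}
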