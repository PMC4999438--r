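# The abnormality sweep: grid enumeration, paired 30/40 Hz simulations per
# parameter vector, and the named parameter-vector fixtures.

#' The abnormality sweep grid
#'
#' Instance lists per parameter: connection-count fractions n_ie, n_ii in
#' {100, 75, 50}\%, weight multipliers w_ie, w_ii in {150, 125, 100, 75,
#' 50}\%, and GABAergic decay times tau_ie, tau_ii in {6, 15, 25} ms;
#' 3*3*5*5*3*3 = 2025 combinations.
#'
#' @param n_ie,n_ii,w_ie,w_ii,tau_ie,tau_ii instance lists
#' @return named list of instance vectors (class \code{sweep_grid})
#' @export
sweep_grid <- function(n_ie = c(1.00, 0.75, 0.50), n_ii = c(1.00, 0.75, 0.50),
                       w_ie = c(1.50, 1.25, 1.00, 0.75, 0.50),
                       w_ii = c(1.50, 1.25, 1.00, 0.75, 0.50),
                       tau_ie = c(6, 15, 25), tau_ii = c(6, 15, 25)) {
  g <- list(n_ie = n_ie, n_ii = n_ii, w_ie = w_ie, w_ii = w_ii,
            tau_ie = tau_ie, tau_ii = tau_ii)
  for (nm in names(g)) {
    if (length(g[[nm]]) == 0) stop("empty instance list for ", nm)
    if (anyDuplicated(g[[nm]])) stop("duplicate instances for ", nm)
  }
  structure(g, class = "sweep_grid")
}

#' Enumerate the grid into an ordered parameter-vector table
#'
#' Cartesian product in lexicographic order over the columns (n_ie, n_ii,
#' w_ie, w_ii, tau_ie, tau_ii), instances in their listed order; n_ie
#' varies slowest. The baseline vector appears exactly once.
#'
#' @param grid a \code{sweep_grid}
#' @return data.frame with columns tau_ie, tau_ii, n_ie, n_ii, w_ie, w_ii
#'   and one row per parameter vector
#' @export
enumerate_grid <- function(grid = sweep_grid()) {
  stopifnot(inherits(grid, "sweep_grid"))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  ex <- expand.grid(tau_ii = grid$tau_ii, tau_ie = grid$tau_ie,
                    w_ii = grid$w_ii, w_ie = grid$w_ie,
                    n_ii = grid$n_ii, n_ie = grid$n_ie,
                    KEEP.OUT.ATTRS = FALSE)
  ex[, c("tau_ie", "tau_ii", "n_ie", "n_ii", "w_ie", "w_ii")]
}

#' The three named parameter vectors selected for dynamics analysis
#'
#' PV_M1 maximizes the raw 40 Hz reduction, PV_M2 the reduction among
#' vectors with a valid 30 Hz response, PV_M3 the combined 40 Hz reduction
#' plus 20 Hz facilitation.
#'
#' @param tag one of "PV_M1", "PV_M2", "PV_M3"
#' @return a \code{parameter_vector}
#' @export
named_pv <- function(tag = c("PV_M1", "PV_M2", "PV_M3")) {
  tag <- match.arg(tag)
  switch(tag,
    PV_M1 = parameter_vector(tau_ie = 25, tau_ii = 15, n_ie = 1.00,
                             n_ii = 0.50, w_ie = 1.50, w_ii = 0.75),
    PV_M2 = parameter_vector(tau_ie = 6, tau_ii = 25, n_ie = 1.00,
                             n_ii = 1.00, w_ie = 0.75, w_ii = 1.25),
    PV_M3 = parameter_vector(tau_ie = 6, tau_ii = 6, n_ie = 1.00,
                             n_ii = 0.50, w_ie = 1.50, w_ii = 0.50))
}

#' Run the sweep: paired 30/40 Hz simulations per parameter vector
#'
#' Every parameter vector is applied to the same baseline network (same
#' seed), so differences between records are attributable to the vector
#' alone. With an output directory the sweep is checkpointed per vector and
#' resumes without recomputation.
#'
#' @param grid a \code{sweep_grid}, or \code{pv_table} directly
#' @param net_config baseline \code{sz_network_config}
#' @param sim_config \code{sz_sim_config}
#' @param stim_40,stim_30 \code{stimulus_spec} for the two drive conditions
#' @param out_dir optional checkpoint directory
#' @param pv_table optional explicit parameter-vector table (overrides grid)
#' @return data.frame: the parameter columns plus \code{p40_40},
#'   \code{p20_40}, \code{p30_30}, \code{status}, \code{seed}
#' @export
run_sweep <- function(grid = sweep_grid(), net_config = network_config(),
                      sim_config = simulation_config(),
                      stim_40 = stimulus_spec("periodic", 40,
                                              sim_config$duration_ms),
                      stim_30 = stimulus_spec("periodic", 30,
                                              sim_config$duration_ms),
                      out_dir = NULL, pv_table = NULL) {
  pvs <- pv_table %||% enumerate_grid(grid)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_net <- build_network(net_config)
  n_fail <- 0
  rows <- lapply(seq_len(nrow(pvs)), function(i) {
    ck <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("pv_%04d.csv", i)) else NULL
    if (!is.null(ck) && file.exists(ck)) return(read.csv(ck))
    pv <- do.call(parameter_vector, as.list(pvs[i, ]))
    rec <- tryCatch({
      net <- apply_parameter_vector(base_net, pv)
      r40 <- run_simulation(net, stimulus = stim_40, config = sim_config)
      r30 <- run_simulation(net, stimulus = stim_30, config = sim_config)
      bp <- extract_band_powers(r40, r30)
      cbind(pvs[i, ], data.frame(p40_40 = bp$p40_40, p20_40 = bp$p20_40,
                                 p30_30 = bp$p30_30, status = "ok",
                                 seed = net_config$seed))
    }, error = function(e) {
      cbind(pvs[i, ], data.frame(p40_40 = NA_real_, p20_40 = NA_real_,
                                 p30_30 = NA_real_, status = "failed",
                                 seed = net_config$seed))
    })
    if (!is.null(ck)) write.csv(rec, ck, row.names = FALSE)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_fail <- sum(out$status == "failed")
  if (n_fail > 0)
    warning(sprintf("%d of %d sweep records failed", n_fail, nrow(out)))
  out
}

#' Fraction of parameter vectors passing the 30 Hz validity gate
#'
#' @param records sweep (or surrogate) table with a \code{p30_30} column
#' @param ctrl \code{control_stats}
#' @return list with \code{n_valid}, \code{n_total}, \code{fraction}
#' @export
valid_fraction <- function(records, ctrl) {
  ok <- records$status %||% rep("ok", nrow(records))
  v <- vapply(seq_len(nrow(records)), function(i) {
    if (ok[i] != "ok") return(FALSE)
    is_valid(band_powers(records$p40_40[i], records$p20_40[i],
                         records$p30_30[i]), ctrl)
  }, logical(1))
  list(n_valid = sum(v), n_total = nrow(records),
       fraction = sum(v) / nrow(records))
}
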