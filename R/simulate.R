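# Time-stepping of the stimulated network and management of seeded
# "subjects" (networks identical in statistics, differing in realized
# connectivity and background noise).

#' Simulation configuration
#'
#' @param dt integration step, ms; 0.02 ms by default (the conventional step
#'   for conductance-based models of this kind)
#' @param duration_ms simulated time, ms (10 s by default)
#' @param transient_ms onset transient discarded before spectral analysis
#' @param integrator "crank_nicolson" (semi-implicit voltage update,
#'   default) or "exponential_euler" (GENESIS-style)
#' @param eeg_dt_ms EEG sample interval (1 ms = 1 kHz, matching EEG practice)
#' @param seed base seed for run-level randomness (background noise draws)
#' @return object of class \code{sz_sim_config}
#' @export
simulation_config <- function(dt = 0.02, duration_ms = 10000,
                              transient_ms = 1000,
                              integrator = c("crank_nicolson",
                                             "exponential_euler"),
                              eeg_dt_ms = 1, seed = 1) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, duration_ms > 0, transient_ms < duration_ms,
            eeg_dt_ms >= dt)
  structure(list(dt = dt, duration_ms = duration_ms,
                 transient_ms = transient_ms, integrator = integrator,
                 eeg_dt_ms = eeg_dt_ms, seed = seed),
            class = "sz_sim_config")
}

# Assemble the pathway list consumed by the C++ integrator.
.build_cpp_pathways <- function(net) {
  st <- net$synapse_table
  tmplE <- cell_template(net$config$pyramidal)
  tmplI <- cell_template(net$config$basket)
  site <- function(class, category)
    unname((if (class == "E") tmplE else tmplI)$sites[[category]])
  # electrotonic attenuation of the target compartment (cell-model property)
  atten <- function(class, category) {
    tm <- if (class == "E") tmplE else tmplI
    tm$atten[tm$sites[[category]] + 1L]
  }
  pws <- list()
  rec <- list(EE = c("E", "recurrent_e", TRUE), EI = c("I", "recurrent_e", FALSE),
              IE = c("E", "recurrent_i", FALSE), II = c("I", "recurrent_i", FALSE))
  for (pw in names(rec)) {
    idx <- net$edges$pathway == pw
    if (!any(idx)) next
    row <- st[st$pathway == pw, ]
    pws[[pw]] <- list(
      external = FALSE, tau1 = row$tau1_ms, tau2 = row$tau2_ms,
      erev = row$e_rev_mv, delay = row$delay_ms,
      target_comp = as.integer(site(rec[[pw]][1], rec[[pw]][2])),
      eeg = as.logical(rec[[pw]][3]),
      pre = as.integer(net$edges$pre[idx] - 1L),
      post = as.integer(net$edges$post[idx] - 1L),
      w = net$edges$weight_ns[idx] * atten(rec[[pw]][1], rec[[pw]][2]))
  }
  ext_pathway <- function(row, targets, trains, shared, class, category) {
    if (length(targets) == 0) return(NULL)
    w <- rep(row$g_ns * atten(class, category), length(targets))
    if (shared) {
      src_events <- list(trains$times)
      src_targets <- list(as.integer(targets - 1L))
      src_w <- list(w)
    } else {
      src_events <- lapply(trains, `[[`, "times")
      src_targets <- lapply(targets, function(tg) as.integer(tg - 1L))
      src_w <- as.list(w)
    }
    list(external = TRUE, tau1 = row$tau1_ms, tau2 = row$tau2_ms,
         erev = row$e_rev_mv, delay = row$delay_ms,
         target_comp = as.integer(site(class, category)),
         eeg = class == "E" && row$e_rev_mv > -30,
         events = src_events, targets = src_targets, weights = src_w)
  }
  th <- net$drives$thalamic
  if (!is.null(th)) {
    if (th$shared) {
      pws$ThE <- ext_pathway(th$spec$E, th$targets$E, th$trains, TRUE, "E", "thalamic")
      pws$ThI <- ext_pathway(th$spec$I, th$targets$I, th$trains, TRUE, "I", "thalamic")
    } else {
      nE <- length(th$targets$E)
      pws$ThE <- ext_pathway(th$spec$E, th$targets$E, th$trains[seq_len(nE)],
                             FALSE, "E", "thalamic")
      pws$ThI <- ext_pathway(th$spec$I, th$targets$I,
                             th$trains[nE + seq_along(th$targets$I)],
                             FALSE, "I", "thalamic")
    }
  }
  bg <- net$drives$background
  if (!is.null(bg))
    pws$BgE <- ext_pathway(bg$spec$E, bg$targets$E, bg$trains, bg$shared,
                           "E", "background")
  Filter(Negate(is.null), pws)
}

#' Run one network simulation
#'
#' Integrates the stimulated network and records all spikes plus the
#' simulated EEG: the sum of every excitatory-category postsynaptic current
#' (recurrent E->E, thalamic, background) arriving at excitatory cells,
#' averaged within each EEG sample interval. Sign convention: larger values
#' mean larger total excitatory current. Deterministic given the network,
#' drive trains and config.
#'
#' @param net an \code{sz_network}; drives may be pre-attached with
#'   \code{\link{attach_drive}}
#' @param stimulus optional \code{stimulus_spec} or \code{event_train}
#'   attached as the thalamic drive
#' @param config an \code{sz_sim_config}
#' @param force accept an integration step above the stability bound
#' @param record_v optional vector of cell ids whose soma voltage is sampled
#' @return object of class \code{sz_simulation}: \code{spikes} (data.frame
#'   cell, population, time_ms), \code{eeg}, \code{eeg_dt_ms},
#'   \code{thalamic_train}, and complete provenance
#' @export
run_simulation <- function(net, stimulus = NULL,
                           config = simulation_config(), force = FALSE,
                           record_v = integer(0)) {
  stopifnot(inherits(net, "sz_network"), inherits(config, "sz_sim_config"))
  if (config$dt > 0.05) {
    warning("integration step above the 0.05 ms stability bound")
    if (!force) stop("refusing dt > 0.05 ms; pass force = TRUE to override")
  }
  if (!is.null(stimulus)) {
    if (inherits(stimulus, "event_train") || inherits(stimulus, "stimulus_spec"))
      net <- attach_drive(net, stimulus, "thalamic", seed = net$config$seed)
    else stop("stimulus must be a stimulus_spec or event_train")
  }
  if (is.null(net$drives$background) && net$config$background_rate_hz > 0) {
    bg <- generate_background(net$config$background_rate_hz, net$n_e,
                              config$duration_ms,
                              seed = net$config$seed + 131071)
    net <- attach_drive(net, bg, "background")
  }
  tmpl <- list(cell_template(net$config$pyramidal),
               cell_template(net$config$basket))
  cls <- as.integer(net$cells$class == "I")
  pws <- .build_cpp_pathways(net)
  out <- .sim_network_cpp(
    cell_class = cls, templates = tmpl, pathways = unname(pws),
    config = list(dt = config$dt, duration = config$duration_ms,
                  eeg_dt = config$eeg_dt_ms,
                  integrator = match_integrator(config$integrator),
                  i_inject = numeric(length(cls)),
                  record_v = as.integer(record_v - 1L)))
  spikes <- data.frame(cell = out$spike_cell + 1L,
                       population = ifelse(out$spike_cell + 1L <= net$n_e,
                                           "E", "I"),
                       time_ms = out$spike_time)
  colnames(out$eeg_components) <- names(pws)
  th <- net$drives$thalamic
  structure(list(
    spikes = spikes, eeg = out$eeg, eeg_dt_ms = out$eeg_dt,
    eeg_components = out$eeg_components,
    v = out$v, n_e = net$n_e, n_i = net$n_i,
    thalamic_train = if (!is.null(th) && th$shared) th$trains else NULL,
    provenance = list(network_config = net$config, pv = net$pv,
                      stimulus = stimulus, sim_config = config)),
    class = "sz_simulation")
}

#' Simulate an ensemble of seeded subjects
#'
#' One simulation per seed: each subject shares connectivity statistics but
#' has its own realized connectivity and background noise. The stimulus
#' (click train) is the same physical stimulus for every subject.
#'
#' @param net_config base \code{sz_network_config}; its seed field is
#'   replaced by each subject's seed
#' @param pv \code{parameter_vector} applied to every subject's baseline
#'   network
#' @param n_subjects number of subjects (ignored if \code{seeds} given)
#' @param stimulus \code{stimulus_spec} for the thalamic drive
#' @param sim_config \code{sz_sim_config}
#' @param seeds explicit distinct subject seeds
#' @return list of \code{sz_simulation}, one per subject, with the subject
#'   seed attached as attribute \code{subject_seed}
#' @export
run_subject_ensemble <- function(net_config, pv = parameter_vector(),
                                 n_subjects = 20, stimulus,
                                 sim_config = simulation_config(),
                                 seeds = NULL) {
  if (is.null(seeds)) seeds <- net_config$seed + seq_len(n_subjects) - 1L
  if (anyDuplicated(seeds)) stop("subject seeds must be distinct")
  lapply(seeds, function(s) {
    cfg <- net_config
    cfg$seed <- s
    net <- build_network(cfg)
    net <- apply_parameter_vector(net, pv, seed = s)
    res <- run_simulation(net, stimulus = stimulus, config = sim_config)
    attr(res, "subject_seed") <- s
    res
  })
}
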