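# Reduced multi-compartment cell models.
#
# The excitatory (pyramidal) cell is a reduced regular-spiking neocortical
# cell: soma with RTM-style Na/K_dr spiking channels plus a high-threshold Ca
# current and a calcium-gated K_AHP that produce spike-frequency adaptation;
# passive apical and basal dendrites carry the synapses. The inhibitory
# (basket) cell is a two-compartment fast-spiking cell with Wang-Buzsaki
# kinetics in the soma and a single passive cylindrical dendrite carrying all
# synapses. Channel parameters are calibrated to qualitative firing
# phenotypes (adapting regular spiking vs. sustained fast spiking, stable
# rest, low spontaneous rates under background drive).

.comp_fields <- c("length_um", "diam_um", "cm_uf_cm2", "g_leak_ms_cm2",
                  "e_leak_mv", "g_axial_ns", "syn_attenuation")
.channel_kinds <- c("Na", "K_dr", "Ca", "K_AHP", "K_M")

#' Build the excitatory (pyramidal) cell specification
#'
#' Four compartments: a soma holding the active channels (Na, K_dr,
#' high-threshold Ca, calcium-gated K_AHP), a proximal apical segment that
#' receives the thalamic drive, a distal apical segment that receives the
#' convergent recurrent excitation, and a weakly coupled basal dendrite that
#' receives the background drive. Recurrent inhibition targets the soma
#' (basket cells are perisomatic). Geometry is in micrometers, channel
#' maximum conductances in mS/cm2, leak in mS/cm2, capacitance in uF/cm2.
#'
#' Each compartment carries a \code{syn_attenuation} factor that scales the
#' peak conductance of synapses it receives. This represents the
#' electrotonic attenuation of inputs that are distributed over a large
#' dendritic tree in the detailed morphology but converge onto a single
#' compartment in this reduced model; without it, tens of convergent
#' nanosiemens-scale synapses would saturate the small compartment and
#' distort both dynamics and recorded EPSCs.
#'
#' @param overrides named list of documented override keys:
#'   \code{"<compartment>.<field>"} with field one of \code{length_um},
#'   \code{diam_um}, \code{cm_uf_cm2}, \code{g_leak_ms_cm2}, \code{e_leak_mv},
#'   \code{g_axial_ns}; \code{"<channel>.gbar"} with channel one of
#'   \code{na}, \code{k_dr}, \code{ca}, \code{k_ahp}, \code{k_m};
#'   \code{spike_threshold_mv}; \code{refractory_ms}. Unknown keys are an
#'   error naming the key.
#' @return an object of class \code{cell_spec}
#' @export
build_pyramidal_spec <- function(overrides = list()) {
  comps <- data.frame(
    name = c("soma", "apical_proximal", "apical", "basal"),
    length_um = c(20, 60, 200, 150),
    diam_um = c(20, 4, 3, 2),
    cm_uf_cm2 = c(1, 1, 1, 1),
    g_leak_ms_cm2 = c(0.1, 0.05, 0.05, 0.05),
    e_leak_mv = c(-67, -67, -67, -67),
    parent = c(NA, "soma", "apical_proximal", "soma"),
    g_axial_ns = c(0, 8, 8, 0.25),
    syn_attenuation = c(1, 0.25, 0.12, 1),
    stringsAsFactors = FALSE
  )
  chans <- data.frame(
    compartment = c("soma", "soma", "soma", "soma"),
    kind = c("Na", "K_dr", "Ca", "K_AHP"),
    gbar_ms_cm2 = c(100, 80, 0.5, 0.5),
    kinetics = c("rtm", "rtm", "rtm", "rtm"),
    stringsAsFactors = FALSE
  )
  spec <- structure(list(
    cell_class = "excitatory",
    compartments = comps,
    channels = chans,
    synapse_sites = list(recurrent_e = "apical", recurrent_i = "soma",
                         thalamic = "apical_proximal", background = "basal"),
    spike_threshold_mv = -20,
    refractory_ms = 2
  ), class = "cell_spec")
  spec <- apply_cell_overrides(spec, overrides)
  validate_cell_spec(spec)
  spec
}

#' Build the inhibitory (basket) cell specification
#'
#' A fast-spiking cell with exactly two compartments: a soma with
#' Wang-Buzsaki Na/K_dr kinetics (no adaptation channel, so firing is
#' sustained and regular under constant drive) and a single passive
#' cylindrical dendrite that receives all synaptic input, including the
#' thalamic drive.
#'
#' @inheritParams build_pyramidal_spec
#' @return an object of class \code{cell_spec}
#' @export
build_basket_spec <- function(overrides = list()) {
  comps <- data.frame(
    name = c("soma", "dendrite"),
    length_um = c(15, 100),
    diam_um = c(15, 2),
    cm_uf_cm2 = c(1, 1),
    g_leak_ms_cm2 = c(0.1, 0.1),
    e_leak_mv = c(-65, -65),
    parent = c(NA, "soma"),
    g_axial_ns = c(0, 6),
    syn_attenuation = c(1, 1),
    stringsAsFactors = FALSE
  )
  chans <- data.frame(
    compartment = c("soma", "soma"),
    kind = c("Na", "K_dr"),
    gbar_ms_cm2 = c(35, 9),
    kinetics = c("wb", "wb"),
    stringsAsFactors = FALSE
  )
  spec <- structure(list(
    cell_class = "inhibitory",
    compartments = comps,
    channels = chans,
    synapse_sites = list(recurrent_e = "dendrite", recurrent_i = "dendrite",
                         thalamic = "dendrite", background = "dendrite"),
    spike_threshold_mv = -20,
    refractory_ms = 2
  ), class = "cell_spec")
  spec <- apply_cell_overrides(spec, overrides)
  validate_cell_spec(spec)
  spec
}

apply_cell_overrides <- function(spec, overrides) {
  if (length(overrides) == 0) return(spec)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a named list")
  chan_keys <- paste0(tolower(.channel_kinds), ".gbar")
  names(chan_keys) <- .channel_kinds
  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (key == "spike_threshold_mv") {
      spec$spike_threshold_mv <- val
    } else if (key == "refractory_ms") {
      spec$refractory_ms <- val
    } else if (key %in% chan_keys) {
      kind <- names(chan_keys)[match(key, chan_keys)]
      i <- which(spec$channels$kind == kind)
      if (length(i) == 0) {
        # adding a channel not in the default set goes on the soma
        spec$channels <- rbind(spec$channels, data.frame(
          compartment = "soma", kind = kind, gbar_ms_cm2 = val,
          kinetics = spec$channels$kinetics[1], stringsAsFactors = FALSE))
      } else spec$channels$gbar_ms_cm2[i] <- val
    } else if (grepl("\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      comp <- parts[1]; field <- parts[2]
      i <- match(comp, spec$compartments$name)
      if (is.na(i) || !(field %in% .comp_fields))
        stop(sprintf("unknown cell spec override key: '%s'", key))
      spec$compartments[[field]][i] <- val
    } else {
      stop(sprintf("unknown cell spec override key: '%s'", key))
    }
  }
  spec
}

validate_cell_spec <- function(spec) {
  comps <- spec$compartments
  stopifnot(nrow(comps) >= 1)
  for (site in names(spec$synapse_sites))
    if (!(spec$synapse_sites[[site]] %in% comps$name))
      stop(sprintf("synapse site '%s' maps to unknown compartment '%s'",
                   site, spec$synapse_sites[[site]]))
  if (any(spec$channels$gbar_ms_cm2 < 0))
    stop("channel conductance densities must be non-negative")
  if (!all(spec$channels$kind %in% .channel_kinds))
    stop("unknown channel kind")
  if (spec$cell_class == "excitatory") {
    if (!any(spec$channels$kind %in% c("Ca", "K_AHP", "K_M")))
      stop("excitatory spec requires at least one adaptation channel")
  } else {
    if (sum(comps$name == "soma") != 1 || nrow(comps) > 2)
      stop("inhibitory spec must have exactly one soma and at most one dendrite")
  }
  invisible(spec)
}

# cylinder lateral area in cm2
.comp_area_cm2 <- function(comps) pi * comps$diam_um * comps$length_um * 1e-8

# Flatten a cell_spec into the absolute-unit template consumed by the C++
# integrator (conductances nS, capacitances pF).
cell_template <- function(spec) {
  comps <- spec$compartments
  area <- .comp_area_cm2(comps)
  n <- nrow(comps)
  g <- function(kind) {
    out <- numeric(n)
    rows <- spec$channels[spec$channels$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      k <- match(rows$compartment[i], comps$name)
      out[k] <- out[k] + rows$gbar_ms_cm2[i] * area[k] * 1e6  # mS -> nS
    }
    out
  }
  kin <- if (any(spec$channels$kinetics == "wb")) 1L else 0L
  list(
    C = comps$cm_uf_cm2 * area * 1e6,          # uF/cm2 * cm2 -> pF
    gL = comps$g_leak_ms_cm2 * area * 1e6,     # mS -> nS
    EL = comps$e_leak_mv,
    gax = comps$g_axial_ns,
    parent = ifelse(is.na(comps$parent), -1L,
                    match(comps$parent, comps$name) - 1L),
    gna = g("Na"), gkdr = g("K_dr"), gca = g("Ca"),
    gkahp = g("K_AHP"), gkm = g("K_M"),
    kin = kin,
    atten = comps$syn_attenuation,
    thresh = spec$spike_threshold_mv,
    refract = spec$refractory_ms,
    sites = vapply(spec$synapse_sites, function(s) match(s, comps$name) - 1L,
                   integer(1))
  )
}

#' Simulate a single cell in isolation
#'
#' Harness for calibration and unit tests: a lone cell with an optional
#' constant somatic current injection and optional synaptic event trains.
#'
#' @param spec a \code{cell_spec}
#' @param i_inject_pa constant current injected at the soma, pA
#' @param duration_ms simulated time, ms
#' @param dt integration step, ms
#' @param v_dt sampling interval of the returned soma voltage trace, ms
#' @param events optional list of lists with elements \code{times} (ms),
#'   \code{site} (a synapse-site name), \code{g_peak_ns}, \code{tau1},
#'   \code{tau2}, \code{e_rev}
#' @param integrator "crank_nicolson" or "exponential_euler"
#' @return list with \code{spike_times} (ms) and \code{v} (soma voltage, mV)
#' @export
simulate_cell <- function(spec, i_inject_pa = 0, duration_ms = 1000,
                          dt = 0.02, v_dt = 0.1, events = list(),
                          integrator = "crank_nicolson") {
  tmpl <- cell_template(spec)
  pws <- lapply(events, function(ev) {
    list(external = TRUE, tau1 = ev$tau1, tau2 = ev$tau2,
         erev = ev$e_rev, delay = 0, eeg = FALSE,
         target_comp = unname(tmpl$sites[[ev$site]]),
         events = list(as.numeric(ev$times)), targets = list(0L),
         weights = list(ev$g_peak_ns))
  })
  out <- .sim_network_cpp(
    cell_class = 0L, templates = list(tmpl), pathways = pws,
    config = list(dt = dt, duration = duration_ms, eeg_dt = v_dt,
                  integrator = match_integrator(integrator),
                  i_inject = as.numeric(i_inject_pa), record_v = 0L))
  list(spike_times = out$spike_time, v = out$v[, 1], v_dt = v_dt)
}

match_integrator <- function(x) {
  x <- match.arg(x, c("crank_nicolson", "exponential_euler"))
  if (x == "exponential_euler") 1L else 0L
}

#' Firing rate versus injected current
#'
#' Simulates the cell for each current level and returns the mean firing
#' rate, the standard calibration curve for matching qualitative firing
#' phenotypes (adapting regular spiking for the pyramidal cell, sustained
#' fast spiking for the basket cell).
#'
#' @param spec a \code{cell_spec}
#' @param currents_pa injected currents in pA, sorted ascending
#' @param duration_ms simulation length per current level (>= 1000 ms)
#' @param dt integration step, ms
#' @return data.frame with columns \code{current_pa} and \code{rate_hz}
#' @export
f_i_curve <- function(spec, currents_pa, duration_ms = 1000, dt = 0.02) {
  if (is.unsorted(currents_pa))
    stop("currents must be sorted ascending")
  if (duration_ms < 1000)
    stop("simulation duration must be at least 1 s per current level")
  rate <- vapply(currents_pa, function(I) {
    r <- simulate_cell(spec, i_inject_pa = I, duration_ms = duration_ms,
                       dt = dt, v_dt = duration_ms)
    length(r$spike_times) / (duration_ms / 1000)
  }, numeric(1))
  data.frame(current_pa = currents_pa, rate_hz = rate)
}

#' Serialize or restore a cell specification
#'
#' @param spec a \code{cell_spec}
#' @param path file path for the JSON document
#' @return \code{read_cell_spec} returns a \code{cell_spec}
#' @export
write_cell_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cell_spec
#' @export
read_cell_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$synapse_sites <- as.list(x$synapse_sites)
  spec <- structure(x, class = "cell_spec")
  validate_cell_spec(spec)
  spec
}
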