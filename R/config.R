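# Layered configuration and end-to-end reproduction recipes.

.default_config <- function() {
  list(
    network = list(
      e_grid = c(24, 24), i_grid = c(12, 12),
      distance_decay_lambda = 4, background_rate_hz = 10, seed = 1),
    simulation = list(
      dt = 0.02, duration_ms = 10000, transient_ms = 1000,
      integrator = "crank_nicolson", eeg_dt_ms = 1),
    stimulus = list(mode = "periodic", shared = TRUE),
    grid = unclass(sweep_grid()),
    synapses = default_synapse_table()
  )
}

#' Load a layered configuration
#'
#' Later layers override earlier ones, starting from the package defaults
#' (the default synaptic parameter table and abnormality grid). Unknown
#' keys are rejected with the offending key named. Command-line style
#' overrides take dotted paths, e.g. \code{"network.seed=7"} or
#' \code{"grid.tau_ie=6,25"}.
#'
#' @param paths ordered character vector of JSON config files
#' @param overrides character vector of \code{"dotted.key=value"} strings
#' @return the fully resolved configuration list
#' @export
load_config <- function(paths = character(), overrides = character()) {
  cfg <- .default_config()
  merge_layer <- function(base, layer, prefix = "") {
    for (key in names(layer)) {
      full <- if (prefix == "") key else paste0(prefix, ".", key)
      if (!(key %in% names(base)))
        stop(sprintf("unknown configuration key: '%s'", full))
      if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
        if (!is.list(layer[[key]]))
          stop(sprintf("configuration key '%s' must be a section", full))
        base[[key]] <- merge_layer(base[[key]], layer[[key]], full)
      } else {
        base[[key]] <- layer[[key]]
      }
    }
    base
  }
  for (p in paths) {
    layer <- jsonlite::read_json(p, simplifyVector = TRUE)
    cfg <- tryCatch(merge_layer(cfg, layer),
                    error = function(e) stop(conditionMessage(e),
                                             " (in file ", p, ")"))
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value: ", ov)
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    layer <- val
    for (key in rev(path)) layer <- setNames(list(layer), key)
    cfg <- merge_layer(cfg, layer)
  }
  cfg
}

#' Build a network config from a resolved configuration
#'
#' @param cfg a configuration list from \code{\link{load_config}}
#' @return an \code{sz_network_config}
#' @export
config_to_network <- function(cfg) {
  st <- as.data.frame(cfg$synapses)
  network_config(e_grid = cfg$network$e_grid, i_grid = cfg$network$i_grid,
                 synapse_table = st,
                 distance_decay_lambda = cfg$network$distance_decay_lambda,
                 background_rate_hz = cfg$network$background_rate_hz,
                 seed = cfg$network$seed)
}

#' Run a named end-to-end reproduction recipe
#'
#' Recipes at mini scale (12x12 excitatory / 6x6 inhibitory cells, 3 s
#' runs): \code{control_entrainment} (spectra under 30 and 40 Hz drive),
#' \code{sweep_mini} (a small abnormality sweep plus metrics),
#' \code{dynamics_pv_m3} (stimulus-locked EEG and spike histograms for the
#' beat-skipping vector), \code{mi_surrogate} (normalized MI over parameter
#' subsets of a surrogate table). Writes CSV outputs plus a JSON manifest
#' and returns the output paths.
#'
#' @param recipe recipe name
#' @param out_dir output directory
#' @param seed base seed
#' @return invisibly, list of written files
#' @export
reproduce <- function(recipe = c("control_entrainment", "sweep_mini",
                                 "dynamics_pv_m3", "mi_surrogate"),
                      out_dir = "results", seed = 1) {
  recipe <- match.arg(recipe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  mini_cfg <- function(s) network_config(e_grid = c(12, 12), i_grid = c(6, 6),
                                         seed = s)
  sim <- simulation_config(duration_ms = 3000, transient_ms = 500)

  if (recipe == "control_entrainment") {
    for (f in c(30, 40)) {
      net <- build_network(mini_cfg(seed))
      res <- run_simulation(net, stimulus_spec("periodic", f, 3000),
                            config = sim)
      sp <- power_spectrum(compute_eeg(res), window = c(500, 3000))
      emit(as.data.frame(sp), sprintf("control_spectrum_%dhz.csv", f))
    }
  } else if (recipe == "sweep_mini") {
    grid <- sweep_grid(n_ie = 1, n_ii = 1, w_ie = 1, w_ii = c(1, 0.5),
                       tau_ie = c(6, 25), tau_ii = 6)
    tab <- run_sweep(grid, mini_cfg(seed), sim)
    emit(tab, "sweep_mini.csv")
  } else if (recipe == "dynamics_pv_m3") {
    net <- apply_parameter_vector(build_network(mini_cfg(seed)),
                                  named_pv("PV_M3"))
    res <- run_simulation(net, stimulus_spec("periodic", 40, 3000),
                          config = sim)
    sla <- stimulus_locked_average(compute_eeg(res), res$thalamic_train,
                                   transient_ms = 500)
    emit(data.frame(bin_ms = seq_along(sla$avg) * sla$bin_ms - sla$bin_ms / 2,
                    eeg = sla$avg), "pv_m3_locked_eeg.csv")
    for (pop in c("E", "I")) {
      h <- spike_histogram(res$spikes[res$spikes$population == pop, ],
                           res$thalamic_train, transient_ms = 500)
      emit(data.frame(bin_center_ms = h$bin_centers_ms, count = h$counts),
           sprintf("pv_m3_hist_%s.csv", tolower(pop)))
    }
  } else {
    rule <- surrogate_rule("xor", noise_sd = 0, seed = seed)
    ds <- generate_bandpower_table(
      sweep_grid(tau_ii = c(6, 25), n_ii = c(1, 0.5)), rule)
    ctrl <- surrogate_control_stats(ds)
    scored <- compute_metrics(ds$table, ctrl)
    scored$label <- discretize_phenotype(scored$M1, "threshold", t = 0.25)
    emit(nmi_all_subsets(scored, "label", max_order = 3), "mi_surrogate.csv")
  }
  manifest <- list(recipe = recipe, seed = seed, files = files,
                   package_version = as.character(utils::packageVersion("szgamma")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir,
                                           paste0(recipe, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
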