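# Network assembly: grid-organized E/I populations, distance-dependent
# random connectivity, dual-exponential synapses, and application of
# GABAergic abnormality parameter vectors.

.pathways <- c("EE", "EI", "IE", "II", "ThE", "ThI", "BgE")

#' Default synaptic parameter table
#'
#' Connection probabilities p, peak conductances g (nS) and dual-exponential
#' time constants (tau1 rise, tau2 decay, ms) for the seven pathways:
#' recurrent E->E, E->I, I->E, I->I, thalamic->E, thalamic->I and
#' background->E (inhibitory cells receive no background drive). Reversal
#' potentials default to 0 mV (excitatory) and -75 mV (GABA-A); recurrent
#' connections carry a uniform 0.5 ms conduction+synaptic delay, external
#' drives none.
#'
#' @return data.frame with one row per pathway
#' @export
default_synapse_table <- function() {
  data.frame(
    pathway = .pathways,
    p = c(0.15, 0.45, 0.60, 0.60, 1.00, 0.65, 1.00),
    g_ns = c(30, 0.1, 0.6, 0.15, 50, 1.5, 90),
    tau1_ms = c(1, 3, 1, 1, 1, 3, 1),
    tau2_ms = c(3, 3, 6, 6, 3, 3, 3),
    e_rev_mv = c(0, 0, -75, -75, 0, 0, 0),
    delay_ms = c(0.5, 0.5, 0.5, 0.5, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Network configuration
#'
#' @param e_grid,i_grid rows/cols of the excitatory and inhibitory lattices.
#'   The inhibitory lattice spans the same physical extent as the excitatory
#'   one (its spacing is \code{e_grid[1]/i_grid[1]} excitatory grid units).
#' @param synapse_table per-pathway synaptic parameters; defaults to
#'   \code{\link{default_synapse_table}}
#' @param distance_decay_lambda length constant of the exponential
#'   distance-dependence of connection probability, in E-grid units
#' @param background_rate_hz Poisson background rate per excitatory cell
#' @param seed RNG seed defining the realized connectivity ("subject")
#' @param pyramidal,basket cell specifications
#' @return object of class \code{sz_network_config}
#' @export
network_config <- function(e_grid = c(24, 24), i_grid = c(12, 12),
                           synapse_table = default_synapse_table(),
                           distance_decay_lambda = 4,
                           background_rate_hz = 10,
                           seed = 1,
                           pyramidal = build_pyramidal_spec(),
                           basket = build_basket_spec()) {
  stopifnot(length(e_grid) == 2, length(i_grid) == 2,
            all(e_grid >= 1), all(i_grid >= 1),
            distance_decay_lambda > 0, background_rate_hz >= 0)
  if (!all(.pathways %in% synapse_table$pathway))
    stop("synapse_table must contain rows for: ",
         paste(setdiff(.pathways, synapse_table$pathway), collapse = ", "))
  structure(list(e_grid = e_grid, i_grid = i_grid,
                 synapse_table = synapse_table,
                 distance_decay_lambda = distance_decay_lambda,
                 background_rate_hz = background_rate_hz, seed = seed,
                 pyramidal = pyramidal, basket = basket),
            class = "sz_network_config")
}

#' Abnormality parameter vector
#'
#' The six GABAergic abnormality knobs applied to a baseline network:
#' decay times of the I->E and I->I synaptic conductances (ms), fractions of
#' baseline I->E and I->I connection counts retained, and multipliers on the
#' I->E and I->I weights. The baseline vector is
#' (6 ms, 6 ms, 1.0, 1.0, 1.0, 1.0).
#'
#' @param tau_ie,tau_ii decay time constants, ms (> 0)
#' @param n_ie,n_ii connection-count fractions in (0, 1]
#' @param w_ie,w_ii weight multipliers (> 0)
#' @return object of class \code{parameter_vector}
#' @export
parameter_vector <- function(tau_ie = 6, tau_ii = 6, n_ie = 1, n_ii = 1,
                             w_ie = 1, w_ii = 1) {
  pv <- list(tau_ie = tau_ie, tau_ii = tau_ii, n_ie = n_ie, n_ii = n_ii,
             w_ie = w_ie, w_ii = w_ii)
  if (!all(vapply(pv, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("parameter vector fields must be single finite numbers")
  if (tau_ie <= 0 || tau_ii <= 0) stop("decay times must be positive")
  if (n_ie <= 0 || n_ie > 1 || n_ii <= 0 || n_ii > 1)
    stop("connection fractions must lie in (0, 1]: the sweep only removes connections")
  if (w_ie <= 0 || w_ii <= 0) stop("weight multipliers must be positive")
  structure(pv, class = "parameter_vector")
}

# lattice coordinates in E-grid units; the I lattice is offset to sit
# centered within the same physical extent as the E lattice
.grid_coords <- function(grid, spacing = 1) {
  off <- (spacing - 1) / 2
  expand.grid(x = (seq_len(grid[2]) - 1) * spacing + off,
              y = (seq_len(grid[1]) - 1) * spacing + off)
}

#' Distance-dependent connection probability
#'
#' Probability decays exponentially with radial distance,
#' p(d) = c * exp(-d / lambda), with c normalized so that the average
#' probability over the supplied ordered pair distances equals \code{base_p}
#' exactly, accounting for clipping to [0, 1] (for dense pathways the naive
#' constant saturates nearby pairs, so c is re-solved on the clipped form);
#' hence expected pathway connection counts match the base probability
#' regardless of lambda. If saturation would cover most pairs, destroying
#' the distance dependence, the configuration is rejected.
#'
#' @param distance distances (E-grid units) at which to evaluate
#' @param base_p target population-average connection probability
#' @param lambda decay length constant, E-grid units
#' @param pair_distances distances over all ordered pairs of the pathway's
#'   pre/post populations (self-pairs excluded); defaults to the E->E pairs
#'   of the default 24x24 grid
#' @return probabilities, same length as \code{distance}
#' @export
connection_probability <- function(distance, base_p, lambda,
                                   pair_distances = NULL) {
  stopifnot(all(distance >= 0), lambda > 0, base_p >= 0, base_p <= 1)
  if (is.null(pair_distances)) {
    co <- .grid_coords(c(24, 24))
    pair_distances <- .pair_distances(co, co, self = TRUE)
  }
  if (length(pair_distances) == 0)   # degenerate population: no ordered pairs
    return(rep(min(base_p, 1), length(distance)))
  e_pair <- exp(-pair_distances / lambda)
  cc <- base_p / mean(e_pair)
  if (cc > 1 && base_p > 0 && any(cc * e_pair > 1)) {
    # naive normalization saturates near pairs; re-solve c so the clipped
    # population average still equals base_p exactly
    f <- function(c_try) mean(pmin(c_try * e_pair, 1)) - base_p
    hi <- cc
    while (f(hi) < 0) hi <- hi * 2
    cc <- stats::uniroot(f, c(cc, hi * 1.000001), tol = 1e-10)$root
    if (mean(cc * e_pair >= 1) > 0.5)
      stop(sprintf(paste0("normalization constant %.3f saturates most pairs: ",
                          "the distance dependence would be destroyed; ",
                          "use a larger distance_decay_lambda"), cc))
  }
  pmin(cc * exp(-distance / lambda), 1)
}

# full ordered-pair distance matrix between two coordinate sets; self = TRUE
# marks the populations as identical so the diagonal (self-pairs) is dropped
# from the returned vector
.pair_distances <- function(from, to, self = FALSE) {
  d <- sqrt(outer(from$x, to$x, "-")^2 + outer(from$y, to$y, "-")^2)
  if (self) d <- d[row(d) != col(d)]
  as.numeric(d)
}

#' Build a network instance
#'
#' Places cells on their lattices and draws every ordered pair independently
#' with the distance-dependent probability; synaptic weights are fixed
#' independent of distance. Fully reproducible from the config seed.
#'
#' @param config an \code{sz_network_config}
#' @return object of class \code{sz_network} with elements \code{cells}
#'   (id, class, x, y), \code{edges} (pre, post, pathway, weight_ns),
#'   \code{synapse_table}, \code{config}, \code{pv}
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "sz_network_config"))
  e_co <- .grid_coords(config$e_grid)
  sp <- config$e_grid[1] / config$i_grid[1]
  i_co <- .grid_coords(config$i_grid, spacing = sp)
  n_e <- nrow(e_co); n_i <- nrow(i_co)
  cells <- data.frame(
    id = seq_len(n_e + n_i),
    class = rep(c("E", "I"), c(n_e, n_i)),
    x = c(e_co$x, i_co$x), y = c(e_co$y, i_co$y))

  st <- config$synapse_table
  lam <- config$distance_decay_lambda
  pops <- list(E = seq_len(n_e), I = n_e + seq_len(n_i))
  coords <- list(E = e_co, I = i_co)

  draw_pathway <- function(pw, from, to) {
    row <- st[st$pathway == pw, ]
    d <- sqrt(outer(coords[[from]]$x, coords[[to]]$x, "-")^2 +
              outer(coords[[from]]$y, coords[[to]]$y, "-")^2)
    same <- identical(from, to)
    dv <- if (same) d[row(d) != col(d)] else as.numeric(d)
    p <- connection_probability(as.numeric(d), row$p, lam, pair_distances = dv)
    p <- matrix(p, nrow = nrow(d))
    if (same) diag(p) <- 0            # no self-connections
    hit <- which(matrix(runif(length(p)), nrow = nrow(p)) < p, arr.ind = TRUE)
    data.frame(pre = pops[[from]][hit[, 1]], post = pops[[to]][hit[, 2]],
               pathway = rep(pw, nrow(hit)),
               weight_ns = rep(row$g_ns, nrow(hit)))
  }

  edges <- with_seed(config$seed, {
    do.call(rbind, list(draw_pathway("EE", "E", "E"),
                        draw_pathway("EI", "E", "I"),
                        draw_pathway("IE", "I", "E"),
                        draw_pathway("II", "I", "I")))
  })
  edges <- edges[order(match(edges$pathway, .pathways), edges$pre, edges$post), ]
  rownames(edges) <- NULL
  structure(list(cells = cells, n_e = n_e, n_i = n_i, edges = edges,
                 synapse_table = st, config = config,
                 pv = parameter_vector(), drives = list()),
            class = "sz_network")
}

#' Apply an abnormality parameter vector to a baseline network
#'
#' I->E connections are subsampled uniformly at random to
#' \code{round(n_ie * baseline count)} (likewise I->I with \code{n_ii});
#' I->E weights are multiplied by \code{w_ie} and I->I by \code{w_ii}; the
#' decay times of the I->E and I->I conductances are set to \code{tau_ie}
#' and \code{tau_ii} (rise times unchanged). Pruning uses a dedicated
#' sub-seed and a single permutation per pathway, so the pruned sets are
#' nested across n levels of the sweep. The input network is not mutated.
#'
#' @param net a baseline \code{sz_network}
#' @param pv a \code{parameter_vector}
#' @param seed pruning sub-seed; defaults to the network seed
#' @return a new \code{sz_network}
#' @export
apply_parameter_vector <- function(net, pv, seed = net$config$seed) {
  stopifnot(inherits(net, "sz_network"), inherits(pv, "parameter_vector"))
  out <- net
  prune <- function(edges, pw, frac, salt) {
    idx <- which(edges$pathway == pw)
    keep_n <- round(frac * length(idx))
    if (keep_n == length(idx)) return(edges)
    perm <- with_seed(seed + salt, sample(length(idx)))
    drop <- idx[perm[(keep_n + 1):length(idx)]]
    edges[-drop, ]
  }
  out$edges <- prune(out$edges, "IE", pv$n_ie, salt = 104729)
  out$edges <- prune(out$edges, "II", pv$n_ii, salt = 224737)
  out$edges$weight_ns[out$edges$pathway == "IE"] <-
    out$edges$weight_ns[out$edges$pathway == "IE"] * pv$w_ie
  out$edges$weight_ns[out$edges$pathway == "II"] <-
    out$edges$weight_ns[out$edges$pathway == "II"] * pv$w_ii
  out$synapse_table$tau2_ms[out$synapse_table$pathway == "IE"] <- pv$tau_ie
  out$synapse_table$tau2_ms[out$synapse_table$pathway == "II"] <- pv$tau_ii
  rownames(out$edges) <- NULL
  out$pv <- pv
  out
}

#' Dual-exponential synaptic conductance
#'
#' g(t) = g_peak * N * (exp(-t/tau2) - exp(-t/tau1)), peak-normalized so the
#' maximum equals \code{g_peak}; the equal-time-constant case falls back to
#' the alpha function g_peak * (t/tau) * exp(1 - t/tau).
#'
#' @param t time since the presynaptic event, ms (>= 0); vectorized
#' @param tau1 rise time constant, ms
#' @param tau2 decay time constant, ms (>= tau1)
#' @param g_peak peak conductance, nS
#' @return conductance values, nS
#' @export
dual_exp_conductance <- function(t, tau1, tau2, g_peak = 1) {
  stopifnot(all(t >= 0), tau1 > 0)
  if (tau1 > tau2) stop("tau1 must not exceed tau2")
  if (tau1 == tau2) return(g_peak * (t / tau1) * exp(1 - t / tau1))
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  nrm <- 1 / (exp(-tp / tau2) - exp(-tp / tau1))
  g_peak * nrm * (exp(-t / tau2) - exp(-t / tau1))
}

#' Serialize a network to a JSON header and CSV edge list
#'
#' @param net an \code{sz_network}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- net$synapse_table
  hdr <- list(e_grid = net$config$e_grid, i_grid = net$config$i_grid,
              distance_decay_lambda = net$config$distance_decay_lambda,
              background_rate_hz = net$config$background_rate_hz,
              seed = net$config$seed, pv = unclass(net$pv))
  jsonlite::write_json(hdr, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  e <- merge(net$edges, st[, c("pathway", "tau1_ms", "tau2_ms", "delay_ms")],
             by = "pathway", sort = FALSE)
  write.csv(e[, c("pre", "post", "pathway", "weight_ns",
                  "tau1_ms", "tau2_ms", "delay_ms")],
            file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}
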