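# Plug-in entropy, mutual information and normalized MI between parameter
# subsets and the discretized network phenotype. The sweep enumerates the
# whole parameter grid, so the empirical joint IS the population joint and
# the maximum-likelihood (plug-in) estimator is exact: no bias correction.

#' Shannon entropy of a discrete distribution
#'
#' H = -sum p log2 p with 0 log 0 := 0, in bits. Accepts a probability
#' table of any dimensionality (vector, matrix, array) or a count table
#' (normalized internally when it does not sum to 1).
#'
#' @param joint non-negative probabilities or counts
#' @return entropy in bits (>= 0)
#' @export
shannon_entropy <- function(joint) {
  p <- as.numeric(joint)
  if (any(p < 0)) stop("probabilities must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("distribution sums to zero")
  if (abs(s - 1) > 1e-9) p <- p / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy of the empirical joint of a set of data.frame columns
.empirical_entropy <- function(data, cols) {
  key <- do.call(paste, c(lapply(cols, function(cl) data[[cl]]), sep = "\r"))
  shannon_entropy(table(key))
}

#' Plug-in mutual information between a parameter subset and the phenotype
#'
#' MI(X_i..X_j; Y) = H(X_i..X_j) + H(Y) - H(X_i..X_j, Y), computed from the
#' empirical joint of the data table, treating the subset as one compound
#' variable.
#'
#' @param data data.frame with one row per parameter vector
#' @param vars character vector of parameter column names (non-empty)
#' @param y phenotype column name
#' @return mutual information in bits
#' @export
mutual_information <- function(data, vars, y = "label") {
  stopifnot(length(vars) >= 1, all(c(vars, y) %in% names(data)))
  hx <- .empirical_entropy(data, vars)
  hy <- .empirical_entropy(data, y)
  hxy <- .empirical_entropy(data, c(vars, y))
  max(hx + hy - hxy, 0)
}

#' Normalized mutual information (percent)
#'
#' nMI = 100 * MI(X; Y) / H(Y), clipped to [0, 100]. 0 means the parameters
#' carry no phenotype information, 100 that they fully determine it.
#'
#' @inheritParams mutual_information
#' @return percent in [0, 100]
#' @export
normalized_mi <- function(data, vars, y = "label") {
  hy <- .empirical_entropy(data, y)
  if (hy <= 0)
    stop("degenerate phenotype: H(Y) = 0, normalized MI undefined")
  nmi <- 100 * mutual_information(data, vars, y) / hy
  if (nmi > 100 + 1e-6 || nmi < -1e-6)
    warning("normalized MI outside [0, 100] beyond tolerance before clipping")
  min(max(nmi, 0), 100)
}

#' Discretize metric scores into phenotype labels
#'
#' @param scores numeric metric scores, one per parameter vector, in grid
#'   enumeration order
#' @param rule "top_quantile" (label 1 for the top fraction \code{q},
#'   matching \code{\link{top_fraction}}), "threshold" (label 1 when score
#'   > \code{t}), or "k_bins" (equal-width bins over the score range)
#' @param q,t,k rule parameters
#' @return integer labels
#' @export
discretize_phenotype <- function(scores, rule = c("top_quantile", "threshold",
                                                  "k_bins"),
                                 q = 0.05, t = NULL, k = NULL) {
  rule <- match.arg(rule)
  if (rule == "top_quantile") {
    if (length(unique(scores)) == 1)
      stop("degenerate scores: all equal, quantile rule undefined")
    lab <- integer(length(scores))
    lab[top_fraction(scores, q)] <- 1L
    lab
  } else if (rule == "threshold") {
    stopifnot(!is.null(t))
    as.integer(scores > t)
  } else {
    stopifnot(!is.null(k), k >= 2)
    rng <- range(scores)
    if (diff(rng) == 0) return(rep(1L, length(scores)))
    br <- seq(rng[1], rng[2], length.out = k + 1)
    as.integer(cut(scores, breaks = br, include.lowest = TRUE))
  }
}

#' Normalized MI for all parameter subsets up to a given order
#'
#' One result per non-empty subset of the six abnormality parameters
#' (6 singles, 15 pairs, 20 triples, ...), plus a per-order mean and
#' standard deviation summary attached as attribute \code{order_summary}.
#'
#' @param data data.frame of parameter vectors plus the phenotype column
#' @param y phenotype column name
#' @param max_order largest subset size (<= number of parameters)
#' @param params parameter column names
#' @return data.frame (\code{subset}, \code{order}, \code{mi_bits},
#'   \code{h_y_bits}, \code{nmi_percent}) with attribute
#'   \code{order_summary}
#' @export
nmi_all_subsets <- function(data, y = "label", max_order = 3,
                            params = c("tau_ie", "tau_ii", "n_ie", "n_ii",
                                       "w_ie", "w_ii")) {
  params <- intersect(params, names(data))
  stopifnot(max_order >= 1, max_order <= length(params))
  hy <- .empirical_entropy(data, y)
  rows <- list()
  for (ord in seq_len(max_order)) {
    for (combo in as.data.frame(combn(params, ord), stringsAsFactors = FALSE)) {
      combo <- as.character(combo)
      mi <- mutual_information(data, combo, y)
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(combo, collapse = "+"), order = ord,
        mi_bits = mi, h_y_bits = hy,
        nmi_percent = min(max(100 * mi / hy, 0), 100),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- aggregate(nmi_percent ~ order, data = out,
                    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  attr(out, "order_summary") <- data.frame(
    order = summ$order, mean_nmi = summ$nmi_percent[, "mean"],
    sd_nmi = summ$nmi_percent[, "sd"])
  out
}
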