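# Mixed-design (split-plot) ANOVA with Greenhouse-Geisser correction:
# between-subjects factor GROUP, repeated-measures factor POWER (the three
# band powers P40@40, P20@40, P30@30).

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Classical sums-of-squares split-plot ANOVA for a balanced design with one
#' between-subjects factor and one repeated-measures factor. Sphericity is
#' adjusted with the Greenhouse-Geisser epsilon computed from the pooled
#' within-group covariance of the repeated measures; corrected degrees of
#' freedom are epsilon*(k-1) and epsilon*(k-1)*(N-g).
#'
#' @param design data.frame with a \code{group} column (two or more levels,
#'   equal sizes) and one numeric column per within-subject level, one row
#'   per subject; by default the band-power columns \code{p40_40},
#'   \code{p20_40}, \code{p30_30}
#' @param within names of the within-subject response columns
#' @return object of class \code{mixed_anova}: F statistics, uncorrected
#'   and corrected dfs, epsilon, p values
#' @export
mixed_anova <- function(design, within = c("p40_40", "p20_40", "p30_30")) {
  stopifnot(is.data.frame(design), "group" %in% names(design),
            all(within %in% names(design)))
  g_lab <- factor(design$group)
  g <- nlevels(g_lab)
  stopifnot(g >= 2)
  counts <- table(g_lab)
  if (length(unique(counts)) != 1)
    stop("the default analysis requires a balanced design (equal group sizes)")
  Y <- as.matrix(design[, within])
  N <- nrow(Y); k <- ncol(Y)
  stopifnot(k >= 2)

  gm <- mean(Y)
  subj_mean <- rowMeans(Y)
  grp_mean <- tapply(subj_mean, g_lab, mean)
  lvl_mean <- colMeans(Y)
  cell_mean <- apply(Y, 2, function(col) tapply(col, g_lab, mean)) # g x k

  ss_group <- k * sum(counts * (grp_mean - gm)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[g_lab])^2)
  ss_power <- N * sum((lvl_mean - gm)^2)
  ss_gp <- sum(rep(counts, k) *
                 (cell_mean - outer(as.numeric(grp_mean), rep(1, k)) -
                    outer(rep(1, g), lvl_mean) + gm)^2)
  ss_within_total <- sum((Y - subj_mean)^2)
  ss_err <- ss_within_total - ss_power - ss_gp

  df_group <- g - 1; df_subj <- N - g
  df_power <- k - 1; df_gp <- (g - 1) * (k - 1); df_err <- (N - g) * (k - 1)
  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  if (ms_subj <= 0 && ms_err <= 0)
    stop("degenerate design: zero within-cell variance everywhere")
  f_group <- (ss_group / df_group) / ms_subj
  f_power <- (ss_power / df_power) / ms_err
  f_gp <- (ss_gp / df_gp) / ms_err

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  S <- matrix(0, k, k)
  for (lv in levels(g_lab)) {
    Yg <- Y[g_lab == lv, , drop = FALSE]
    S <- S + (nrow(Yg) - 1) * stats::cov(Yg)
  }
  S <- S / (N - g)
  C <- .orthonormal_contrasts(k)
  M <- C %*% S %*% t(C)
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  structure(list(
    F_group = f_group, df_group = c(df_group, df_subj),
    p_group = pf(f_group, df_group, df_subj, lower.tail = FALSE),
    F_power = f_power, df_power = c(df_power, df_err),
    df_power_gg = eps * c(df_power, df_err),
    p_power_gg = pf(f_power, eps * df_power, eps * df_err, lower.tail = FALSE),
    F_interaction = f_gp, df_interaction = c(df_gp, df_err),
    df_interaction_gg = eps * c(df_gp, df_err),
    p_interaction_gg = pf(f_gp, eps * df_gp, eps * df_err,
                          lower.tail = FALSE),
    epsilon = eps,
    ss = c(group = ss_group, subj = ss_subj, power = ss_power,
           interaction = ss_gp, error = ss_err)),
    class = "mixed_anova")
}

# (k-1) x k matrix of orthonormal contrasts orthogonal to the unit vector
.orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)           # k x (k-1), columns orthogonal
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  t(H)
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA (Greenhouse-Geisser corrected)\n")
  cat(sprintf("  GROUP:       F(%d, %d) = %.2f, p = %.4g\n",
              x$df_group[1], x$df_group[2], x$F_group, x$p_group))
  cat(sprintf("  POWER:       F(%.2f, %.2f) = %.2f, p = %.4g (eps = %.3f)\n",
              x$df_power_gg[1], x$df_power_gg[2], x$F_power, x$p_power_gg,
              x$epsilon))
  cat(sprintf("  GROUP:POWER: F(%.2f, %.2f) = %.2f, p = %.4g\n",
              x$df_interaction_gg[1], x$df_interaction_gg[2],
              x$F_interaction, x$p_interaction_gg))
  invisible(x)
}

#' Log-transform the repeated measures of a group design
#'
#' Variance-stabilization option: natural log applied elementwise to the
#' response columns after adding \code{offset}.
#'
#' @param design as in \code{\link{mixed_anova}}
#' @param offset added before taking logs; all values + offset must be > 0
#' @param within response column names
#' @return the transformed design, with attribute \code{log_offset}
#' @export
log_transform_powers <- function(design, offset = 0,
                                 within = c("p40_40", "p20_40", "p30_30")) {
  for (cl in within) {
    v <- design[[cl]] + offset
    if (any(v <= 0))
      stop("non-positive response after offset; increase offset")
    design[[cl]] <- log(v)
  }
  attr(design, "log_offset") <- offset
  design
}
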