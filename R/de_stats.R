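# Differential expression on the unified abundance matrix.

#' Trim an abundance matrix for differential analysis
#'
#' Drops pool-role sample columns (bridge and validation pools are technical
#' replicates, not individuals) and keeps only entries measured in every
#' remaining sample.
#'
#' @param a an abundance `quant_matrix`.
#' @param design the `plex_design`.
#' @return list with `matrix` (complete-case `quant_matrix`), `groups`
#'   (named phenotype factor over the retained samples) and `n_dropped_incomplete`.
#' @export
trim_matrix <- function(a, design) {
  nonref <- design[design$role != "reference", , drop = FALSE]
  keep_samples <- nonref$sample_id[nonref$role == "individual"]
  keep_samples <- intersect(colnames(a), keep_samples)
  m <- a[, keep_samples, drop = FALSE]
  complete <- rowSums(is.na(m)) == 0
  if (!any(complete)) pb_stop("empty_result", "no complete entries remain")
  m <- m[complete, , drop = FALSE]
  groups <- nonref$phenotype[match(keep_samples, nonref$sample_id)]
  list(matrix = quant_matrix(unclass(m), level = attr(a, "level"),
                             kind = attr(a, "kind")),
       groups = stats::setNames(groups, keep_samples),
       n_dropped_incomplete = sum(!complete))
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma scale
# (monotone, well conditioned).  Used to fit the prior df by matching the
# dispersion of log sample variances to a scaled F distribution.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-12) break
  }
  y
}

# Fit prior df d0 and prior variance s0sq of the scaled-F model for sample
# variances: s2_g ~ s0sq * F(df_g, d0).  Moment matching on log variances.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0sq = stats::median(s2[s2 > 0])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (sum(ok) - 1) - trigamma(df / 2)
  if (e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed dispersion below the theoretical minimum: no excess
    # entry-to-entry variance heterogeneity, shrink completely
    d0 <- Inf
    s0sq <- exp(e_mean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Fits, per entry, a two-group comparison (PDR minus control by
#' convention): the pooled residual variance `s2_g` on `df_g = n1 + n2 - 2`
#' degrees of freedom is shrunk toward a prior variance `s0sq` fitted across
#' all entries, `s2_post = (d0*s0sq + df_g*s2_g) / (d0 + df_g)`, and the
#' moderated t-statistic `t = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` is
#' referred to a t distribution on `d0 + df_g` degrees of freedom
#' (two-sided).  The hyperparameters `(d0, s0sq)` are fitted by matching
#' moments of the log sample variances to a scaled F distribution; `d0` may
#' be `+Inf` (complete shrinkage) when the observed variance dispersion is
#' below the theoretical minimum.
#'
#' @param m complete-case entries x samples matrix (log2 abundances).
#' @param groups character/factor of length `ncol(m)` with exactly two
#'   levels; the fold change is `mean(group2) - mean(group1)` with groups in
#'   `levels` order (default sorts so that `CTL` is the baseline).
#' @param d0 optional fixed prior df (testing hook): `0` gives the ordinary
#'   pooled-variance t-test, `Inf` fixes every posterior variance at `s0sq`.
#' @param s0sq optional fixed prior variance (used with `d0`).
#' @return list with `table` (a `data.frame`: `entry_id`, `mean_ctl`,
#'   `mean_pdr`, `log2fc`, `linear_fc` (signed fold magnitude >= 1), `s2`,
#'   `s2_posterior`, `t_mod`, `df_total`, `p`) and `hyper` (`d0`, `s0sq`).
#' @export
fit_moderated_t <- function(m, groups, d0 = NULL, s0sq = NULL) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) pb_stop("design_error", "exactly two groups required")
  g1 <- groups == lev[1]; g2 <- groups == lev[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) pb_stop("design_error", "each group needs >= 2 samples")
  m <- as.matrix(m)
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, g2, drop = FALSE])
  ss1 <- rowSums((m[, g1, drop = FALSE] - mean1)^2)
  ss2 <- rowSums((m[, g2, drop = FALSE] - mean2)^2)
  df_g <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df_g
  if (is.null(d0)) {
    if (all(s2 == 0)) {
      pb_warn("zero variance in all entries; falling back to ordinary t")
      hyper <- list(d0 = 0, s0sq = 0)
    } else {
      hyper <- fit_variance_prior(s2, df_g)
    }
  } else {
    hyper <- list(d0 = d0, s0sq = s0sq %||% stats::median(s2))
  }
  if (is.infinite(hyper$d0)) {
    s2_post <- rep(hyper$s0sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (hyper$d0 == 0) {
    s2_post <- s2
    df_total <- rep(df_g, length(s2))
  } else {
    s2_post <- (hyper$d0 * hyper$s0sq + df_g * s2) / (hyper$d0 + df_g)
    df_total <- rep(hyper$d0 + df_g, length(s2))
  }
  log2fc <- mean2 - mean1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  tab <- data.frame(entry_id = rownames(m),
                    mean_ctl = mean1, mean_pdr = mean2,
                    log2fc = log2fc,
                    linear_fc = sign(log2fc) * 2^abs(log2fc),
                    s2 = s2, s2_posterior = s2_post,
                    t_mod = t_mod, df_total = df_total, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, hyper = hyper,
       groups = stats::setNames(list(lev[1], lev[2]), c("baseline", "contrast")))
}

#' Storey q-values
#'
#' Estimates the null proportion with the fixed-lambda estimator
#' `pi0 = #\{p > lambda\} / ((1 - lambda) * m)` (capped at 1) and converts
#' p-values to q-values by the step-up minimum
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.  With `pi0 = 1` the q-values
#' equal Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda tuning parameter of the pi0 estimator (default 0.5).
#' @param pi0 optionally override the estimate.
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  if (!length(p)) return(list(q = numeric(0), pi0 = NA_real_))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    pb_stop("domain_error", "p-values must lie in [0,1]")
  }
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Run differential expression on a trimmed matrix
#'
#' Convenience wrapper: moderated t per entry, Storey q-values, and blood
#' annotation carried through.
#'
#' @param trimmed result of [trim_matrix()] (or a list with `matrix` and
#'   `groups`).
#' @param lambda Storey lambda.
#' @param annotation optional named annotation vector (`plasma`/`rbc`/`other`)
#'   as from [annotate_blood()].
#' @return list with `table` (DE results including `q`), `hyper`, `pi0`.
#' @export
run_de <- function(trimmed, lambda = 0.5, annotation = NULL) {
  fit <- fit_moderated_t(trimmed$matrix, trimmed$groups)
  st <- storey_q(fit$table$p, lambda = lambda)
  fit$table$q <- st$q
  fit$table$annotation <-
    if (is.null(annotation)) "other"
    else unname(annotation[fit$table$entry_id])
  list(table = fit$table, hyper = fit$hyper, pi0 = st$pi0)
}

#' Classify DE results for a volcano display
#'
#' Flags entries significant at `q < q_cut` (strict), high-fold-change at
#' linear fold magnitude `> fc_cut` (strict), and both.
#'
#' @param results DE result `data.frame` with `q` and `linear_fc` columns.
#' @param fc_cut linear fold-change cut (default 1.5).
#' @param q_cut q-value cut (default 0.05).
#' @return the input with logical columns `significant`, `high_fc`, `both`.
#' @export
volcano_table <- function(results, fc_cut = 1.5, q_cut = 0.05) {
  if (!nrow(results)) pb_stop("domain_error", "no DE results to classify")
  results$significant <- results$q < q_cut
  results$high_fc <- abs(results$linear_fc) > fc_cut
  results$both <- results$significant & results$high_fc
  results
}
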