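# Standardized effect sizes and FDR-controlled prospective power.

#' Hedges' g effect size with noncentral-t confidence interval
#'
#' The bias-corrected standardized mean difference
#' `g = J * (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and the
#' small-sample correction `J = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`.
#' The 95% CI is obtained by inverting the noncentral-t pivot of the
#' two-sample t-statistic (a normal approximation is used for df > 200).
#' Groups with zero pooled SD in both arms yield an undefined effect, which
#' is reported with a warning flag rather than dropped silently.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param conf confidence level (default 0.95).
#' @return list with `delta` (`mean(x) - mean(y)`), `s_pooled`, `g`,
#'   `ci_low`, `ci_high`, `df`, `J`, and `degenerate` (TRUE when
#'   `s_pooled == 0`).
#' @export
hedges_g <- function(x, y, conf = 0.95) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) pb_stop("domain_error", "each group needs >= 2 values")
  df <- n1 + n2 - 2
  delta <- mean(x) - mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  s_pooled <- sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  if (s_pooled == 0) {
    return(list(delta = delta, s_pooled = 0, g = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, df = df, J = J,
                degenerate = TRUE))
  }
  d <- delta / s_pooled
  g <- J * d
  n_eff <- n1 * n2 / (n1 + n2)
  t_obs <- d * sqrt(n_eff)
  alpha <- 1 - conf
  if (df > 200) {
    # normal approximation to the g sampling distribution
    se_g <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
    ci <- g + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se_g
  } else {
    ci_ncp <- c(ncp_root(t_obs, df, 1 - alpha / 2),
                ncp_root(t_obs, df, alpha / 2))
    ci <- J * ci_ncp / sqrt(n_eff)
  }
  list(delta = delta, s_pooled = s_pooled, g = g,
       ci_low = ci[1], ci_high = ci[2], df = df, J = J, degenerate = FALSE)
}

# Solve pt(t_obs, df, ncp) = target for the noncentrality parameter.
ncp_root <- function(t_obs, df, target) {
  f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - target
  width <- max(4, abs(t_obs)) * 4
  lo <- t_obs - width; hi <- t_obs + width
  # pt is decreasing in ncp; widen the bracket until it straddles the root
  for (i in 1:20) {
    if (f(lo) > 0 && f(hi) < 0) break
    lo <- lo - width; hi <- hi + width
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Two-sided two-sample t power at per-comparison level alpha, equal group
# size n per group: noncentrality g * sqrt(n/2) on 2n - 2 df.
# unequal = c(n1, n2) switches to noncentrality g * sqrt(n1 n2 / (n1 + n2)).
t_power <- function(alpha, g, n, unequal = NULL) {
  if (is.null(unequal)) {
    df <- 2 * n - 2
    ncp <- abs(g) * sqrt(n / 2)
  } else {
    df <- sum(unequal) - 2
    ncp <- abs(g) * sqrt(prod(unequal) / sum(unequal))
  }
  tc <- stats::qt(1 - alpha / 2, df)
  suppressWarnings(stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp))
}

#' Per-comparison alpha and power under FDR control
#'
#' For a planned experiment with `n` samples per group, an anticipated
#' standardized effect `g` for the non-null features, and a fraction `pi0`
#' of true nulls, finds the per-comparison significance level `alpha`
#' at which the expected false discovery rate equals the target:
#' `fdr = pi0 * alpha / (pi0 * alpha + (1 - pi0) * power(alpha))`,
#' where `power` is the two-sided two-sample t power with noncentrality
#' `g * sqrt(n/2)` on `2n - 2` degrees of freedom.  `alpha` is solved by
#' bracketed root-finding to an FDR residual below 1e-10, and the power at
#' the solution is returned.
#'
#' @param n per-group sample size (>= 2).
#' @param g assumed effect size (nonzero).
#' @param fdr target false discovery rate in (0, 1).
#' @param pi0 assumed null proportion in (0, 1).
#' @return list with `alpha`, `power`, and `attained` (FALSE with power 0
#'   when no root exists in (0, 1), e.g. an unattainably low fdr for a tiny
#'   effect).
#' @export
fdr_alpha <- function(n, g, fdr, pi0) {
  stopifnot(n >= 2, g != 0, fdr > 0, fdr < 1, pi0 > 0, pi0 < 1)
  fdr_at <- function(alpha) {
    pw <- t_power(alpha, g, n)
    pi0 * alpha / (pi0 * alpha + (1 - pi0) * pw)
  }
  eps <- 1e-12
  f <- function(a) fdr_at(a) - fdr
  if (f(eps) > 0 || f(1 - eps) < 0) {
    return(list(alpha = NA_real_, power = 0, attained = FALSE))
  }
  root <- stats::uniroot(f, c(eps, 1 - eps), tol = 1e-14)$root
  # polish until the defining identity holds to 1e-10
  for (i in 1:5) {
    if (abs(f(root)) < 1e-10) break
    root <- stats::uniroot(f, c(max(eps, root / 2), min(1 - eps, root * 2)),
                           tol = 1e-15)$root
  }
  list(alpha = root, power = t_power(root, g, n), attained = TRUE)
}

#' FDR-controlled power curve over sample size
#'
#' Evaluates [fdr_alpha()] power over `n = 2 .. n_max` and reports the
#' smallest per-group sample size reaching a target power.
#'
#' @param g assumed effect size.
#' @param fdr target FDR (default 0.05).
#' @param pi0 assumed null proportion (default 0.7).
#' @param n_max largest per-group size evaluated (default 30).
#' @param target_power power threshold for `n_min` (default 0.8; a common
#'   but arbitrary convention).
#' @return list with `n_grid`, `power` (nondecreasing in n), `n_min`
#'   (NA when the target is not reached by `n_max`), `g`, `fdr`, `pi0`.
#' @export
power_curve <- function(g, fdr = 0.05, pi0 = 0.7, n_max = 30,
                        target_power = 0.8) {
  stopifnot(n_max >= 2)
  n_grid <- 2:n_max
  pw <- vapply(n_grid, function(n) fdr_alpha(n, g, fdr, pi0)$power, numeric(1))
  reach <- which(pw >= target_power)
  list(n_grid = n_grid, power = pw,
       n_min = if (length(reach)) n_grid[min(reach)] else NA_integer_,
       g = g, fdr = fdr, pi0 = pi0, target_power = target_power)
}

#' Per-entry effect sizes over an abundance matrix
#'
#' Computes Hedges' g (PDR minus control) for every entry of a complete-case
#' matrix, plus the percentile rank of each |g| among all entries
#' (convention: percentage of entries with |g| less than or equal).
#'
#' @param trimmed result of [trim_matrix()].
#' @return `data.frame` with `entry_id`, `delta`, `s_pooled`, `g`, `ci_low`,
#'   `ci_high`, `percentile_rank`, `degenerate`.
#' @export
effect_table <- function(trimmed) {
  m <- as.matrix(trimmed$matrix)
  groups <- as.character(trimmed$groups)
  lev <- sort(unique(groups))
  g2 <- m[, groups == lev[2], drop = FALSE]   # contrast group (e.g. PDR)
  g1 <- m[, groups == lev[1], drop = FALSE]   # baseline (e.g. CTL)
  res <- lapply(seq_len(nrow(m)), function(i) hedges_g(g2[i, ], g1[i, ]))
  tab <- data.frame(entry_id = rownames(m),
                    delta = vapply(res, `[[`, 0, "delta"),
                    s_pooled = vapply(res, `[[`, 0, "s_pooled"),
                    g = vapply(res, `[[`, 0, "g"),
                    ci_low = vapply(res, `[[`, 0, "ci_low"),
                    ci_high = vapply(res, `[[`, 0, "ci_high"),
                    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
                    stringsAsFactors = FALSE, row.names = NULL)
  absg <- abs(tab$g)
  ok <- !is.na(absg)
  pr <- rep(NA_real_, nrow(tab))
  pr[ok] <- vapply(absg[ok], function(v) 100 * mean(absg[ok] <= v), numeric(1))
  tab$percentile_rank <- pr
  tab
}

#' Scatter-table of effect components
#'
#' Emits, per entry, the delta magnitude, the inverse dispersion
#' (`1 / s_pooled`), the Hedges' g estimate, and its percentile rank: the
#' product of the first two coordinates times the small-sample correction
#' reconstructs g.
#'
#' @param effects result of [effect_table()].
#' @param df residual degrees of freedom used for the correction factor
#'   (inferred from the design when called via [effect_table()] outputs of a
#'   two-group comparison; needed to reconstruct `J`).
#' @return `data.frame` with `entry_id`, `abs_delta`, `inv_dispersion`, `g`,
#'   `percentile_rank`.
#' @export
effect_scatter_table <- function(effects, df) {
  if (!nrow(effects)) pb_stop("domain_error", "no effects supplied")
  data.frame(entry_id = effects$entry_id,
             abs_delta = abs(effects$delta),
             inv_dispersion = ifelse(effects$s_pooled > 0,
                                     1 / effects$s_pooled, NA_real_),
             J = 1 - 3 / (4 * df - 1),
             g = effects$g,
             percentile_rank = effects$percentile_rank,
             stringsAsFactors = FALSE)
}
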