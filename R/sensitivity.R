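#' Cochran Q heterogeneity statistic
#'
#' Q = sum of `w_j (ratio_j - beta)^2` over instruments, with IVW weights
#' `w_j = b_x^2 / s_y^2`; under homogeneity Q is chi-squared with
#' `n_snp - 1` degrees of freedom. A p-value below 0.05 flags heterogeneity
#' among the instruments.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param beta_ivw The IVW causal estimate (defaults to computing it).
#' @return A `heterogeneity_report`: list with `q`, `df`, `pval`,
#'   `heterogeneous` (p < 0.05).
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  n <- nrow(h)
  if (n < 2) stop("Cochran Q requires at least 2 instruments")
  if (is.null(beta_ivw)) beta_ivw <- mr_ivw(h)$beta
  w <- h$beta_exposure^2 / h$se_outcome^2
  ratio <- h$beta_outcome / h$beta_exposure
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- n - 1
  pval <- pchisq(q, df = df, lower.tail = FALSE)
  structure(list(q = q, df = df, pval = pval,
                 heterogeneous = pval < 0.05),
            class = "heterogeneity_report")
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Flags directional pleiotropy when the intercept p-value is below
#' `alpha`; the screening cascade passes a pair only when the intercept
#' p-value is strictly greater than 0.05.
#'
#' @param e An `mr_egger_estimate` (see [mr_egger()]).
#' @param alpha Significance level, default 0.05.
#' @return List with `intercept_pval`, `pleiotropy_present`
#'   (`p < alpha`), and `pass` (`p > alpha`, strict).
#' @export
egger_intercept_test <- function(e, alpha = 0.05) {
  stopifnot(inherits(e, "mr_egger_estimate"))
  p <- e$intercept_pval
  list(intercept_pval = p,
       pleiotropy_present = p < alpha,
       pass = p > alpha)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate `n_snp` times, omitting each instrument in turn,
#' to check whether any single variant drives the result. A variant is
#' flagged as driving when its omission flips the sign of the estimate or
#' moves the p-value across 0.05.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param effects_model IVW effects model.
#' @return A `data.frame` with one row per omitted variant:
#'   `omitted_variant_id`, `beta`, `se`, `pval`, `driving`; the full-set
#'   estimate is carried in attributes `full_beta` and `full_pval`.
#' @export
leave_one_out <- function(h, effects_model = "multiplicative_random") {
  n <- nrow(h)
  if (n < 3) stop("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(h, effects_model)
  rows <- lapply(seq_len(n), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], effects_model)
    data.frame(omitted_variant_id = h$variant_id[j],
               beta = fit$beta, se = fit$se, pval = fit$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$driving <- sign(out$beta) != sign(full$beta) |
    ((out$pval < 0.05) != (full$pval < 0.05))
  structure(out, full_beta = full$beta, full_pval = full$pval)
}

ivw_fixed_slope <- function(bx, by, sy) {
  sum(bx * by / sy^2) / sum(bx^2 / sy^2)
}

# leave-one-out fixed-effect IVW slopes for every index at once
loo_slopes <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(bx * by * w)
  sxx <- sum(bx^2 * w)
  (sxy - bx * by * w) / (sxx - bx^2 * w)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal-pleiotropy outliers by parametric resampling. The
#' observed leave-one-out weighted residual sum of squares is compared with
#' its distribution under `n_sim` simulations from the no-pleiotropy model
#' (global test); each instrument's observed squared residual is compared
#' with its simulated distribution (per-SNP test, Bonferroni-adjusted over
#' instruments); when outliers are flagged, the IVW estimate is recomputed
#' without them and the shift is assessed against removals of random
#' non-outlier subsets of the same size (distortion test). Deterministic
#' given `seed`.
#'
#' @param h A `harmonized_set` with at least 4 instruments.
#' @param n_sim Number of simulations, default 1000.
#' @param outlier_alpha Per-SNP significance level after Bonferroni
#'   adjustment, default 0.05.
#' @param seed RNG seed, default 42.
#' @return A `presso_report`: list with `global_pval`, `outlier_indices`,
#'   `outlier_pvals` (Bonferroni-adjusted, one per instrument),
#'   `raw_estimate`, `corrected_estimate` (`NULL` when no outliers),
#'   `distortion_pval` (`NA` when no outliers).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 42) {
  n <- nrow(h)
  if (n < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 1) stop("n_sim must be a positive count")
  set.seed(seed)
  bx <- h$beta_exposure; sx <- h$se_exposure
  by <- h$beta_outcome; sy <- h$se_outcome
  w <- 1 / sy^2

  b_loo <- loo_slopes(bx, by, sy)
  res_obs <- (by - bx * b_loo)^2 * w
  rss_obs <- sum(res_obs)

  # simulate under the no-pleiotropy model: each SNP's expected outcome
  # effect is its exposure effect times the leave-one-out slope
  exp_by <- bx * b_loo
  rss_sim <- numeric(n_sim)
  exceed <- numeric(n)
  for (i in seq_len(n_sim)) {
    bx_s <- rnorm(n, bx, sx)
    by_s <- rnorm(n, exp_by, sy)
    b_loo_s <- loo_slopes(bx_s, by_s, sy)
    res_s <- (by_s - bx_s * b_loo_s)^2 * w
    rss_sim[i] <- sum(res_s)
    exceed <- exceed + (res_s >= res_obs)
  }
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + exceed) / (n_sim + 1)
  adj_p <- pmin(1, raw_p * n)
  outliers <- which(adj_p < outlier_alpha)

  raw_est <- mr_ivw(h)
  corrected <- NULL
  distortion_pval <- NA_real_
  if (length(outliers) > 0 && length(outliers) < n - 1) {
    corrected <- mr_ivw(h[-outliers, , drop = FALSE])
    obs_shift <- raw_est$beta - corrected$beta
    keep <- setdiff(seq_len(n), outliers)
    n_draw <- 1000
    shifts <- vapply(seq_len(n_draw), function(i) {
      drop_i <- sample(keep, length(outliers), replace = TRUE)
      sub <- setdiff(seq_len(n), drop_i)
      raw_est$beta - ivw_fixed_slope(bx[sub], by[sub], sy[sub])
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(shifts) >= abs(obs_shift))) /
      (n_draw + 1)
  }
  structure(list(global_pval = global_pval,
                 outlier_indices = outliers,
                 outlier_pvals = adj_p,
                 raw_estimate = raw_est,
                 corrected_estimate = corrected,
                 distortion_pval = distortion_pval),
            class = "presso_report")
}

#' Scatter- and funnel-plot data tables
#'
#' Emits the per-instrument tables behind the standard MR diagnostic
#' figures: the scatter table pairs each instrument's exposure and outcome
#' betas with the fitted IVW and Egger lines; the funnel table pairs each
#' Wald ratio with its precision `1/se(ratio)`.
#'
#' @param h A `harmonized_set`.
#' @return List of two `data.frame`s, `scatter` and `funnel`.
#' @export
diagnostic_tables <- function(h) {
  ivw <- mr_ivw(h)
  egger <- if (nrow(h) >= 3) mr_egger(h) else NULL
  wr <- wald_ratios(h)
  scatter <- data.frame(variant_id = h$variant_id,
                        b_x = h$beta_exposure, s_x = h$se_exposure,
                        b_y = h$beta_outcome, s_y = h$se_outcome,
                        fit_ivw = ivw$beta * h$beta_exposure,
                        fit_egger = if (is.null(egger)) NA_real_ else
                          egger$intercept + egger$beta * abs(h$beta_exposure),
                        stringsAsFactors = FALSE)
  funnel <- data.frame(variant_id = h$variant_id,
                       ratio = wr$ratio,
                       precision = 1 / wr$se,
                       stringsAsFactors = FALSE)
  list(scatter = scatter, funnel = funnel)
}
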