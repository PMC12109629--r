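new_mr_estimate <- function(method, beta, se, pval, n_snp,
                            extra = list(), class = "mr_estimate") {
  or_ci <- to_odds_ratio(beta, se)
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                   pval = pval, n_snp = n_snp,
                   or_ = or_ci[["or_"]], or_low = or_ci[["or_low"]],
                   or_high = or_ci[["or_high"]]),
              extra),
            class = class)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.4f (95%% CI %.4f-%.4f)\n",
              x$or_, x$or_low, x$or_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or_ = x$or_, or_low = x$or_low, or_high = x$or_high,
             stringsAsFactors = FALSE)
}

two_sided_normal_p <- function(beta, se) {
  ifelse(se > 0, 2 * pnorm(-abs(beta / se)), as.numeric(beta == 0))
}

wald_ratios <- function(h) {
  if (any(h$beta_exposure == 0)) {
    stop("degenerate instrument: exposure beta of 0")
  }
  list(ratio = h$beta_outcome / h$beta_exposure,
       se = h$se_outcome / abs(h$beta_exposure))
}

#' Wald ratio estimate for a single instrument
#'
#' The per-SNP causal estimate: outcome beta divided by exposure beta, with
#' the first-order standard error `s_y / |b_x|`.
#'
#' @param b_x,s_x Exposure beta and standard error.
#' @param b_y,s_y Outcome beta and standard error.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(b_x, s_x, b_y, s_y) {
  if (b_x == 0) stop("degenerate instrument: exposure beta of 0")
  beta <- b_y / b_x
  se <- s_y / abs(b_x)
  new_mr_estimate("wald_ratio", beta, se, two_sided_normal_p(beta, se), 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/s_y^2` — equivalently the inverse-variance
#' weighted mean of per-SNP Wald ratios. Under the multiplicative
#' random-effects model (default) the standard error is inflated by
#' `sqrt(Q/(n-1))` when the heterogeneity exceeds its expectation; the
#' fixed-effect model never inflates. A single instrument falls back to the
#' Wald ratio with a message.
#'
#' @param h A `harmonized_set`.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
mr_ivw <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  n <- nrow(h)
  if (n == 0) stop("no instruments")
  if (n == 1) {
    message("single instrument: IVW falls back to the Wald ratio")
    est <- mr_wald_ratio(h$beta_exposure, h$se_exposure,
                         h$beta_outcome, h$se_outcome)
    est$method <- "ivw"
    return(est)
  }
  w <- h$beta_exposure^2 / h$se_outcome^2
  beta <- sum(h$beta_exposure * h$beta_outcome / h$se_outcome^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (effects_model == "multiplicative_random" && n > 1) {
    ratio <- h$beta_outcome / h$beta_exposure
    q <- sum(w * (ratio - beta)^2)
    phi <- q / (n - 1)
    if (phi > 1) se <- se * sqrt(phi)
  }
  new_mr_estimate("ivw", beta, se, two_sided_normal_p(beta, se), n)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept and weights `1/s_y^2`, after orienting every instrument so the
#' exposure beta is non-negative. The slope is the causal estimate; a
#' non-zero intercept indicates directional pleiotropy. Inference uses the
#' t distribution with n - 2 degrees of freedom; coefficient standard
#' errors are never deflated below the homoskedastic weighted fit
#' (the residual scale is floored at 1, the usual multiplicative
#' random-effects convention).
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return An `mr_egger_estimate` (an `mr_estimate` carrying `intercept`,
#'   `intercept_se`, `intercept_pval`).
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / h$se_outcome^2)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # floor the dispersion at 1: underdispersion must not shrink the SEs
  adj <- if (is.finite(sigma) && sigma > 0) 1 / min(1, sigma) else 1
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] * adj
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * adj
  slope_p <- 2 * pt(-abs(slope / slope_se), df = n - 2)
  int_p <- 2 * pt(-abs(int / int_se), df = n - 2)
  new_mr_estimate("egger", slope, slope_se, slope_p, n,
                  extra = list(intercept = int, intercept_se = int_se,
                               intercept_pval = int_p),
                  class = c("mr_egger_estimate", "mr_estimate"))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  # an instrument holding a majority of the weight is the exact 0.5 quantile
  if (any(w > 0.5)) return(r[which.max(w)])
  s <- cumsum(w) - w / 2
  if (any(abs(s - 0.5) < 1e-12)) return(r[which.min(abs(s - 0.5))])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

boot_se <- function(h, point_fun, n_boot, seed) {
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(h), h$beta_exposure, h$se_exposure)
    by <- rnorm(nrow(h), h$beta_outcome, h$se_outcome)
    point_fun(by / bx, 1 / (h$se_outcome / abs(bx))^2)
  }, numeric(1))
  sd(est)
}

#' Weighted-median estimate
#'
#' The weighted median of per-SNP Wald ratios with inverse-variance weights
#' `1/se(ratio)^2`: ratios are sorted and the estimate is the value at which
#' the centred normalized cumulative weight crosses 0.5, linearly
#' interpolating between bracketing ratios. Consistent when instruments
#' carrying at least half the weight are valid. The standard error comes
#' from a parametric bootstrap (resampling each study's betas from
#' `N(beta, se)`).
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap, default 42.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 42) {
  n <- nrow(h)
  if (n < 3) stop("weighted median requires at least 3 instruments")
  wr <- wald_ratios(h)
  w <- 1 / wr$se^2
  beta <- weighted_median_point(wr$ratio, w)
  se <- boot_se(h, weighted_median_point, n_boot, seed)
  new_mr_estimate("weighted_median", beta, se,
                  two_sided_normal_p(beta, se), n)
}

mode_point <- function(ratio, w, bandwidth_factor = 1) {
  s <- 0.9 * min(sd(ratio), mad(ratio)) * length(ratio)^(-1 / 5)
  if (!is.finite(s) || s <= 0) {
    # degenerate spread: fall back to the (weighted) modal value itself
    tab <- tapply(w, ratio, sum)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  d <- density(ratio, weights = w / sum(w), bw = s * bandwidth_factor)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios:
#' unweighted for the simple mode, inverse-variance weighted for the
#' weighted mode. The kernel bandwidth is `bandwidth_factor` times the
#' modified Silverman rule `0.9 min(sd, mad) n^(-1/5)` applied to the ratio
#' distribution. Consistent when the largest group of instruments sharing a
#' causal effect is valid (ZEMPA). Standard error by parametric bootstrap.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the Silverman bandwidth, default 1.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed RNG seed, default 42.
#' @return An `mr_estimate` with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(h, variant = c("simple", "weighted"),
                    bandwidth_factor = 1, n_boot = 1000, seed = 42) {
  variant <- match.arg(variant)
  n <- nrow(h)
  if (n < 3) stop("mode estimator requires at least 3 instruments")
  wr <- wald_ratios(h)
  if (diff(range(wr$ratio)) < 1e-12) {
    # exact consensus: the ratio distribution is degenerate and so is the
    # sampling distribution of its mode
    return(new_mr_estimate(paste0(variant, "_mode"), wr$ratio[1], 0,
                           as.numeric(wr$ratio[1] == 0), n))
  }
  point_fun <- if (variant == "simple") {
    function(ratio, w) mode_point(ratio, rep(1, length(ratio)),
                                  bandwidth_factor)
  } else {
    function(ratio, w) mode_point(ratio, w, bandwidth_factor)
  }
  w <- 1 / wr$se^2
  beta <- point_fun(wr$ratio, w)
  se <- boot_se(h, point_fun, n_boot, seed)
  new_mr_estimate(paste0(variant, "_mode"), beta, se,
                  two_sided_normal_p(beta, se), n)
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (non-negative).
#' @return Named numeric vector `or_`, `or_low`, `or_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se < 0)) stop("se must be non-negative")
  c(or_ = exp(beta), or_low = exp(beta - Z95 * se),
    or_high = exp(beta + Z95 * se))
}

#' Run the five-method MR suite
#'
#' Computes IVW (the primary method), MR-Egger, weighted median, and the
#' simple and weighted modes on one harmonized exposure-outcome pair. With
#' fewer than three instruments the methods that cannot run are reported as
#' `NULL` and listed in the `unavailable` attribute; IVW degrades to the
#' Wald ratio on a single instrument.
#'
#' @param h A `harmonized_set`.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param n_boot,seed,bandwidth_factor Settings passed to the bootstrap
#'   estimators.
#' @return An `mr_method_bundle`: named list of `mr_estimate`s
#'   (`ivw`, `egger`, `weighted_median`, `simple_mode`, `weighted_mode`).
#' @export
mr_all_methods <- function(h, effects_model = "multiplicative_random",
                           n_boot = 1000, seed = 42, bandwidth_factor = 1) {
  n <- nrow(h)
  bundle <- list(ivw = mr_ivw(h, effects_model),
                 egger = NULL, weighted_median = NULL,
                 simple_mode = NULL, weighted_mode = NULL)
  if (n >= 3) {
    bundle$egger <- mr_egger(h)
    bundle$weighted_median <- mr_weighted_median(h, n_boot, seed)
    bundle$simple_mode <- mr_mode(h, "simple", bandwidth_factor,
                                  n_boot, seed)
    bundle$weighted_mode <- mr_mode(h, "weighted", bandwidth_factor,
                                    n_boot, seed)
  }
  unavailable <- names(bundle)[vapply(bundle, is.null, logical(1))]
  structure(bundle, unavailable = unavailable,
            exposure_name = attr(h, "exposure_name"),
            outcome_name = attr(h, "outcome_name"),
            class = "mr_method_bundle")
}

#' Tabulate an MR method bundle
#'
#' @param x An `mr_method_bundle`.
#' @param ... Unused.
#' @return A `data.frame` with one row per available method: `method`,
#'   `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or_`, `or_low`,
#'   `or_high`.
#' @export
as.data.frame.mr_method_bundle <- function(x, ...) {
  rows <- lapply(Filter(Negate(is.null), unclass(x)), as.data.frame)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_method_bundle <- function(x, ...) {
  cat(sprintf("MR method suite: %s -> %s\n",
              attr(x, "exposure_name") %||% "exposure",
              attr(x, "outcome_name") %||% "outcome"))
  print(as.data.frame(x), digits = 4)
  ua <- attr(x, "unavailable")
  if (length(ua) > 0) {
    cat("unavailable (too few instruments):", paste(ua, collapse = ", "),
        "\n")
  }
  invisible(x)
}
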