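#' Configuration for the synthetic GWAS generator
#'
#' Defines a tripartite summary-statistic scenario: an exposure (e.g. a
#' lipid species), a mediator (e.g. an immune-cell trait), and a binary
#' outcome analysed on the log-odds scale, with known causal parameters.
#' Defaults describe a well-powered quantitative-trait GWAS for the
#' exposure and outcome (n = 100,000 and 200,000) and a smaller
#' immunophenotype-scale study for the mediator (n = 8,000), with 30
#' instruments per trait, per-allele effects around 0.15 SD, and common
#' variants (MAF 0.1-0.4). At these scales every exposure instrument
#' comfortably clears genome-wide significance and the strength filter,
#' while exposure effects transmitted to the mediator stay well below
#' the significance threshold in the mediator study, so the two
#' instrument sets remain essentially disjoint, as in real two-step
#' designs.
#'
#' @param n_snp_exposure,n_snp_mediator Instrument counts per trait.
#' @param gamma_mean,gamma_sd Mean and SD of the per-SNP instrument effect
#'   distribution (shared by exposure and mediator instruments).
#' @param alpha True exposure-to-mediator effect.
#' @param b_m True mediator-to-outcome effect (log-odds per mediator unit).
#' @param tau_direct True direct exposure-to-outcome effect; the total
#'   effect is `tau_direct + alpha * b_m`.
#' @param pleiotropy `"none"`, or `list(type = "balanced", sd = ...)`, or
#'   `list(type = "directional", mean = ..., sd = ...)`: per-instrument
#'   direct effects on the outcome, independent of instrument strength
#'   (the InSIDE condition).
#' @param n_exp,n_med,n_out GWAS sample sizes for the three studies.
#' @param maf_range Minor-allele-frequency interval, subset of (0, 0.5].
#' @param ld_blocks Optional `list(sizes = integer vector summing to
#'   n_snp_exposure, r2 = within-block squared correlation)`; instrument
#'   effects are shared within a block so that clumping has real work.
#' @param palindrome_fraction Fraction of variants assigned A/T or C/G
#'   allele pairs, default 0.25.
#' @param seed RNG seed, default 42.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_snp_exposure = 30,
                             n_snp_mediator = 30,
                             gamma_mean = 0.15,
                             gamma_sd = 0.03,
                             alpha = 0.4,
                             b_m = 0.25,
                             tau_direct = 0.1,
                             pleiotropy = "none",
                             n_exp = 100000,
                             n_med = 8000,
                             n_out = 200000,
                             maf_range = c(0.1, 0.4),
                             ld_blocks = NULL,
                             palindrome_fraction = 0.25,
                             seed = 42) {
  if (is.character(pleiotropy)) pleiotropy <- list(type = pleiotropy)
  stopifnot(n_snp_exposure >= 1, n_snp_mediator >= 1,
            n_exp >= 100, n_med >= 100, n_out >= 100,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleiotropy$type %in% c("none", "balanced", "directional"),
            palindrome_fraction >= 0, palindrome_fraction <= 1)
  if (!is.null(ld_blocks)) {
    stopifnot(sum(ld_blocks$sizes) == n_snp_exposure,
              ld_blocks$r2 >= 0, ld_blocks$r2 <= 1)
  }
  structure(list(n_snp_exposure = n_snp_exposure,
                 n_snp_mediator = n_snp_mediator,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 alpha = alpha, b_m = b_m, tau_direct = tau_direct,
                 pleiotropy = pleiotropy,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 palindrome_fraction = palindrome_fraction,
                 seed = seed),
            class = "synthetic_config")
}

draw_alleles <- function(n, palindrome_fraction) {
  plain <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  palin <- list(c("A", "T"), c("C", "G"), c("T", "A"), c("G", "C"))
  pal <- runif(n) < palindrome_fraction
  pick <- function(pool) pool[[sample.int(length(pool), 1)]]
  t(vapply(pal, function(p) if (p) pick(palin) else pick(plain),
           character(2)))
}

draw_pleiotropy <- function(n, model) {
  switch(model$type,
         none = rep(0, n),
         balanced = rnorm(n, 0, model$sd),
         directional = rnorm(n, model$mean, model$sd))
}

make_study <- function(ids, alleles, eaf, chrom, pos, true_beta, n) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  beta <- rnorm(length(ids), true_beta, se)
  data.frame(variant_id = ids,
             effect_allele = alleles[, 1],
             other_allele = alleles[, 2],
             eaf = eaf, beta = beta, se = se,
             # floor at the smallest normal double: p-values of exactly 0
             # would violate the record invariant p in (0, 1]
             pval = pmax(2 * pnorm(-abs(beta / se)),
                         .Machine$double.xmin),
             n = n, chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

#' Simulate tripartite GWAS summary statistics with known truth
#'
#' Generates exposure, mediator and outcome summary-statistic tables under
#' the structural model: the mediator responds to the exposure with effect
#' `alpha`, and the outcome (log-odds scale) receives `tau_direct` from the
#' exposure directly, `b_m` from the mediator, and optional per-instrument
#' pleiotropy. Each study reports all variants; estimated betas are the
#' true effects plus normal noise with standard error
#' `1/sqrt(2 maf (1-maf) n)`, emulating three fully independent cohorts.
#' A random subset of variants is reported with swapped alleles in the
#' mediator and outcome studies (beta sign flipped accordingly) so that
#' harmonization is exercised on realistic input. Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   (summary-statistics `data.frame`s) and `truth` (a `simulation_truth`
#'   list: realized `gamma` and `delta` vectors, `alpha`, `b_m`,
#'   `tau_direct`, `total_effect`, `mediated_proportion_true`, and the ID
#'   vectors of the two instrument sets).
#' @export
simulate_tripartite <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nx <- config$n_snp_exposure
  nm <- config$n_snp_mediator
  n_all <- nx + nm
  ids <- sprintf("rs%05d", seq_len(n_all))
  ids_x <- ids[seq_len(nx)]
  ids_m <- ids[nx + seq_len(nm)]

  # block structure: exposure instruments may share LD blocks; mediator
  # instruments are always singletons
  if (!is.null(config$ld_blocks)) {
    block_of <- rep(seq_along(config$ld_blocks$sizes),
                    config$ld_blocks$sizes)
  } else {
    block_of <- seq_len(nx)
  }
  gamma_block <- rnorm(max(block_of), config$gamma_mean, config$gamma_sd)
  gamma <- gamma_block[block_of]
  delta <- rnorm(nm, config$gamma_mean, config$gamma_sd)

  eaf <- runif(n_all, config$maf_range[1], config$maf_range[2])
  alleles <- draw_alleles(n_all, config$palindrome_fraction)
  # block members sit close together on one chromosome; distinct blocks
  # are far apart
  pos_block <- c(block_of, max(block_of) + seq_len(nm))
  chrom <- as.character((pos_block - 1) %% 22 + 1)
  within <- stats::ave(pos_block, pos_block, FUN = seq_along)
  pos <- pos_block * 2e7 + within * 5e3

  pl_x <- draw_pleiotropy(nx, config$pleiotropy)
  pl_m <- draw_pleiotropy(nm, config$pleiotropy)
  total <- config$tau_direct + config$alpha * config$b_m

  true_x <- c(gamma, rep(0, nm))
  true_m <- c(config$alpha * gamma, delta)
  true_y <- c(total * gamma + pl_x, config$b_m * delta + pl_m)

  exposure <- make_study(ids, alleles, eaf, chrom, pos, true_x,
                         config$n_exp)
  mediator <- make_study(ids, alleles, eaf, chrom, pos, true_m,
                         config$n_med)
  outcome <- make_study(ids, alleles, eaf, chrom, pos, true_y,
                        config$n_out)

  # report a random subset with swapped allele labels downstream so that
  # harmonization has real work to do
  for (nm_study in c("mediator", "outcome")) {
    st <- get(nm_study)
    sw <- runif(n_all) < 0.3
    st[sw, c("effect_allele", "other_allele")] <-
      st[sw, c("other_allele", "effect_allele")]
    st$beta[sw] <- -st$beta[sw]
    st$eaf[sw] <- 1 - st$eaf[sw]
    assign(nm_study, st)
  }

  truth <- structure(list(gamma = gamma, delta = delta,
                          alpha = config$alpha, b_m = config$b_m,
                          tau_direct = config$tau_direct,
                          total_effect = total,
                          mediated_proportion_true =
                            config$alpha * config$b_m / total,
                          exposure_ids = ids_x, mediator_ids = ids_m),
                     class = "simulation_truth")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a block-diagonal LD matrix
#'
#' Within-block squared correlations are constant at `ld_blocks$r2`,
#' between-block correlations are zero, over the exposure-instrument IDs.
#'
#' @param config A [synthetic_config()] with `ld_blocks` set.
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(config) {
  stopifnot(inherits(config, "synthetic_config"),
            !is.null(config$ld_blocks))
  nx <- config$n_snp_exposure
  ids <- sprintf("rs%05d", seq_len(nx))
  block_of <- rep(seq_along(config$ld_blocks$sizes),
                  config$ld_blocks$sizes)
  r2 <- outer(block_of, block_of, "==") * config$ld_blocks$r2
  diag(r2) <- 1
  ld_matrix(ids, r2)
}

#' Displace one outcome beta by a multiple of its standard error
#'
#' Fixture helper for outlier-detection tests: shifts the effect estimate
#' of one variant by `shift_in_se_units * se`, leaving everything else
#' unchanged.
#'
#' @param stats Summary-statistics `data.frame`.
#' @param index Row index of the variant to displace.
#' @param shift_in_se_units Displacement in SE units.
#' @return The modified `data.frame`.
#' @export
inject_outlier <- function(stats, index, shift_in_se_units) {
  if (length(index) != 1 || index < 1 || index > nrow(stats)) {
    stop("index out of range")
  }
  stats$beta[index] <- stats$beta[index] +
    shift_in_se_units * stats$se[index]
  stats
}

#' Write summary statistics in the TSV dialect the reader expects
#'
#' @param stats Summary-statistics `data.frame`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}
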