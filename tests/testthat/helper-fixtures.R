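# Shared test fixtures and independent oracles, built in code.

# harmonized set straight from vectors
make_h <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                   ids = sprintf("rs%03d", seq_along(bx))) {
  structure(data.frame(variant_id = ids,
                       beta_exposure = bx, se_exposure = sx,
                       beta_outcome = by, se_outcome = sy,
                       stringsAsFactors = FALSE),
            exposure_name = "exposure", outcome_name = "outcome",
            class = c("harmonized_set", "data.frame"))
}

# summary-statistics table straight from vectors
make_stats <- function(ids, ea, oa, beta, se, eaf = NA_real_,
                       pval = 2 * pnorm(-abs(beta / se)), n = 10000) {
  data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             chrom = NA_character_, pos = NA_real_,
             stringsAsFactors = FALSE)
}

# a five-method bundle with prescribed betas and p-values, for screen tests
fake_bundle <- function(betas, ivw_p, egger_intercept_p = 0.5) {
  methods <- c("ivw", "egger", "weighted_median", "simple_mode",
               "weighted_mode")
  bundle <- lapply(seq_along(methods), function(i) {
    e <- list(method = methods[i], beta = betas[i], se = 0.05,
              pval = if (i == 1) ivw_p else 0.04, n_snp = 10)
    class(e) <- if (methods[i] == "egger") {
      c("mr_egger_estimate", "mr_estimate")
    } else {
      "mr_estimate"
    }
    if (methods[i] == "egger") e$intercept_pval <- egger_intercept_p
    e
  })
  names(bundle) <- methods
  structure(bundle, unavailable = character(0), class = "mr_method_bundle")
}

# exhaustive clumping oracle: enumerate all subsets and return the unique
# feasible, priority-maximal one (every excluded variant must conflict with
# an included variant of higher priority). Independent of the greedy code.
clump_oracle <- function(records, ld, r2_max) {
  n <- nrow(records)
  prio <- order(records$pval, records$variant_id)
  rank_of <- integer(n)
  rank_of[prio] <- seq_len(n)
  conflict <- function(i, j) {
    ld$r2[records$variant_id[i], records$variant_id[j]] > r2_max
  }
  for (mask in seq_len(2^n) - 1) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    feasible <- TRUE
    for (i in s) for (j in s) {
      if (i < j && conflict(i, j)) feasible <- FALSE
    }
    if (!feasible) next
    maximal <- TRUE
    for (i in setdiff(seq_len(n), s)) {
      blocked <- any(vapply(s, function(j) {
        rank_of[j] < rank_of[i] && conflict(i, j)
      }, logical(1)))
      if (!blocked) maximal <- FALSE
    }
    if (maximal) return(sort(records$variant_id[s]))
  }
  stop("oracle found no greedy-feasible subset")
}

# random LD instance on <= 8 SNPs for oracle comparison
random_ld_instance <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("rs%03d", sample(100, n))
  r2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) r2[i, j] <- r2[j, i] <- sample(c(0, 0.5, 1), 1,
                                              prob = c(0.5, 0.3, 0.2))
  }
  diag(r2) <- 1
  pvals <- sample(c(1e-12, 1e-10, 1e-9, 1e-8), n, replace = TRUE)
  rec <- make_stats(ids, "A", "G", beta = rep(0.1, n), se = rep(0.01, n),
                    pval = pvals)
  list(records = rec, ld = ld_matrix(ids, r2))
}
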