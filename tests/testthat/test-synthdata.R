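test_that("generation is deterministic and the truth object is consistent", {
  cfg <- synthetic_config(seed = 12)
  s1 <- simulate_tripartite(cfg)
  s2 <- simulate_tripartite(cfg)
  expect_identical(s1, s2)

  tr <- s1$truth
  expect_identical(tr$total_effect, tr$tau_direct + tr$alpha * tr$b_m)
  expect_identical(tr$mediated_proportion_true,
                   tr$alpha * tr$b_m / tr$total_effect)
  expect_equal(nrow(s1$exposure), 60)
  expect_true(all(s1$exposure$se > 0))
  expect_true(all(s1$exposure$pval > 0 & s1$exposure$pval <= 1))

  expect_error(synthetic_config(maf_range = c(0, 0.6)))
  expect_error(synthetic_config(n_exp = 10))
})

test_that("the global null produces null MR estimates", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_tripartite(
      synthetic_config(alpha = 0, b_m = 0, tau_direct = 0, seed = seed))
    iv <- select_instruments(sim$exposure)
    est <- mr_ivw(harmonize(iv, sim$outcome))
    if (abs(est$beta) < 3 * est$se) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("default instruments clear significance and strength filters", {
  pass <- total <- 0
  for (seed in 1:20) {
    sim <- simulate_tripartite(synthetic_config(seed = seed))
    ex <- sim$exposure[sim$exposure$variant_id %in%
                         sim$truth$exposure_ids, ]
    kept <- filter_weak(select_significant(ex), 10)
    pass <- pass + nrow(kept)
    total <- total + nrow(ex)
  }
  expect_gte(pass / total, 0.99)
})

test_that("estimated standard errors shrink as 1/sqrt(n)", {
  ns <- c(1e4, 1e5, 1e6)
  mean_se <- vapply(ns, function(n) {
    sim <- simulate_tripartite(
      synthetic_config(n_exp = n, maf_range = c(0.25, 0.25), seed = 2))
    mean(sim$exposure$se)
  }, numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.01)
})

test_that("LD blocks collapse under clumping as expected", {
  # one 3-SNP block at r2 = 0.8: a single representative survives
  cfg1 <- synthetic_config(n_snp_exposure = 3,
                           ld_blocks = list(sizes = 3, r2 = 0.8), seed = 5)
  sim1 <- simulate_tripartite(cfg1)
  ex1 <- sim1$exposure[sim1$exposure$variant_id %in%
                         sim1$truth$exposure_ids, ]
  expect_equal(nrow(clump(ex1, simulate_ld(cfg1), instrument_criteria())), 1)

  # singleton blocks: nothing is shed
  cfg2 <- synthetic_config(n_snp_exposure = 4,
                           ld_blocks = list(sizes = rep(1, 4), r2 = 0.8),
                           seed = 5)
  sim2 <- simulate_tripartite(cfg2)
  ex2 <- sim2$exposure[sim2$exposure$variant_id %in%
                         sim2$truth$exposure_ids, ]
  expect_equal(nrow(clump(ex2, simulate_ld(cfg2), instrument_criteria())), 4)

  # two blocks of two: one representative each
  cfg3 <- synthetic_config(n_snp_exposure = 4,
                           ld_blocks = list(sizes = c(2, 2), r2 = 0.9),
                           seed = 5)
  sim3 <- simulate_tripartite(cfg3)
  ex3 <- sim3$exposure[sim3$exposure$variant_id %in%
                         sim3$truth$exposure_ids, ]
  expect_equal(nrow(clump(ex3, simulate_ld(cfg3), instrument_criteria())), 2)
})

test_that("outlier injection displaces exactly one outcome beta", {
  sim <- simulate_tripartite(synthetic_config(seed = 3))
  out0 <- sim$outcome
  expect_identical(inject_outlier(out0, 5, 0), out0)
  out1 <- inject_outlier(out0, 5, 10)
  expect_equal(out1$beta[5], out0$beta[5] + 10 * out0$se[5])
  expect_identical(out1$beta[-5], out0$beta[-5])
  expect_error(inject_outlier(out0, 0, 10), "out of range")

  # two injected outliers are both flagged in a clear majority of seeds
  both <- 0
  for (seed in 1:10) {
    s <- simulate_tripartite(synthetic_config(seed = seed + 50))
    iv <- select_instruments(
      s$exposure[s$exposure$variant_id %in% s$truth$exposure_ids, ])
    h <- harmonize(iv, s$outcome)
    h_out <- h
    h_out$beta_outcome[c(2, 9)] <- h_out$beta_outcome[c(2, 9)] +
      10 * h_out$se_outcome[c(2, 9)]
    pr <- mr_presso(h_out, n_sim = 1000, seed = seed)
    if (all(c(2, 9) %in% pr$outlier_indices)) both <- both + 1
  }
  expect_gte(both, 7)
})

test_that("IVW interval coverage of the true total effect is near nominal", {
  n_rep <- 1000
  covered <- 0
  for (seed in seq_len(n_rep)) {
    sim <- simulate_tripartite(synthetic_config(seed = seed + 2000))
    ex <- sim$exposure[sim$exposure$variant_id %in%
                         sim$truth$exposure_ids, ]
    est <- mr_ivw(harmonize(filter_weak(select_significant(ex), 10),
                            sim$outcome))
    if (est$ci_low <= sim$truth$total_effect &&
        sim$truth$total_effect <= est$ci_high) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.93)
  expect_lte(covered / n_rep, 0.97)
})

test_that("summary statistics round-trip through the TSV dialect", {
  sim <- simulate_tripartite(synthetic_config(seed = 8))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, tmp)
  back <- read_summary_stats(tmp)
  expect_equal(back$beta, sim$exposure$beta)
  expect_equal(back$variant_id, sim$exposure$variant_id)
})
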