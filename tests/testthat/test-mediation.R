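test_that("product of coefficients and delta-method CI behave analytically", {
  expect_equal(mediated_effect(-0.1312, 0.051), -0.0066912)
  expect_equal(mediated_effect(0, 0.3), 0)

  ci0 <- mediation_ci(0.4, 0, 0.25, 0)
  expect_equal(ci0$se_xy, 0)
  expect_equal(ci0$ci_low, 0.1)
  expect_equal(ci0$ci_high, 0.1)
  # degenerate product: zero first-stage beta and se
  cid <- mediation_ci(0, 0, 0.25, 0.1)
  expect_equal(cid$se_xy, 0)
  expect_error(mediation_ci(0.1, -0.1, 0.2, 0.1), "non-negative")

  # known variance: var = bx^2 sy^2 + by^2 sx^2
  ci <- mediation_ci(0.5, 0.1, 0.2, 0.05)
  expect_equal(ci$se_xy, sqrt(0.25 * 0.0025 + 0.04 * 0.01))
})

test_that("mediated proportion divides by the total effect in order", {
  expect_error(mediated_proportion(0.1, 0), "undefined")
  expect_equal(mediated_proportion(0.3, 0.3)$proportion, 1)
  p <- mediated_proportion(-0.02, -0.1, ci = c(-0.04, -0.005))
  expect_equal(p$proportion, 0.2)
  # division by a negative total preserves division order (descending pair)
  expect_equal(p$proportion_ci, c(0.4, 0.05))
  # opposing signs give a negative proportion
  expect_lt(mediated_proportion(0.02, -0.1)$proportion, 0)
})

test_that("the mediation decomposition closes exactly", {
  set.seed(41)
  for (i in 1:25) {
    m <- mediation_result(rnorm(1), runif(1, 0, 0.2), rnorm(1),
                          runif(1, 0, 0.2), rnorm(1))
    expect_equal(m$direct_effect + m$beta_xy, m$beta_total, tolerance = 1e-12)
    expect_equal(m$beta_xy, m$beta_x * m$beta_y)
    expect_equal(m$mediated_proportion, m$beta_xy / m$beta_total)
  }
})

test_that("mediation proportion is invariant to exposure unit rescaling", {
  m1 <- mediation_result(0.4, 0.05, 0.25, 0.02, 0.2)
  m2 <- mediation_result(0.4 * 3, 0.05 * 3, 0.25, 0.02, 0.2 * 3)
  expect_equal(m1$mediated_proportion, m2$mediated_proportion)
})

test_that("direction labels distinguish partial mediation from attenuation", {
  # both published pathways: negative mediated effect along a negative
  # total effect -> partial mediation in the protective (negative)
  # direction, the configuration reported as partial negative mediation
  row1 <- mediation_result(-0.1312, 0.057, 0.051, 0.013, log(0.9053))
  row2 <- mediation_result(-0.1512, 0.058, 0.152, 0.036, log(0.9053))
  expect_equal(mediation_label(row1), "partial mediation (negative direction)")
  expect_equal(mediation_label(row2), "partial mediation (negative direction)")
  expect_gt(row1$mediated_proportion, 0)
  expect_gt(row2$mediated_proportion, 0)

  # mediated effect opposing the total -> attenuation, negative proportion
  att <- mediation_result(0.2, 0.05, 0.25, 0.02, -0.1)
  expect_equal(mediation_label(att), "attenuation")
  expect_lt(att$mediated_proportion, 0)
})

test_that("screening applies the three criteria and the Bonferroni verdict", {
  crit <- screen_criteria(ivw_p_max = 0.05, bonferroni_n = 179)
  # suggestive: p = 0.004 passes nominal but not 0.05/179
  v1 <- screen_pair(fake_bundle(rep(0.12, 5), ivw_p = 0.004), criteria = crit)
  expect_equal(v1$verdict, "suggestive")
  # one discordant direction fails
  v2 <- screen_pair(fake_bundle(c(0.12, 0.1, -0.02, 0.1, 0.1),
                                ivw_p = 0.004), criteria = crit)
  expect_equal(v2$verdict, "fail")
  expect_false(v2$direction_pass)
  # below the corrected level: significant
  v3 <- screen_pair(fake_bundle(rep(0.12, 5), ivw_p = 1e-5), criteria = crit)
  expect_equal(v3$verdict, "significant")
  # pleiotropy evidence fails the screen regardless of p
  v4 <- screen_pair(fake_bundle(rep(0.12, 5), ivw_p = 1e-5,
                                egger_intercept_p = 0.01), criteria = crit)
  expect_equal(v4$verdict, "fail")
  # intercept p exactly 0.05 is not a pass
  v5 <- screen_pair(fake_bundle(rep(0.12, 5), ivw_p = 1e-5,
                                egger_intercept_p = 0.05), criteria = crit)
  expect_equal(v5$verdict, "fail")
})

test_that("two-step mediation recovers planted effects end to end", {
  sim <- simulate_tripartite(synthetic_config(seed = 27))
  med <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome)
  expect_equal(med$beta_x, sim$truth$alpha, tolerance = 0.1)
  expect_equal(med$beta_y, sim$truth$b_m, tolerance = 0.15)
  expect_equal(med$beta_xy, sim$truth$alpha * sim$truth$b_m,
               tolerance = 0.05)
  expect_equal(med$mediated_proportion,
               sim$truth$mediated_proportion_true, tolerance = 0.1)
  expect_equal(med$direct_effect + med$beta_xy, med$beta_total, tolerance = 1e-12)

  # null mediator-outcome path: mediated effect centred on zero
  sim0 <- simulate_tripartite(synthetic_config(b_m = 0, seed = 28))
  med0 <- two_step_mediation(sim0$exposure, sim0$mediator, sim0$outcome)
  expect_lt(abs(med0$beta_xy), 4 * abs(med0$beta_x) *
              sqrt(med0$se_y^2 + 1e-12))
})

test_that("reverse MR swaps roles faithfully", {
  sim <- simulate_tripartite(synthetic_config(seed = 33))
  # double swap: reverse of the reverse is the forward analysis
  fwd <- reverse_mr(sim$exposure, sim$outcome, n_boot = 50)
  iv <- select_instruments(sim$exposure)
  manual <- mr_all_methods(harmonize(iv, sim$outcome), n_boot = 50)
  expect_equal(fwd$ivw$beta, manual$ivw$beta)
  expect_equal(fwd$egger$beta, manual$egger$beta)

  # no reverse path: instruments of a trait with no causal effect on the
  # exposure give an estimate centred on zero (mediator's own instruments
  # under alpha = 0 have no exposure association)
  sim_null <- simulate_tripartite(synthetic_config(alpha = 0, seed = 34))
  rev_null <- reverse_mr(sim_null$mediator, sim_null$exposure, n_boot = 50)
  expect_lt(abs(rev_null$ivw$beta), 4 * rev_null$ivw$se)

  # a study with nothing at genome-wide significance cannot instrument
  sim_flat <- simulate_tripartite(
    synthetic_config(alpha = 0, b_m = 0, tau_direct = 0, seed = 35))
  expect_error(reverse_mr(sim_flat$outcome, sim_flat$exposure),
               "no instruments|no variants")
})
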