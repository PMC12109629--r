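test_that("Wald ratio follows b_y/b_x with first-order se", {
  e <- mr_wald_ratio(0.10, 0.01, 0.05, 0.01)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1)
  expect_equal(mr_wald_ratio(0.10, 0.01, 0, 0.01)$beta, 0)
  e2 <- mr_wald_ratio(-0.2, 0.01, 0.06, 0.02)
  expect_equal(e2$beta, -0.3)
  expect_equal(e2$se, 0.1)
  expect_error(mr_wald_ratio(0, 0.01, 0.05, 0.01), "degenerate")
})

test_that("IVW matches the closed-form weighted regression through the origin", {
  h <- make_h(bx = c(0.1, 0.2), by = c(0.06, 0.08), sy = c(0.01, 0.02))
  e <- mr_ivw(h, "fixed")
  expect_equal(e$beta, 0.5)  # (60 + 40) / (100 + 100)
  expect_equal(e$se, 1 / sqrt(200))

  # consensus ratios give the consensus
  h2 <- make_h(c(0.1, 0.3), c(0.05, 0.15), c(0.01, 0.01))
  expect_equal(mr_ivw(h2)$beta, 0.5)

  # a single instrument falls back to the Wald ratio
  h1 <- make_h(0.1, 0.07, 0.02)
  expect_message(e1 <- mr_ivw(h1), "Wald")
  expect_equal(e1$beta, 0.7)
  expect_equal(e1$se, 0.2)

  # algebraic identity: fixed-effects IVW equals the weighted mean of
  # Wald ratios with weights b_x^2/s_y^2
  set.seed(11)
  h3 <- make_h(rnorm(20, 0.1, 0.02), rnorm(20, 0.03, 0.01),
               runif(20, 0.005, 0.02))
  w <- h3$beta_exposure^2 / h3$se_outcome^2
  expect_equal(mr_ivw(h3, "fixed")$beta,
               weighted.mean(h3$beta_outcome / h3$beta_exposure, w))

  # multiplicative random effects never deflates the fixed se
  expect_gte(mr_ivw(h3, "multiplicative_random")$se,
             mr_ivw(h3, "fixed")$se)
})

test_that("Egger regression recovers slope and intercept exactly on a line", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, by = 0.01 + 0.2 * bx, sy = rep(0.01, 4))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)

  # all-null outcome: slope and intercept are zero
  h0 <- make_h(bx, by = rep(0, 4), sy = rep(0.01, 4))
  e0 <- mr_egger(h0)
  expect_equal(e0$beta, 0, tolerance = 1e-12)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)

  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))),
               "at least 3")

  # instruments are oriented to non-negative exposure beta before fitting:
  # flipping the sign of both betas at one SNP changes nothing
  set.seed(4)
  hf <- make_h(rnorm(10, 0.15, 0.03), rnorm(10, 0.05, 0.02),
               runif(10, 0.005, 0.02))
  hswap <- hf
  hswap$beta_exposure[3] <- -hswap$beta_exposure[3]
  hswap$beta_outcome[3] <- -hswap$beta_outcome[3]
  expect_equal(mr_egger(hswap)$beta, mr_egger(hf)$beta)
  expect_equal(mr_egger(hswap)$intercept, mr_egger(hf)$intercept)
})

test_that("weighted median interpolates the cumulative-weight crossing", {
  # equal weights: plain median
  h <- make_h(c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 0.2)

  # a ratio holding the weight majority is the exact 0.5 quantile
  hdom <- make_h(c(1, 1, 1), by = c(0.1, 0.4, 0.9),
                 sy = c(0.5, 0.1, 0.5))  # middle SNP weight share ~0.93
  expect_equal(mr_weighted_median(hdom, n_boot = 50)$beta, 0.4)

  # four ratios with weights (1, 2, 3, 2)/8: centred cumulative weights
  # (0.0625, 0.25, 0.5625, 0.875) cross 0.5 between 0.2 and 0.3 at 0.28
  h4 <- make_h(rep(1, 4), by = c(0.1, 0.2, 0.3, 0.4),
               sy = 1 / sqrt(c(1, 2, 3, 2)))
  expect_equal(mr_weighted_median(h4, n_boot = 50)$beta, 0.28)
  expect_error(mr_weighted_median(make_h(1, 0.1, 0.1)), "at least 3")
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- make_h(rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9), sy = rep(0.05, 4))
  e <- mr_mode(h, "simple", n_boot = 50)
  expect_lt(abs(e$beta - 0.2), 0.05)

  # exact consensus: degenerate distribution, zero bootstrap se
  hc <- make_h(c(0.1, 0.2, 0.4), by = c(0.05, 0.10, 0.20),
               sy = rep(0.01, 3))
  ec <- mr_mode(hc, "simple", n_boot = 50)
  expect_equal(ec$beta, 0.5)
  expect_equal(ec$se, 0)

  # bimodal ratios: the weighted mode sits in the heavier cluster, and
  # matches a fine-grid weighted-density maximization oracle
  set.seed(21)
  ratios <- c(rnorm(6, 0.4, 0.01), rnorm(4, 0.8, 0.01))
  sy <- c(rep(0.02, 6), rep(0.08, 4))  # heavy weights on the 0.4 cluster
  hb <- make_h(rep(1, 10), by = ratios, sy = sy)
  eb <- mr_mode(hb, "weighted", n_boot = 50)
  expect_lt(abs(eb$beta - 0.4), 0.1)
  w <- 1 / sy^2
  bw <- 0.9 * min(sd(ratios), mad(ratios)) * 10^(-1 / 5)
  grid <- seq(0, 1.2, by = 1e-4)
  dens <- vapply(grid, function(x) {
    sum(w * dnorm((x - ratios) / bw))
  }, numeric(1))
  expect_equal(eb$beta, grid[which.max(dens)], tolerance = 0.01)
  expect_error(mr_mode(make_h(c(1, 1), c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
})

test_that("odds-ratio conversion exponentiates the interval", {
  expect_equal(unname(to_odds_ratio(0, 0.1)["or_"]), 1)
  or1 <- to_odds_ratio(0.5, 0.1)
  expect_equal(unname(or1["or_low"]), exp(0.5 - 1.96 * 0.1))
  expect_error(to_odds_ratio(0.1, -1), "non-negative")
})

test_that("the five-method suite agrees on consensus data and degrades gracefully", {
  h <- make_h(c(0.1, 0.2, 0.4, 0.3), by = c(0.05, 0.10, 0.20, 0.15),
              sy = rep(0.01, 4))
  bundle <- mr_all_methods(h, n_boot = 50)
  betas <- vapply(Filter(Negate(is.null), unclass(bundle)),
                  function(e) e$beta, numeric(1))
  expect_equal(length(betas), 5)
  expect_true(all(abs(betas - 0.5) < 1e-6))

  # gross outlier: median and modes resist it better than IVW
  set.seed(9)
  hx <- make_h(rnorm(12, 0.2, 0.02), by = NA, sy = rep(0.01, 12))
  hx$beta_outcome <- 0.5 * hx$beta_exposure + rnorm(12, 0, 0.002)
  hx$beta_outcome[1] <- hx$beta_outcome[1] + 0.30
  b2 <- mr_all_methods(hx, n_boot = 50)
  expect_lt(abs(b2$weighted_median$beta - 0.5), abs(b2$ivw$beta - 0.5))
  expect_lt(abs(b2$weighted_mode$beta - 0.5), abs(b2$ivw$beta - 0.5))

  # two instruments: IVW only, the rest flagged unavailable
  h2 <- make_h(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))
  b3 <- mr_all_methods(h2)
  expect_null(b3$egger)
  expect_setequal(attr(b3, "unavailable"),
                  c("egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_equal(nrow(as.data.frame(b3)), 1)
})

test_that("causal estimates are equivariant to exposure rescaling", {
  set.seed(31)
  h <- make_h(rnorm(15, 0.2, 0.03), rnorm(15, 0.06, 0.02),
              runif(15, 0.005, 0.02))
  h2 <- h
  h2$beta_exposure <- 2 * h$beta_exposure
  h2$se_exposure <- 2 * h$se_exposure
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta / 2)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta / 2)
  expect_equal(mr_weighted_median(h2, n_boot = 50)$beta,
               mr_weighted_median(h, n_boot = 50)$beta / 2)
  expect_equal(mr_mode(h2, "weighted", n_boot = 50)$beta,
               mr_mode(h, "weighted", n_boot = 50)$beta / 2,
               tolerance = 1e-6)
})
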