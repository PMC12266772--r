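test_that("waldRatio matches hand arithmetic and the printed worked example", {
  ## identity instrument
  r1 <- waldRatio(mk_pairs(1, 0.02, 0.3, 0.1))
  expect_equal(r1@beta, 0.3)
  expect_equal(r1@se, 0.1)
  expect_equal(r1@method, "wald")

  ## negative exposure effect
  r2 <- waldRatio(mk_pairs(-0.5, 0.02, 0.2, 0.1))
  expect_equal(r2@beta, -0.4)
  expect_equal(r2@se, 0.2)

  ## PDAP1 whole-blood expression on lifespan, printed effect -0.308 (0.073):
  ## the two-sided p of that estimate is 2.45e-5 at the printed precision
  p <- 2 * pnorm(-abs(-0.308 / 0.073))
  expect_equal(signif(p, 3), 2.45e-5)

  expect_error(waldRatio(mk_pairs(0, 0.02, 0.3, 0.1)), "zero")
  expect_error(waldRatio(mk_pairs(c(1, 1), 0.02, 0.3, 0.1)), "one instrument")
})

test_that("ivw is the precision-weighted mean of ratios", {
  ## two identical ratios: same estimate, se shrinks by sqrt(2)
  r <- ivw(mk_pairs(c(1, 1), 0.02, c(0.4, 0.4), c(0.1, 0.1)))
  expect_equal(r@beta, 0.4)
  expect_equal(r@se, 0.1 / sqrt(2))

  ## hand-computed weighted mean: ratios 0.5 (se .1), 0.3 (se .2)
  r2 <- ivw(mk_pairs(c(1, 1), 0.02, c(0.5, 0.3), c(0.1, 0.2)))
  expect_equal(r2@beta, 0.46)
  expect_equal(r2@se, 1 / sqrt(125))

  ## with equal SEs the estimate reduces to the arithmetic mean
  ratios <- c(0.1, 0.3, 0.2, 0.5)
  r3 <- ivw(mk_pairs(rep(1, 4), 0.02, ratios, rep(0.1, 4)))
  expect_equal(r3@beta, mean(ratios))

  expect_error(ivw(mk_pairs(1, 0.02, 0.4, 0.1)), "waldRatio")
})

test_that("ivw recovers a planted effect from simulated instruments", {
  sim <- simulateInstrumentPanel(50, trueEffect = 0.2, seed = 21)
  r <- ivw(harmonizedPairs(harmonize(sim$exposure, sim$outcome)))
  expect_lt(abs(r@beta - 0.2), 3 * r@se)
})

test_that("mrEgger matches weighted least squares and recovers pleiotropy", {
  ## exact linearity: intercept 0, slope c
  h <- mk_pairs(c(0.1, 0.2, 0.3, 0.4), 0.01,
                0.7 * c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.12, 0.09, 0.11))
  r <- mrEgger(h)
  expect_equal(r@beta, 0.7, tolerance = 1e-12)
  expect_equal(r@eggerIntercept, 0, tolerance = 1e-12)

  ## oracle: stats::lm with the same weights, after orientation
  sim <- simulateInstrumentPanel(15, trueEffect = 0.3, pleiotropy = 0.02,
                                 seed = 4)
  hp <- harmonizedPairs(harmonize(sim$exposure, sim$outcome))
  r2 <- mrEgger(hp)
  s <- ifelse(hp$beta_exp < 0, -1, 1)
  fit <- lm(I(hp$beta_out * s) ~ I(hp$beta_exp * s),
            weights = 1 / hp$se_out^2)
  cf <- summary(fit)$coefficients
  expect_equal(r2@eggerIntercept, unname(cf[1, 1]), tolerance = 1e-10)
  expect_equal(r2@beta, unname(cf[2, 1]), tolerance = 1e-10)
  expect_equal(r2@eggerInterceptPval, unname(cf[1, 4]), tolerance = 1e-8)

  ## planted directional pleiotropy +0.05 is recovered on average
  ints <- vapply(1:60, function(s) {
    sim <- simulateInstrumentPanel(20, trueEffect = 0.2, pleiotropy = 0.05,
                                   seed = 100 + s)
    mrEgger(harmonizedPairs(harmonize(sim$exposure, sim$outcome)))@eggerIntercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05), 0.01)

  ## fewer than 3 instruments: NA fields, not an error
  r3 <- mrEgger(mk_pairs(c(1, 1), 0.02, c(0.4, 0.5), 0.1))
  expect_true(is.na(r3@beta))
  expect_true(is.na(r3@eggerIntercept))
})

test_that("egger intercept test is calibrated under no pleiotropy", {
  ps <- vapply(1:100, function(s) {
    sim <- simulateInstrumentPanel(15, trueEffect = 0.2, seed = 300 + s)
    mrEgger(harmonizedPairs(harmonize(sim$exposure, sim$outcome)))@eggerInterceptPval
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("egger slope with a zero-constrained intercept equals IVW", {
  sim <- simulateInstrumentPanel(12, trueEffect = 0.25, seed = 8)
  hp <- harmonizedPairs(harmonize(sim$exposure, sim$outcome))
  ivw_beta <- ivw(hp)@beta
  fit0 <- lm(beta_out ~ 0 + beta_exp, data = hp, weights = 1 / hp$se_out^2)
  expect_equal(unname(coef(fit0)), ivw_beta, tolerance = 1e-10)
})

test_that("cochranQ matches hand arithmetic and detects heterogeneity", {
  ## identical ratios: Q = 0, p = 1
  q0 <- cochranQ(mk_pairs(c(1, 1), 0.02, c(0.4, 0.4), 0.1))
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_pval, 1)

  ## ratios 0.4 and 0.5 with equal se 0.1: Q = 0.5 on 1 df
  q1 <- cochranQ(mk_pairs(c(1, 1), 0.02, c(0.4, 0.5), 0.1))
  expect_equal(q1$q_stat, 0.5)
  expect_equal(q1$q_pval, pchisq(0.5, 1, lower.tail = FALSE))

  ## heterogeneous ratios reject in most replicates
  rej <- vapply(1:40, function(s) {
    set.seed(s)
    k <- 10
    ratios <- rnorm(k, 0.2, 0.3)          # spread far beyond the SEs
    cochranQ(mk_pairs(rep(1, k), 0.02, ratios, rep(0.05, k)))$q_pval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)

  expect_true(is.na(cochranQ(mk_pairs(1, 0.02, 0.4, 0.1))$q_stat))
})

test_that("steigerFilter follows the variance-explained rule with FALSE ties", {
  ## dominant exposure signal
  h1 <- mk_pairs(30 * 1 / sqrt(30000), 1 / sqrt(30000),
                 3 * 1 / sqrt(500000), 1 / sqrt(500000),
                 n_exp = 30000, n_out = 500000)
  expect_true(steigerFilter(h1))
  ## symmetric signals tie, resolved FALSE
  h2 <- mk_pairs(0.05, 0.01, 0.05, 0.01, n_exp = 1e4, n_out = 1e4)
  expect_false(steigerFilter(h2))
  ## missing n is a hard error
  h3 <- mk_pairs(0.05, 0.01, 0.01, 0.01)
  expect_error(steigerFilter(h3), "ample size")
})

test_that("steiger is accurate under a true exposure-to-outcome chain", {
  ok <- vapply(1:60, function(s) {
    sim <- simulateInstrumentPanel(10, nExp = 30000, nOut = 500000,
                                   trueEffect = 0.2, seed = 500 + s)
    steigerFilter(harmonizedPairs(harmonize(sim$exposure, sim$outcome)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("mrPresso is seed-deterministic and flags a planted outlier", {
  sim <- simulateInstrumentPanel(21, trueEffect = 0.2,
                                 pleiotropy = c(rep(0, 20), 10 / sqrt(50000)),
                                 seed = 77)
  hp <- harmonizedPairs(harmonize(sim$exposure, sim$outcome))
  a <- mrPresso(hp, nSim = 500, seed = 9)
  b <- mrPresso(hp, nSim = 500, seed = 9)
  expect_identical(a, b)
  expect_true("rs0021" %in% a$outlier_ids)
  expect_lt(a$global_pval, 0.05)

  ## too few instruments: absent fields
  few <- mrPresso(mk_pairs(c(1, 1, 1), 0.02, c(0.4, 0.5, 0.3), 0.1))
  expect_true(is.na(few$global_pval))
})

test_that("mrPresso global p is well calibrated under the null", {
  ps <- vapply(1:100, function(s) {
    sim <- simulateInstrumentPanel(10, trueEffect = 0.2, seed = 700 + s)
    mrPresso(harmonizedPairs(harmonize(sim$exposure, sim$outcome)),
             nSim = 300, seed = s)$global_pval
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("runMR dispatches on instrument count and fills the battery", {
  one <- runMR(mk_pairs(1, 0.02, 0.3, 0.1, n_exp = 1e4, n_out = 1e5))
  expect_equal(one@method, "wald")
  expect_true(is.na(one@qStat))

  three <- runMR(mk_pairs(c(0.1, 0.2, 0.3), 0.01, c(0.05, 0.1, 0.14), 0.02,
                          n_exp = 1e4, n_out = 1e5))
  expect_equal(three@method, "ivw")
  expect_false(is.na(three@qPval))
  expect_false(is.na(three@eggerInterceptPval))
  expect_true(is.na(three@pressoGlobalPval))   # needs >= 4

  sim <- simulateInstrumentPanel(10, trueEffect = 0.2, seed = 13)
  ten <- runMR(harmonize(sim$exposure, sim$outcome), seed = 1)
  expect_equal(ten@nSnp, 10L)
  expect_false(is.na(ten@qPval))
  expect_false(is.na(ten@eggerInterceptPval))
  expect_false(is.na(ten@pressoGlobalPval))
  expect_false(is.na(ten@steigerCorrect))

  expect_error(runMR(mk_pairs(1, 0.02, 0.3, 0.1)[0, ]), "no usable")
})
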