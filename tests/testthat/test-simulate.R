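test_that("makeLd builds the documented structures and stays PSD", {
  expect_equal(corMatrix(makeLd(5, "identity")), diag(5),
               ignore_attr = TRUE)

  ar <- makeLd(10, "ar1", 0.9)
  r <- corMatrix(ar)
  expect_equal(r[1, 2], 0.9)
  expect_equal(r[1, 3], 0.81)
  expect_equal(r[4, 8], 0.9^4)

  bl <- makeLd(10, "block", 0.5, blockSize = 5)
  rb <- corMatrix(bl)
  expect_equal(rb[1, 5], 0.5)
  expect_equal(rb[1, 6], 0)

  expect_error(makeLd(5, "ar1", 1), "rho")

  ## PSD across random scenarios (validity would reject otherwise)
  set.seed(2)
  for (i in 1:20) {
    st <- sample(c("ar1", "block", "identity"), 1)
    ld <- makeLd(sample(5:60, 1), st, runif(1, 0, 0.95),
                 blockSize = sample(3:10, 1))
    ev <- eigen(corMatrix(ld), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("simulateTraitSumstats is seed-reproducible and respects invariants", {
  ld <- makeLd(30, "ar1", 0.5)
  a <- simulateTraitSumstats(ld, c(rs0015 = 0.1), 20000, seed = 42)
  b <- simulateTraitSumstats(ld, c(rs0015 = 0.1), 20000, seed = 42)
  expect_identical(records(a), records(b))
  c_ <- simulateTraitSumstats(ld, c(rs0015 = 0.1), 20000, seed = 43)
  expect_false(identical(records(a), records(c_)))

  ## byte-identical files on re-simulation with the same seed
  p1 <- tempfile(); p2 <- tempfile()
  writeSumStats(a, p1); writeSumStats(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(simulateTraitSumstats(ld, c(rs0001 = 0.9), 20000), "0.5")
  expect_error(simulateTraitSumstats(ld, c(zzz = 0.1), 20000), "zzz")
})

test_that("null z-scores have mean ~0, variance ~1 and LD-shaped correlation", {
  ld <- makeLd(12, "ar1", 0.8)
  z <- t(vapply(1:1200, function(s) {
    d <- records(simulateTraitSumstats(ld, numeric(0), 10000, seed = s))
    d$beta / d$se
  }, numeric(12)))
  expect_lt(max(abs(colMeans(z))), 0.12)
  expect_lt(max(abs(apply(z, 2, var) - 1)), 0.15)
  expect_lt(max(abs(cor(z) - corMatrix(ld))), 0.12)
})

test_that("a single causal variant yields the closed-form expected z", {
  ## lambda = sqrt(h2), identity LD: E z_top = sqrt(n h2) ~ 17.3
  ld <- makeLd(20, "identity")
  zs <- vapply(1:60, function(s) {
    d <- records(simulateTraitSumstats(ld, c(rs0010 = 0.1), 30000, seed = s))
    (d$beta / d$se)[10]
  }, numeric(1))
  expect_lt(abs(mean(zs) - sqrt(30000 * 0.01)), 0.5)
})

test_that("p-values under the global null are uniform", {
  ld <- makeLd(2000, "identity")
  d <- records(simulateTraitSumstats(ld, numeric(0), 50000, seed = 99))
  expect_gt(ks.test(d$pval, "punif")$p.value, 0.01)
})

test_that("triangulation scenarios encode their configurations", {
  ## H0: everything null
  h0 <- simulateTriangulationScenario(
    locusScenario(nVariants = 60, causalConfig = "H0", seed = 1))
  expect_null(h0$eqtl)
  expect_equal(length(h0$truth$causal$b), 0)
  expect_gt(min(records(h0$pqtl)$pval), 1e-5)

  ## H4: shared variant recovered as the top coloc variant in most reps
  hit <- vapply(1:10, function(s) {
    sim <- simulateTriangulationScenario(
      locusScenario(nVariants = 150, causalConfig = "H4", seed = s))
    res <- colocAbf(sim$pqtl, sim$outcome)
    res@topSharedVariant == sim$truth$causal$b
  }, logical(1))
  expect_gte(mean(hit), 0.9)

  ## H3 places distinct variants near the requested r2
  h3 <- simulateTriangulationScenario(
    locusScenario(nVariants = 150, causalConfig = "H3", r2Target = 0.5,
                  seed = 2))
  v1 <- h3$truth$causal$b; v2 <- h3$truth$causal$c
  expect_false(v1 == v2)
  r2 <- corMatrix(h3$ld)[v1, v2]^2
  expect_lt(abs(r2 - 0.5), 0.15)

  ## distinct placement under a tight cap fails loudly on a tiny dense panel
  expect_error(simulateTriangulationScenario(
    locusScenario(nVariants = 4, rho = 0.99, causalConfig = "H3",
                  r2Cap = 1e-6, seed = 3)), "cannot place")

  ## reproducibility contract
  s1 <- simulateTriangulationScenario(locusScenario(seed = 7))
  s2 <- simulateTriangulationScenario(locusScenario(seed = 7))
  expect_identical(records(s1$pqtl), records(s2$pqtl))
  expect_identical(records(s1$outcome), records(s2$outcome))
})

test_that("multi-study protein panels behave at the degenerate corners", {
  ## k = 1: a single table; meta is the identity on its MR estimate
  one <- simulateMultiStudyProtein(1, tau2 = 0, baseEffect = -0.2, seed = 3)
  expect_length(one$studies, 1L)
  expect_length(one$outcomes, 1L)
  expect_equal(one$truth$theta, -0.2)

  ## tau2 = 0: every study draws the same causal effect
  flat <- simulateMultiStudyProtein(5, tau2 = 0, baseEffect = -0.15, seed = 4)
  expect_equal(flat$truth$theta, rep(-0.15, 5))
})

test_that("multi-study tau2 is recovered by DL meta on downstream MR", {
  res <- t(vapply(1:60, function(s) {
    msp <- simulateMultiStudyProtein(5, tau2 = 0.01, baseEffect = -0.15,
                                     seed = s)
    ests <- vapply(1:5, function(j) {
      d <- records(msp$studies[[j]])
      inst <- SumStats(d[which.min(d$pval), , drop = FALSE], "s")
      m <- runMR(harmonize(inst, msp$outcomes[[j]]))
      c(m@beta, m@se)
    }, numeric(2))
    mt <- dlMeta(ests[1, ], ests[2, ])
    c(estimate(mt), mt@tau2)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) + 0.15), 0.02)
  expect_gt(mean(res[, 2]), 0.005)
  expect_lt(mean(res[, 2]), 0.02)
})

test_that("instrument panels scale effects and respect the h2 cap", {
  sim <- simulateInstrumentPanel(10, trueEffect = 0.3, seed = 5)
  expect_equal(nVariants(sim$exposure), 10L)
  expect_true(all(abs(sim$truth$lambda) <= 0.15))
  ## same seed reproduces
  sim2 <- simulateInstrumentPanel(10, trueEffect = 0.3, seed = 5)
  expect_identical(records(sim$outcome), records(sim2$outcome))
})
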