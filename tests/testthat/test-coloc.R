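test_that("wakefieldAbf evaluates the shrinkage formula", {
  ## direct evaluation: beta 0.1, se 0.02, prior 0.2
  r <- 0.04 / (0.04 + 4e-4)
  expect_equal(wakefieldAbf(0.1, 0.02, 0.2),
               0.5 * log(1 - r) + 25 * r / 2)
  expect_equal(exp(wakefieldAbf(0.1, 0.02, 0.2)), oracle_abf(0.1, 0.02, 0.2))

  ## z = 0: negative (evidence against association)
  expect_lt(wakefieldAbf(0, 0.05, 0.2), 0)

  ## monotone increasing in |z| at fixed se
  zs <- seq(0, 8, by = 0.5)
  vals <- wakefieldAbf(zs * 0.03, 0.03, 0.2)
  expect_true(all(diff(vals) > 0))

  expect_error(wakefieldAbf(0.1, 0), "se")
})

test_that("colocAbf posteriors equal brute-force enumeration", {
  set.seed(31)
  for (rep in 1:6) {
    k <- sample(10:25, 1)
    beta1 <- rnorm(k, 0, 0.05)
    beta2 <- rnorm(k, 0, 0.05)
    if (rep %% 2 == 0) {          # plant a moderate shared signal
      beta1[3] <- 0.18
      beta2[3] <- 0.15
    }
    se <- rep(0.03, k)
    t1 <- mk_sumstats(sprintf("v%02d", 1:k), beta1, se)
    t2 <- mk_sumstats(sprintf("v%02d", 1:k), beta2, se)
    got <- colocAbf(t1, t2)
    want <- oracle_coloc(beta1, se, beta2, se, 0.2, 0.2)
    expect_equal(posteriors(got), want, tolerance = 1e-10)
  }
})

test_that("colocAbf handles the null and degenerate cases", {
  ## all z ~ 0 in both traits: H0 dominates
  k <- 30
  t1 <- mk_sumstats(sprintf("v%02d", 1:k), rep(1e-6, k), 0.03)
  t2 <- mk_sumstats(sprintf("v%02d", 1:k), rep(-1e-6, k), 0.03)
  res <- colocAbf(t1, t2)
  expect_gt(posteriors(res)["H0"], 0.99)
  expect_false(attr(res, "colocalized"))

  ## too few shared variants is a hard error
  s1 <- mk_sumstats(c("a", "b"), 0.1, 0.02)
  expect_error(colocAbf(s1, s1), "shared variants")
})

test_that("coloc posteriors are invariant to variant ordering", {
  sim <- simulateTriangulationScenario(
    locusScenario(nVariants = 50, causalConfig = "H4", seed = 5))
  d <- records(sim$pqtl)
  perm <- sample(nrow(d))
  shuffled <- SumStats(d[perm, ], traitId(sim$pqtl))
  a <- colocAbf(sim$pqtl, sim$outcome)
  b <- colocAbf(shuffled, sim$outcome)
  expect_equal(posteriors(a), posteriors(b), tolerance = 1e-12)
  expect_equal(a@topSharedVariant, b@topSharedVariant)
})

test_that("increasing the shared prior p12 weakly increases PP.H4", {
  sim <- simulateTriangulationScenario(
    locusScenario(nVariants = 80, causalConfig = "H4",
                  h2 = c(a = 0, b = 0.003, c = 0.003), seed = 6))
  p12s <- c(1e-6, 1e-5, 1e-4, 1e-3)
  h4 <- vapply(p12s, function(p)
    unname(posteriors(colocAbf(sim$pqtl, sim$outcome, p12 = p))["H4"]),
    numeric(1))
  expect_true(all(diff(h4) >= 0))
})

test_that("regionalProbability is PP.H3 + PP.H4", {
  pp <- c(H0 = 0.1, H1 = 0.1, H2 = 0.1, H3 = 0.3, H4 = 0.4)
  res <- new("ColocResult", pp = pp, priors = c(p1 = 1e-4, p2 = 1e-4,
                                                p12 = 1e-5),
             topSharedVariant = "v1", nVariants = 10L)
  expect_equal(regionalProbability(res), 0.7)

  set.seed(9)
  for (i in 1:5) {
    raw <- runif(5)
    pp <- setNames(raw / sum(raw), paste0("H", 0:4))
    r <- new("ColocResult", pp = pp, priors = c(p1 = 1e-4, p2 = 1e-4,
                                                p12 = 1e-5),
             topSharedVariant = "v", nVariants = 10L)
    expect_equal(regionalProbability(r), unname(pp["H3"] + pp["H4"]))
  }
})

test_that("moloc posteriors equal brute-force configuration enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    k <- sample(10:12, 1)
    mk <- function(shift = 0) {
      b <- rnorm(k, 0, 0.04)
      if (shift > 0) b[shift] <- 0.2
      b
    }
    ## mix of null, single-signal and shared-signal layers
    b1 <- mk(ifelse(rep > 2, 4, 0))
    b2 <- mk(ifelse(rep > 1, 4, 0))
    b3 <- mk(ifelse(rep > 3, 7, 0))
    se <- rep(0.03, k)
    t1 <- mk_sumstats(sprintf("v%02d", 1:k), b1, se)
    t2 <- mk_sumstats(sprintf("v%02d", 1:k), b2, se)
    t3 <- mk_sumstats(sprintf("v%02d", 1:k), b3, se)
    got <- moloc(t1, t2, t3)
    want <- oracle_moloc(oracle_abf(b1, se, 0.2), oracle_abf(b2, se, 0.2),
                         oracle_abf(b3, se, 0.2))
    expect_equal(posteriors(got), want, tolerance = 1e-10)
    expect_equal(sum(posteriors(got)), 1, tolerance = 1e-12)
    expect_lte(got@ppCausalVariant, got@ppCausalRegion + 1e-12)
  }
})

test_that("moloc recovers an all-shared causal variant", {
  sim <- simulateTriangulationScenario(
    locusScenario(nVariants = 200, causalConfig = "abc", seed = 19))
  res <- moloc(sim$eqtl, sim$pqtl, sim$outcome)
  expect_gt(res@ppCausalVariant, 0.7)
  expect_true(attr(res, "colocalized"))
  expect_equal(res@bestSnp, sim$truth$causal$a)
})

test_that("moloc marginalized over a noise trait matches two-trait coloc", {
  ## when trait C is pure noise, the total posterior that A and B share a
  ## variant (ab + ab,c + abc) approximates coloc PP.H4 on A,B at matched
  ## per-variant priors
  devs <- vapply(1:6, function(s) {
    sim <- simulateTriangulationScenario(
      locusScenario(nVariants = 100, causalConfig = "ab", seed = 40 + s))
    cr <- colocAbf(sim$eqtl, sim$pqtl, p12 = 1e-5)
    m <- moloc(sim$eqtl, sim$pqtl, sim$outcome, prior2 = 1e-5)
    pp_ab <- sum(posteriors(m)[c("ab", "ab,c", "abc")])
    abs(pp_ab - unname(posteriors(cr)["H4"]))
  }, numeric(1))
  expect_lt(max(devs), 0.05)
})

test_that("moloc rejects mismatched panels", {
  t1 <- mk_sumstats(sprintf("a%02d", 1:12), 0.01, 0.03)
  t2 <- mk_sumstats(sprintf("b%02d", 1:12), 0.01, 0.03)
  expect_error(moloc(t1, t2, t1), "panel")
})
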