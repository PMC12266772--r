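## Synthetic GWAS/QTL summary statistics with the statistical structure the
## pipeline assumes: LD-correlated marginal effects under the RSS model
## z ~ N(sqrt(n) R lambda, R), shared vs. distinct causal variants across an
## expression trait, a protein trait and an outcome, multi-study protein
## panels with between-study heterogeneity, and mediator chains.

#' Build a synthetic LD matrix
#'
#' Three structures: \code{ar1} with \code{r_jk = rho^|j-k|}, \code{block}
#' with diagonal blocks of constant correlation \code{rho}, and
#' \code{identity}. All outputs satisfy the [LDMatrix-class] invariants
#' including positive semi-definiteness. Deterministic.
#'
#' @param nVariants panel size.
#' @param structure \code{"ar1"}, \code{"block"} or \code{"identity"}.
#' @param rho correlation parameter in [0, 1).
#' @param blockSize block width for \code{structure = "block"} (default 50).
#' @param prefix variant-id prefix (ids are \code{<prefix>0001} ...).
#' @return An [LDMatrix-class].
#' @export
makeLd <- function(nVariants, structure = c("ar1", "block", "identity"),
                   rho = 0, blockSize = 50L, prefix = "rs") {
  structure <- match.arg(structure)
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  ids <- sprintf("%s%04d", prefix, seq_len(nVariants))
  r <- switch(structure,
    identity = diag(nVariants),
    ar1 = rho^abs(outer(seq_len(nVariants), seq_len(nVariants), `-`)),
    block = {
      m <- diag(nVariants)
      starts <- seq(1L, nVariants, by = blockSize)
      for (s in starts) {
        e <- min(s + blockSize - 1L, nVariants)
        m[s:e, s:e] <- rho
        diag(m)[s:e] <- 1
      }
      m
    })
  LDMatrix(r, ids)
}

#' Simulate marginal summary statistics for one trait at one locus
#'
#' Draws z-scores from the RSS model \code{z ~ N(sqrt(n) R lambda, R)} given
#' the LD matrix R and standardized causal effects lambda, then converts to
#' the standardized scale: \code{beta = z/sqrt(n)}, \code{se = 1/sqrt(n)}.
#' Effect-allele frequencies are drawn uniform on (0.05, 0.95); alleles are
#' fixed A/G so harmonization is exact. Deterministic given \code{seed}.
#'
#' @param ld [LDMatrix-class] for the locus panel.
#' @param causal named numeric vector of standardized effects lambda; names
#'   must be panel variant ids. Empty or zero for a null trait. The implied
#'   local heritability \code{lambda' R lambda} must not exceed 0.5.
#' @param n GWAS sample size (>= 100).
#' @param traitType \code{"quantitative"} or \code{"case_control"} (the
#'   latter fills ncase/ncontrol with an even split of the effective n and
#'   reports beta on the log-odds scale).
#' @param traitId trait identifier.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param chrom,posStart,posStep coordinates assigned to the panel
#'   (positions \code{posStart + (j-1) posStep}).
#' @param cholR optional precomputed upper Cholesky factor of the LD matrix
#'   (reused across traits/replicates for speed).
#' @return A [SumStats-class].
#' @export
simulateTraitSumstats <- function(ld, causal = numeric(0), n,
                                  traitType = "quantitative",
                                  traitId = "trait", seed = NULL,
                                  chrom = "1", posStart = 1000000L,
                                  posStep = 1000L, cholR = NULL) {
  stopifnot(is(ld, "LDMatrix"), n >= 100)
  k <- nVariants(ld)
  lambda <- numeric(k)
  if (length(causal)) {
    miss <- setdiff(names(causal), ld@variantIds)
    if (length(miss))
      stopf("causal variant(s) not in panel: %s", paste(miss, collapse = ", "))
    lambda[match(names(causal), ld@variantIds)] <- causal
  }
  h2 <- as.numeric(lambda %*% ld@r %*% lambda)
  if (h2 > 0.5)
    stopf("causal effects imply local heritability %.3f > 0.5", h2)
  if (is.null(cholR)) cholR <- chol(ld@r + diag(1e-10, k))
  mean_z <- sqrt(n) * as.numeric(ld@r %*% lambda)

  with_local_seed(seed, {
    z <- rss_draw(cholR, mean_z)
    eaf <- stats::runif(k, 0.05, 0.95)
    d <- data.frame(snp = ld@variantIds, chrom = chrom,
                    pos = posStart + (seq_len(k) - 1L) * posStep,
                    ea = "A", oa = "G", eaf = eaf,
                    beta = z / sqrt(n), se = 1 / sqrt(n),
                    ## floor to keep extreme signals within the (0, 1] domain
                    pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
                    n = n,
                    ncase = if (traitType == "case_control") n / 2 else NA_real_,
                    ncontrol = if (traitType == "case_control") n / 2 else NA_real_,
                    stringsAsFactors = FALSE)
    SumStats(d, traitId = traitId, traitType = traitType,
             region = list(chrom = chrom, start = d$pos[1], end = d$pos[k]))
  })
}

#' Describe a triangulation locus scenario
#'
#' Bundles the parameters of one simulated locus shared by an expression
#' trait (a), a protein trait (b) and an outcome (c): panel size and LD
#' structure, the causal sharing configuration (two-trait hypotheses
#' \code{H0..H4}, interpreted for the protein/outcome pair, or any of the 15
#' three-trait configurations such as \code{"abc"} or \code{"ab,c"}), local
#' heritabilities, sample sizes and trait types.
#'
#' @param nVariants,ldStructure,rho,blockSize panel parameters, see
#'   [makeLd()].
#' @param causalConfig \code{"H0".."H4"} or a three-trait configuration name.
#' @param h2 named or positional numeric(3) local heritabilities (a, b, c);
#'   entries for unassociated traits are ignored. Must lie in [0, 0.5].
#' @param n numeric(3) sample sizes (>= 100 each).
#' @param traitTypes character(3) trait types.
#' @param r2Target when the configuration places distinct causal variants,
#'   aim for this pairwise r^2 between them (NULL: just respect
#'   \code{r2Cap}).
#' @param r2Cap maximum allowed pairwise r^2 between distinct causal
#'   variants (default 0.05); a hard error is raised when no placement
#'   satisfies it.
#' @param seed integer seed.
#' @return list of class \code{"LocusScenario"}.
#' @export
locusScenario <- function(nVariants = 500L, ldStructure = "ar1", rho = 0.9,
                          blockSize = 50L, causalConfig = "H4",
                          h2 = c(a = 0.01, b = 0.01, c = 0.01),
                          n = c(a = 30000, b = 30000, c = 30000),
                          traitTypes = c("quantitative", "quantitative",
                                         "quantitative"),
                          r2Target = NULL, r2Cap = 0.05, seed = 1L) {
  stopifnot(all(h2 >= 0), all(h2 <= 0.5), all(n >= 100))
  cfg <- as.character(causalConfig)
  if (!cfg %in% c(paste0("H", 0:4), .MOLOC_CONFIGS))
    stopf("unknown causal configuration '%s'", cfg)
  structure(list(nVariants = as.integer(nVariants),
                 ldStructure = ldStructure, rho = rho,
                 blockSize = as.integer(blockSize), causalConfig = cfg,
                 h2 = h2, n = n, traitTypes = traitTypes,
                 r2Target = r2Target, r2Cap = r2Cap,
                 seed = as.integer(seed)),
            class = "LocusScenario")
}

## Map the two-trait hypotheses onto sharing groups of the b (exposure) and
## c (outcome) traits.
.two_trait_groups <- list(H0 = list(), H1 = list("b"), H2 = list("c"),
                          H3 = list("b", "c"), H4 = list(c("b", "c")))

## Pick causal variant indices for each sharing group: the first group sits
## at the panel centre; further groups get variants whose pairwise r^2 to
## all previous picks respects r2Cap (or is closest to r2Target).
.place_causals <- function(ld, nGroups, r2Target = NULL, r2Cap = 0.05) {
  k <- nVariants(ld)
  picks <- integer(0)
  for (g in seq_len(nGroups)) {
    if (g == 1L) { picks <- as.integer(ceiling(k / 2)); next }
    r2 <- ld@r[picks, , drop = FALSE]^2
    worst <- apply(r2, 2, max)
    worst[picks] <- Inf
    if (!is.null(r2Target)) {
      cand <- which.min(abs(worst - r2Target))
      if (!is.finite(worst[cand]))
        stopf("cannot place %d distinct causal variants", nGroups)
    } else {
      ok <- which(worst < r2Cap)
      if (length(ok) == 0)
        stopf("cannot place %d distinct causal variants under r2 cap %.3g",
              nGroups, r2Cap)
      cand <- ok[which.min(abs(ok - picks[1]))]  # nearest admissible variant
    }
    picks <- c(picks, as.integer(cand))
  }
  picks
}

#' Simulate a triangulation scenario
#'
#' Generates summary-statistic tables for an expression trait (a), a protein
#' trait (b) and an outcome (c) at one locus, placing shared or distinct
#' causal variants according to the scenario's configuration, plus the ground
#' truth needed for assertions. Two-trait hypotheses \code{H0..H4} apply to
#' the protein/outcome pair, and the expression table is omitted (NULL).
#'
#' @param scenario a [locusScenario()].
#' @return list with elements \code{eqtl}, \code{pqtl}, \code{outcome}
#'   ([SumStats-class] or NULL), \code{ld} and \code{truth} (configuration,
#'   causal variant ids per trait, lambda values).
#' @export
simulateTriangulationScenario <- function(scenario) {
  stopifnot(inherits(scenario, "LocusScenario"))
  ld <- makeLd(scenario$nVariants, scenario$ldStructure, scenario$rho,
               scenario$blockSize)
  cholR <- chol(ld@r + diag(1e-10, nVariants(ld)))
  cfg <- scenario$causalConfig
  two_trait <- cfg %in% paste0("H", 0:4)
  groups <- if (two_trait) .two_trait_groups[[cfg]]
            else .moloc_config_groups[[cfg]]

  picks <- if (length(groups))
    .place_causals(ld, length(groups), scenario$r2Target, scenario$r2Cap)
  else integer(0)

  trait_names <- c("a", "b", "c")
  h2 <- scenario$h2; names(h2) <- trait_names
  nn <- scenario$n; names(nn) <- trait_names
  tt <- scenario$traitTypes; names(tt) <- trait_names

  causal <- list(a = numeric(0), b = numeric(0), c = numeric(0))
  for (g in seq_along(groups)) {
    vid <- ld@variantIds[picks[g]]
    for (tr in groups[[g]]) {
      lam <- sqrt(h2[[tr]])
      causal[[tr]] <- stats::setNames(lam, vid)
    }
  }

  tab <- function(tr, label) {
    simulateTraitSumstats(ld, causal[[tr]], nn[[tr]], tt[[tr]],
                          traitId = label,
                          seed = scenario$seed + match(tr, trait_names),
                          cholR = cholR)
  }
  eqtl <- if (two_trait) NULL else tab("a", "eqtl")
  pqtl <- tab("b", "pqtl")
  outcome <- tab("c", "outcome")

  list(eqtl = eqtl, pqtl = pqtl, outcome = outcome, ld = ld,
       truth = list(config = cfg,
                    causal = lapply(causal, names),
                    lambda = causal))
}

#' Simulate one protein measured in several studies
#'
#' Emulates a protein assayed by k proteomic studies with between-study
#' heterogeneity in the causal effect: the true causal effect seen by study j
#' is drawn \code{theta_j ~ N(baseEffect, tau2)} (between-study variance
#' tau2, e.g. from assay and population differences), a single causal variant
#' drives the protein with effect \code{sqrt(h2Exposure)} in every study, and
#' each study is paired with an outcome draw whose local effect is
#' \code{theta_j} times the protein effect. A DerSimonian-Laird meta-analysis
#' of the per-study MR estimates recovers \code{baseEffect} and \code{tau2}
#' within Monte-Carlo error.
#'
#' @param kStudies number of studies (>= 1).
#' @param tau2 between-study variance of the causal effect (>= 0).
#' @param baseEffect mean causal effect of the protein on the outcome.
#' @param ld locus [LDMatrix-class] (default 100-variant AR(1), rho 0.6).
#' @param h2Exposure local heritability of the protein in each study
#'   (default 0.04, a strong cis signal).
#' @param nExposure,nOutcome study and outcome GWAS sample sizes.
#' @param seed integer seed.
#' @return list with \code{studies} (list of exposure [SumStats-class]),
#'   \code{outcomes} (one outcome draw per study), \code{ld} and
#'   \code{truth} (per-study theta, causal variant id).
#' @export
simulateMultiStudyProtein <- function(kStudies, tau2 = 0, baseEffect = 0,
                                      ld = makeLd(100L, "ar1", 0.6),
                                      h2Exposure = 0.04, nExposure = 30000,
                                      nOutcome = 300000, seed = 1L) {
  stopifnot(kStudies >= 1L, tau2 >= 0)
  cv <- ld@variantIds[ceiling(nVariants(ld) / 2)]
  lam_exp <- sqrt(h2Exposure)
  cholR <- chol(ld@r + diag(1e-10, nVariants(ld)))

  with_local_seed(seed, {
    theta <- stats::rnorm(kStudies, baseEffect, sqrt(tau2))
    studies <- lapply(seq_len(kStudies), function(j)
      simulateTraitSumstats(ld, stats::setNames(lam_exp, cv), nExposure,
                            traitId = sprintf("study%02d", j),
                            cholR = cholR))
    outcomes <- lapply(seq_len(kStudies), function(j) {
      lam_out <- theta[j] * lam_exp
      simulateTraitSumstats(ld,
                            if (lam_out == 0) numeric(0)
                            else stats::setNames(lam_out, cv),
                            nOutcome, traitId = sprintf("outcome%02d", j),
                            cholR = cholR)
    })
    list(studies = studies, outcomes = outcomes, ld = ld,
         truth = list(theta = theta, causal = cv, baseEffect = baseEffect,
                      tau2 = tau2))
  })
}

#' Simulate a target -> mediator -> outcome chain
#'
#' The target has a causal variant at the panel centre with effect
#' \code{sqrt(h2Target)}; the mediator inherits \code{beta1} times the
#' target's effects plus its own independent causal variant; the outcome
#' inherits \code{beta2} times the mediator's effects plus a direct
#' \code{direct} times the target's effects. The implied total effect is
#' \code{beta1 * beta2 + direct}.
#'
#' @param beta1 causal effect target -> mediator.
#' @param beta2 causal effect mediator -> outcome.
#' @param direct direct target -> outcome effect.
#' @param ld locus [LDMatrix-class].
#' @param h2Target local heritability of the target trait.
#' @param h2MediatorOwn variance contributed by the mediator's own variant.
#' @param n numeric(3) sample sizes (target, mediator, outcome).
#' @param seed integer seed.
#' @return list with \code{target}, \code{mediator}, \code{outcome} tables,
#'   \code{ld} and \code{truth}.
#' @export
simulateMediationChain <- function(beta1, beta2, direct = 0,
                                   ld = makeLd(100L, "ar1", 0.6),
                                   h2Target = 0.04, h2MediatorOwn = 0.02,
                                   n = c(30000, 100000, 300000), seed = 1L) {
  k <- nVariants(ld)
  v1 <- ceiling(k / 4)
  v2 <- ceiling(3 * k / 4)
  lamT <- numeric(k); lamT[v1] <- sqrt(h2Target)
  lamM <- beta1 * lamT; lamM[v2] <- lamM[v2] + sqrt(h2MediatorOwn)
  lamO <- beta2 * lamM + direct * lamT
  cholR <- chol(ld@r + diag(1e-10, k))
  ids <- ld@variantIds

  target <- simulateTraitSumstats(ld, stats::setNames(lamT[v1], ids[v1]),
                                  n[1], traitId = "target", seed = seed,
                                  cholR = cholR)
  mediator <- simulateTraitSumstats(
    ld, stats::setNames(lamM[lamM != 0], ids[lamM != 0]), n[2],
    traitId = "mediator", seed = seed + 1L, cholR = cholR)
  outcome <- simulateTraitSumstats(
    ld, stats::setNames(lamO[lamO != 0], ids[lamO != 0]), n[3],
    traitId = "outcome", seed = seed + 2L, cholR = cholR)

  list(target = target, mediator = mediator, outcome = outcome, ld = ld,
       truth = list(beta1 = beta1, beta2 = beta2, direct = direct,
                    total = beta1 * beta2 + direct,
                    targetVariant = ids[v1], mediatorVariant = ids[v2]))
}

#' Simulate a panel of independent instruments for one exposure-outcome pair
#'
#' Instrument-level simulation for calibration and parameter-recovery studies
#' of the MR estimators: k independent variants (identity LD, e.g. one per
#' locus after clumping) with exposure effects spread uniformly over
#' \code{lambdaRange}, and outcome effects \code{trueEffect * lambda +
#' pleiotropy} (a scalar adds directional pleiotropy to every instrument; a
#' vector sets per-instrument pleiotropy, e.g. a single outlier).
#'
#' @param k instrument count.
#' @param nExp,nOut exposure and outcome GWAS sample sizes.
#' @param trueEffect causal effect of the exposure on the outcome.
#' @param pleiotropy scalar or length-k direct effects on the outcome.
#' @param lambdaRange range of exposure instrument effects (standardized).
#' @param seed integer seed.
#' @return list with \code{exposure}, \code{outcome} ([SumStats-class]) and
#'   \code{truth}.
#' @export
simulateInstrumentPanel <- function(k, nExp = 50000, nOut = 50000,
                                    trueEffect = 0, pleiotropy = 0,
                                    lambdaRange = c(0.05, 0.15), seed = 1L) {
  stopifnot(k >= 1)
  ld <- makeLd(k, "identity")
  pl <- rep_len(pleiotropy, k)
  with_local_seed(seed, {
    lam <- stats::runif(k, lambdaRange[1], lambdaRange[2])
    if (sum(lam^2) > 0.5) lam <- lam * sqrt(0.5 / sum(lam^2)) * 0.99
    lam_out <- trueEffect * lam + pl
    exposure <- simulateTraitSumstats(ld, stats::setNames(lam, ld@variantIds),
                                      nExp, traitId = "exposure")
    outcome <- simulateTraitSumstats(
      ld, stats::setNames(lam_out, ld@variantIds)[lam_out != 0], nOut,
      traitId = "outcome")
    list(exposure = exposure, outcome = outcome,
         truth = list(lambda = lam, trueEffect = trueEffect,
                      pleiotropy = pl))
  })
}

#' Simulate a pair of genetically correlated polygenic traits
#'
#' Genome-wide (multi-locus) simulation for bivariate LD score regression:
#' per-variant standardized effects are drawn from a bivariate normal with
#' per-trait variance \code{h2/M} and correlation \code{rg} (infinitesimal
#' model), and z-scores follow the RSS model per LD block. The LD panel is a
#' sequence of constant-correlation blocks whose rho cycles through
#' \code{rhos}, so LD scores vary across variants (a requirement for the
#' regression to be identifiable).
#'
#' @param M number of variants (default 2000).
#' @param n1,n2 GWAS sample sizes.
#' @param h2 numeric(2) trait heritabilities.
#' @param rg true genetic correlation in [-1, 1].
#' @param blockSize LD block width (default 25).
#' @param rhos block correlations cycled across blocks.
#' @param seed integer seed.
#' @return list with \code{z1}, \code{z2}, \code{ell} (LD scores) and
#'   \code{truth}.
#' @seealso [bivariateRg()]
#' @export
simulateBivariateTraits <- function(M = 2000L, n1 = 50000, n2 = 50000,
                                    h2 = c(0.4, 0.4), rg = 0,
                                    blockSize = 25L,
                                    rhos = c(0, 0.3, 0.5, 0.7), seed = 1L) {
  stopifnot(abs(rg) <= 1, all(h2 > 0), M %% blockSize == 0)
  nb <- M / blockSize
  block_rho <- rhos[((seq_len(nb) - 1L) %% length(rhos)) + 1L]
  s <- blockSize

  with_local_seed(seed, {
    ## per-variant effects: bivariate normal, var h2/M, correlation rg
    e1 <- stats::rnorm(M)
    e2 <- rg * e1 + sqrt(1 - rg^2) * stats::rnorm(M)
    lam1 <- sqrt(h2[1] / M) * e1
    lam2 <- sqrt(h2[2] / M) * e2

    z1 <- numeric(M); z2 <- numeric(M); ell <- numeric(M)
    for (b in seq_len(nb)) {
      idx <- ((b - 1L) * s + 1L):(b * s)
      Rb <- matrix(block_rho[b], s, s); diag(Rb) <- 1
      cb <- chol(Rb + diag(1e-10, s))
      ell[idx] <- rowSums(Rb^2)
      z1[idx] <- sqrt(n1) * Rb %*% lam1[idx] + crossprod(cb, stats::rnorm(s))
      z2[idx] <- sqrt(n2) * Rb %*% lam2[idx] + crossprod(cb, stats::rnorm(s))
    }
    list(z1 = z1, z2 = z2, ell = ell,
         truth = list(h2 = h2, rg = rg, M = M, n1 = n1, n2 = n2))
  })
}

#' Simulate the staged-funnel worked fixture
#'
#' A panel of synthetic protein targets in the three classes the filtration
#' funnel must separate: \code{true} targets whose exposure and outcome share
#' a causal variant, \code{confounded} targets whose exposure and outcome
#' carry distinct causal variants in LD (the classic colocalization H3
#' confounding case), and \code{null} targets with an exposure signal but no
#' outcome effect. Every target gets \code{kStudies} exposure studies, one
#' external validation study and a locus-restricted outcome table.
#'
#' @param seed integer seed.
#' @param nTrue,nConfounded,nNull class sizes (defaults 3, 3, 4).
#' @param kStudies exposure studies per target (default 2).
#' @param nVariantsLocus panel size per locus (default 150).
#' @param rho AR(1) LD parameter (default 0.8).
#' @param h2Exposure exposure local heritability (default 0.02).
#' @param causalEffect protein-on-outcome effect for true targets
#'   (default -0.15, a harmful protein).
#' @param confoundedR2 LD r^2 between the distinct causal variants of
#'   confounded targets (default 0.5).
#' @param nExposure,nOutcome sample sizes (defaults 30000 and 500000).
#' @return list with \code{targets} (per-target inputs and truth class) and
#'   \code{seed}.
#' @export
simulateFunnelFixture <- function(seed = 1L, nTrue = 3L, nConfounded = 3L,
                                  nNull = 4L, kStudies = 2L,
                                  nVariantsLocus = 150L, rho = 0.8,
                                  h2Exposure = 0.02, causalEffect = -0.15,
                                  confoundedR2 = 0.5, nExposure = 30000,
                                  nOutcome = 500000) {
  classes <- rep(c("true", "confounded", "null"),
                 c(nTrue, nConfounded, nNull))
  ld <- makeLd(nVariantsLocus, "ar1", rho)
  cholR <- chol(ld@r + diag(1e-10, nVariantsLocus))
  k <- nVariantsLocus
  v1 <- ceiling(k / 2)
  lam_exp <- sqrt(h2Exposure)

  targets <- lapply(seq_along(classes), function(i) {
    cls <- classes[i]
    id <- sprintf("target%02d", i)
    base_seed <- seed * 1000L + i * 10L
    chrom <- as.character(i)
    locus <- geneLocus(id, chrom, 1000000 + (v1 - 10) * 1000,
                       1000000 + (v1 + 10) * 1000)

    out_causal <- switch(cls,
      "true" = stats::setNames(causalEffect * lam_exp, ld@variantIds[v1]),
      "confounded" = {
        v2 <- .place_causals(ld, 2L, r2Target = confoundedR2)[2]
        stats::setNames(causalEffect * lam_exp, ld@variantIds[v2])
      },
      "null" = numeric(0))

    studies <- lapply(seq_len(kStudies), function(j)
      simulateTraitSumstats(ld, stats::setNames(lam_exp, ld@variantIds[v1]),
                            nExposure, traitId = sprintf("%s_study%d", id, j),
                            seed = base_seed + j, chrom = chrom,
                            cholR = cholR))
    external <- simulateTraitSumstats(
      ld, stats::setNames(lam_exp, ld@variantIds[v1]), nExposure,
      traitId = paste0(id, "_external"), seed = base_seed + kStudies + 1L,
      chrom = chrom, cholR = cholR)
    outcome <- simulateTraitSumstats(
      ld, out_causal, nOutcome, traitId = "outcome",
      seed = base_seed + kStudies + 2L, chrom = chrom, cholR = cholR)

    list(id = id, class = cls, locus = locus, ld = ld, studies = studies,
         external = external, outcome = outcome)
  })
  names(targets) <- vapply(targets, `[[`, character(1), "id")
  list(targets = targets, seed = as.integer(seed),
       truth = stats::setNames(classes, names(targets)))
}
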