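#' @import methods
NULL

## Canonical per-variant column set used throughout the package. Every
## SumStats object carries exactly these columns in this order.
.SUMSTAT_COLS <- c("snp", "chrom", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n", "ncase", "ncontrol")

.TRAIT_TYPES <- c("quantitative", "case_control")

#' SumStats: GWAS/QTL summary statistics for one trait
#'
#' Container for per-variant marginal association records of a single trait,
#' typically restricted to one genomic region. Each record holds the variant
#' identifier, coordinates, effect/other allele, effect-allele frequency,
#' marginal effect estimate (\code{beta}, trait units for quantitative traits
#' or log-odds for case-control traits), its standard error, p-value and
#' sample size.
#'
#' @slot traitId character(1), identifier of the trait.
#' @slot traitType \code{"quantitative"} or \code{"case_control"}.
#' @slot data data.frame with columns \code{snp, chrom, pos, ea, oa, eaf,
#'   beta, se, pval, n, ncase, ncontrol}.
#' @slot region list; either empty or \code{list(chrom=, start=, end=)}.
#'
#' @seealso [SumStats()] constructor, [readSumStats()], [harmonize()]
#' @export
setClass("SumStats",
         slots = c(traitId = "character",
                   traitType = "character",
                   data = "data.frame",
                   region = "list"))

setValidity("SumStats", function(object) {
  msg <- character()
  d <- object@data
  if (!identical(colnames(d), .SUMSTAT_COLS))
    msg <- c(msg, paste0("data must have columns ",
                         paste(.SUMSTAT_COLS, collapse = ", ")))
  if (length(object@traitType) != 1L || !object@traitType %in% .TRAIT_TYPES)
    msg <- c(msg, "traitType must be 'quantitative' or 'case_control'")
  if (length(msg) == 0 && nrow(d) > 0) {
    if (anyDuplicated(d$snp))
      msg <- c(msg, "variant ids must be unique within a table")
    if (any(!is.finite(d$se) | d$se <= 0))
      msg <- c(msg, "all se must be finite and > 0")
    eaf <- d$eaf[!is.na(d$eaf)]
    if (any(eaf <= 0 | eaf >= 1))
      msg <- c(msg, "eaf must lie in (0, 1) when present")
    pv <- d$pval[!is.na(d$pval)]
    if (any(pv <= 0 | pv > 1))
      msg <- c(msg, "pval must lie in (0, 1]")
    if (any(!nzchar(d$ea)) || any(!nzchar(d$oa)))
      msg <- c(msg, "alleles must be non-empty strings")
    ncase <- d$ncase
    bad <- !is.na(ncase) & !is.na(d$ncontrol) & !is.na(d$n) &
      (ncase + d$ncontrol != d$n)
    if (any(bad))
      msg <- c(msg, "ncase + ncontrol must equal n where both present")
    if (length(object@region) == 3 &&
        any(d$chrom != object@region$chrom))
      msg <- c(msg, "all records must lie on the region chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' LDMatrix: pairwise allelic correlations for a variant panel
#'
#' Square symmetric matrix of pairwise correlations r between the allele
#' counts of a panel of variants; r^2 drives LD clumping and the matrix is
#' the covariance of the summary-statistic simulator.
#'
#' @slot variantIds character, variant identifiers (row/column order).
#' @slot r numeric matrix of correlations in [-1, 1], unit diagonal,
#'   positive semi-definite within tolerance 1e-8.
#'
#' @seealso [LDMatrix()] constructor, [makeLd()], [ldClump()]
#' @export
setClass("LDMatrix",
         slots = c(variantIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  msg <- character()
  r <- object@r
  k <- length(object@variantIds)
  if (nrow(r) != k || ncol(r) != k)
    msg <- c(msg, "matrix dimension must equal the number of variant ids")
  if (anyDuplicated(object@variantIds))
    msg <- c(msg, "variant ids must be unique")
  if (k > 0 && length(msg) == 0) {
    if (any(abs(r) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (max(abs(diag(r) - 1)) > 1e-8)
      msg <- c(msg, "diagonal must be 1")
    if (max(abs(r - t(r))) > 1e-8)
      msg <- c(msg, "matrix must be symmetric")
    ## PSD within tolerance; smallest eigenvalue of a symmetric matrix
    if (k <= 3000) {
      ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8 * max(1, abs(max(r))))
        msg <- c(msg, sprintf("matrix is not positive semi-definite (min eigenvalue %.3g)", ev))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GeneLocus: coordinates of a protein-coding or expression locus
#'
#' @slot geneId character(1).
#' @slot chrom character(1).
#' @slot start,end integer, 1-based inclusive gene-body coordinates.
#' @export
setClass("GeneLocus",
         slots = c(geneId = "character", chrom = "character",
                   start = "numeric", end = "numeric"))

setValidity("GeneLocus", function(object) {
  if (object@start > object@end) "start must be <= end" else TRUE
})

#' MRResult: one exposure-to-outcome causal estimate with sensitivity battery
#'
#' Point estimate from the dispatched estimator (Wald ratio for a single
#' instrument, inverse-variance weighting otherwise) together with all
#' sensitivity diagnostics computable at the available instrument count:
#' Cochran's Q heterogeneity (>= 2 instruments), the MR-Egger intercept test
#' for directional pleiotropy (>= 3), the MR-PRESSO global test and outlier
#' flags (>= 4) and the Steiger directionality flag. Fields not computable
#' are NA, mirroring how such results are reported for single-instrument
#' targets.
#'
#' @slot exposureId,outcomeId character(1).
#' @slot method \code{"wald"}, \code{"ivw"} or \code{"egger"}.
#' @slot beta,se,pval numeric(1) causal estimate, SE, two-sided p.
#' @slot nSnp integer(1) number of instruments used.
#' @slot qStat,qPval Cochran's Q and its chi-square p (NA when nSnp < 2).
#' @slot eggerIntercept,eggerInterceptPval Egger intercept and its t-test p
#'   (NA when nSnp < 3).
#' @slot pressoGlobalPval MR-PRESSO global test p (NA when nSnp < 4).
#' @slot pressoOutliers character, variant ids flagged as outliers.
#' @slot steigerCorrect logical(1), TRUE when instruments explain more
#'   variance in the exposure than in the outcome.
#' @export
setClass("MRResult",
         slots = c(exposureId = "character", outcomeId = "character",
                   method = "character",
                   beta = "numeric", se = "numeric", pval = "numeric",
                   nSnp = "integer",
                   qStat = "numeric", qPval = "numeric",
                   eggerIntercept = "numeric", eggerInterceptPval = "numeric",
                   pressoGlobalPval = "numeric", pressoOutliers = "character",
                   steigerCorrect = "logical"))

setValidity("MRResult", function(object) {
  msg <- character()
  if (object@nSnp < 1L) msg <- c(msg, "nSnp must be >= 1")
  if (!object@method %in% c("wald", "ivw", "egger"))
    msg <- c(msg, "method must be wald, ivw or egger")
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be > 0")
  if (object@nSnp < 2L && !is.na(object@qStat))
    msg <- c(msg, "Q defined only for nSnp >= 2")
  if (object@nSnp < 3L && !is.na(object@eggerIntercept))
    msg <- c(msg, "Egger fields defined only for nSnp >= 3")
  if (length(msg)) msg else TRUE
})

#' MetaResult: random-effects meta-analysis of one target across studies
#'
#' @slot targetId character(1).
#' @slot kStudies integer(1) number of pooled studies.
#' @slot beta,se,pval pooled estimate (DerSimonian-Laird random effects).
#' @slot tau2 numeric(1) between-study variance estimate (>= 0).
#' @slot fdrQ numeric(1) BH q-value once the FDR family is formed (NA before).
#' @export
setClass("MetaResult",
         slots = c(targetId = "character", kStudies = "integer",
                   beta = "numeric", se = "numeric", pval = "numeric",
                   tau2 = "numeric", fdrQ = "numeric"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@kStudies < 1L) msg <- c(msg, "kStudies must be >= 1")
  if (!is.na(object@tau2) && object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ColocResult: two-trait colocalization posterior
#'
#' Posterior mass over the five hypotheses about a locus: H0 no association
#' with either trait, H1/H2 association with one trait only, H3 both traits
#' associated through distinct causal variants, H4 a single shared causal
#' variant.
#'
#' @slot pp named numeric(5) posterior probabilities, names H0..H4, sum 1.
#' @slot priors named numeric(3) per-variant priors (p1, p2, p12).
#' @slot topSharedVariant character(1), variant with the largest H4
#'   contribution.
#' @slot nVariants integer(1) shared variants used.
#' @export
setClass("ColocResult",
         slots = c(pp = "numeric", priors = "numeric",
                   topSharedVariant = "character", nVariants = "integer"))

setValidity("ColocResult", function(object) {
  msg <- character()
  if (!identical(names(object@pp), paste0("H", 0:4)))
    msg <- c(msg, "pp must be named H0..H4")
  else if (abs(sum(object@pp) - 1) > 1e-9 || any(object@pp < 0))
    msg <- c(msg, "pp must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

## The 15 sharing configurations for three traits a, b, c. Commas separate
## distinct causal variants; juxtaposition means a shared variant.
.MOLOC_CONFIGS <- c("null", "a", "b", "c", "a,b", "a,c", "b,c",
                    "ab", "ac", "bc", "ab,c", "ac,b", "bc,a",
                    "a,b,c", "abc")

#' MolocResult: three-trait colocalization posterior
#'
#' Posterior mass over the 15 sharing configurations of three traits plus the
#' two regional summaries used for target prioritization: the posterior that
#' all three traits share one causal variant (configuration \code{abc}) and
#' the posterior that all three are associated within the region
#' (\code{a,b,c + a,bc + ab,c + ac,b + abc}).
#'
#' @slot configPosteriors named numeric(15), posterior per configuration.
#' @slot ppCausalVariant numeric(1), posterior of configuration \code{abc}.
#' @slot ppCausalRegion numeric(1), sum over the five all-associated
#'   configurations.
#' @slot priors named numeric(3), per-variant priors for 1, 2 and 3 shared
#'   layers.
#' @slot bestSnp character(1), variant with the largest \code{abc}
#'   contribution.
#' @export
setClass("MolocResult",
         slots = c(configPosteriors = "numeric",
                   ppCausalVariant = "numeric", ppCausalRegion = "numeric",
                   priors = "numeric", bestSnp = "character"))

setValidity("MolocResult", function(object) {
  msg <- character()
  if (!identical(names(object@configPosteriors), .MOLOC_CONFIGS))
    msg <- c(msg, "configPosteriors must be named with the 15 configurations")
  else {
    if (abs(sum(object@configPosteriors) - 1) > 1e-9 ||
        any(object@configPosteriors < 0))
      msg <- c(msg, "posteriors must be non-negative and sum to 1")
    if (object@ppCausalVariant > object@ppCausalRegion + 1e-12)
      msg <- c(msg, "ppCausalVariant must not exceed ppCausalRegion")
  }
  if (length(msg)) msg else TRUE
})

#' MediationResult: two-step mediation MR decomposition
#'
#' @slot total,step1,step2,indirect named numeric(2) vectors (beta, se):
#'   total target-to-outcome effect, target-to-mediator, mediator-to-outcome
#'   and the product-of-coefficients indirect effect with delta-method SE.
#' @slot proportionMediated numeric(1), indirect / total beta (NA when the
#'   total effect is zero).
#' @export
setClass("MediationResult",
         slots = c(total = "numeric", step1 = "numeric", step2 = "numeric",
                   indirect = "numeric", proportionMediated = "numeric"))

#' RgResult: bivariate LD score regression estimates
#'
#' @slot h2 numeric(2) per-trait heritability estimates.
#' @slot gencov numeric(1) genetic covariance.
#' @slot rg numeric(1) genetic correlation (may slightly exceed 1 in
#'   magnitude through estimation noise).
#' @slot rgSe numeric(1) delete-one-block jackknife standard error.
#' @slot intercepts numeric(3) free intercepts of the two univariate and the
#'   cross regression.
#' @export
setClass("RgResult",
         slots = c(h2 = "numeric", gencov = "numeric", rg = "numeric",
                   rgSe = "numeric", intercepts = "numeric"))

#' FunnelReport: staged filtration record of the target-prioritization funnel
#'
#' @slot stages data.frame with columns \code{stage, n_in, n_out}.
#' @slot removed data.frame with columns \code{target, stage, reason}.
#' @slot finalTargets character, ids surviving every stage.
#' @slot details named list of per-target result objects (meta-analysis,
#'   colocalization, replication flags).
#' @slot seed integer(1) seed recorded for reproducibility.
#' @export
setClass("FunnelReport",
         slots = c(stages = "data.frame", removed = "data.frame",
                   finalTargets = "character", details = "list",
                   seed = "integer"))

setValidity("FunnelReport", function(object) {
  s <- object@stages
  if (nrow(s) >= 2 && any(s$n_out[-nrow(s)] != s$n_in[-1]))
    return("n_out of each stage must equal n_in of the next")
  if (any(s$n_out > s$n_in))
    return("funnel must be monotone: n_out <= n_in")
  TRUE
})
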