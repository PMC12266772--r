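## Wakefield approximate-Bayes-factor colocalization for two traits and
## configuration-enumeration colocalization for three traits. All Bayes
## factor algebra is carried out in log space (log-sum-exp), so arbitrarily
## strong association signals cannot overflow.

#' Wakefield approximate Bayes factor
#'
#' Per-variant log Bayes factor for association from a marginal estimate and
#' its standard error, under a normal prior on the true effect with standard
#' deviation \code{priorSd}. With \code{V = se^2}, \code{W = priorSd^2},
#' shrinkage \code{r = W/(W+V)} and \code{z = beta/se}:
#' \code{log ABF = 0.5 log(1-r) + z^2 r / 2} (natural log). Monotone
#' increasing in |z| at fixed se; negative at z = 0 (evidence against
#' association).
#'
#' @param beta,se numeric vectors of marginal effects and SEs (se > 0).
#' @param priorSd prior effect-scale standard deviation; the conventional
#'   defaults are 0.2 for quantitative traits and 0.15 for case-control
#'   traits on the log-odds scale.
#' @return numeric vector of log ABFs.
#' @examples
#' wakefieldAbf(0.1, 0.02, 0.2)  # ~ 10.07
#' @export
wakefieldAbf <- function(beta, se, priorSd = 0.2) {
  if (any(!is.finite(se) | se <= 0)) stopf("se must be finite and > 0")
  stopifnot(priorSd > 0)
  V <- se^2
  r <- priorSd^2 / (priorSd^2 + V)
  0.5 * log(1 - r) + (beta / se)^2 * r / 2
}

.default_prior_sd <- function(traitType)
  if (traitType == "case_control") 0.15 else 0.2

## log(exp(a) - exp(b)) for a >= b, -Inf when the difference vanishes
.logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Two-trait colocalization under the single-causal-variant model
#'
#' Enumerates the five hypotheses about a locus shared by two traits -- H0 no
#' association, H1/H2 one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant -- using per-variant Wakefield log ABFs and
#' per-variant prior probabilities \code{p1}, \code{p2} (single-trait
#' association) and \code{p12} (shared association). Posteriors are
#' normalized over the five hypotheses. A locus is flagged
#' \emph{colocalized} when PP.H4 strictly exceeds \code{threshold}.
#'
#' @param traitA,traitB [SumStats-class] objects; only variants present in
#'   both (matched by id, assumed harmonized to common alleles) are used.
#' @param p1,p2,p12 per-variant priors (defaults 1e-4, 1e-4, 1e-5).
#' @param priorSdA,priorSdB Wakefield prior effect scales; default 0.2 for
#'   quantitative and 0.15 for case-control traits.
#' @param minVariants minimum shared-variant count (default 10).
#' @param threshold colocalization posterior threshold (default 0.7).
#' @return A [ColocResult-class]; \code{attr(, "colocalized")} holds the
#'   threshold flag.
#' @seealso [regionalProbability()], [moloc()]
#' @export
colocAbf <- function(traitA, traitB, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     priorSdA = NULL, priorSdB = NULL, minVariants = 10L,
                     threshold = 0.7) {
  stopifnot(is(traitA, "SumStats"), is(traitB, "SumStats"))
  da <- traitA@data
  db <- traitB@data
  shared <- intersect(da$snp, db$snp)
  if (length(shared) < minVariants)
    stopf("only %d shared variants (minimum %d)", length(shared), minVariants)
  da <- da[match(shared, da$snp), ]
  db <- db[match(shared, db$snp), ]
  if (is.null(priorSdA)) priorSdA <- .default_prior_sd(traitA@traitType)
  if (is.null(priorSdB)) priorSdB <- .default_prior_sd(traitB@traitType)

  la <- wakefieldAbf(da$beta, da$se, priorSdA)
  lb <- wakefieldAbf(db$beta, db$se, priorSdB)

  L1 <- logsumexp(la)
  L2 <- logsumexp(lb)
  L4 <- logsumexp(la + lb)
  L3 <- .logdiff(L1 + L2, L4)          # sum over ordered pairs i != j

  lognum <- c(H0 = 0,
              H1 = log(p1) + L1,
              H2 = log(p2) + L2,
              H3 = log(p1) + log(p2) + L3,
              H4 = log(p12) + L4)
  pp <- exp(lognum - logsumexp(lognum))
  pp <- pp / sum(pp)

  res <- methods::new("ColocResult", pp = pp,
                      priors = c(p1 = p1, p2 = p2, p12 = p12),
                      topSharedVariant = shared[which.max(la + lb)],
                      nVariants = length(shared))
  attr(res, "colocalized") <- unname(pp["H4"] > threshold)
  res
}

#' Regional colocalization probability
#'
#' The posterior that both traits are associated within the region regardless
#' of sharing: PP.H3 + PP.H4.
#'
#' @param x a [ColocResult-class].
#' @return numeric(1).
#' @export
regionalProbability <- function(x) {
  stopifnot(is(x, "ColocResult"))
  unname(x@pp["H3"] + x@pp["H4"])
}

## Configuration table: groups of traits sharing one causal variant.
## Commas separate distinct causal variants, juxtaposition means shared.
.moloc_config_groups <- list(
  "null" = list(),
  "a" = list("a"), "b" = list("b"), "c" = list("c"),
  "a,b" = list("a", "b"), "a,c" = list("a", "c"), "b,c" = list("b", "c"),
  "ab" = list(c("a", "b")), "ac" = list(c("a", "c")),
  "bc" = list(c("b", "c")),
  "ab,c" = list(c("a", "b"), "c"), "ac,b" = list(c("a", "c"), "b"),
  "bc,a" = list(c("b", "c"), "a"),
  "a,b,c" = list("a", "b", "c"),
  "abc" = list(c("a", "b", "c")))

#' Three-trait colocalization by configuration enumeration
#'
#' Enumerates the 15 sharing configurations of three traits (e.g. an
#' expression trait, a protein trait and an outcome): each trait either has
#' no causal variant in the region or one, and associated traits may share a
#' variant or carry distinct ones (distinct-variant assignments exclude
#' coincident variants). Per-configuration likelihoods are assembled from
#' sums and products of per-variant Wakefield ABF terms; the configuration
#' prior is the product, over its shared sets, of the per-variant prior for
#' that set size (\code{prior1} one layer, \code{prior2} two layers,
#' \code{prior3} all three). Two regional summaries are derived: the
#' posterior that all three traits share one causal variant (configuration
#' \code{abc}, flagged \emph{colocalized} above \code{threshold}) and the
#' posterior that all three are associated in the region
#' (\code{a,b,c + a,bc + ab,c + ac,b + abc}, flagged \emph{regionally
#' colocalized}).
#'
#' @param traitA,traitB,traitC [SumStats-class] objects on a shared variant
#'   panel (matched by id).
#' @param prior1,prior2,prior3 per-variant configuration priors (defaults
#'   1e-4, 1e-6, 1e-7).
#' @param priorSd optional numeric(3) Wakefield prior scales; defaults by
#'   trait type as in [colocAbf()].
#' @param minVariants minimum shared-variant count (default 10).
#' @param threshold posterior threshold for the flags (default 0.7).
#' @return A [MolocResult-class]; attributes \code{colocalized} and
#'   \code{regionallyColocalized} hold the threshold flags.
#' @export
moloc <- function(traitA, traitB, traitC, prior1 = 1e-4, prior2 = 1e-6,
                  prior3 = 1e-7, priorSd = NULL, minVariants = 10L,
                  threshold = 0.7) {
  traits <- list(a = traitA, b = traitB, c = traitC)
  stopifnot(all(vapply(traits, is, logical(1), "SumStats")))
  panels <- lapply(traits, function(t) t@data$snp)
  shared <- Reduce(intersect, panels)
  if (length(shared) < minVariants)
    stopf("shared variant panel too small or mismatched (%d shared, minimum %d)",
          length(shared), minVariants)
  if (is.null(priorSd))
    priorSd <- vapply(traits, function(t) .default_prior_sd(t@traitType),
                      numeric(1))

  labf <- mapply(function(t, ps) {
    d <- t@data[match(shared, t@data$snp), ]
    wakefieldAbf(d$beta, d$se, ps)
  }, traits, priorSd, SIMPLIFY = FALSE)
  names(labf) <- c("a", "b", "c")

  ## scale each trait's ABFs by its maximum so sums stay in double range
  m <- vapply(labf, max, numeric(1))
  u <- mapply(function(l, mm) exp(l - mm), labf, m, SIMPLIFY = FALSE)

  ## scaled sums over single variants for every trait subset
  S <- list(a = sum(u$a), b = sum(u$b), c = sum(u$c),
            ab = sum(u$a * u$b), ac = sum(u$a * u$c), bc = sum(u$b * u$c),
            abc = sum(u$a * u$b * u$c))
  sumS <- function(group) S[[paste(sort(group), collapse = "")]]
  offset <- function(group) sum(m[group])

  logp <- log(c(prior1, prior2, prior3))
  config_logval <- vapply(.moloc_config_groups, function(groups) {
    if (length(groups) == 0) return(0)                   # null configuration
    lp <- sum(logp[vapply(groups, length, integer(1))])
    off <- sum(vapply(groups, offset, numeric(1)))
    val <- switch(as.character(length(groups)),
      "1" = sumS(groups[[1]]),
      "2" = sumS(groups[[1]]) * sumS(groups[[2]]) -
        sumS(c(groups[[1]], groups[[2]])),
      "3" = S$a * S$b * S$c - S$ab * S$c - S$ac * S$b - S$bc * S$a +
        2 * S$abc)
    if (val <= 0) return(-Inf)       # numerically empty assignment set
    lp + off + log(val)
  }, numeric(1))

  post <- exp(config_logval - logsumexp(config_logval))
  post <- post / sum(post)
  names(post) <- names(.moloc_config_groups)

  region_configs <- c("a,b,c", "a,bc", "ab,c", "ac,b", "abc")
  ## "a,bc" is stored as "bc,a" in the enumeration order
  region_configs[region_configs == "a,bc"] <- "bc,a"
  pp_variant <- unname(post["abc"])
  pp_region <- sum(post[region_configs])

  res <- methods::new("MolocResult", configPosteriors = post,
                      ppCausalVariant = pp_variant,
                      ppCausalRegion = pp_region,
                      priors = c(prior1 = prior1, prior2 = prior2,
                                 prior3 = prior3),
                      bestSnp = shared[which.max(labf$a + labf$b + labf$c)])
  attr(res, "colocalized") <- pp_variant > threshold
  attr(res, "regionallyColocalized") <- pp_region > threshold
  res
}
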