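## Two-sample MR estimators and the sensitivity battery used to filter
## candidate targets: Wald ratio, IVW, MR-Egger, Cochran's Q, Steiger
## directionality and MR-PRESSO.

.mr_result <- function(exposureId = NA_character_, outcomeId = NA_character_,
                       method, beta, se, pval, nSnp,
                       qStat = NA_real_, qPval = NA_real_,
                       eggerIntercept = NA_real_,
                       eggerInterceptPval = NA_real_,
                       pressoGlobalPval = NA_real_,
                       pressoOutliers = character(0),
                       steigerCorrect = NA) {
  methods::new("MRResult", exposureId = exposureId, outcomeId = outcomeId,
               method = method, beta = unname(beta), se = unname(se),
               pval = unname(pval),
               nSnp = as.integer(nSnp), qStat = unname(qStat),
               qPval = unname(qPval),
               eggerIntercept = unname(eggerIntercept),
               eggerInterceptPval = unname(eggerInterceptPval),
               pressoGlobalPval = pressoGlobalPval,
               pressoOutliers = pressoOutliers,
               steigerCorrect = steigerCorrect)
}

## Per-variant Wald ratios with first-order delta-method SEs.
.ratios <- function(h) {
  if (any(h$beta_exp == 0))
    stopf("exposure beta is zero for variant(s): %s",
          paste(h$snp[h$beta_exp == 0], collapse = ", "))
  list(ratio = h$beta_out / h$beta_exp,
       se = h$se_out / abs(h$beta_exp))
}

.two_sided_z <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

#' Wald ratio estimate from a single instrument
#'
#' Causal estimate for a target with one instrument: the ratio of the outcome
#' effect to the exposure effect, with first-order delta-method standard
#' error \code{se_out / |beta_exp|} and a two-sided normal p-value.
#'
#' @param h one usable row of a [harmonize()] result (see
#'   [harmonizedPairs()]).
#' @param exposureId,outcomeId identifiers stored on the result.
#' @return An [MRResult-class] with \code{method = "wald"}.
#' @export
waldRatio <- function(h, exposureId = NA_character_,
                      outcomeId = NA_character_) {
  if (nrow(h) != 1L) stopf("waldRatio expects exactly one instrument")
  r <- .ratios(h)
  .mr_result(exposureId, outcomeId, "wald", r$ratio, r$se,
             .two_sided_z(r$ratio, r$se), 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted average of per-instrument Wald ratios with weights
#' \code{1/ratio_se^2} (fixed-effect form): \code{beta = sum(w r)/sum(w)},
#' \code{se = 1/sqrt(sum(w))}. With \code{randomEffects = TRUE} the standard
#' error is rescaled by \code{max(1, sqrt(Q/df))} (multiplicative random
#' effects).
#'
#' @param h usable harmonized pairs (>= 2 rows).
#' @param randomEffects apply multiplicative random-effect rescaling.
#' @param exposureId,outcomeId identifiers stored on the result.
#' @return An [MRResult-class] with \code{method = "ivw"} and Cochran's Q
#'   fields populated.
#' @export
ivw <- function(h, randomEffects = FALSE, exposureId = NA_character_,
                outcomeId = NA_character_) {
  if (nrow(h) < 2L)
    stopf("ivw needs >= 2 instruments; use waldRatio for a single instrument")
  r <- .ratios(h)
  w <- 1 / r$se^2
  beta <- sum(w * r$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (r$ratio - beta)^2)
  df <- nrow(h) - 1L
  if (randomEffects) se <- se * max(1, sqrt(q / df))
  .mr_result(exposureId, outcomeId, "ivw", beta, se,
             .two_sided_z(beta, se), nrow(h),
             qStat = q, qPval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after orienting all instruments to a non-negative exposure
#' effect; weights are \code{1/se_out^2}. The intercept estimates directional
#' horizontal pleiotropy; its two-sided p-value uses a t distribution with
#' \code{nSnp - 2} degrees of freedom. With fewer than 3 instruments all
#' fields are NA (inadequate number of SNPs).
#'
#' @param h usable harmonized pairs.
#' @param exposureId,outcomeId identifiers stored on the result.
#' @return An [MRResult-class] with \code{method = "egger"}; \code{beta} is
#'   the slope.
#' @export
mrEgger <- function(h, exposureId = NA_character_,
                    outcomeId = NA_character_) {
  k <- nrow(h)
  if (k < 3L)
    return(.mr_result(exposureId, outcomeId, "egger", NA_real_, NA_real_,
                      NA_real_, max(k, 1L)))
  s <- ifelse(h$beta_exp < 0, -1, 1)
  bx <- h$beta_exp * s
  by <- h$beta_out * s
  w <- 1 / h$se_out^2
  ## explicit weighted least squares with intercept
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  df <- k - 2L
  sigma2 <- sum(w * resid^2) / df
  vc <- sigma2 * solve(XtWX)
  est <- as.numeric(coef)
  se <- sqrt(diag(vc))
  pt2 <- function(est, se) 2 * stats::pt(-abs(est / se), df)
  .mr_result(exposureId, outcomeId, "egger", est[2], se[2],
             pt2(est[2], se[2]), k,
             eggerIntercept = est[1], eggerInterceptPval = pt2(est[1], se[1]))
}

#' Cochran's Q heterogeneity test for IVW
#'
#' \code{Q = sum(w (ratio - beta_ivw)^2)} over per-instrument ratios with
#' IVW weights; p from a chi-square distribution with \code{nSnp - 1} df.
#'
#' @param h usable harmonized pairs.
#' @return list with \code{q_stat} and \code{q_pval} (both NA when fewer
#'   than 2 instruments).
#' @export
cochranQ <- function(h) {
  if (nrow(h) < 2L) return(list(q_stat = NA_real_, q_pval = NA_real_))
  r <- .ratios(h)
  w <- 1 / r$se^2
  beta <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta)^2)
  list(q_stat = q,
       q_pval = stats::pchisq(q, nrow(h) - 1L, lower.tail = FALSE))
}

#' Steiger directionality filter
#'
#' Approximates each instrument's correlation with a trait as
#' \code{r = z / sqrt(z^2 + n)} and returns TRUE when the instruments explain
#' more variance in the exposure than in the outcome
#' (\code{sum(r2_exposure) > sum(r2_outcome)}); the tie is resolved as FALSE
#' (conservative). The same approximation is applied to quantitative and
#' case-control traits (log-odds scale).
#'
#' @param h usable harmonized pairs.
#' @param nExp,nOut sample sizes; default to the per-variant \code{n_exp} /
#'   \code{n_out} columns.
#' @return logical(1).
#' @export
steigerFilter <- function(h, nExp = h$n_exp, nOut = h$n_out) {
  if (any(is.na(nExp)) || any(is.na(nOut)))
    stopf("sample sizes are required for Steiger filtering")
  z_exp <- h$beta_exp / h$se_exp
  z_out <- h$beta_out / h$se_out
  r2_exp <- z_exp^2 / (z_exp^2 + nExp)
  r2_out <- z_out^2 / (z_out^2 + nOut)
  sum(r2_exp) > sum(r2_out)
}

#' MR-PRESSO global pleiotropy test and outlier detection
#'
#' Simulation-based residual test. The observed statistic is the residual sum
#' of squares of leave-one-out IVW predictions of the outcome effects; its
#' null distribution is built from \code{nSim} parametric simulations that
#' redraw each outcome effect from a normal distribution centred on its
#' leave-one-out prediction with the observed outcome SE, recomputing the
#' leave-one-out residuals on every simulated data set. Per-variant outlier
#' p-values use the same simulations and are Bonferroni-adjusted across
#' instruments. Deterministic given \code{seed}.
#'
#' @param h usable harmonized pairs (>= 4 rows; otherwise NA results).
#' @param nSim number of parametric simulations (default 1000).
#' @param seed integer seed for the simulation stream (the caller's RNG state
#'   is untouched).
#' @param significance outlier flagging level on the Bonferroni-adjusted
#'   p-value (default 0.05).
#' @return list with \code{global_pval} and \code{outlier_ids}.
#' @export
mrPresso <- function(h, nSim = 1000L, seed = NULL, significance = 0.05) {
  k <- nrow(h)
  if (k < 4L) return(list(global_pval = NA_real_, outlier_ids = character(0)))
  r <- .ratios(h)
  w <- 1 / r$se^2
  sw <- sum(w)
  swr <- sum(w * r$ratio)
  b_loo <- (swr - w * r$ratio) / (sw - w)
  mu <- b_loo * h$beta_exp
  d_obs <- h$beta_out - mu
  rss_obs <- sum(d_obs^2)

  sims <- with_local_seed(seed, {
    E <- matrix(stats::rnorm(nSim * k), nSim, k)
    B <- sweep(E, 2, h$se_out, `*`) + matrix(mu, nSim, k, byrow = TRUE)
    Rm <- sweep(B, 2, h$beta_exp, `/`)              # simulated ratios
    W <- matrix(w, nSim, k, byrow = TRUE)
    swr_s <- Rm %*% w
    b_loo_s <- (matrix(swr_s, nSim, k) - W * Rm) /
      matrix(sw - w, nSim, k, byrow = TRUE)
    D <- B - sweep(b_loo_s, 2, h$beta_exp, `*`)
    list(rss = rowSums(D^2), d2 = D^2)
  })
  global_p <- (sum(sims$rss >= rss_obs) + 1) / (nSim + 1)
  p_var <- (colSums(sims$d2 >= matrix(d_obs^2, nSim, k, byrow = TRUE)) + 1) /
    (nSim + 1)
  p_adj <- pmin(1, p_var * k)
  list(global_pval = global_p, outlier_ids = h$snp[p_adj < significance])
}

#' Run two-sample MR with the full sensitivity battery
#'
#' Dispatches on the instrument count: one instrument gives the Wald ratio,
#' two or more the IVW estimate. Sensitivity fields are populated wherever
#' computable: Cochran's Q at >= 2 instruments, the MR-Egger intercept at
#' >= 3, MR-PRESSO at >= 4, and the Steiger directionality flag whenever
#' sample sizes are available.
#'
#' @param h a [harmonize()] result or its usable subset.
#' @param exposureId,outcomeId identifiers stored on the result.
#' @param randomEffects use multiplicative random-effect IVW SEs.
#' @param pressoNSim,seed MR-PRESSO settings, see [mrPresso()].
#' @return An [MRResult-class].
#' @export
runMR <- function(h, exposureId = NA_character_, outcomeId = NA_character_,
                  randomEffects = FALSE, pressoNSim = 1000L, seed = NULL) {
  h <- harmonizedPairs(h)
  if (nrow(h) == 0) stopf("no usable harmonized instruments")
  steiger <- if (any(is.na(h$n_exp)) || any(is.na(h$n_out))) NA
             else steigerFilter(h)
  if (nrow(h) == 1L) {
    res <- waldRatio(h, exposureId, outcomeId)
    res@steigerCorrect <- steiger
    return(res)
  }
  base <- ivw(h, randomEffects, exposureId, outcomeId)
  egger <- mrEgger(h)
  presso <- mrPresso(h, nSim = pressoNSim, seed = seed)
  .mr_result(exposureId, outcomeId, "ivw", base@beta, base@se, base@pval,
             nrow(h), qStat = base@qStat, qPval = base@qPval,
             eggerIntercept = egger@eggerIntercept,
             eggerInterceptPval = egger@eggerInterceptPval,
             pressoGlobalPval = presso$global_pval,
             pressoOutliers = presso$outlier_ids,
             steigerCorrect = steiger)
}
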