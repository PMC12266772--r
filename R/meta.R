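## Cross-study meta-analysis, FDR control and replication/concordance rules.

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools duplicate measurements of one target (e.g. the same protein assayed
#' in several proteomic studies). Fixed weights \code{w = 1/se^2} give
#' Cochran's Q over studies; the between-study variance is
#' \code{tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))}; random
#' weights \code{1/(se^2 + tau2)} give the pooled estimate and its SE. A
#' single study is returned unchanged with \code{tau2 = 0}.
#'
#' @param beta,se numeric vectors of per-study estimates and SEs.
#' @param targetId identifier stored on the result.
#' @return A [MetaResult-class].
#' @examples
#' dlMeta(c(0.4, 0.5), c(0.1, 0.1))  # pooled 0.45, tau2 = 0
#' @export
dlMeta <- function(beta, se, targetId = NA_character_) {
  k <- length(beta)
  if (k == 0) stopf("dlMeta needs at least one study")
  stopifnot(length(se) == k, all(se > 0))
  if (k == 1L)
    return(methods::new("MetaResult", targetId = targetId, kStudies = 1L,
                        beta = beta, se = se,
                        pval = .two_sided_z(beta, se), tau2 = 0,
                        fdrQ = NA_real_))
  w <- 1 / se^2
  mu_fixed <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - mu_fixed)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * beta) / sum(ws)
  se_pooled <- 1 / sqrt(sum(ws))
  methods::new("MetaResult", targetId = targetId, kStudies = as.integer(k),
               beta = mu, se = se_pooled,
               pval = .two_sided_z(mu, se_pooled), tau2 = tau2,
               fdrQ = NA_real_)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values and significance flags for one test family (one family
#' per outcome across all targets of an omic layer).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{q_values} and logical \code{significant}
#'   (\code{q <= alpha}).
#' @export
bhFdr <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q_values = q, significant = q <= alpha)
}

#' Replication check between a primary and a validation MR result
#'
#' A target replicates when the validation estimate has the same sign as the
#' primary estimate and reaches nominal significance (p < 0.05). Used both
#' for the cis+trans instrument validation and for replication in an
#' independent cohort.
#'
#' @param primary,validation [MRResult-class] objects for the same
#'   target/outcome.
#' @return logical(1).
#' @export
replicationCheck <- function(primary, validation) {
  stopifnot(is(primary, "MRResult"), is(validation, "MRResult"))
  sign(primary@beta) == sign(validation@beta) && validation@pval < 0.05
}

#' Tissue-concordance rule
#'
#' A plasma-protein signal is tissue-concordant when at least one
#' tissue-specific transcript MR result is nominally significant (p < 0.05)
#' with the same direction of effect as the protein result.
#'
#' @param proteinMr [MRResult-class] for the plasma protein.
#' @param tissueMrs non-empty list of [MRResult-class] objects, one per
#'   tissue.
#' @return logical(1).
#' @export
tissueConcordance <- function(proteinMr, tissueMrs) {
  stopifnot(is(proteinMr, "MRResult"), length(tissueMrs) > 0)
  any(vapply(tissueMrs, function(t)
    t@pval < 0.05 && sign(t@beta) == sign(proteinMr@beta), logical(1)))
}
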