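## Phenome-wide MR scan of a prioritized target and two-step mediation MR.

#' Phenome-wide MR scan of one target against a phenotype panel
#'
#' Runs [runMR()] of the target's instruments against every phenotype in the
#' panel, then applies BH FDR across the scan (one family per target).
#' Phenotypes sharing no usable instruments with the target are reported with
#' NA estimate fields and excluded from the FDR family.
#'
#' @param instruments exposure [SumStats-class] restricted to the target's
#'   instrument variants (e.g. the output of [buildInstruments()] wrapped via
#'   [SumStats()], or the full exposure table subset to instrument ids).
#' @param phenotypes non-empty named list of [SumStats-class] phenotype
#'   tables.
#' @param alpha FDR level (default 0.05).
#' @param ... further arguments passed to [runMR()].
#' @return data.frame sorted by \code{fdr_q} with columns
#'   \code{phenotype_id, method, beta, se, pval, n_snp, fdr_q, direction,
#'   significant}.
#' @export
phewasScan <- function(instruments, phenotypes, alpha = 0.05, ...) {
  stopifnot(is(instruments, "SumStats"))
  if (nVariants(instruments) == 0) stopf("empty instrument list")
  if (length(phenotypes) == 0) stopf("phenotype panel is empty")
  ids <- names(phenotypes)
  if (is.null(ids))
    ids <- vapply(phenotypes, traitId, character(1))

  rows <- lapply(seq_along(phenotypes), function(i) {
    mr <- tryCatch({
      h <- harmonize(instruments, phenotypes[[i]])
      runMR(h, exposureId = instruments@traitId, outcomeId = ids[i], ...)
    }, error = function(e) NULL)
    if (is.null(mr))
      data.frame(phenotype_id = ids[i], method = NA_character_,
                 beta = NA_real_, se = NA_real_, pval = NA_real_,
                 n_snp = NA_integer_, stringsAsFactors = FALSE)
    else
      data.frame(phenotype_id = ids[i], method = mr@method, beta = mr@beta,
                 se = mr@se, pval = mr@pval, n_snp = mr@nSnp,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- NA_real_
  out$significant <- NA
  ok <- !is.na(out$pval)
  if (any(ok)) {
    f <- bhFdr(out$pval[ok], alpha)
    out$fdr_q[ok] <- f$q_values
    out$significant[ok] <- f$significant
  }
  out$direction <- ifelse(is.na(out$beta), NA_character_,
                          ifelse(out$beta > 0, "+", "-"))
  out <- out[order(out$fdr_q, out$pval), ]
  rownames(out) <- NULL
  out
}

#' Two-step mediation MR (product of coefficients)
#'
#' Decomposes a target-to-outcome effect through a mediator: the indirect
#' effect is the product of the target-to-mediator and mediator-to-outcome
#' estimates, \code{beta1 * beta2}, with delta-method standard error
#' \code{sqrt(beta1^2 se2^2 + beta2^2 se1^2)}; the proportion mediated is
#' \code{indirect / total} (undefined when the total effect is zero). The
#' product-of-coefficients form is this package's declared operationalization
#' of mediation; directional chains can also be read directly off the step
#' estimates.
#'
#' @param step1 [MRResult-class], target -> mediator.
#' @param step2 [MRResult-class], mediator -> outcome.
#' @param total [MRResult-class], target -> outcome.
#' @return A [MediationResult-class].
#' @examples
#' s1 <- TriangulateMR:::.mr_result(method = "wald", beta = 0.5, se = 0.1,
#'                                  pval = 1e-6, nSnp = 1)
#' s2 <- TriangulateMR:::.mr_result(method = "wald", beta = 0.4, se = 0.1,
#'                                  pval = 1e-4, nSnp = 1)
#' tot <- TriangulateMR:::.mr_result(method = "wald", beta = 0.3, se = 0.1,
#'                                   pval = 0.003, nSnp = 1)
#' twoStepMediation(s1, s2, tot)  # indirect 0.2, SE ~0.064
#' @export
twoStepMediation <- function(step1, step2, total) {
  stopifnot(is(step1, "MRResult"), is(step2, "MRResult"),
            is(total, "MRResult"))
  b1 <- step1@beta; s1 <- step1@se
  b2 <- step2@beta; s2 <- step2@se
  ind <- b1 * b2
  ind_se <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  prop <- if (total@beta == 0) NA_real_ else ind / total@beta
  methods::new("MediationResult",
               total = c(beta = total@beta, se = total@se),
               step1 = c(beta = b1, se = s1),
               step2 = c(beta = b2, se = s2),
               indirect = c(beta = ind, se = ind_se),
               proportionMediated = prop)
}
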