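## Instrument construction: cis-window restriction, significance filtering,
## greedy LD clumping and F-statistic strength filtering.

#' Instrument-selection configuration
#'
#' Thresholds of the instrument-construction pipeline. Defaults follow
#' standard cis-QTL practice: a +/-500 kb window around the gene body,
#' genome-wide significance p < 5e-8 (use \code{pThresholdSparse = 1e-5} for
#' sparse tissue panels with limited sample size), pairwise clumping at
#' r^2 < 0.01, and removal of instruments with F below 10 (weak-instrument
#' guard).
#'
#' @param windowBp cis-window half-width in base pairs (default 500000).
#' @param pThreshold significance threshold (default 5e-8).
#' @param pThresholdSparse alternative threshold for sparse panels (1e-5);
#'   applied when \code{sparse = TRUE} in [buildInstruments()].
#' @param r2Threshold LD clumping threshold on r^2 (default 0.01).
#' @param fMin minimum instrument F-statistic (default 10).
#' @param mode \code{"cis_only"} (default) or \code{"cis_and_trans"}.
#' @return list of class \code{"InstrumentConfig"}.
#' @export
instrumentConfig <- function(windowBp = 500000L, pThreshold = 5e-8,
                             pThresholdSparse = 1e-5, r2Threshold = 0.01,
                             fMin = 10,
                             mode = c("cis_only", "cis_and_trans")) {
  mode <- match.arg(mode)
  stopifnot(windowBp > 0, pThreshold > 0, pThresholdSparse > 0,
            r2Threshold > 0, r2Threshold < 1, fMin > 0)
  structure(list(windowBp = windowBp, pThreshold = pThreshold,
                 pThresholdSparse = pThresholdSparse,
                 r2Threshold = r2Threshold, fMin = fMin, mode = mode),
            class = "InstrumentConfig")
}

#' Restrict a summary-statistic table to the cis window of a locus
#'
#' Retains variants within \code{[start - windowBp, end + windowBp]} (closed
#' interval, gene-body anchored) on the locus chromosome. With
#' \code{mode = "cis_and_trans"} all variants are returned and a logical
#' \code{cis} column is attached via the \code{cis} attribute.
#'
#' @param x a [SumStats-class] object.
#' @param locus a [GeneLocus-class].
#' @param windowBp window half-width (default 500000).
#' @param mode \code{"cis_only"} or \code{"cis_and_trans"}.
#' @return A [SumStats-class]; with \code{cis_and_trans}, carries an
#'   attribute \code{cis} (logical per record).
#' @export
cisWindowFilter <- function(x, locus, windowBp = 500000L,
                            mode = c("cis_only", "cis_and_trans")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "SumStats"), is(locus, "GeneLocus"))
  d <- x@data
  cis <- d$chrom == locus@chrom &
    !is.na(d$pos) &
    d$pos >= locus@start - windowBp &
    d$pos <= locus@end + windowBp
  if (mode == "cis_only") {
    out <- SumStats(d[cis, , drop = FALSE], traitId = x@traitId,
                    traitType = x@traitType, region = x@region)
    attr(out, "cis") <- rep(TRUE, sum(cis))
  } else {
    out <- x
    attr(out, "cis") <- cis
  }
  out
}

#' F-statistic of a genetic instrument
#'
#' Single-variant approximation \code{(beta / se)^2}. The alternative form
#' \code{(n - 2) * R2 / (1 - R2)} with \code{R2 = z^2 / (z^2 + n)} is
#' available via \code{form = "r2"} when the sample size is known.
#'
#' @param beta,se numeric vectors of marginal effects and standard errors.
#' @param n sample size, required for \code{form = "r2"}.
#' @param form \code{"wald"} (default) or \code{"r2"}.
#' @return numeric vector of F-statistics.
#' @examples
#' fStatistic(0.1, 0.02)   # 25
#' fStatistic(0.05, 0.02)  # 6.25, removed at the default fMin = 10
#' @export
fStatistic <- function(beta, se, n = NULL, form = c("wald", "r2")) {
  form <- match.arg(form)
  if (any(!is.finite(se) | se <= 0)) stopf("se must be finite and > 0")
  z2 <- (beta / se)^2
  if (form == "wald") return(z2)
  if (is.null(n)) stopf("sample size n is required for form = 'r2'")
  r2 <- z2 / (z2 + n)
  (n - 2) * r2 / (1 - r2)
}

#' Greedy LD clumping of significant variants
#'
#' Sorts variants with \code{p < pThreshold} by ascending p (ties broken by
#' variant id, lexicographic), repeatedly takes the best remaining variant as
#' an index variant and removes all remaining variants with \code{r^2 >=
#' r2Threshold} to it. Deterministic given the tie-break.
#'
#' @param x a [SumStats-class] object.
#' @param ld an [LDMatrix-class] covering every significant variant.
#' @param r2Threshold clumping threshold on squared correlation (default
#'   0.01).
#' @param pThreshold significance threshold (default 5e-8).
#' @return data.frame of index-variant records in selection order (possibly
#'   zero rows).
#' @export
ldClump <- function(x, ld, r2Threshold = 0.01, pThreshold = 5e-8) {
  stopifnot(is(x, "SumStats"), is(ld, "LDMatrix"))
  d <- x@data
  sig <- d[!is.na(d$pval) & d$pval < pThreshold, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  missing <- setdiff(sig$snp, ld@variantIds)
  if (length(missing))
    stopf("variant(s) absent from the LD matrix: %s",
          paste(missing, collapse = ", "))
  ord <- order(sig$pval, sig$snp)
  sig <- sig[ord, , drop = FALSE]
  idx <- match(sig$snp, ld@variantIds)
  r2 <- ld@r[idx, idx, drop = FALSE]^2

  keep <- integer(0)
  remaining <- seq_len(nrow(sig))
  while (length(remaining) > 0) {
    i <- remaining[1]
    keep <- c(keep, i)
    remaining <- remaining[r2[i, remaining] < r2Threshold]
  }
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build genetic instruments for one exposure target
#'
#' Composition of the instrument pipeline: cis-window restriction (per
#' \code{config$mode}), significance filtering, greedy LD clumping and
#' F-statistic filtering. A diagnostics attribute reports the record count
#' removed at every step.
#'
#' @param x exposure [SumStats-class].
#' @param locus the target's [GeneLocus-class].
#' @param ld [LDMatrix-class] for the significant variants.
#' @param config an [instrumentConfig()].
#' @param sparse use \code{pThresholdSparse} instead of \code{pThreshold}
#'   (sparse tissue panels).
#' @return data.frame of instrument records with added columns \code{cis},
#'   \code{f_stat} and \code{exposure_id}; attribute \code{diagnostics} holds
#'   per-step removal counts.
#' @export
buildInstruments <- function(x, locus, ld, config = instrumentConfig(),
                             sparse = FALSE) {
  stopifnot(is(x, "SumStats"), inherits(config, "InstrumentConfig"))
  pthr <- if (sparse) config$pThresholdSparse else config$pThreshold
  n0 <- nrow(x@data)

  windowed <- cisWindowFilter(x, locus, config$windowBp, config$mode)
  cis_flag <- attr(windowed, "cis")
  n1 <- nrow(windowed@data)

  clumped <- ldClump(windowed, ld, config$r2Threshold, pthr)
  n_sig <- sum(!is.na(windowed@data$pval) & windowed@data$pval < pthr)
  n2 <- nrow(clumped)

  if (n2 > 0) {
    f <- fStatistic(clumped$beta, clumped$se)
    strong <- f >= config$fMin
    out <- clumped[strong, , drop = FALSE]
    out$f_stat <- f[strong]
  } else {
    out <- clumped
    out$f_stat <- numeric(0)
  }
  out$cis <- if (config$mode == "cis_only") rep(TRUE, nrow(out))
             else cis_flag[match(out$snp, windowed@data$snp)]
  out$exposure_id <- rep(x@traitId, nrow(out))
  rownames(out) <- NULL
  attr(out, "diagnostics") <- list(
    input = n0,
    removed_window = n0 - n1,
    removed_p_filter = n1 - n_sig,
    removed_clump = n_sig - n2,
    removed_f_filter = n2 - nrow(out),
    retained = nrow(out))
  out
}
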