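## Simplified bivariate LD score regression for genetic correlation from
## summary statistics. Unweighted least squares with free intercepts; SEs by
## delete-one-block jackknife.

#' LD scores of a variant panel
#'
#' The LD score of variant j is \code{ell_j = sum_k r_jk^2} over the panel
#' (self-LD included, so \code{ell >= 1}); it measures how much variation the
#' variant tags.
#'
#' @param ld an [LDMatrix-class].
#' @return named numeric vector of LD scores.
#' @export
ldScores <- function(ld) {
  stopifnot(is(ld, "LDMatrix"))
  ell <- rowSums(ld@r^2)
  names(ell) <- ld@variantIds
  ell
}

#' Bivariate LD score regression
#'
#' Estimates per-trait heritability, genetic covariance and the genetic
#' correlation rg of two traits from aligned z-scores. Univariate regressions
#' of \code{z^2} on the LD score give slopes \code{h2 * n / M}; the cross
#' regression of \code{z1 * z2} on the LD score gives
#' \code{gencov * sqrt(n1 n2) / M}; all intercepts are left free. rg is
#' \code{gencov / sqrt(h2_1 h2_2)} and may slightly exceed 1 in magnitude
#' through estimation noise. The standard error of rg comes from a
#' delete-one-block jackknife over contiguous variant blocks. This is a
#' simplified estimator: no iterative heteroskedasticity weights and no
#' sample-overlap constraint on the intercepts.
#'
#' @param z1,z2 numeric z-score vectors on the same variant panel.
#' @param ell LD scores aligned with the z-scores (see [ldScores()]).
#' @param n1,n2 GWAS sample sizes.
#' @param nBlocks jackknife block count (default 20).
#' @return An [RgResult-class].
#' @export
bivariateRg <- function(z1, z2, ell, n1, n2, nBlocks = 20L) {
  M <- length(ell)
  stopifnot(length(z1) == M, length(z2) == M, nBlocks >= 2L, M >= 2 * nBlocks)
  if (stats::var(ell) == 0)
    stopf("degenerate panel: all LD scores equal, slope unidentifiable")

  fit <- function(keep) {
    x <- ell[keep]
    slope <- function(y) {
      cf <- stats::lm.fit(cbind(1, x), y)$coefficients
      cf  # (intercept, slope)
    }
    c1 <- slope(z1[keep]^2)
    c2 <- slope(z2[keep]^2)
    cc <- slope((z1 * z2)[keep])
    h2_1 <- c1[2] * M / n1
    h2_2 <- c2[2] * M / n2
    gencov <- cc[2] * M / sqrt(n1 * n2)
    rg <- gencov / sqrt(h2_1 * h2_2)
    list(h2 = c(h2_1, h2_2), gencov = gencov, rg = rg,
         intercepts = c(c1[1], c2[1], cc[1]))
  }

  full <- fit(seq_len(M))
  blocks <- split(seq_len(M), cut(seq_len(M), nBlocks, labels = FALSE))
  rg_jk <- vapply(blocks, function(b) fit(setdiff(seq_len(M), b))$rg,
                  numeric(1))
  rg_jk <- rg_jk[is.finite(rg_jk)]
  B <- length(rg_jk)
  rg_se <- if (B >= 2)
    sqrt((B - 1) / B * sum((rg_jk - mean(rg_jk))^2)) else NA_real_

  methods::new("RgResult", h2 = unname(full$h2), gencov = unname(full$gencov),
               rg = unname(full$rg), rgSe = rg_se,
               intercepts = unname(full$intercepts))
}
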