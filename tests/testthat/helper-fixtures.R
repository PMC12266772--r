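## Shared fixtures and independent oracles. Oracles deliberately avoid the
## package's own computational paths: brute-force enumeration in linear
## space, closed forms evaluated by hand-checkable arithmetic, and stats::lm
## as the weighted-regression reference.

## Tiny SumStats builder with sensible defaults.
mk_sumstats <- function(snp, beta, se, ea = "A", oa = "G", eaf = NA,
                        chrom = "1", pos = seq_along(snp) * 1000,
                        pval = NA, n = NA, traitId = "trait",
                        traitType = "quantitative") {
  SumStats(data.frame(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa,
                      eaf = eaf, beta = beta, se = se, pval = pval, n = n),
           traitId = traitId, traitType = traitType)
}

## Harmonized-pairs data.frame straight from ratio-level quantities.
mk_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                     n_exp = NA, n_out = NA) {
  k <- length(beta_exp)
  data.frame(snp = sprintf("rs%03d", seq_len(k)), ea = "A", oa = "G",
             beta_exp = beta_exp, se_exp = se_exp, eaf_exp = NA,
             pval_exp = NA, n_exp = n_exp,
             beta_out = beta_out, se_out = se_out, eaf_out = NA,
             pval_out = NA, n_out = n_out,
             action = "kept", stringsAsFactors = FALSE)
}

mr_stub <- function(beta, se, pval = 2 * pnorm(-abs(beta / se)),
                    method = "wald", nSnp = 1L) {
  new("MRResult", exposureId = "x", outcomeId = "y", method = method,
      beta = beta, se = se, pval = pval, nSnp = as.integer(nSnp),
      qStat = NA_real_, qPval = NA_real_, eggerIntercept = NA_real_,
      eggerInterceptPval = NA_real_, pressoGlobalPval = NA_real_,
      pressoOutliers = character(0), steigerCorrect = NA)
}

## Independent Wakefield ABF (plain formula, no shared code path).
oracle_abf <- function(beta, se, sd0) {
  V <- se^2; W <- sd0^2
  sqrt(V / (V + W)) * exp(beta^2 / V * W / (V + W) / 2)
}

## Brute-force two-trait colocalization in linear space: enumerate every
## single-variant configuration. Valid for moderate z (<~ 12) and small loci.
oracle_coloc <- function(beta1, se1, beta2, se2, sd1, sd2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a1 <- oracle_abf(beta1, se1, sd1)
  a2 <- oracle_abf(beta2, se2, sd2)
  k <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  h4 <- p12 * sum(a1 * a2)
  v <- c(H0 = h0, H1 = h1, H2 = h2, H3 = h3, H4 = h4)
  v / sum(v)
}

## Brute-force three-trait colocalization: loop over all variant assignments
## for each of the 15 configurations. Small loci only.
oracle_moloc <- function(a, b, c_, p1 = 1e-4, p2 = 1e-6, p3 = 1e-7) {
  k <- length(a)
  abf <- list(a = a, b = b, c = c_)
  groups <- list(
    "null" = list(),
    "a" = list("a"), "b" = list("b"), "c" = list("c"),
    "a,b" = list("a", "b"), "a,c" = list("a", "c"), "b,c" = list("b", "c"),
    "ab" = list(c("a", "b")), "ac" = list(c("a", "c")),
    "bc" = list(c("b", "c")),
    "ab,c" = list(c("a", "b"), "c"), "ac,b" = list(c("a", "c"), "b"),
    "bc,a" = list(c("b", "c"), "a"),
    "a,b,c" = list("a", "b", "c"), "abc" = list(c("a", "b", "c")))
  pri <- c(p1, p2, p3)
  vals <- sapply(groups, function(g) {
    ng <- length(g)
    if (ng == 0) return(1)
    prior <- prod(pri[vapply(g, length, integer(1))])
    tot <- 0
    idx_sets <- switch(as.character(ng),
      "1" = lapply(seq_len(k), function(i) i),
      "2" = {
        out <- list()
        for (i in seq_len(k)) for (j in seq_len(k))
          if (i != j) out[[length(out) + 1L]] <- c(i, j)
        out
      },
      "3" = {
        out <- list()
        for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k))
          if (i != j && i != l && j != l)
            out[[length(out) + 1L]] <- c(i, j, l)
        out
      })
    for (assign in idx_sets) {
      term <- 1
      for (gi in seq_len(ng))
        for (tr in g[[gi]]) term <- term * abf[[tr]][assign[gi]]
      tot <- tot + term
    }
    prior * tot
  })
  vals / sum(vals)
}

## Step-up BH flags by exhaustive threshold search.
oracle_bh_flags <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

## Fixture TSV on disk; returns the path (session tempdir, cleaned by R).
write_fixture_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
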