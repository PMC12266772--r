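#' Construct a SumStats object
#'
#' @param data data.frame holding at least \code{snp, chrom, pos, ea, oa,
#'   beta, se}; \code{eaf, pval, n, ncase, ncontrol} are optional and filled
#'   with NA when absent. A missing \code{pval} is recomputed as the two-sided
#'   normal tail of beta/se.
#' @param traitId character(1) trait identifier.
#' @param traitType \code{"quantitative"} (default) or \code{"case_control"}.
#' @param region optional \code{list(chrom=, start=, end=)} restricting the
#'   table to one region.
#' @return A [SumStats-class] object.
#' @examples
#' d <- data.frame(snp = "rs1", chrom = "1", pos = 100L, ea = "A", oa = "G",
#'                 beta = 0.1, se = 0.02)
#' SumStats(d, traitId = "toy")
#' @export
SumStats <- function(data, traitId, traitType = "quantitative",
                     region = list()) {
  data <- as.data.frame(data)
  for (col in c("eaf", "pval", "n", "ncase", "ncontrol"))
    if (is.null(data[[col]])) data[[col]] <- NA_real_
  if (nrow(data) > 0 && all(is.na(data$pval)))
    data$pval <- 2 * stats::pnorm(-abs(data$beta / data$se))
  data$snp <- as.character(data$snp)
  data$chrom <- as.character(data$chrom)
  data$ea <- toupper(as.character(data$ea))
  data$oa <- toupper(as.character(data$oa))
  rownames(data) <- NULL
  methods::new("SumStats", traitId = traitId, traitType = traitType,
               data = data[, .SUMSTAT_COLS], region = region)
}

#' Construct an LDMatrix object
#'
#' @param r square numeric correlation matrix.
#' @param variantIds character vector of variant ids; defaults to the row
#'   names of \code{r}.
#' @return An [LDMatrix-class] object.
#' @examples
#' LDMatrix(diag(2), c("rs1", "rs2"))
#' @export
LDMatrix <- function(r, variantIds = rownames(r)) {
  if (is.null(variantIds))
    stop("variantIds must be supplied when the matrix has no row names")
  methods::new("LDMatrix", variantIds = as.character(variantIds),
               r = unname(as.matrix(r)))
}

#' Construct a GeneLocus
#'
#' @param geneId character(1).
#' @param chrom character(1).
#' @param start,end 1-based inclusive gene-body coordinates.
#' @return A [GeneLocus-class] object.
#' @examples
#' geneLocus("PDAP1", "7", 99403896, 99420975)
#' @export
geneLocus <- function(geneId, chrom, start, end) {
  methods::new("GeneLocus", geneId = geneId, chrom = as.character(chrom),
               start = as.numeric(start), end = as.numeric(end))
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. seed = NULL runs on the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Draw one z ~ N(sqrt(n) R lambda, R) given an upper Cholesky factor of R.
rss_draw <- function(Rchol, mean_vec) {
  as.numeric(mean_vec + crossprod(Rchol, stats::rnorm(ncol(Rchol))))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
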