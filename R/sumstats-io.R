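## Summary-statistic I/O and cross-trait allele harmonization.

.CANONICAL_SCHEMA <- c(snp = "SNP", chrom = "CHR", pos = "POS", ea = "EA",
                       oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                       pval = "P", n = "N", ncase = "NCASE",
                       ncontrol = "NCONTROL")

.MANDATORY <- c("snp", "ea", "oa", "beta", "se")

#' Read GWAS/QTL summary statistics from a delimited text file
#'
#' Parses a tab- or comma-delimited table with a header row into a
#' [SumStats-class] object. The canonical column names are
#' \code{SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N, NCASE, NCONTROL};
#' files with other headers are read by supplying a \code{schema} mapping.
#' Rows whose beta or SE cannot be parsed as numbers are dropped and counted
#' in the \code{diagnostics} attribute of the result
#' (\code{attr(x, "diagnostics")$unparseable}); row order is otherwise
#' preserved.
#'
#' @param path path to the delimited file.
#' @param traitId trait identifier; defaults to the file base name.
#' @param traitType \code{"quantitative"} or \code{"case_control"}.
#' @param schema optional named character vector remapping canonical names to
#'   file column names, e.g. \code{c(snp = "rsid", beta = "Effect")}; unnamed
#'   canonical columns keep their defaults.
#' @param na character token for missing values (default \code{"NA"}).
#' @return A [SumStats-class] object with a \code{diagnostics} attribute.
#' @seealso [writeSumStats()], [harmonize()]
#' @export
readSumStats <- function(path, traitId = sub("\\.[^.]*$", "", basename(path)),
                         traitType = "quantitative", schema = NULL,
                         na = "NA") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0 || !nzchar(header)) stopf("empty file: %s", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", na.strings = na,
                           check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0) stopf("file %s has a header but no data rows", path)

  map <- .CANONICAL_SCHEMA
  if (!is.null(schema)) map[names(schema)] <- schema
  for (col in .MANDATORY)
    if (!map[[col]] %in% colnames(raw))
      stopf("missing mandatory column '%s' (expected header '%s')",
            col, map[[col]])

  pick <- function(col, numeric = TRUE) {
    src <- map[[col]]
    if (!src %in% colnames(raw)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[src]]
    if (numeric) suppressWarnings(as.numeric(v)) else v
  }
  d <- data.frame(snp = pick("snp", numeric = FALSE),
                  chrom = pick("chrom", numeric = FALSE),
                  pos = pick("pos"),
                  ea = pick("ea", numeric = FALSE),
                  oa = pick("oa", numeric = FALSE),
                  eaf = pick("eaf"), beta = pick("beta"), se = pick("se"),
                  pval = pick("pval"), n = pick("n"),
                  ncase = pick("ncase"), ncontrol = pick("ncontrol"),
                  stringsAsFactors = FALSE)
  bad <- is.na(d$beta) | is.na(d$se)
  out <- SumStats(d[!bad, , drop = FALSE], traitId = traitId,
                  traitType = traitType)
  attr(out, "diagnostics") <- list(unparseable = sum(bad))
  out
}

#' Write summary statistics to a tab-delimited file
#'
#' Canonical-column TSV writer; [readSumStats()] on the written file
#' reproduces the table record for record, and writing the same table twice
#' produces byte-identical files.
#'
#' @param x a [SumStats-class] object.
#' @param path output path.
#' @param na missing-value token (default \code{"NA"}).
#' @return \code{path}, invisibly.
#' @export
writeSumStats <- function(x, path, na = "NA") {
  stopifnot(is(x, "SumStats"))
  d <- x@data
  colnames(d) <- unname(.CANONICAL_SCHEMA[colnames(d)])
  ## full precision so that the round trip is exact
  for (col in colnames(d))
    if (is.numeric(d[[col]])) d[[col]] <- formatC(d[[col]], digits = 17,
                                                  format = "g")
  d[d == " NA" | d == "NA"] <- na
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing", path))
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

#' Read / write an LD matrix
#'
#' Tab-delimited format: the first row holds the variant ids, each subsequent
#' row one row of the correlation matrix.
#'
#' @param path file path.
#' @return \code{readLDMatrix}: an [LDMatrix-class]; \code{writeLDMatrix}:
#'   \code{path}, invisibly.
#' @export
readLDMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stopf("LD matrix file %s is empty or truncated", path)
  ids <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  r <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  LDMatrix(r, ids)
}

#' @rdname readLDMatrix
#' @param x an [LDMatrix-class] object.
#' @export
writeLDMatrix <- function(x, path) {
  stopifnot(is(x, "LDMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x@variantIds, collapse = "\t"), con)
  utils::write.table(formatC(x@r, digits = 17, format = "g"), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.strand_flip <- function(allele) {
  chars <- strsplit(allele, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(.complement))) return(NA_character_)
  paste(rev(.complement[chars]), collapse = "")
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L && nchar(oa) == 1L &&
    ((ea == "A" && oa == "T") || (ea == "T" && oa == "A") ||
       (ea == "C" && oa == "G") || (ea == "G" && oa == "C"))
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' For every variant shared between the two tables, orients the outcome
#' effect to the exposure's effect allele. Variants whose outcome alleles are
#' swapped relative to the exposure get their outcome beta negated and eaf
#' complemented (\code{action = "flipped"}). Palindromic SNPs (A/T or C/G)
#' are kept only when both effect-allele frequencies are present, fall
#' outside the ambiguity window around 0.5, and agree with the nominal allele
#' alignment; otherwise they are \code{dropped_palindromic}. Non-palindromic
#' mismatches are retried after complementing the outcome alleles (strand
#' flip) before being declared \code{dropped_incompatible}. Indels and
#' multi-allelic records are matched directly or swapped but excluded from
#' palindrome and strand-flip logic. Exactly one row with a defined action is
#' emitted per shared variant.
#'
#' @param exposure,outcome [SumStats-class] objects sharing at least one
#'   variant id.
#' @param palindromeEafWindow half-width w of the ambiguity window: a
#'   palindromic SNP is usable only when both eafs lie outside
#'   \code{[0.5 - w, 0.5 + w]} (default 0.08, i.e. the common 0.42-0.58
#'   exclusion band).
#' @return data.frame with one row per shared variant: \code{snp, ea, oa,
#'   beta_exp, se_exp, eaf_exp, pval_exp, n_exp, beta_out, se_out, eaf_out,
#'   pval_out, n_out, action}. Rows with action \code{kept} or \code{flipped}
#'   have both betas oriented to the same effect allele; use
#'   \code{action \%in\% c("kept","flipped")} to subset usable pairs.
#' @examples
#' exp <- SumStats(data.frame(snp = "rs1", chrom = "1", pos = 1, ea = "A",
#'                            oa = "G", beta = 0.1, se = 0.02, n = 1e4),
#'                 "prot")
#' out <- SumStats(data.frame(snp = "rs1", chrom = "1", pos = 1, ea = "G",
#'                            oa = "A", beta = 0.05, se = 0.01, eaf = 0.3,
#'                            n = 1e5), "lifespan")
#' harmonize(exp, out)  # outcome beta becomes -0.05, eaf 0.7
#' @export
harmonize <- function(exposure, outcome, palindromeEafWindow = 0.08) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
  de <- exposure@data
  do <- outcome@data
  shared <- intersect(de$snp, do$snp)
  if (length(shared) == 0)
    stopf("no shared variants between '%s' and '%s'",
          exposure@traitId, outcome@traitId)
  de <- de[match(shared, de$snp), ]
  do <- do[match(shared, do$snp), ]
  w <- palindromeEafWindow

  n <- length(shared)
  action <- character(n)
  beta_out <- do$beta
  eaf_out <- do$eaf

  for (i in seq_len(n)) {
    ea_e <- de$ea[i]; oa_e <- de$oa[i]
    ea_o <- do$ea[i]; oa_o <- do$oa[i]
    pal <- .is_palindromic(ea_e, oa_e)

    if (pal) {
      same_set <- (ea_o == ea_e && oa_o == oa_e) ||
        (ea_o == oa_e && oa_o == ea_e)
      if (!same_set) { action[i] <- "dropped_incompatible"; next }
      fe <- de$eaf[i]; fo <- do$eaf[i]
      if (is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= w || abs(fo - 0.5) <= w) {
        action[i] <- "dropped_palindromic"; next
      }
      swapped <- ea_o == oa_e
      fo_aligned <- if (swapped) 1 - fo else fo
      if ((fe - 0.5) * (fo_aligned - 0.5) <= 0) {
        ## frequencies contradict the nominal alignment: strand ambiguity
        action[i] <- "dropped_palindromic"; next
      }
      if (swapped) {
        action[i] <- "flipped"
        beta_out[i] <- -do$beta[i]
        eaf_out[i] <- 1 - fo
      } else action[i] <- "kept"
      next
    }

    if (ea_o == ea_e && oa_o == oa_e) { action[i] <- "kept"; next }
    if (ea_o == oa_e && oa_o == ea_e) {
      action[i] <- "flipped"
      beta_out[i] <- -do$beta[i]
      if (!is.na(do$eaf[i])) eaf_out[i] <- 1 - do$eaf[i]
      next
    }
    ## strand-flip inference for single-base alleles only
    if (nchar(ea_e) == 1L && nchar(oa_e) == 1L &&
        nchar(ea_o) == 1L && nchar(oa_o) == 1L) {
      ea_f <- .strand_flip(ea_o); oa_f <- .strand_flip(oa_o)
      if (!is.na(ea_f) && ea_f == ea_e && oa_f == oa_e) {
        action[i] <- "kept"; next
      }
      if (!is.na(ea_f) && ea_f == oa_e && oa_f == ea_e) {
        action[i] <- "flipped"
        beta_out[i] <- -do$beta[i]
        if (!is.na(do$eaf[i])) eaf_out[i] <- 1 - do$eaf[i]
        next
      }
    }
    action[i] <- "dropped_incompatible"
  }

  data.frame(snp = shared, ea = de$ea, oa = de$oa,
             beta_exp = de$beta, se_exp = de$se, eaf_exp = de$eaf,
             pval_exp = de$pval, n_exp = de$n,
             beta_out = beta_out, se_out = do$se, eaf_out = eaf_out,
             pval_out = do$pval, n_out = do$n,
             action = action, stringsAsFactors = FALSE)
}

#' Usable rows of a harmonization result
#'
#' Subsets a [harmonize()] result to the rows whose outcome effect is
#' oriented to the exposure effect allele (action \code{kept} or
#' \code{flipped}).
#'
#' @param h data.frame returned by [harmonize()].
#' @return The usable subset, same columns.
#' @export
harmonizedPairs <- function(h) h[h$action %in% c("kept", "flipped"), ,
                                 drop = FALSE]
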