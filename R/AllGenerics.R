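#' Accessors for TriangulateMR objects
#'
#' Small accessor family in the Bioconductor style: `records()` returns the
#' per-variant data.frame of a [SumStats] object, `variantIds()` the variant
#' identifiers of a [SumStats] or [LDMatrix], `nVariants()` their count,
#' `traitId()`/`traitType()` the trait metadata, `corMatrix()` the raw
#' correlation matrix of an [LDMatrix], and `estimate()`, `stdError()`,
#' `pValue()` the point estimate, standard error and p-value of an
#' [MRResult] or [MetaResult]. `posteriors()` returns the posterior vector of
#' a [ColocResult] (H0..H4) or [MolocResult] (15 configurations).
#'
#' @param x an object of the documented class.
#' @return See details per accessor.
#' @name accessors
#' @aliases records variantIds nVariants traitId traitType corMatrix
#'   estimate stdError pValue posteriors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname accessors
#' @export
setMethod("records", "SumStats", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("variantIds", "SumStats", function(x) x@data$snp)

#' @rdname accessors
#' @export
setMethod("variantIds", "LDMatrix", function(x) x@variantIds)

#' @rdname accessors
#' @export
setMethod("nVariants", "SumStats", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("nVariants", "LDMatrix", function(x) length(x@variantIds))

#' @rdname accessors
#' @export
setMethod("traitId", "SumStats", function(x) x@traitId)

#' @rdname accessors
#' @export
setMethod("traitType", "SumStats", function(x) x@traitType)

#' @rdname accessors
#' @export
setMethod("corMatrix", "LDMatrix", function(x) {
  m <- x@r
  dimnames(m) <- list(x@variantIds, x@variantIds)
  m
})

#' @rdname accessors
#' @export
setMethod("estimate", "MRResult", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("estimate", "MetaResult", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("stdError", "MRResult", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("stdError", "MetaResult", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("pValue", "MRResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("pValue", "MetaResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("posteriors", "ColocResult", function(x) x@pp)

#' @rdname accessors
#' @export
setMethod("posteriors", "MolocResult", function(x) x@configPosteriors)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats '%s' (%s): %d variants\n",
              object@traitId, object@traitType, nrow(object@data)))
  if (length(object@region) == 3)
    cat(sprintf("  region: %s:%d-%d\n", object@region$chrom,
                object@region$start, object@region$end))
  if (nrow(object@data) > 0) {
    print(utils::head(object@data, 4L))
    if (nrow(object@data) > 4) cat("  ...\n")
  }
  invisible(NULL)
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@variantIds)))
  invisible(NULL)
})

setMethod("show", "GeneLocus", function(object) {
  cat(sprintf("GeneLocus %s: %s:%d-%d\n", object@geneId, object@chrom,
              object@start, object@end))
  invisible(NULL)
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult %s -> %s [%s, %d SNP%s]\n", object@exposureId,
              object@outcomeId, object@method, object@nSnp,
              if (object@nSnp == 1L) "" else "s"))
  cat(sprintf("  beta = %.4g (SE %.4g), p = %.3g\n",
              object@beta, object@se, object@pval))
  if (!is.na(object@qPval))
    cat(sprintf("  Cochran Q = %.3g (p = %.3g)\n", object@qStat, object@qPval))
  if (!is.na(object@eggerInterceptPval))
    cat(sprintf("  Egger intercept = %.3g (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptPval))
  if (!is.na(object@pressoGlobalPval))
    cat(sprintf("  MR-PRESSO global p = %.3g, %d outlier(s)\n",
                object@pressoGlobalPval, length(object@pressoOutliers)))
  if (!is.na(object@steigerCorrect))
    cat(sprintf("  Steiger direction correct: %s\n", object@steigerCorrect))
  invisible(NULL)
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult %s: k = %d, beta = %.4g (SE %.4g), p = %.3g, tau2 = %.3g",
              object@targetId, object@kStudies, object@beta, object@se,
              object@pval, object@tau2))
  if (!is.na(object@fdrQ)) cat(sprintf(", q = %.3g", object@fdrQ))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult (single shared causal variant model)\n")
  print(round(object@pp, 4))
  cat(sprintf("  top shared variant: %s\n", object@topSharedVariant))
  invisible(NULL)
})

setMethod("show", "MolocResult", function(object) {
  cat("MolocResult (three-trait configuration enumeration)\n")
  cat(sprintf("  PP causal variant (abc): %.4f\n", object@ppCausalVariant))
  cat(sprintf("  PP causal region: %.4f\n", object@ppCausalRegion))
  cat(sprintf("  best shared variant: %s\n", object@bestSnp))
  invisible(NULL)
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult: indirect = %.4g (SE %.4g)",
              object@indirect["beta"], object@indirect["se"]))
  if (!is.na(object@proportionMediated))
    cat(sprintf(", proportion mediated = %.3f", object@proportionMediated))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "RgResult", function(object) {
  cat(sprintf("RgResult: rg = %.3f (SE %.3f); h2 = (%.3g, %.3g); gencov = %.3g\n",
              object@rg, object@rgSe, object@h2[1], object@h2[2],
              object@gencov))
  invisible(NULL)
})

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport\n")
  print(object@stages, row.names = FALSE)
  cat(sprintf("  final targets: %s\n",
              if (length(object@finalTargets))
                paste(object@finalTargets, collapse = ", ") else "(none)"))
  invisible(NULL)
})
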