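#' Number of SNP records
#'
#' @param x An `AssociationTable` or `HarmonizedPanel`.
#' @return Integer number of SNP records.
#' @export
setGeneric("nSNPs", function(x) standardGeneric("nSNPs"))

#' Extract the underlying per-SNP table
#'
#' @param x An `AssociationTable`, `HarmonizedPanel` or `LDTable`.
#' @return The `data.frame` of per-SNP records.
#' @export
setGeneric("snpData", function(x) standardGeneric("snpData"))

#' Causal-effect point estimate
#' @param x An `MREstimate`.
#' @return Numeric scalar.
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' Standard error of the causal-effect estimate
#' @param x An `MREstimate`.
#' @return Numeric scalar.
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' Two-sided p-value of the causal-effect estimate
#' @param x An `MREstimate`.
#' @return Numeric scalar.
#' @export
setGeneric("mrPvalue", function(x) standardGeneric("mrPvalue"))

#' @rdname nSNPs
#' @export
setMethod("nSNPs", "AssociationTable", function(x) nrow(x@data))
#' @rdname nSNPs
#' @export
setMethod("nSNPs", "HarmonizedPanel", function(x) nrow(x@data))
#' @rdname nSNPs
#' @export
setMethod("nSNPs", "MREstimate", function(x) x@nSNPs)

#' @rdname snpData
#' @export
setMethod("snpData", "AssociationTable", function(x) x@data)
#' @rdname snpData
#' @export
setMethod("snpData", "HarmonizedPanel", function(x) x@data)
#' @rdname snpData
#' @export
setMethod("snpData", "LDTable", function(x) x@data)

#' @rdname mrBeta
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)
#' @rdname mrSE
#' @export
setMethod("mrSE", "MREstimate", function(x) x@se)
#' @rdname mrPvalue
#' @export
setMethod("mrPvalue", "MREstimate", function(x) x@pvalue)

#' @describeIn MREstimate 95% confidence bounds as a length-2 vector.
#' @param object,x An `MREstimate`.
#' @export
mrCI <- function(x) c(x@ciLow, x@ciHigh)

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable for '%s': %d SNPs (%d input rows rejected)\n",
              object@trait, nrow(object@data), object@nDropped))
  if (nrow(object@data) > 0L)
    print(utils::head(object@data, 5L))
  if (nrow(object@data) > 5L)
    cat(sprintf("  ... and %d more\n", nrow(object@data) - 5L))
})

setMethod("show", "HarmonizedPanel", function(object) {
  cat(sprintf("HarmonizedPanel: %s -> %s, %d SNPs\n",
              object@exposure, object@outcome, nrow(object@data)))
  if (length(object@provenance))
    cat(sprintf("  provenance: %d note(s), first: %s\n",
                length(object@provenance), object@provenance[1]))
})

setMethod("show", "LDTable", function(object) {
  cat(sprintf("LDTable: %d SNP pairs\n", nrow(object@data)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s], %d SNPs\n", object@method, object@nSNPs))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
  if (is.finite(object@intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                object@intercept, object@interceptSE, object@interceptP))
  if (is.finite(object@Q))
    cat(sprintf("  Cochran Q = %.3f on %d df, p = %.3g\n",
                object@Q, as.integer(object@Qdf), object@Qp))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "FilterTrace", function(object) {
  cat(sprintf("FilterTrace: %d SNP(s) removed, %d retained\n",
              nrow(object@removed), length(object@retained)))
  cat(sprintf("  final Q = %.3f, p = %.3g%s\n", object@finalQ, object@finalP,
              if (object@converged) "" else " (floor reached, still significant)"))
  if (nrow(object@removed) > 0L) print(object@removed)
})

#' @describeIn MREstimate Flatten to a one-row report data.frame.
#' @export
setMethod("as.data.frame", "MREstimate", function(x, ...) {
  data.frame(method = x@method, n_snps = x@nSNPs, beta = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, pvalue = x@pvalue,
             intercept = x@intercept, intercept_se = x@interceptSE,
             intercept_p = x@interceptP,
             notes = paste(x@flags, collapse = ";"),
             stringsAsFactors = FALSE)
})
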