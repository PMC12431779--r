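#' @rdname TreeSample-class
#' @param x,object a `TreeSample`
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @rdname TreeSample-class
#' @export
setGeneric("treeList", function(x) standardGeneric("treeList"))

#' @rdname TreeSample-class
#' @export
setGeneric("tipNames", function(x) standardGeneric("tipNames"))

#' @rdname TreeSample-class
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))

#' @rdname TreeSample-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname QuartetCount-class
#' @param x,object a `QuartetCount`
#' @export
setGeneric("nMono", function(x) standardGeneric("nMono"))

#' @rdname QuartetCount-class
#' @export
setGeneric("nNonmono", function(x) standardGeneric("nNonmono"))

#' @rdname QuartetCount-class
#' @export
setGeneric("nUninformative", function(x) standardGeneric("nUninformative"))

#' @rdname QuartetCount-class
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))

#' @rdname QuartetCount-class
#' @export
setGeneric("quartetTips", function(x) standardGeneric("quartetTips"))

#' @rdname BayesFactorResult-class
#' @param x,object a `BayesFactorResult`
#' @export
setGeneric("kValue", function(x) standardGeneric("kValue"))

#' @rdname BayesFactorResult-class
#' @export
setGeneric("isLowerBound", function(x) standardGeneric("isLowerBound"))

#' @rdname BayesFactorResult-class
#' @export
setGeneric("bestQuartet", function(x) standardGeneric("bestQuartet"))

#' @rdname BayesFactorResult-class
#' @export
setGeneric("quartetCounts", function(x) standardGeneric("quartetCounts"))

#' @rdname RateProfile-class
#' @param x,object a `RateProfile`
#' @export
setGeneric("meanRate", function(x) standardGeneric("meanRate"))

#' @rdname RateProfile-class
#' @export
setGeneric("baselineMask", function(x) standardGeneric("baselineMask"))

#' @rdname RateProfile-class
#' @export
setGeneric("baselineMean", function(x) standardGeneric("baselineMean"))

#' @rdname RateProfile-class
#' @export
setGeneric("foldChange", function(x) standardGeneric("foldChange"))

#' @rdname TreeSample-class
#' @export
setMethod("nTrees", "TreeSample", function(x) length(x@trees))

#' @rdname TreeSample-class
#' @export
setMethod("treeList", "TreeSample", function(x) x@trees)

#' @rdname TreeSample-class
#' @export
setMethod("tipNames", "TreeSample", function(x) x@taxa$raw)

#' @rdname TreeSample-class
#' @export
setMethod("taxonTable", "TreeSample", function(x) x@taxa)

#' @rdname TreeSample-class
#' @export
setMethod("provenance", "TreeSample", function(x) x@provenance)

#' @rdname TreeSample-class
#' @export
setMethod("length", "TreeSample", function(x) length(x@trees))

setMethod("show", "TreeSample", function(object) {
  cat(sprintf("TreeSample with %d trees over %d tips (%d replicate%s)\n",
              length(object@trees), nrow(object@taxa),
              length(unique(object@provenance$replicate_id)),
              if (length(unique(object@provenance$replicate_id)) == 1L) "" else "s"))
  sp <- table(object@taxa$species_code)
  cat("  species:", paste(sprintf("%s(%d)", names(sp), sp), collapse = " "), "\n")
})

#' @rdname QuartetCount-class
#' @export
setMethod("nMono", "QuartetCount", function(x) x@nMono)

#' @rdname QuartetCount-class
#' @export
setMethod("nNonmono", "QuartetCount", function(x) x@nNonmono)

#' @rdname QuartetCount-class
#' @export
setMethod("nUninformative", "QuartetCount", function(x) x@nUninformative)

#' @rdname QuartetCount-class
#' @export
setMethod("nInformative", "QuartetCount", function(x) x@nMono + x@nNonmono)

#' @rdname QuartetCount-class
#' @export
setMethod("quartetTips", "QuartetCount", function(x) x@quartet)

setMethod("show", "QuartetCount", function(object) {
  q <- object@quartet
  cat(sprintf("QuartetCount {%s,%s | %s,%s}: mono=%d nonmono=%d uninformative=%d\n",
              q[1], q[2], q[3], q[4], object@nMono, object@nNonmono,
              object@nUninformative))
})

#' @rdname BayesFactorResult-class
#' @export
setMethod("kValue", "BayesFactorResult", function(x) x@K)

#' @rdname BayesFactorResult-class
#' @export
setMethod("isLowerBound", "BayesFactorResult", function(x) x@isLowerBound)

#' @rdname BayesFactorResult-class
#' @export
setMethod("bestQuartet", "BayesFactorResult", function(x) x@bestQuartet)

#' @rdname BayesFactorResult-class
#' @export
setMethod("quartetCounts", "BayesFactorResult", function(x) x@counts)

setMethod("show", "BayesFactorResult", function(object) {
  cat(sprintf("Bayes factor K = %s%.6g (%d quartet%s tested)\n",
              if (object@isLowerBound && object@counts@nMono == 0L) ">" else "",
              object@K, object@nQuartetsTested,
              if (object@nQuartetsTested == 1L) "" else "s"))
  if (!anyNA(object@bestQuartet))
    cat("  best quartet:", paste(object@bestQuartet, collapse = ", "), "\n")
})

#' @rdname RateProfile-class
#' @export
setMethod("meanRate", "RateProfile", function(x) x@meanRate)

#' @rdname RateProfile-class
#' @export
setMethod("baselineMask", "RateProfile", function(x) x@baselineMask)

#' @rdname RateProfile-class
#' @export
setMethod("baselineMean", "RateProfile", function(x) x@baselineMean)

#' @rdname RateProfile-class
#' @export
setMethod("foldChange", "RateProfile", function(x) x@foldChange)

#' @rdname RateProfile-class
#' @export
setMethod("length", "RateProfile", function(x) length(x@meanRate))

setMethod("show", "RateProfile", function(object) {
  cat(sprintf("RateProfile over %d columns (%d baseline); baseline mean rate %.4g\n",
              length(object@meanRate), sum(object@baselineMask),
              object@baselineMean))
  cat(sprintf("  fold change range: [%.3g, %.3g]\n",
              min(object@foldChange), max(object@foldChange)))
})
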