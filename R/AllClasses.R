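#' @import methods
#' @importFrom stats var acf lm fisher.test complete.cases rnorm runif setNames
#' @importFrom utils combn read.delim write.table head
NULL

setOldClass("multiPhylo")
setOldClass("phylo")

#' TreeSample: an ordered posterior sample of phylogenies
#'
#' Holds an ordered collection of phylogenies over a fixed, shared tip set,
#' together with the parsed taxon labels and per-tree provenance
#' (replicate identifier and state index).  This is the container for
#' posterior tree samples produced by Bayesian phylogenetic samplers and by
#' [simulatePosteriorSample()]; downstream quartet tallies and
#' maximum-clade-credibility summaries operate on it.
#'
#' @slot trees a `multiPhylo` list of trees, all over the same tip set.
#' @slot taxa `data.frame` of parsed tip labels (see [parseTaxonLabels()]),
#'   one row per tip, in canonical (sorted) tip order.
#' @slot provenance `data.frame` with columns `replicate_id` and
#'   `state_index`, one row per tree, in tree order.
#'
#' @seealso [readTreeSamples()], [applyBurnin()], [combineReplicates()],
#'   [mccTree()], [countTopologies()]
#' @export
setClass("TreeSample",
  representation(trees = "multiPhylo", taxa = "data.frame",
                 provenance = "data.frame"))

setValidity("TreeSample", function(object) {
  trees <- object@trees
  if (length(trees) < 1L) return("a TreeSample must contain at least one tree")
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- trees[[i]]$tip.label
    if (length(tl) != length(ref) || !setequal(tl, ref)) {
      miss <- setdiff(ref, tl)
      extra <- setdiff(tl, ref)
      return(sprintf("tree %d does not match the shared tip set (missing: %s; extra: %s)",
                     i, paste(miss, collapse = ","), paste(extra, collapse = ",")))
    }
  }
  if (nrow(object@provenance) != length(trees))
    return("provenance must have one row per tree")
  if (!all(c("replicate_id", "state_index") %in% names(object@provenance)))
    return("provenance needs columns replicate_id and state_index")
  if (nrow(object@taxa) != length(ref) || !setequal(object@taxa$raw, ref))
    return("taxa table must describe exactly the shared tip set")
  TRUE
})

#' Construct a TreeSample
#'
#' @param trees a `multiPhylo` object or list of `phylo` trees sharing one
#'   tip set.
#' @param replicate_id replicate label recorded in the provenance, recycled
#'   across trees.  Ignored when `provenance` is supplied.
#' @param provenance optional `data.frame` with columns `replicate_id` and
#'   `state_index`, one row per tree.
#' @param species_table optional vector of recognized species codes passed
#'   to [parseTaxonLabels()].
#' @param groups optional named list mapping taxon-group keys to species
#'   codes, passed to [parseTaxonLabels()].
#' @return a [TreeSample-class] object.
#' @export
TreeSample <- function(trees, replicate_id = "r1", provenance = NULL,
                       species_table = NULL, groups = NULL) {
  if (inherits(trees, "phylo")) trees <- c(.as_multiPhylo(list(trees)))
  trees <- .as_multiPhylo(trees)
  if (is.null(provenance)) {
    provenance <- data.frame(replicate_id = rep_len(replicate_id, length(trees)),
                             state_index = seq_along(trees),
                             stringsAsFactors = FALSE)
  }
  taxa <- parseTaxonLabels(sort(trees[[1L]]$tip.label),
                           species_table = species_table, groups = groups)
  new("TreeSample", trees = trees, taxa = taxa, provenance = provenance)
}

.as_multiPhylo <- function(trees) {
  if (inherits(trees, "multiPhylo")) return(trees)
  stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
  class(trees) <- "multiPhylo"
  trees
}

#' QuartetCount: quartet topology tallies over a tree sample
#'
#' Monophyletic / non-monophyletic / uninformative tallies for a single
#' four-tip query (two alleles from a focal group A, two from a comparison
#' group B) over a [TreeSample-class].  A tree is *monophyletic* for the
#' quartet when the induced unrooted four-tip tree has an internal edge
#' separating the A pair from the B pair, *non-monophyletic* when it is
#' resolved otherwise, and *uninformative* when the induced quartet is a
#' star.  Uninformative trees are excluded from the informative total `n`.
#'
#' @slot quartet named character vector `c(a1, a2, b1, b2)` of tip labels.
#' @slot nMono,nNonmono,nUninformative integer tallies.
#' @export
setClass("QuartetCount",
  representation(quartet = "character", nMono = "integer",
                 nNonmono = "integer", nUninformative = "integer"))

setValidity("QuartetCount", function(object) {
  q <- object@quartet
  if (length(q) != 4L || anyDuplicated(q))
    return("quartet must be four distinct tip labels")
  cnt <- c(object@nMono, object@nNonmono, object@nUninformative)
  if (any(is.na(cnt)) || any(cnt < 0L)) return("counts must be non-negative")
  TRUE
})

#' Construct a QuartetCount
#'
#' @param quartet character vector of four distinct tip labels
#'   `(a1, a2, b1, b2)`; the first two are the focal-group pair.
#' @param nMono,nNonmono,nUninformative non-negative tallies.
#' @return a [QuartetCount-class] object.
#' @export
QuartetCount <- function(quartet = c("a1", "a2", "b1", "b2"),
                         nMono, nNonmono, nUninformative = 0L) {
  quartet <- as.character(quartet)
  names(quartet) <- c("a1", "a2", "b1", "b2")
  new("QuartetCount", quartet = quartet, nMono = as.integer(nMono),
      nNonmono = as.integer(nNonmono),
      nUninformative = as.integer(nUninformative))
}

#' BayesFactorResult: quartet Bayes factor for trans-species polymorphism
#'
#' The Bayes factor K compares the hypothesis that the focal pair of
#' alleles is non-monophyletic (trans-species polymorphism) against
#' monophyly, computed from posterior topology frequencies and multiplied
#' by the prior odds in favor of monophyly (1/2 under a uniform prior on
#' the three unrooted quartet resolutions).  When one topology count is
#' zero it is regularized to probability 1/(n+1) and the result is flagged:
#' with zero monophyletic trees the reported K is a lower bound.
#'
#' @slot K numeric Bayes factor, > 0.
#' @slot isLowerBound flag set when a zero count was regularized.
#' @slot bestQuartet tip labels of the maximizing quartet (`NA` for a
#'   single-quartet computation).
#' @slot counts the [QuartetCount-class] behind `K`.
#' @slot nQuartetsTested number of quartets examined.
#' @export
setClass("BayesFactorResult",
  representation(K = "numeric", isLowerBound = "logical",
                 bestQuartet = "character", counts = "QuartetCount",
                 nQuartetsTested = "integer"))

setValidity("BayesFactorResult", function(object) {
  if (length(object@K) != 1L || is.na(object@K) || object@K <= 0)
    return("K must be a single positive number")
  if (object@isLowerBound &&
      object@counts@nMono > 0L && object@counts@nNonmono > 0L)
    return("isLowerBound implies one of the topology counts was zero")
  TRUE
})

#' RateProfile: normalized per-column evolutionary rates
#'
#' Per-alignment-column posterior-mean substitution rates together with the
#' gappy-baseline mask, the baseline mean rate, and per-column base-2 log
#' fold changes relative to that baseline.  By construction the mean of
#' `2^foldChange` over baseline columns is exactly 1.
#'
#' @slot meanRate per-column posterior mean rate (> 0).
#' @slot baselineMask logical, `TRUE` for baseline (gappy) columns.
#' @slot baselineMean mean of `meanRate` over baseline columns.
#' @slot foldChange `log2(meanRate / baselineMean)` per column.
#' @export
setClass("RateProfile",
  representation(meanRate = "numeric", baselineMask = "logical",
                 baselineMean = "numeric", foldChange = "numeric"))

setValidity("RateProfile", function(object) {
  L <- length(object@meanRate)
  if (length(object@baselineMask) != L || length(object@foldChange) != L)
    return("meanRate, baselineMask and foldChange must have equal length")
  if (!any(object@baselineMask)) return("at least one baseline column required")
  bm <- mean(object@meanRate[object@baselineMask])
  if (!isTRUE(all.equal(bm, object@baselineMean)))
    return("baselineMean must equal the mean rate over baseline columns")
  TRUE
})
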