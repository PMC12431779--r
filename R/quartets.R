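#' Classify the induced unrooted quartet topology
#'
#' The tree is treated as unrooted and restricted to the four query tips.
#' The quartet is *monophyletic* when some internal edge of the induced
#' four-tip tree separates the focal pair `{a1, a2}` from `{b1, b2}`,
#' *non-monophyletic* when the induced quartet is resolved the other way,
#' and *uninformative* when it is a star (polytomy).  Of the three labeled
#' unrooted resolutions of four tips, exactly one is monophyletic for a
#' given two-vs-two labeling, which is where the 1/2 prior odds in
#' [bayesFactor()] come from.
#'
#' @param tree a `phylo` tree containing all four tips.
#' @param quartet character vector of four distinct tip labels
#'   `(a1, a2, b1, b2)`; the first two form the focal pair.
#' @return one of `"monophyletic"`, `"nonmonophyletic"`, `"uninformative"`.
#' @export
quartetTopology <- function(tree, quartet) {
  stopifnot(inherits(tree, "phylo"))
  quartet <- as.character(quartet)
  if (length(quartet) != 4L || anyDuplicated(quartet))
    stop("quartet must be four distinct tip labels")
  missing <- setdiff(quartet, tree$tip.label)
  if (length(missing))
    stop("tip(s) not present in tree: ", paste(missing, collapse = ", "))
  sub <- ape::keep.tip(tree, quartet)
  if (ape::is.rooted(sub)) sub <- ape::unroot(sub)
  if (sub$Nnode == 1L) return("uninformative")
  # unrooted binary 4-tip tree: two internal nodes, two tips on each
  parent <- sub$edge[match(seq_len(4L), sub$edge[, 2L]), 1L]
  pq <- parent[match(quartet, sub$tip.label)]
  if (pq[1L] == pq[2L]) "monophyletic" else "nonmonophyletic"
}

# Array of unit-branch-length tip-tip path distances, dims (tip, tip, tree),
# tips in canonical sorted order.  The induced quartet topology of any tree
# follows from the four-point condition on these distances.
.unit_dist_array <- function(x) {
  trees <- x@trees
  ref <- sort(trees[[1L]]$tip.label)
  t <- length(ref)
  arr <- array(NA_real_, dim = c(t, t, length(trees)),
               dimnames = list(ref, ref, NULL))
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    tr$edge.length <- rep(1, nrow(tr$edge))
    D <- ape::cophenetic.phylo(tr)
    arr[, , k] <- D[ref, ref]
  }
  arr
}

# Per-tree quartet classification from a unit-distance array; idx are the
# canonical indices of (a1, a2, b1, b2).  Returns integer counts
# c(mono, nonmono, uninformative).
.count_quartet <- function(arr, idx) {
  s1 <- arr[idx[1L], idx[2L], ] + arr[idx[3L], idx[4L], ]
  s2 <- arr[idx[1L], idx[3L], ] + arr[idx[2L], idx[4L], ]
  s3 <- arr[idx[1L], idx[4L], ] + arr[idx[2L], idx[3L], ]
  mono <- s1 < s2 & s1 < s3
  star <- s1 == s2 & s1 == s3
  c(sum(mono), sum(!mono & !star), sum(star))
}

#' Tally quartet topologies over a tree sample
#'
#' Applies [quartetTopology()] to every tree of the sample and tallies
#' monophyletic, non-monophyletic and uninformative outcomes.  The default
#' method classifies each tree through the four-point condition on
#' unit-branch-length path distances (equivalent to pruning, but far
#' faster over large samples); `method = "prune"` restricts each tree
#' explicitly.
#'
#' @param x a [TreeSample-class].
#' @param quartet character vector `(a1, a2, b1, b2)` of tip labels.
#' @param method `"fourpoint"` (default) or `"prune"`.
#' @return a [QuartetCount-class].
#' @export
countTopologies <- function(x, quartet, method = c("fourpoint", "prune")) {
  stopifnot(is(x, "TreeSample"))
  method <- match.arg(method)
  quartet <- as.character(quartet)
  missing <- setdiff(quartet, x@taxa$raw)
  if (length(missing))
    stop("tip(s) not present in sample: ", paste(missing, collapse = ", "))
  if (method == "prune") {
    res <- vapply(x@trees, quartetTopology, character(1L), quartet = quartet)
    cnt <- c(sum(res == "monophyletic"), sum(res == "nonmonophyletic"),
             sum(res == "uninformative"))
  } else {
    arr <- .unit_dist_array(x)
    cnt <- .count_quartet(arr, match(quartet, dimnames(arr)[[1L]]))
  }
  QuartetCount(quartet, nMono = cnt[1L], nNonmono = cnt[2L],
               nUninformative = cnt[3L])
}

# Scalar Bayes factor from raw counts; returns list(K, lower_bound).
.bf_from_counts <- function(n_mono, n_nonmono, prior_odds_H) {
  n <- n_mono + n_nonmono
  if (n < 1L) stop("Bayes factor undefined: no informative trees")
  f_mono <- n_mono / n
  f_non <- n_nonmono / n
  lower <- FALSE
  if (f_mono == 0 || f_non == 0) {
    p <- 1 / (n + 1)
    if (f_mono == 0) { f_mono <- p; f_non <- 1 - p } else { f_non <- p; f_mono <- 1 - p }
    lower <- TRUE
  }
  list(K = (f_non / f_mono) * prior_odds_H, lower_bound = lower)
}

#' Bayes factor for trans-species polymorphism from quartet counts
#'
#' Computes `K = Pr(Hc|D) / Pr(H|D) * prior_odds_H`, where `H` is
#' monophyly of the focal allele pair, `Hc` non-monophyly, and the
#' posterior probabilities are the topology frequencies over informative
#' trees.  The prior-odds factor defaults to 1/2: of the three unrooted
#' four-tip resolutions, one is monophyletic and two are not.  If either
#' frequency is zero it is replaced by `p = 1/(n+1)` (the complement by
#' `1 - p`) and the result is flagged; when no tree is monophyletic the
#' reported K is thus a lower bound (e.g. a sample of 14,000 trees with
#' zero monophyletic topologies yields K = 7,000 at minimum).  K > 100 is
#' conventionally decisive support for trans-species polymorphism and
#' K < 1 is evidence against it.
#'
#' @param counts a [QuartetCount-class] with at least one informative tree.
#' @param prior_odds_H prior odds in favor of monophyly; default `1/2`.
#' @return a [BayesFactorResult-class].
#' @export
bayesFactor <- function(counts, prior_odds_H = 0.5) {
  stopifnot(is(counts, "QuartetCount"))
  bf <- .bf_from_counts(counts@nMono, counts@nNonmono, prior_odds_H)
  new("BayesFactorResult", K = bf$K, isLowerBound = bf$lower_bound,
      bestQuartet = NA_character_, counts = counts, nQuartetsTested = 1L)
}

#' Enumerate allele quartets between two taxon groups
#'
#' Forms all `choose(|A|, 2) * choose(|B|, 2)` quartets of two focal-group
#' and two comparison-group tips, after removing excluded tips (e.g.
#' gene-conversion acceptors).  If the total exceeds `cap`, a uniform
#' subsample of size `cap` is drawn deterministically under `seed`.
#' With fewer than two usable tips on either side a classed
#' `tspscan_not_enough_alleles` error is signalled (rendered as a blank
#' cell by [bfMatrix()]).
#'
#' @param groupA_tips,groupB_tips character vectors of tip labels.
#' @param excluded tips removed from both groups before enumeration.
#' @param cap maximum number of quartets returned; default 10,000.
#' @param seed integer seed for the subsample when the cap binds.
#' @return `data.frame` with columns `a1`, `a2`, `b1`, `b2`.
#' @export
enumerateQuartets <- function(groupA_tips, groupB_tips,
                              excluded = character(), cap = 10000L,
                              seed = 1L) {
  A <- setdiff(unique(as.character(groupA_tips)), excluded)
  B <- setdiff(unique(as.character(groupB_tips)), excluded)
  B <- setdiff(B, A)
  if (length(A) < 2L || length(B) < 2L)
    stop(.not_enough_alleles(sprintf(
      "not enough alleles after exclusion (|A| = %d, |B| = %d; two from each group required)",
      length(A), length(B))))
  pa <- utils::combn(sort(A), 2L)
  pb <- utils::combn(sort(B), 2L)
  ia <- rep(seq_len(ncol(pa)), times = ncol(pb))
  ib <- rep(seq_len(ncol(pb)), each = ncol(pa))
  q <- data.frame(a1 = pa[1L, ia], a2 = pa[2L, ia],
                  b1 = pb[1L, ib], b2 = pb[2L, ib],
                  stringsAsFactors = FALSE)
  if (nrow(q) > cap) {
    keep <- .with_seed(seed, sort(sample.int(nrow(q), cap)))
    q <- q[keep, , drop = FALSE]
    rownames(q) <- NULL
  }
  q
}

#' Maximum Bayes factor over allele quartets
#'
#' Computes [bayesFactor()] for every enumerated quartet between two tip
#' groups and reports the maximum, since any quartet with compelling
#' evidence for allele-lineage sharing is of interest.  Ties are broken by
#' lowest quartet index.  Quartets with no informative tree are skipped.
#'
#' @param x a [TreeSample-class].
#' @param groupA_tips,groupB_tips,excluded,cap,seed see
#'   [enumerateQuartets()].
#' @param prior_odds_H prior odds in favor of monophyly; default `1/2`.
#' @return a [BayesFactorResult-class]; `bestQuartet` holds the maximizing
#'   quartet and `counts` its tallies.
#' @export
maxBayesFactor <- function(x, groupA_tips, groupB_tips,
                           excluded = character(), cap = 10000L, seed = 1L,
                           prior_odds_H = 0.5) {
  stopifnot(is(x, "TreeSample"))
  q <- enumerateQuartets(groupA_tips, groupB_tips, excluded = excluded,
                         cap = cap, seed = seed)
  missing <- setdiff(unique(unlist(q, use.names = FALSE)), x@taxa$raw)
  if (length(missing))
    stop("tip(s) not present in sample: ", paste(missing, collapse = ", "))
  arr <- .unit_dist_array(x)
  ref <- dimnames(arr)[[1L]]
  bestK <- -Inf; best_i <- NA_integer_; best_cnt <- NULL; best_lb <- FALSE
  for (i in seq_len(nrow(q))) {
    idx <- match(c(q$a1[i], q$a2[i], q$b1[i], q$b2[i]), ref)
    cnt <- .count_quartet(arr, idx)
    if (cnt[1L] + cnt[2L] == 0L) next
    bf <- .bf_from_counts(cnt[1L], cnt[2L], prior_odds_H)
    if (bf$K > bestK) {
      bestK <- bf$K; best_i <- i; best_cnt <- cnt; best_lb <- bf$lower_bound
    }
  }
  if (is.na(best_i))
    stop("Bayes factor undefined: no quartet had informative trees")
  quartet <- c(q$a1[best_i], q$a2[best_i], q$b1[best_i], q$b2[best_i])
  counts <- QuartetCount(quartet, nMono = best_cnt[1L],
                         nNonmono = best_cnt[2L],
                         nUninformative = best_cnt[3L])
  new("BayesFactorResult", K = bestK, isLowerBound = best_lb,
      bestQuartet = stats::setNames(quartet, c("a1", "a2", "b1", "b2")),
      counts = counts, nQuartetsTested = nrow(q))
}

# Resolve a group key to tip labels of a sample via parsed species codes.
.group_tips <- function(x, group_key, groups) {
  if (!group_key %in% names(groups))
    stop("unknown group key: ", group_key)
  taxa <- x@taxa
  taxa$raw[taxa$species_code %in% groups[[group_key]]]
}

#' Bayes factor matrix across gene regions and taxon comparisons
#'
#' One [maxBayesFactor()] cell per (comparison x region).  Group
#' membership is resolved through the parsed species codes of each
#' sample's tip labels.  Cells with fewer than two usable alleles on
#' either side are reported blank (`K = NA`, note
#' `"insufficient alleles"`); cells whose maximum required zero-count
#' regularization carry `lower_bound = TRUE` (conventionally rendered with
#' a `>` prefix).
#'
#' @param samples named list of [TreeSample-class] objects, one per gene
#'   region.
#' @param comparisons `data.frame` (or list of 2-vectors) with columns
#'   `groupA`, `groupB` naming entries of `groups`.
#' @param groups named list mapping group keys to species-code vectors.
#' @param exclusions optional named list (by region) of excluded tip
#'   labels, e.g. from [exclusionList()].
#' @param cap,seed,prior_odds_H see [maxBayesFactor()].
#' @return `data.frame` with columns `comparison`, `region`, `K`,
#'   `lower_bound`, `n_quartets`, `best_quartet`, `note`.
#' @export
bfMatrix <- function(samples, comparisons, groups, exclusions = list(),
                     cap = 10000L, seed = 1L, prior_odds_H = 0.5) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            !is.null(names(samples)))
  if (!is.data.frame(comparisons)) {
    comparisons <- do.call(rbind, lapply(comparisons, function(p)
      data.frame(groupA = p[[1L]], groupB = p[[2L]],
                 stringsAsFactors = FALSE)))
  }
  rows <- list()
  for (ci in seq_len(nrow(comparisons))) {
    gA <- comparisons$groupA[ci]; gB <- comparisons$groupB[ci]
    for (region in names(samples)) {
      x <- samples[[region]]
      excl <- if (region %in% names(exclusions)) exclusions[[region]] else character()
      cell <- tryCatch({
        res <- maxBayesFactor(x, .group_tips(x, gA, groups),
                              .group_tips(x, gB, groups), excluded = excl,
                              cap = cap, seed = seed,
                              prior_odds_H = prior_odds_H)
        data.frame(comparison = paste(gA, "vs", gB), region = region,
                   K = res@K, lower_bound = res@isLowerBound,
                   n_quartets = res@nQuartetsTested,
                   best_quartet = paste(res@bestQuartet, collapse = ","),
                   note = "", stringsAsFactors = FALSE)
      }, tspscan_not_enough_alleles = function(e) {
        data.frame(comparison = paste(gA, "vs", gB), region = region,
                   K = NA_real_, lower_bound = FALSE, n_quartets = 0L,
                   best_quartet = NA_character_,
                   note = "insufficient alleles", stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
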