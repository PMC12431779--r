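#' Parse MHC-style taxon labels
#'
#' Tip labels of the form `<SpeciesCode><sep><AlleleName>` (for example
#' `Patr_B*01:01` or `HLA-B*07:02`) are split into a four-letter species
#' code (or `HLA`) and an allele name.  Labels that do not match the
#' pattern, or whose code is absent from a supplied species table, get
#' species code `unknown` with the whole label as allele name.  Parsing is
#' total: it never fails on well-formed text, and for matched labels
#' re-serializing `species_code + separator + allele_name` reproduces the
#' input.
#'
#' @param labels character vector of tip labels.
#' @param species_table optional character vector of recognized species
#'   codes; when supplied, matched codes outside the table are demoted to
#'   `unknown`.
#' @param groups optional named list mapping taxon-group keys (e.g.
#'   `"OWM"`) to character vectors of species codes; each label is
#'   assigned the first group containing its code.
#' @return `data.frame` with columns `raw`, `species_code`, `separator`,
#'   `allele_name`, `group`.
#' @examples
#' parseTaxonLabels(c("HLA-B*07:02", "Patr_B*01:01", "oddball"))
#' @export
parseTaxonLabels <- function(labels, species_table = NULL, groups = NULL) {
  m <- regexec("^([A-Za-z]{4}|HLA)([-_])(.+)$", labels)
  parts <- regmatches(labels, m)
  out <- data.frame(raw = labels,
                    species_code = "unknown",
                    separator = NA_character_,
                    allele_name = labels,
                    group = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    p <- parts[[i]]
    if (length(p) == 4L) {
      code <- p[2L]
      if (is.null(species_table) || code %in% species_table) {
        out$species_code[i] <- code
        out$separator[i] <- p[3L]
        out$allele_name[i] <- p[4L]
      }
    }
  }
  if (!is.null(groups)) {
    for (g in names(groups)) {
      hit <- out$species_code %in% groups[[g]] & is.na(out$group)
      out$group[hit] <- g
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a posterior tree sample
#'
#' Reads an ordered sample of phylogenies from a Nexus file (BEAST-style,
#' translate block supported) or a plain Newick file with one tree per
#' line.  All trees must share an identical tip set; the first offending
#' tree is named otherwise.  Branch lengths are preserved.
#'
#' @param path file path.
#' @param format `"auto"` (sniff for `#NEXUS`), `"nexus"`, or `"newick"`.
#' @param replicate_id replicate label recorded in the provenance; defaults
#'   to the file name without extension.
#' @param species_table,groups passed to [parseTaxonLabels()].
#' @return a [TreeSample-class].
#' @export
readTreeSamples <- function(path, format = c("auto", "nexus", "newick"),
                            replicate_id = NULL, species_table = NULL,
                            groups = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(replicate_id))
    replicate_id <- tools::file_path_sans_ext(basename(path))
  if (format == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && grepl("^#NEXUS", trimws(first[1L]),
                                         ignore.case = TRUE)) "nexus" else "newick"
  }
  if (format == "nexus") {
    trees <- ape::read.nexus(path)
    if (inherits(trees, "phylo")) trees <- .as_multiPhylo(list(trees))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no trees found in ", path)
    trees <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      tr <- tryCatch(ape::read.tree(text = lines[i]),
                     error = function(e) NULL, warning = function(w) NULL)
      if (is.null(tr) || !inherits(tr, "phylo"))
        stop(sprintf("malformed Newick for tree %d in %s", i, path))
      trees[[i]] <- tr
    }
    trees <- .as_multiPhylo(trees)
  }
  names(trees) <- NULL
  .check_shared_tips(trees)
  TreeSample(trees, replicate_id = replicate_id,
             species_table = species_table, groups = groups)
}

.check_shared_tips <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- trees[[i]]$tip.label
    if (length(tl) != length(ref) || !setequal(tl, ref)) {
      miss <- setdiff(ref, tl)
      extra <- setdiff(tl, ref)
      stop(sprintf("tree %d has a different tip set than tree 1 (missing: %s; extra: %s)",
                   i, paste(miss, collapse = ","), paste(extra, collapse = ",")))
    }
  }
  invisible(TRUE)
}

#' Write a TreeSample to disk
#'
#' @param x a [TreeSample-class].
#' @param path output file path.
#' @param format `"newick"` (one tree per line) or `"nexus"` (with a
#'   translate block).
#' @return `path`, invisibly.
#' @export
writeTreeSample <- function(x, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(x, "TreeSample"))
  if (format == "newick") {
    ape::write.tree(x@trees, file = path)
  } else {
    ape::write.nexus(x@trees, file = path, translate = TRUE)
  }
  invisible(path)
}

#' Discard burn-in states from a tree sample
#'
#' Removes the first `floor(burnin_fraction * n)` trees, mirroring the
#' convention of discarding the initial 10% of MCMC states before
#' downstream summaries.  Provenance rows are preserved for the remainder.
#'
#' @param x a [TreeSample-class].
#' @param burnin_fraction proportion in `[0, 1)`; default 0.10.
#' @return the trimmed [TreeSample-class].
#' @export
applyBurnin <- function(x, burnin_fraction = 0.10) {
  stopifnot(is(x, "TreeSample"))
  if (!is.numeric(burnin_fraction) || length(burnin_fraction) != 1L ||
      is.na(burnin_fraction) || burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must lie in [0, 1)")
  n <- length(x@trees)
  drop <- floor(burnin_fraction * n)
  keep <- seq.int(drop + 1L, n)
  new("TreeSample", trees = x@trees[keep], taxa = x@taxa,
      provenance = x@provenance[keep, , drop = FALSE])
}

#' Combine replicate tree samples
#'
#' Concatenates replicates in argument order (the aggregation performed
#' after per-replicate burn-in removal, before computing posterior
#' topology frequencies).  All replicates must share an identical tip set.
#'
#' @param samples list of [TreeSample-class] objects (a single
#'   `TreeSample` is returned unchanged).
#' @return the combined [TreeSample-class].
#' @export
combineReplicates <- function(samples) {
  if (is(samples, "TreeSample")) return(samples)
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, is, TRUE, "TreeSample")))
  if (length(samples) == 1L) return(samples[[1L]])
  ref <- sort(samples[[1L]]@taxa$raw)
  for (i in seq_along(samples)[-1L]) {
    tl <- samples[[i]]@taxa$raw
    if (!setequal(tl, ref))
      stop(sprintf("replicates 1 and %d have different tip sets (missing: %s; extra: %s)",
                   i, paste(setdiff(ref, tl), collapse = ","),
                   paste(setdiff(tl, ref), collapse = ",")))
  }
  trees <- do.call(c, lapply(samples, function(s) s@trees))
  prov <- do.call(rbind, lapply(samples, function(s) s@provenance))
  rownames(prov) <- NULL
  new("TreeSample", trees = .as_multiPhylo(trees), taxa = samples[[1L]]@taxa,
      provenance = prov)
}

# Canonical clade keys for one tree: for rooted trees these are rooted
# clades; unrooted trees are first rooted at the canonical (alphabetically
# first) tip so that keys correspond to bipartitions.  Keys are sorted tip
# indices relative to ref_labels.
.clade_keys <- function(tree, ref_labels, reroot) {
  if (reroot) {
    tree <- ape::root(tree, outgroup = ref_labels[1L], resolve.root = TRUE)
  }
  ntip <- length(tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  idx <- match(tree$tip.label, ref_labels)
  vapply(desc, function(d) paste(sort(idx[d]), collapse = ","), character(1L))
}

#' Maximum clade credibility tree
#'
#' Returns the sampled tree maximizing the product of posterior clade
#' frequencies, with clade frequencies tallied over the whole sample.
#' When every tree in the sample is rooted, rooted clades are counted;
#' otherwise all trees are rooted at the canonical (alphabetically first)
#' tip so that counted clades correspond to unrooted bipartitions.  Ties
#' are broken by lowest sample index.  Node heights and branch lengths of
#' the selected tree are passed through unmodified.
#'
#' @param x a [TreeSample-class].
#' @return the selected `phylo` tree, with attributes `index` (its position
#'   in the sample) and `logCladeScore` (sum of log clade frequencies).
#' @export
mccTree <- function(x) {
  stopifnot(is(x, "TreeSample"))
  trees <- x@trees
  ref <- sort(trees[[1L]]$tip.label)
  reroot <- !all(vapply(trees, ape::is.rooted, TRUE))
  keys <- lapply(trees, .clade_keys, ref_labels = ref, reroot = reroot)
  freq <- table(unlist(keys, use.names = FALSE)) / length(trees)
  scores <- vapply(keys, function(k) sum(log(as.numeric(freq[k]))), numeric(1L))
  best <- which.max(scores)
  out <- trees[[best]]
  attr(out, "index") <- best
  attr(out, "logCladeScore") <- scores[best]
  out
}

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time ESS: the empirical autocorrelation function is
#' summed over the initial positive sequence (truncated at the first
#' non-positive lag), giving an integrated autocorrelation time
#' `tau = 1 + 2 * sum(rho_k)` and `ESS = n / tau`.  A constant
#' (zero-variance) series reports ESS equal to its length, by convention.
#' Samplers are typically gated on ESS >= 100 for every parameter.
#'
#' @param series ordered numeric values of length >= 10.
#' @param max_lag largest lag considered (default `min(n - 1, 1000)`).
#' @return the effective sample size (a single number).
#' @export
essValue <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("ESS needs a series of length >= 10")
  if (anyNA(series)) stop("series must not contain NA")
  if (stats::var(series) == 0) return(n)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 1000L)
  rho <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1L] - 1L)]
  tau <- 1 + 2 * sum(rho)
  n / max(tau, .Machine$double.eps)
}
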