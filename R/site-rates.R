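# Per-site evolutionary-rate aggregation: posterior means, the gappy
# baseline, log2 fold changes, per-codon rates, exon summaries, and the
# association-count regression.

#' Read a per-site rate posterior
#'
#' Tab-separated table with a header of alignment-column ids and one row
#' per sampled state (burn-in assumed already applied upstream).
#'
#' @param path file path.
#' @return numeric matrix, states x columns.
#' @export
readRatePosterior <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  m
}

#' Posterior-mean rate per alignment column
#'
#' Arithmetic mean of the sampled relative rates over all states, per
#' column (mean first, log transform later — fold changes are computed
#' from these means).
#'
#' @param post numeric matrix of relative rates, states x columns, all
#'   positive.
#' @return named numeric vector of per-column means.
#' @export
meanSiteRates <- function(post) {
  post <- as.matrix(post)
  if (nrow(post) < 1L) stop("at least one sampled state is required")
  if (any(post <= 0)) stop("all rates must be positive")
  colMeans(post)
}

#' Identify gappy baseline columns
#'
#' Baseline ("gappy") columns are those in which *all* of the designated
#' backbone sequences carry a gap character.  Because such columns carry
#' little signal and are common to every alignment in a family, their mean
#' inferred rate serves as the normalization denominator for fold changes.
#'
#' @param aln alignment accepted by [detectFragments()].
#' @param backbone_ids sequence ids whose joint gap pattern defines the
#'   baseline; all must be present.
#' @return logical mask, one entry per alignment column.
#' @export
identifyBaselineSites <- function(aln, backbone_ids) {
  m <- .aln_matrix(aln)
  missing <- setdiff(backbone_ids, rownames(m))
  if (length(missing))
    stop("backbone sequence(s) not in alignment: ",
         paste(missing, collapse = ", "))
  sub <- m[backbone_ids, , drop = FALSE]
  apply(sub, 2L, function(col) all(.is_gap(col)))
}

#' Normalize rates to log2 fold changes over the gappy baseline
#'
#' The baseline mean is the arithmetic mean of the per-column posterior
#' mean rates over baseline columns; each column's fold change is
#' `log2(mean_rate / baseline_mean)`.  A fold change of 1 means more than
#' twice the baseline rate, 2 means four times.  Fold changes are
#' invariant to rescaling all rates by a common factor, and the mean of
#' `2^foldChange` over baseline columns is exactly 1.
#'
#' @param means per-column posterior mean rates (see [meanSiteRates()]).
#' @param baseline_mask logical mask from [identifyBaselineSites()]; at
#'   least one `TRUE` entry.
#' @return a [RateProfile-class].
#' @export
foldChanges <- function(means, baseline_mask) {
  means <- as.numeric(means)
  baseline_mask <- as.logical(baseline_mask)
  if (length(means) != length(baseline_mask))
    stop("means and baseline_mask must have equal length")
  if (!any(baseline_mask)) stop("no baseline sites")
  if (any(means <= 0)) stop("all mean rates must be positive")
  bm <- mean(means[baseline_mask])
  new("RateProfile", meanRate = means, baselineMask = baseline_mask,
      baselineMean = bm, foldChange = log2(means / bm))
}

#' Per-amino-acid rates from per-column values
#'
#' Each codon's rate is the mean of its three member columns' values;
#' codons with any unmapped or missing (NA) column are emitted as missing.
#'
#' @param site_values numeric vector indexed by alignment column (e.g.
#'   `foldChange(profile)` or `meanRate(profile)`); NA marks gap columns.
#' @param cds_map `data.frame` with columns `column` (alignment column)
#'   and `codon` (codon index); see [makeCdsMap()].
#' @return named numeric vector, one entry per codon index (NA = missing).
#' @export
codonRates <- function(site_values, cds_map) {
  stopifnot(is.data.frame(cds_map), all(c("column", "codon") %in% names(cds_map)))
  codons <- sort(unique(cds_map$codon))
  out <- vapply(codons, function(cd) {
    cols <- cds_map$column[cds_map$codon == cd]
    if (length(cols) != 3L) return(NA_real_)
    v <- site_values[cols]
    if (anyNA(v)) return(NA_real_)
    mean(v)
  }, numeric(1L))
  names(out) <- codons
  out
}

#' Build a codon map from ordered coding columns
#'
#' Chunks an ordered vector of coding alignment columns into consecutive
#' codons; a trailing partial codon is dropped.
#'
#' @param coding_columns integer vector of alignment columns in coding
#'   order.
#' @param frame_offset columns skipped before the first codon (0, 1 or 2).
#' @return `data.frame` with columns `column`, `codon`, `codon_pos`.
#' @export
makeCdsMap <- function(coding_columns, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  cols <- coding_columns[seq.int(frame_offset + 1L, length(coding_columns))]
  ncod <- length(cols) %/% 3L
  cols <- cols[seq_len(ncod * 3L)]
  data.frame(column = cols, codon = rep(seq_len(ncod), each = 3L),
             codon_pos = rep(1:3, times = ncod))
}

#' Per-exon summary of rapidly-evolving sites
#'
#' Counts, per exon, the non-baseline columns whose fold change exceeds a
#' cutoff, and compares each exon's proportion against the pooled "other"
#' exons by a two-sided Fisher exact test.  Two conventional cutoffs:
#' `threshold = 1, inclusive = TRUE` selects sites evolving at more than
#' twice the baseline rate (fold change >= 1), and `threshold = 2,
#' inclusive = FALSE` sites at more than four times baseline (fold
#' change > 2).
#'
#' @param profile a [RateProfile-class].
#' @param exon_bounds named list of length-2 integer vectors
#'   `c(start, end)` (1-based inclusive alignment columns), disjoint.
#' @param threshold fold-change cutoff.
#' @param other character vector of exon names forming the pooled "other"
#'   comparison category (e.g. exons excluding 2, 3 and, for Class I, 4);
#'   an exon belonging to the pool is compared against the pool minus
#'   itself.
#' @param inclusive if `TRUE` sites at exactly the threshold count as
#'   rapid; default `FALSE` (strictly greater).
#' @return `data.frame` with columns `exon`, `n_sites`, `n_rapid`,
#'   `proportion`, `p_vs_other`.
#' @export
exonRapidSummary <- function(profile, exon_bounds, threshold = 2,
                             other = character(), inclusive = FALSE) {
  stopifnot(is(profile, "RateProfile"), is.list(exon_bounds),
            !is.null(names(exon_bounds)), is.finite(threshold))
  fc <- profile@foldChange
  base <- profile@baselineMask
  cols <- lapply(exon_bounds, function(b) {
    b <- as.integer(b)
    stopifnot(length(b) == 2L, b[1L] <= b[2L], b[1L] >= 1L,
              b[2L] <= length(fc))
    setdiff(seq.int(b[1L], b[2L]), which(base))
  })
  all_cols <- unlist(cols, use.names = FALSE)
  if (anyDuplicated(all_cols)) stop("exon bounds must be disjoint")
  empty <- lengths(cols) == 0L
  if (any(empty)) {
    warning("excluding empty exon(s): ",
            paste(names(cols)[empty], collapse = ", "))
    cols <- cols[!empty]
  }
  unknown <- setdiff(other, names(cols))
  if (length(unknown))
    stop("unknown exon(s) in `other`: ", paste(unknown, collapse = ", "))
  rapid <- if (inclusive) fc >= threshold else fc > threshold
  n_sites <- lengths(cols)
  n_rapid <- vapply(cols, function(cc) sum(rapid[cc]), integer(1L))
  p <- rep(NA_real_, length(cols))
  for (e in seq_along(cols)) {
    pool <- setdiff(other, names(cols)[e])
    if (!length(pool)) next
    pc <- unlist(cols[pool], use.names = FALSE)
    tab <- matrix(c(n_rapid[e], n_sites[e] - n_rapid[e],
                    sum(rapid[pc]), length(pc) - sum(rapid[pc])),
                  nrow = 2L, byrow = TRUE)
    p[e] <- stats::fisher.test(tab)$p.value
  }
  data.frame(exon = names(cols), n_sites = as.integer(n_sites),
             n_rapid = as.integer(n_rapid),
             proportion = n_rapid / n_sites, p_vs_other = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress trait-association counts on per-residue rates
#'
#' Ordinary least squares of the number of significant, unique trait
#' associations per amino-acid position on that position's evolutionary
#' rate, with the usual t-test p-value for the slope.
#'
#' @param aa_rates per-position rates (fold changes).
#' @param assoc_counts per-position non-negative association counts, same
#'   length/order as `aa_rates`.
#' @return list with `slope`, `intercept`, `p_value`, `n`.
#' @export
associationRegression <- function(aa_rates, assoc_counts) {
  if (length(aa_rates) != length(assoc_counts))
    stop("aa_rates and assoc_counts must have equal length")
  ok <- stats::complete.cases(aa_rates, assoc_counts)
  x <- as.numeric(aa_rates[ok]); y <- as.numeric(assoc_counts[ok])
  if (length(x) < 3L) stop("at least 3 positions with both values required")
  if (stats::var(x) == 0) stop("undefined slope: zero-variance rates")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2L, 1L]), intercept = unname(sm[1L, 1L]),
       p_value = unname(sm[2L, 4L]), n = length(x))
}
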