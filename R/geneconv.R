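# Gene-conversion screening: a permutation-tested matching-runs statistic
# over polymorphic columns (a simplified global-inner fragment search in
# the Sawyer tradition), a direction heuristic, and per-region exclusion
# lists for downstream quartet tests.

# Columns with at least two distinct non-gap characters across the
# alignment; the runs statistic is computed on these only.
.poly_columns <- function(m) {
  which(apply(m, 2L, function(col) {
    u <- unique(col[!.is_gap(col)])
    length(u) >= 2L
  }))
}

# Best-scoring run (Kadane) for one increment vector; returns score and the
# index range attaining it (in the coordinate of v).
.best_run <- function(v) {
  best <- 0; cur <- 0; s <- 1L; bs <- 0L; be <- 0L
  for (k in seq_along(v)) {
    x <- v[k]
    if (cur + x > 0) {
      if (cur == 0) s <- k
      cur <- cur + x
    } else cur <- 0
    if (cur > best) { best <- cur; bs <- s; be <- k }
  }
  list(score = best, start = bs, end = be)
}

#' Detect candidate gene-conversion fragments
#'
#' For every pair of sequences the alignment is restricted to its
#' polymorphic columns; matching sites score +1 and mismatching sites
#' either break the run (default, `mismatch_penalty = Inf`) or subtract a
#' finite penalty.  The best observed run score per pair is compared to
#' the best scores obtained when the order of polymorphic columns is
#' permuted (`n_perms` seeded permutations shared across pairs), and the
#' permutation p-value is Bonferroni-corrected across pairs — so the
#' reported `sim_pval` is already corrected for multiple comparisons.
#' Pairs with corrected p below `alpha` are returned as fragments whose
#' bounds are mapped back to alignment columns.  Because each pair's
#' number of matches is preserved under permutation, overall relatedness
#' of a pair does not by itself produce significance: only an unusually
#' clustered run of matches does.
#'
#' @param aln alignment: character matrix, named character vector, or
#'   `XStringSet` (gaps `-` or `.`); at least 3 sequences.
#' @param n_perms number of column-order permutations (>= 100); note the
#'   smallest achievable corrected p is `n_pairs / (n_perms + 1)`.
#' @param mismatch_penalty penalty per mismatching polymorphic site;
#'   `Inf` (default) forbids mismatches within a run.
#' @param seed integer seed; identical seeds give identical output.
#' @param alpha significance level on the corrected p; default 0.05.
#' @param region optional region label stored on returned fragments.
#' @return `data.frame` with columns `seq_i`, `seq_j`, `start`, `end`
#'   (1-based inclusive alignment columns), `score`, `sim_pval`,
#'   `direction` (`"undetermined"`; see [assignDirection()]), `region`;
#'   attribute `n_pairs` records the number of pairs tested.
#' @export
detectFragments <- function(aln, n_perms = 1000L, mismatch_penalty = Inf,
                            seed = 1L, alpha = 0.05, region = NA_character_) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 3L) stop("at least 3 sequences are required")
  if (n_perms < 100L) stop("n_perms must be at least 100")
  if (!is.numeric(mismatch_penalty) || mismatch_penalty <= 0)
    stop("mismatch_penalty must be positive (possibly Inf)")
  empty <- data.frame(seq_i = character(), seq_j = character(),
                      start = integer(), end = integer(), score = numeric(),
                      sim_pval = numeric(), direction = character(),
                      region = character(), stringsAsFactors = FALSE)
  P <- .poly_columns(m)
  if (length(P) < 2L) { attr(empty, "n_pairs") <- 0L; return(empty) }
  ids <- rownames(m)
  pr <- utils::combn(nrow(m), 2L)
  npair <- ncol(pr)
  S <- length(P)
  # increment matrix: +1 match, -penalty mismatch, 0 where either is gapped
  inc <- matrix(0, nrow = S, ncol = npair)
  for (k in seq_len(npair)) {
    xi <- m[pr[1L, k], P]; xj <- m[pr[2L, k], P]
    gap <- .is_gap(xi) | .is_gap(xj)
    v <- ifelse(xi == xj, 1, -mismatch_penalty)
    v[gap] <- 0
    inc[, k] <- v
  }
  obs <- lapply(seq_len(npair), function(k) .best_run(inc[, k]))
  obs_score <- vapply(obs, `[[`, numeric(1L), "score")
  exceed <- integer(npair)
  .with_seed(seed, {
    for (b in seq_len(n_perms)) {
      ip <- inc[sample.int(S), , drop = FALSE]
      cur <- numeric(npair); best <- numeric(npair)
      for (s in seq_len(S)) {
        cur <- pmax(0, cur + ip[s, ])
        best <- pmax(best, cur)
      }
      exceed <- exceed + (best >= obs_score)
    }
  })
  p_raw <- (exceed + 1) / (n_perms + 1)
  p_corr <- pmin(1, p_raw * npair)
  hit <- which(p_corr < alpha & obs_score > 0)
  if (!length(hit)) { attr(empty, "n_pairs") <- npair; return(empty) }
  out <- do.call(rbind, lapply(hit, function(k) {
    data.frame(seq_i = ids[pr[1L, k]], seq_j = ids[pr[2L, k]],
               start = P[obs[[k]]$start], end = P[obs[[k]]$end],
               score = obs_score[k], sim_pval = p_corr[k],
               direction = "undetermined", region = region,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_pairs") <- npair
  out
}

#' Read global-inner fragments from a GENECONV-style table
#'
#' Parses a whitespace-delimited `.frags`-style file, keeping only rows of
#' type `GI` (within-alignment candidate tracts).  The expected row layout
#' is `GI  name1;name2  sim_pval  ka_pval  begin  end  ...`; additional
#' trailing columns are ignored.
#'
#' @param path file path.
#' @return fragment `data.frame` as for [detectFragments()] (with
#'   `score = NA`).
#' @export
readGeneconvOutput <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (tok[1L] != "GI") next
    if (length(tok) < 6L)
      stop(sprintf("cannot parse GENECONV row at line %d: too few fields", ln))
    pair <- strsplit(tok[2L], ";", fixed = TRUE)[[1L]]
    p <- suppressWarnings(as.numeric(tok[3L]))
    b <- suppressWarnings(as.integer(tok[5L]))
    e <- suppressWarnings(as.integer(tok[6L]))
    if (length(pair) != 2L || is.na(p) || is.na(b) || is.na(e))
      stop(sprintf("cannot parse GENECONV row at line %d", ln))
    rows[[length(rows) + 1L]] <- data.frame(
      seq_i = pair[1L], seq_j = pair[2L], start = b, end = e,
      score = NA_real_, sim_pval = p, direction = "undetermined",
      region = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(seq_i = character(), seq_j = character(),
                      start = integer(), end = integer(), score = numeric(),
                      sim_pval = numeric(), direction = character(),
                      region = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a fragment table
#'
#' Plain TSV serialization of a fragment `data.frame` (columns `seq_i`,
#' `seq_j`, `start`, `end`, `score`, `sim_pval`, `direction`, `region`);
#' `readFragmentTable` is its inverse.
#'
#' @param fragments fragment `data.frame`.
#' @param path file path.
#' @return `writeFragmentTable`: `path`, invisibly.  `readFragmentTable`:
#'   the fragment `data.frame`.
#' @export
writeFragmentTable <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentTable
#' @export
readFragmentTable <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$region <- as.character(out$region)
  out
}

# Nearest neighbour of row s over the given columns, excluding `exclude`;
# ties broken by lowest row index; NA when no comparison reaches min_sites.
.nearest_neighbor <- function(m, s, cols, exclude, min_sites) {
  others <- setdiff(seq_len(nrow(m)), c(s, exclude))
  d <- vapply(others, function(o) .p_distance(m, s, o, cols, min_sites),
              numeric(1L))
  if (all(is.na(d))) return(NA_integer_)
  others[which.min(d)]
}

#' Infer donor/acceptor direction of a conversion fragment
#'
#' Compares how each member of the pair clusters using sites inside the
#' fragment bounds versus sites outside the bounds (but within the same
#' region, e.g. exon).  Nearest neighbours are computed by p-distance
#' among all sequences other than the partner: a converted acceptor
#' carries the donor's tract, so inside the fragment its nearest
#' non-partner neighbour belongs to the donor's neighbourhood, while
#' outside it reverts to its own — its neighbourhood shifts.  The donor's
#' neighbourhood is the same inside and out.  The sequence whose
#' inside/outside neighbours differ while its partner's agree is labeled
#' the acceptor; if the rule fires for both or neither, or either side has
#' fewer than `min_sites` informative columns, the direction is
#' `undetermined`.
#'
#' @param aln alignment accepted by [detectFragments()].
#' @param fragment one fragment (single-row `data.frame` or list with
#'   `seq_i`, `seq_j`, `start`, `end`).
#' @param region_bounds length-2 integer vector of region (exon) bounds
#'   containing the fragment; defaults to the whole alignment.
#' @param min_sites minimum informative columns required on each side;
#'   default 5.
#' @return the fragment as a single-row `data.frame` with `direction` set
#'   to `"i_is_acceptor"`, `"j_is_acceptor"` or `"undetermined"`, and an
#'   attribute `reason` explaining undetermined calls.
#' @export
assignDirection <- function(aln, fragment, region_bounds = NULL,
                            min_sites = 5L) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 3L) stop("at least 3 sequences are required")
  frag <- as.data.frame(fragment, stringsAsFactors = FALSE)[1L, ]
  i <- match(frag$seq_i, rownames(m)); j <- match(frag$seq_j, rownames(m))
  if (is.na(i) || is.na(j))
    stop("fragment sequences not found in alignment: ",
         paste(c(frag$seq_i, frag$seq_j)[c(is.na(i), is.na(j))], collapse = ", "))
  if (is.null(region_bounds)) region_bounds <- c(1L, ncol(m))
  region_bounds <- as.integer(region_bounds)
  if (frag$start < region_bounds[1L] || frag$end > region_bounds[2L])
    stop("region_bounds must contain the fragment")
  region_cols <- seq.int(region_bounds[1L], region_bounds[2L])
  inside <- seq.int(frag$start, frag$end)
  outside <- setdiff(region_cols, inside)
  undetermined <- function(reason) {
    frag$direction <- "undetermined"
    attr(frag, "reason") <- reason
    frag
  }
  if (length(inside) < min_sites || length(outside) < min_sites)
    return(undetermined(sprintf(
      "fewer than %d columns on one side of the fragment", min_sites)))
  nin_i <- .nearest_neighbor(m, i, inside, j, min_sites)
  nout_i <- .nearest_neighbor(m, i, outside, j, min_sites)
  nin_j <- .nearest_neighbor(m, j, inside, i, min_sites)
  nout_j <- .nearest_neighbor(m, j, outside, i, min_sites)
  if (anyNA(c(nin_i, nout_i, nin_j, nout_j)))
    return(undetermined("insufficient informative columns for neighbour calls"))
  shift_i <- nin_i != nout_i
  shift_j <- nin_j != nout_j
  if (shift_i && !shift_j) frag$direction <- "i_is_acceptor"
  else if (shift_j && !shift_i) frag$direction <- "j_is_acceptor"
  else return(undetermined(
    if (shift_i) "neighbourhood shift for both sequences"
    else "neighbourhood shift for neither sequence"))
  attr(frag, "reason") <- ""
  frag
}

#' Direction calls for a whole fragment table
#'
#' Applies [assignDirection()] row-wise.
#'
#' @inheritParams assignDirection
#' @param fragments fragment `data.frame`.
#' @return the fragment `data.frame` with `direction` filled in.
#' @export
assignDirections <- function(aln, fragments, region_bounds = NULL,
                             min_sites = 5L) {
  if (!nrow(fragments)) return(fragments)
  out <- lapply(seq_len(nrow(fragments)), function(r)
    assignDirection(aln, fragments[r, ], region_bounds = region_bounds,
                    min_sites = min_sites))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-region exclusion lists from directed fragments
#'
#' Acceptor sequences are excluded from the quartet analyses of the
#' region they were converted in; where the direction could not be
#' determined, both members of the pair are excluded.  Adding fragments
#' never removes exclusions.
#'
#' @param fragments fragment `data.frame` with `direction` (and optionally
#'   `region`; missing regions pool under `"all"`).
#' @return named list mapping each region to a sorted character vector of
#'   excluded sequence ids.
#' @export
exclusionList <- function(fragments) {
  if (!nrow(fragments)) return(list())
  region <- fragments$region
  if (is.null(region)) region <- rep(NA_character_, nrow(fragments))
  region[is.na(region)] <- "all"
  out <- list()
  for (r in seq_len(nrow(fragments))) {
    ids <- switch(fragments$direction[r],
                  i_is_acceptor = fragments$seq_i[r],
                  j_is_acceptor = fragments$seq_j[r],
                  c(fragments$seq_i[r], fragments$seq_j[r]))
    key <- region[r]
    out[[key]] <- sort(unique(c(out[[key]], ids)))
  }
  out
}
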