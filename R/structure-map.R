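# Mapping per-codon evolutionary rates onto peptide-bound structures:
# translation, query-to-chain alignment, minimum atom-atom distances to
# the peptide, averaging over structures, and the rate~distance OLS.

#' Translate a (gapped) coding sequence
#'
#' Standard genetic code, reading from `frame_offset`.  Codons containing
#' a gap character translate to a gap residue `-`, codons with ambiguous
#' bases to `X`, and stop codons to `*`.  A trailing partial codon is
#' dropped (recorded in attribute `dropped_tail`).
#'
#' @param seq nucleotide sequence: single string, character vector of
#'   bases, or `DNAString`.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @return single amino-acid string.
#' @examples
#' translateCds("ATGGCT")   # "MA"
#' translateCds("ATG-CT")   # "M-"
#' @export
translateCds <- function(seq, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  if (inherits(seq, "XString")) seq <- as.character(seq)
  chars <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1L]] else as.character(seq)
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  chars <- chars[seq.int(frame_offset + 1L, length(chars))]
  ncod <- length(chars) %/% 3L
  code <- Biostrings::GENETIC_CODE
  aa <- vapply(seq_len(ncod), function(k) {
    cod <- chars[(3L * k - 2L):(3L * k)]
    if (any(.is_gap(cod))) return("-")
    hit <- code[paste(cod, collapse = "")]
    if (is.na(hit)) "X" else unname(hit)
  }, character(1L))
  out <- paste(aa, collapse = "")
  attr(out, "dropped_tail") <- length(chars) - 3L * ncod
  out
}

#' Align a translated query to a structure chain sequence
#'
#' Global pairwise alignment (match +1, mismatch -1, gap open -5, gap
#' extend -1 by default) between the translated query and the residue
#' sequence of a structure chain, returning a one-to-one map over aligned
#' non-gap pairs.  Gap residues (`-`) in the query are never mapped.
#' Alignment identity below 30% flags the map (attribute `low_identity`,
#' plus a warning) as a likely wrong-chain pairing.
#'
#' @param query amino-acid string (may contain `-` gap residues).
#' @param chain_seq amino-acid string of the structure chain (see
#'   [chainSequence()]).
#' @param gap_open,gap_extend positive gap penalties.
#' @return integer vector mapping query positions (names) to chain residue
#'   ordinals (values), with attributes `identity` and `low_identity`.
#' @export
alignToStructure <- function(query, chain_seq, gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(chain_seq))
  qchars <- strsplit(query, "", fixed = TRUE)[[1L]]
  keep <- !.is_gap(qchars)
  qpos <- which(keep)
  q2 <- paste(qchars[keep], collapse = "")
  letters <- sort(unique(c(strsplit(q2, "")[[1L]],
                           strsplit(chain_seq, "")[[1L]])))
  mat <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(q2), Biostrings::BString(chain_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qi <- 0L; si <- 0L
  map <- integer(0)
  matches <- 0L; aligned <- 0L
  for (k in seq_along(ap)) {
    pgap <- ap[k] == "-"; sgap <- as[k] == "-"
    if (!pgap) qi <- qi + 1L
    if (!sgap) si <- si + 1L
    if (!pgap && !sgap) {
      aligned <- aligned + 1L
      if (ap[k] == as[k]) matches <- matches + 1L
      map[as.character(qpos[qi])] <- si
    }
  }
  identity <- if (aligned) matches / aligned else 0
  attr(map, "identity") <- identity
  attr(map, "low_identity") <- identity < 0.30
  if (identity < 0.30)
    warning(sprintf("alignment identity %.1f%% below 30%%: likely wrong chain",
                    100 * identity))
  map
}

#' Read a PDB-format structure
#'
#' Thin wrapper over [bio3d::read.pdb()]; only the first model of
#' multi-model files is read.
#'
#' @param path PDB file path.
#' @return a `bio3d` `pdb` object.
#' @export
readStructure <- function(path) {
  bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
}

#' One-letter residue sequence of a structure chain
#'
#' Residues are taken in author resolution order from CA atoms of the
#' chain; unknown residue types become `X`.
#'
#' @param pdb a `bio3d` `pdb` object.
#' @param chain chain identifier.
#' @return character vector of one-letter codes, named by author residue
#'   numbers (collapse with `paste0` for [alignToStructure()]).
#' @export
chainSequence <- function(pdb, chain) {
  atom <- pdb$atom
  sel <- atom$chain == chain & atom$elety == "CA" & atom$type == "ATOM"
  if (!any(sel)) stop("no CA atoms found for chain ", chain)
  sub <- atom[sel, , drop = FALSE]
  sub <- sub[!duplicated(sub$resno), , drop = FALSE]
  aa <- bio3d::aa321(sub$resid)
  aa[is.na(aa) | aa == ""] <- "X"
  stats::setNames(aa, sub$resno)
}

# Atom table after the shared coordinate-file conventions: waters dropped
# everywhere, heteroatoms dropped except on the peptide chain, alternate
# locations resolved by highest occupancy then altloc A/blank.
.filtered_atoms <- function(pdb, mhc_chains, peptide_chain) {
  atom <- pdb$atom
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  keep_mhc <- atom$chain %in% mhc_chains & atom$type == "ATOM"
  keep_pep <- atom$chain == peptide_chain
  atom <- atom[keep_mhc | keep_pep, , drop = FALSE]
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  pref <- ifelse(alt %in% c("", "A"), 0L, 1L)
  atom <- atom[order(-occ, pref), , drop = FALSE]
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  atom <- atom[!duplicated(key), , drop = FALSE]
  atom[order(atom$chain, atom$resno), , drop = FALSE]
}

#' Minimum atom-atom distance from each residue to the bound peptide
#'
#' For every residue of the named MHC chains, the minimum Euclidean
#' distance over all pairs of (residue atom, peptide-chain atom), using
#' all deposited atoms.  Waters are excluded; heteroatoms are excluded
#' except on the declared peptide chain; alternate locations are resolved
#' by highest occupancy then altloc `A`.
#'
#' @param pdb a `bio3d` `pdb` object (see [readStructure()]).
#' @param mhc_chains chain id(s) of the MHC molecule.
#' @param peptide_chain chain id of the bound peptide (must be nonempty).
#' @return `data.frame` with columns `chain`, `resno`, `resid`,
#'   `min_dist` (Angstrom).
#' @export
minDistanceToPeptide <- function(pdb, mhc_chains, peptide_chain) {
  atom <- .filtered_atoms(pdb, mhc_chains, peptide_chain)
  pep <- atom[atom$chain == peptide_chain, , drop = FALSE]
  mhc <- atom[atom$chain %in% mhc_chains & atom$chain != peptide_chain, ,
              drop = FALSE]
  if (!nrow(pep)) stop("peptide chain ", peptide_chain, " is empty")
  if (!nrow(mhc)) stop("no atoms found for MHC chain(s) ",
                       paste(mhc_chains, collapse = ","))
  A <- as.matrix(mhc[, c("x", "y", "z")])
  B <- as.matrix(pep[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0  # numerical guard
  amin <- sqrt(apply(d2, 1L, min))
  key <- paste(mhc$chain, mhc$resno, sep = "|")
  res_min <- tapply(amin, key, min)
  first <- !duplicated(key)
  out <- data.frame(chain = mhc$chain[first], resno = mhc$resno[first],
                    resid = mhc$resid[first],
                    min_dist = as.numeric(res_min[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Average per-position peptide distances over structures
#'
#' Arithmetic mean, per alignment position, of the minimum peptide
#' distances from several structures; positions unresolved in a structure
#' simply do not contribute there, and positions resolved in no structure
#' are omitted.  The result is invariant to the order of structures.
#'
#' @param distances_by_position list (one entry per structure) of numeric
#'   vectors named by alignment position, e.g. built by composing
#'   [minDistanceToPeptide()] with an [alignToStructure()] map.
#' @return `data.frame` with columns `position`, `min_dist` (mean
#'   Angstrom), `n_structures`.
#' @export
averageDistances <- function(distances_by_position) {
  stopifnot(is.list(distances_by_position), length(distances_by_position) >= 1L)
  positions <- sort(unique(as.integer(unlist(lapply(distances_by_position,
                                                    names)))))
  if (!length(positions)) stop("no mapped positions in any structure")
  vals <- vapply(positions, function(p) {
    v <- vapply(distances_by_position, function(d) {
      x <- d[as.character(p)]
      if (length(x)) unname(x) else NA_real_
    }, numeric(1L))
    v <- v[!is.na(v)]
    c(mean(v), length(v))
  }, numeric(2L))
  data.frame(position = positions, min_dist = vals[1L, ],
             n_structures = as.integer(vals[2L, ]))
}

#' Map one structure's peptide distances into alignment coordinates
#'
#' Convenience composition: given a residue-level distance table from
#' [minDistanceToPeptide()] (restricted to one chain) and an
#' [alignToStructure()] position map for that chain, returns the
#' per-alignment-position distances used by [averageDistances()].
#'
#' @param dists `data.frame` from [minDistanceToPeptide()].
#' @param map position map from [alignToStructure()].
#' @param chain chain the map refers to.
#' @return numeric vector of distances named by alignment position.
#' @export
mapDistances <- function(dists, map, chain) {
  d <- dists[dists$chain == chain, , drop = FALSE]
  res_d <- stats::setNames(d$min_dist, seq_len(nrow(d)))
  out <- res_d[as.character(map)]
  names(out) <- names(map)
  out[!is.na(out)]
}

#' Regression of evolutionary rate on peptide distance
#'
#' Ordinary least squares of per-residue rate on mean minimum distance to
#' the peptide, with the t-test p-value for the slope.  Rapid evolution
#' concentrated in the peptide-binding groove shows up as a significantly
#' negative slope.
#'
#' @param map `data.frame` with columns `rate` and `min_dist` (e.g. a
#'   residue-rate map built from [codonRates()] and
#'   [averageDistances()]).
#' @return list with `slope` (rate per Angstrom), `intercept`, `p_value`,
#'   `n`.
#' @export
rateDistanceRegression <- function(map) {
  stopifnot(all(c("rate", "min_dist") %in% names(map)))
  ok <- stats::complete.cases(map$rate, map$min_dist)
  x <- map$min_dist[ok]; y <- map$rate[ok]
  if (length(x) < 3L) stop("at least 3 residues required")
  if (stats::var(x) == 0) stop("undefined slope: zero-variance distances")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2L, 1L]), intercept = unname(sm[1L, 1L]),
       p_value = unname(sm[2L, 4L]), n = length(x))
}
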