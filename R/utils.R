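# Shared internal helpers.

.GAP_CHARS <- c("-", ".")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Coerce the accepted alignment representations to an upper-case character
# matrix with one row per sequence.  Accepts a character matrix, a named
# character vector of equal-length strings, or any XStringSet /
# MultipleAlignment with equal widths.
.aln_matrix <- function(aln) {
  if (inherits(aln, "MultipleAlignment"))
    aln <- Biostrings::unmasked(aln)
  if (inherits(aln, "XStringSet")) {
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L)
      stop("alignment sequences must all have the same width")
    m <- t(vapply(as.character(aln),
                  function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(w[1L])))
    rownames(m) <- names(aln)
    aln <- m
  } else if (is.character(aln) && !is.matrix(aln)) {
    nc <- nchar(aln)
    if (length(unique(nc)) != 1L)
      stop("alignment sequences must all have the same width")
    m <- t(vapply(aln, function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(nc[1L])))
    rownames(m) <- names(aln)
    aln <- m
  }
  if (!is.matrix(aln) || !is.character(aln))
    stop("unsupported alignment representation")
  if (is.null(rownames(aln)))
    rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
  toupper(aln)
}

.is_gap <- function(x) x %in% .GAP_CHARS

# Uncorrected p-distance between two aligned rows over the given columns;
# returns NA when fewer than min_sites columns are non-gap in both.
.p_distance <- function(m, i, j, cols, min_sites = 1L) {
  xi <- m[i, cols]
  xj <- m[j, cols]
  ok <- !.is_gap(xi) & !.is_gap(xj)
  if (sum(ok) < min_sites) return(NA_real_)
  mean(xi[ok] != xj[ok])
}

# Condition constructor for the "not enough alleles" signal rendered as a
# blank cell in Bayes-factor tables.
.not_enough_alleles <- function(msg) {
  structure(class = c("tspscan_not_enough_alleles", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
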