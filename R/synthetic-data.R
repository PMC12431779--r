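# Synthetic-data generators: posterior tree sets under species-monophyly
# vs. trans-species genealogies, alignments with planted rate classes and
# conversion tracts, rate posteriors, and toy peptide-groove structures.
# Every generator is seed-deterministic and returns the ground truth
# needed to score recovery in the analysis modules.

.default_species_tree <- function() {
  ape::read.tree(text = "((((Homo:1,Patr:1):1,Gogo:2):1,Popy:3):1,Mamu:4);")
}

# Random within-species allele clade scaled to the given height; NULL for
# a single allele (the species tip is renamed instead).
.allele_clade <- function(labels, height) {
  if (length(labels) == 1L) return(NULL)
  cl <- ape::rcoal(length(labels), tip.label = labels)
  depth <- max(ape::node.depth.edgelength(cl))
  cl$edge.length <- cl$edge.length * (height / depth)
  cl
}

# Replace each tip of `backbone` named in `alleles` by a clade of the
# corresponding allele labels (or rename it, for a single allele).
# Species without alleles are dropped.
.graft_alleles <- function(backbone, alleles, clade_height) {
  keep <- names(alleles)[lengths(alleles) > 0L]
  drop <- setdiff(backbone$tip.label, keep)
  if (length(drop)) {
    if (length(keep) == 1L) {
      # degenerate backbone: single species left
      cl <- .allele_clade(alleles[[keep]], clade_height)
      if (is.null(cl)) {
        backbone <- ape::keep.tip(backbone, keep)
        backbone$tip.label <- alleles[[keep]]
        return(backbone)
      }
      return(cl)
    }
    backbone <- ape::drop.tip(backbone, drop)
  }
  for (sp in keep) {
    labs <- alleles[[sp]]
    cl <- .allele_clade(labs, clade_height)
    at <- which(backbone$tip.label == sp)
    if (is.null(cl)) {
      backbone$tip.label[at] <- labs
    } else {
      backbone <- ape::bind.tree(backbone, cl, where = at)
    }
  }
  backbone
}

#' Simulate a posterior sample of allele genealogies
#'
#' Emulates the output of a Bayesian tree sampler under the two
#' genealogical hypotheses behind the quartet test.  Under
#' `"monophyly"`, allele gene trees follow the species tree with
#' within-species coalescence only, so each species' alleles are
#' monophyletic.  Under `"tsp"`, alleles are first assigned (round-robin
#' within species) to `n_lineages` ancient allelic lineages whose splits
#' predate all species splits, producing lineage-major, species-minor
#' clades — the signature of trans-species polymorphism.  Topology
#' sampling noise is emulated by perturbing each emitted tree with one
#' random nearest-neighbor-interchange move with probability `epsilon`.
#' Emitted genealogies are unrooted, matching how the quartet test reads
#' them.
#'
#' @param scenario `"monophyly"` or `"tsp"`.
#' @param species_tree `phylo` with branch lengths (split times, arbitrary
#'   units); defaults to a five-species primate-like ladder
#'   (Homo, Patr, Gogo, Popy, Mamu).
#' @param n_alleles_per_species single count or named vector over species
#'   tips; default 6.
#' @param n_lineages number of ancient lineages (tsp only, >= 2).
#' @param epsilon per-tree perturbation probability in `[0, 0.5)`.
#' @param n_trees number of trees to emit.
#' @param seed integer seed; identical configuration and seed give
#'   identical output.
#' @return list with `sample` (a [TreeSample-class]), `truth`
#'   (`data.frame` of `tip`, `species`, `lineage`; lineage is NA under
#'   monophyly) and `perturbed` (logical per tree).
#' @export
simulatePosteriorSample <- function(scenario = c("monophyly", "tsp"),
                                    species_tree = NULL,
                                    n_alleles_per_species = 6L,
                                    n_lineages = 2L, epsilon = 0,
                                    n_trees = 200L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(species_tree)) species_tree <- .default_species_tree()
  stopifnot(inherits(species_tree, "phylo"))
  if (epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must lie in [0, 0.5): larger noise would swamp the signal")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  sp <- species_tree$tip.label
  if (length(n_alleles_per_species) == 1L && is.null(names(n_alleles_per_species)))
    n_alleles_per_species <- stats::setNames(rep(as.integer(n_alleles_per_species),
                                                 length(sp)), sp)
  if (!setequal(names(n_alleles_per_species), sp))
    stop("n_alleles_per_species must be named by the species-tree tips")
  if (any(n_alleles_per_species < 1L)) stop("all allele counts must be >= 1")
  if (scenario == "tsp" && n_lineages < 2L)
    stop("the tsp scenario needs n_lineages >= 2")
  sp_depth <- max(ape::node.depth.edgelength(species_tree))
  clade_height <- 0.2 * min(species_tree$edge.length[
    species_tree$edge[, 2L] <= length(sp)])
  alleles <- lapply(sp, function(s)
    sprintf("%s_a%02d", s, seq_len(n_alleles_per_species[[s]])))
  names(alleles) <- sp
  .with_seed(seed, {
    if (scenario == "monophyly") {
      base <- .graft_alleles(species_tree, alleles, clade_height)
      lineage <- rep(NA_integer_, sum(lengths(alleles)))
    } else {
      assign_l <- lapply(alleles, function(a)
        ((seq_along(a) - 1L) %% n_lineages) + 1L)
      spine <- ape::rcoal(n_lineages,
                          tip.label = sprintf("LIN%d", seq_len(n_lineages)))
      spine$edge.length <- spine$edge.length *
        ((2 * sp_depth + 1) / max(ape::node.depth.edgelength(spine)))
      base <- spine
      for (l in seq_len(n_lineages)) {
        sub_alleles <- lapply(sp, function(s) alleles[[s]][assign_l[[s]] == l])
        names(sub_alleles) <- sp
        sub <- .graft_alleles(species_tree, sub_alleles, clade_height)
        base <- ape::bind.tree(base, sub,
                               where = which(base$tip.label == sprintf("LIN%d", l)))
      }
      lineage <- unlist(lapply(sp, function(s) assign_l[[s]]), use.names = FALSE)
    }
    if (is.null(base$edge.length)) base <- ape::compute.brlen(base)
    base$edge.length[base$edge.length <= 0] <- 1e-8
    # emitted genealogies are unrooted, matching how the quartet test reads
    # them; this also makes every NNI move a genuine topology change
    base <- ape::unroot(base)
    perturbed <- stats::runif(n_trees) < epsilon
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      if (perturbed[i]) {
        t <- phangorn::rNNI(base, moves = 1L)
        if (is.null(t$edge.length)) t <- ape::compute.brlen(t)
        trees[[i]] <- t
      } else trees[[i]] <- base
    }
  })
  truth <- data.frame(tip = unlist(alleles, use.names = FALSE),
                      species = rep(sp, lengths(alleles)),
                      lineage = lineage, stringsAsFactors = FALSE)
  list(sample = TreeSample(.as_multiPhylo(trees), replicate_id = "sim1"),
       truth = truth, perturbed = perturbed)
}

#' Simulate a gapped alignment with planted rate classes
#'
#' Sequences are evolved down the tree under a simple reversible
#' equal-frequency substitution model, with per-column rate multipliers
#' taken from `site_classes` (rate 1 elsewhere).  Columns listed in
#' `gappy_columns` are overwritten with gaps in the designated backbone
#' rows, emulating the mostly-gap baseline columns used for rate
#' normalization.  The true per-column rates are returned.
#'
#' @param tree `phylo` with branch lengths in expected substitutions per
#'   site at rate 1 (Grafen lengths are assigned when absent).
#' @param n_columns alignment width.
#' @param site_classes optional `data.frame` with columns `start`, `end`,
#'   `rate` (disjoint 1-based inclusive intervals; rates > 0).
#' @param gappy_columns columns gapped in all backbone rows.
#' @param backbone_ids rows receiving the gaps (required when
#'   `gappy_columns` is nonempty).
#' @param seed integer seed.
#' @return list with `alignment` (character matrix, rows = tips), `rates`
#'   (true per-column multipliers), `gappy_columns`, `backbone_ids`.
#' @export
simulateAlignment <- function(tree, n_columns = 300L, site_classes = NULL,
                              gappy_columns = integer(),
                              backbone_ids = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_columns >= 1L)
  if (is.null(tree$edge.length)) tree <- ape::compute.brlen(tree)
  rates <- rep(1, n_columns)
  if (!is.null(site_classes)) {
    stopifnot(is.data.frame(site_classes),
              all(c("start", "end", "rate") %in% names(site_classes)))
    covered <- integer(0)
    for (r in seq_len(nrow(site_classes))) {
      s <- site_classes$start[r]; e <- site_classes$end[r]
      if (s < 1L || e > n_columns || s > e)
        stop("site class interval out of range: ", s, "-", e)
      idx <- seq.int(s, e)
      if (any(idx %in% covered)) stop("site class intervals must be disjoint")
      if (site_classes$rate[r] <= 0) stop("rate multipliers must be > 0")
      covered <- c(covered, idx)
      rates[idx] <- site_classes$rate[r]
    }
  }
  gappy_columns <- as.integer(gappy_columns)
  if (length(gappy_columns)) {
    if (is.null(backbone_ids))
      stop("backbone_ids are required when gappy_columns are requested")
    if (any(gappy_columns < 1L | gappy_columns > n_columns))
      stop("gappy_columns out of range")
    missing <- setdiff(backbone_ids, tree$tip.label)
    if (length(missing))
      stop("backbone id(s) not in tree: ", paste(missing, collapse = ", "))
  }
  M <- matrix("", nrow = length(tree$tip.label), ncol = n_columns,
              dimnames = list(tree$tip.label, NULL))
  .with_seed(seed, {
    for (r in unique(rates)) {
      cols <- which(rates == r)
      sim <- phangorn::simSeq(tree, l = length(cols), type = "DNA", rate = r)
      m <- toupper(as.character(sim))
      M[rownames(m), cols] <- m
    }
  })
  if (length(gappy_columns)) M[backbone_ids, gappy_columns] <- "-"
  list(alignment = M, rates = rates, gappy_columns = gappy_columns,
       backbone_ids = backbone_ids)
}

#' Plant a gene-conversion tract
#'
#' Overwrites the acceptor's columns in `[start, end]` with the donor's,
#' emulating the unidirectional transfer of a DNA tract from donor to
#' acceptor.  The operation is deterministic.
#'
#' @param aln alignment accepted by [detectFragments()].
#' @param donor,acceptor sequence ids.
#' @param start,end 1-based inclusive tract bounds.
#' @return list with `alignment` (character matrix) and `truth`
#'   (`donor`, `acceptor`, `start`, `end`).
#' @export
injectGeneConversion <- function(aln, donor, acceptor, start, end) {
  m <- .aln_matrix(aln)
  missing <- setdiff(c(donor, acceptor), rownames(m))
  if (length(missing))
    stop("sequence id(s) not in alignment: ", paste(missing, collapse = ", "))
  if (start < 1L || end > ncol(m) || start > end)
    stop("tract bounds must satisfy 1 <= start <= end <= alignment length")
  m[acceptor, start:end] <- m[donor, start:end]
  list(alignment = m,
       truth = list(donor = donor, acceptor = acceptor,
                    start = as.integer(start), end = as.integer(end)))
}

#' Simulate a per-site rate posterior
#'
#' Each sampled state's rate at a column is the true rate times an
#' independent lognormal deviate `exp(N(0, noise_sigma^2))`.  Note the
#' lognormal mean is `exp(noise_sigma^2 / 2)`, so posterior means converge
#' to `truth * exp(noise_sigma^2 / 2)`; the common factor cancels in fold
#' changes.
#'
#' @param true_rates positive per-column rates.
#' @param n_states number of sampled states.
#' @param noise_sigma lognormal sigma (>= 0).
#' @param seed integer seed.
#' @return numeric matrix, states x columns.
#' @export
simulateRatePosterior <- function(true_rates, n_states = 1000L,
                                  noise_sigma = 0.2, seed = 1L) {
  true_rates <- as.numeric(true_rates)
  if (any(true_rates <= 0)) stop("true rates must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  L <- length(true_rates)
  .with_seed(seed, {
    noise <- exp(stats::rnorm(n_states * L, 0, noise_sigma))
  })
  m <- matrix(rep(true_rates, each = n_states) * noise, nrow = n_states)
  colnames(m) <- if (!is.null(names(true_rates))) names(true_rates)
                 else seq_len(L)
  m
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Generate a toy peptide-groove structure
#'
#' Writes a minimal PDB-format structure with a one-atom-per-residue MHC
#' chain `A` and a straight peptide chain `C`.  Residues listed in
#' `groove_positions` are seated under 4 Angstrom from the peptide; all
#' other residues sit over 8 Angstrom away.  The file parses under
#' [readStructure()] with the chain roles intact, and the planted
#' geometry supports end-to-end tests of the rate-versus-distance
#' regression.
#'
#' @param n_residues number of MHC-chain residues.
#' @param peptide_length number of peptide residues.
#' @param groove_positions residue numbers (subset of `1:n_residues`)
#'   placed in the groove.
#' @param seed integer seed (residue types and small coordinate jitter).
#' @param path optional output file; when given, the PDB text is written
#'   there.
#' @return list with `lines` (PDB text), `truth` (`groove_positions`,
#'   `mhc_chain`, `peptide_chain`) and `path` (NULL unless written).
#' @export
synthStructure <- function(n_residues = 150L, peptide_length = 9L,
                           groove_positions = integer(), seed = 1L,
                           path = NULL) {
  stopifnot(n_residues >= 1L, peptide_length >= 1L)
  groove_positions <- as.integer(groove_positions)
  if (length(setdiff(groove_positions, seq_len(n_residues))))
    stop("groove_positions must be a subset of 1:n_residues")
  spacing <- 3.8
  pep_x <- spacing * seq_len(peptide_length)
  .with_seed(seed, {
    res3 <- sample(.AA3, n_residues, replace = TRUE)
    pep3 <- sample(.AA3, peptide_length, replace = TRUE)
    jitter_y <- stats::runif(n_residues, -0.3, 0.3)
  })
  mhc_x <- if (n_residues == 1L) mean(pep_x) else
    seq(min(pep_x), max(pep_x), length.out = n_residues)
  mhc_z <- ifelse(seq_len(n_residues) %in% groove_positions, 2.5, 10)
  fmt <- function(serial, resname, chain, resno, x, y, z)
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, resname, chain, resno, x, y, z, 1, 0, "C")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, res3[i], "A", i, mhc_x[i], jitter_y[i],
                          mhc_z[i]))
  }
  lines <- c(lines, "TER")
  for (i in seq_len(peptide_length)) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, pep3[i], "C", i, pep_x[i], 0, 0))
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  list(lines = lines,
       truth = list(groove_positions = groove_positions, mhc_chain = "A",
                    peptide_chain = "C"),
       path = path)
}
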