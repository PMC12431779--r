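# Independent oracles and fixture builders used across the suite.

# Brute-force quartet classification by scanning every clade of the tree:
# the quartet is resolved iff some clade contains exactly two of its tips,
# and the identity of that pair decides monophyly.  Independent of both
# the pruning and the four-point implementation paths.
brute_quartet <- function(tree, quartet) {
  ntip <- length(tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  qidx <- match(quartet, tree$tip.label)
  stopifnot(!anyNA(qidx))
  for (d in desc) {
    inside <- quartet[qidx %in% d]
    if (length(inside) == 2L) {
      if (setequal(inside, quartet[1:2]) || setequal(inside, quartet[3:4]))
        return("monophyletic")
      return("nonmonophyletic")
    }
  }
  "uninformative"
}

# All-pairs brute-force minimum residue-to-peptide distance, straight from
# the filtered atom table.
brute_min_dist <- function(pdb, mhc_chain, peptide_chain) {
  atom <- pdb$atom
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD")), ]
  pep <- atom[atom$chain == peptide_chain, ]
  mhc <- atom[atom$chain == mhc_chain & atom$type == "ATOM", ]
  out <- numeric(0)
  for (r in unique(mhc$resno)) {
    ra <- mhc[mhc$resno == r, c("x", "y", "z")]
    best <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(pep))) {
      d <- sqrt(sum((as.numeric(ra[i, ]) -
                     as.numeric(pep[j, c("x", "y", "z")]))^2))
      if (d < best) best <- d
    }
    out[as.character(r)] <- best
  }
  out
}

# Eight-sequence background tree for gene-conversion fixtures: donor D has
# sister Ds, acceptor A has sister As, plus two unrelated pairs.
geneconv_tree <- function() {
  ape::read.tree(text = paste0(
    "(((D:0.05,Ds:0.05):0.3,(X1:0.05,X2:0.05):0.3):0.1,",
    "((A:0.05,As:0.05):0.3,(Y1:0.05,Y2:0.05):0.3):0.1);"))
}

# Alignment with a planted donor->acceptor conversion tract.
converted_alignment <- function(seed, n_columns = 240L, tract = c(101L, 160L)) {
  sim <- simulateAlignment(geneconv_tree(), n_columns = n_columns, seed = seed)
  injectGeneConversion(sim$alignment, "D", "A", tract[1L], tract[2L])
}

# Newick strings for the three labeled unrooted resolutions of four tips.
quartet_resolutions <- function() {
  c("((a1,a2),(b1,b2));", "((a1,b1),(a2,b2));", "((a1,b2),(a2,b1));")
}

# A tiny TreeSample built from newick strings.
sample_from_newick <- function(texts, replicate_id = "r1") {
  trees <- lapply(texts, function(s) ape::read.tree(text = s))
  TreeSample(trees, replicate_id = replicate_id)
}
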