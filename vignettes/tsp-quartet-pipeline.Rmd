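---
title: "Detecting trans-species polymorphism with quartet Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trans-species polymorphism with quartet Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspscan)
```

## The problem

Classical MHC genes are under long-lived balancing selection: allelic
lineages can be older than the species carrying them, so that a human
allele may coalesce with a chimpanzee or macaque allele more recently
than with another human allele.  This *trans-species polymorphism* (TSP)
leaves a characteristic signature in allele genealogies — alleles group
by lineage rather than by species.  `tspscan` implements a pipeline for
quantifying evidence of TSP from posterior samples of allele phylogenies
(as produced by Bayesian samplers such as BEAST2), for guarding that
inference against gene conversion, and for relating per-site
evolutionary rates to peptide-binding function on protein structures.

## The quartet Bayes factor

Full-tree model testing is impractical on samples where every posterior
tree is unique, so the test is performed on quartets: two alleles from a
focal taxon A and two from a comparison taxon B (the B pair may span two
species of a clade, e.g. one baboon and one macaque allele).  For a tree
sample $D$ and the hypothesis $H$ that the focal pair is monophyletic in
the induced unrooted quartet (against its complement $H^c$),

$$K \;=\; \frac{\Pr(H^c \mid D)}{\Pr(H \mid D)} \cdot \frac{1}{2},$$

where the posterior odds are estimated by the fraction of sampled trees
in which the focal pair is non-monophyletic over the fraction in which
it is monophyletic, and $1/2$ is the prior odds in favor of monophyly:
of the three labeled unrooted resolutions of four tips, exactly one
separates the focal pair from the comparison pair.  `quartetTopology()`
classifies a tree by the four-point condition on unit-branch-length path
distances, which is exact for the induced quartet topology; trees whose
induced quartet is a star are *uninformative* and are excluded from both
counts (posterior samples from binary-tree samplers never contain them;
the rule matters only for synthetic edge cases).

If either topology count is zero, its probability is set to
$p = 1/(n+1)$ — $n$ the number of informative trees — and the
complement's to $1-p$, and the result is flagged: with zero monophyletic
trees the reported $K$ is a lower bound (at $n = 14{,}000$, $K = 7{,}000$).
Following the usual evidence scale, $K > 100$ is decisive support for
TSP and $K < 1$ is evidence against it; the threshold is used only for
rendering, never inside a computation.

Because any quartet with compelling evidence is of interest, the
reported statistic for a pair of taxon groups is the *maximum* $K$ over
enumerated quartets (`maxBayesFactor()`, `bfMatrix()`).  Enumeration is
exhaustive up to a cap (default 10,000) with seeded uniform subsampling
beyond it, and ties are broken by lowest index so that every run is
deterministic.  Note the maximum over many quartets is deliberately an
existence statistic: it is not corrected for the number of quartets, and
under monophyly it stays far below 1 because every quartet is then
concordantly monophyletic.

### Sample processing

`readTreeSamples()` reads BEAST-style Nexus (translate block honored) or
plain Newick, requiring a shared tip set; `applyBurnin()` removes the
first `floor(f * n)` trees (default `f = 0.10`, mirroring the common
practice of discarding the initial 10% of states — configurable because
short runs sometimes keep an absolute state cut instead);
`combineReplicates()` concatenates replicates after per-replicate
burn-in.  `essValue()` implements the autocorrelation-time effective
sample size with initial-positive-sequence truncation, the usual gate
being ESS $\ge$ 100; a constant trace reports ESS equal to its length by
convention.  `mccTree()` summarizes a sample as the member tree
maximizing the product of posterior clade frequencies; rooted clades are
counted when every tree is rooted, otherwise all trees are rooted at the
canonical (alphabetically first) tip so that counts correspond to
unrooted bipartitions.  Node heights are passed through unmodified —
nothing downstream consumes them.

## Gene conversion

Gene conversion copies a DNA tract from a donor into an acceptor allele,
which can make the acceptor cluster with the donor's family and mimic
TSP.  `detectFragments()` screens every sequence pair with a
matching-runs statistic over the alignment's polymorphic columns:
matches score +1 and a mismatch ends the run (default; a finite
`mismatch_penalty` turns the search into a Kadane scan).  Significance
is assessed by permuting the *order* of polymorphic columns — which
preserves each pair's match total, so overall relatedness alone cannot
produce a signal — and the permutation p-value is Bonferroni-corrected
across pairs; the reported `sim_pval` is therefore already corrected,
and the smallest achievable value is `n_pairs / (n_perms + 1)` (use
enough permutations for your pair count).  All sites are used rather
than silent sites only, which can slightly overestimate tract lengths
but not presence.  A reader for GENECONV-style `GI` fragment tables
(`readGeneconvOutput()`) supports interop with the external tool.

Direction is an educated guess with no formal standard, and the naive
rule "the acceptor's nearest neighbour inside the fragment is its
partner" degenerates on real conversion tracts: inside the tract the two
sequences are near-identical, so each is the other's nearest neighbour
and the rule fires for both.  `assignDirection()` therefore excludes the
partner when computing nearest neighbours (by p-distance, minimum 5
informative columns per side): the acceptor is the sequence whose
nearest non-partner neighbour *inside* the fragment differs from its
nearest neighbour *outside* (within the same exon), while the donor
keeps the same neighbourhood on both sides.  If the rule fires for both
sequences or for neither, the direction is undetermined.  Per the
exclusion policy, acceptors are excluded from the quartet analyses of
the affected region, and undetermined pairs are excluded wholesale
(`exclusionList()`); exclusions are monotone in the fragment set.  A
tree-based placement test would be a reasonable alternative direction
rule; it is noted but not implemented.

## Site rates and the gappy baseline

Samplers that partition sites and estimate a rate multiplier per
partition yield a posterior sample of relative rates per alignment
column.  `meanSiteRates()` averages over states first;
`foldChanges()` then normalizes by the mean rate over *gappy baseline*
columns — columns gapped in all designated backbone alleles, which are
shared across the alignments of a gene family and carry little signal —
and reports base-2 log fold changes.  Mean-then-log is the implemented
order (the posterior mean rate is the quantity being normalized).  Fold
changes are invariant to global rescaling of the rates, and the mean of
$2^{\mathrm{fold\ change}}$ over baseline columns is exactly 1 by
construction.  Two conventional cutoffs are exposed: fold change
$\ge 1$ ("more than twice baseline") and fold change $> 2$ ("more than
four times baseline").

`exonRapidSummary()` tallies rapid sites per exon and compares each exon
against the pooled "other" exons (for Class I genes, exons excluding 2,
3 and 4) with a two-sided Fisher exact test — chosen because it is exact
at these counts; the source analyses report significance without naming
a test, so this is this package's own choice.  `codonRates()` averages
the three member columns of each codon, emitting codons that touch a gap
or unmapped column as missing.  `associationRegression()` is the simple
OLS of per-position trait-association counts on per-position rate.

## Structures

`translateCds()` translates gapped coding sequence (gap codons become
gap residues, ambiguity gives `X`, stops `*`);
`alignToStructure()` produces a query-to-chain residue map by global
pairwise alignment (match +1, mismatch -1, gap open -5, extend -1) and
flags maps under 30% identity as likely wrong-chain pairings.
`minDistanceToPeptide()` takes, per MHC-chain residue, the minimum
Euclidean distance over all (residue atom, peptide atom) pairs, using
every deposited atom; waters are excluded, heteroatoms are excluded
except on the declared peptide chain, alternate locations resolve by
highest occupancy then altloc `A`, and only the first model of
multi-model files is used.  `averageDistances()` averages per position
over structures, recording coverage, and `rateDistanceRegression()` fits
rate on distance by OLS — rapid evolution concentrated in the
peptide-binding groove appears as a significantly negative slope.

## What the synthetic data emulate — and what they do not

`simulatePosteriorSample()` generates the two genealogical hypotheses
directly: under *monophyly*, allele trees follow a five-species
primate-like ladder with within-species coalescence only; under *tsp*,
alleles are assigned round-robin to `n_lineages` ancient lineages whose
splits predate every species split, giving lineage-major clades.
Sampling noise is one random NNI move per tree with probability
`epsilon` — topology noise only, because the Bayes factor consumes
topology only.  Defaults (5 species x 6 alleles, 200–1,000 trees,
epsilon up to a few percent) are desk-scale by design.
`simulateAlignment()` evolves sequences under a simple reversible
equal-frequency model with planted per-column rate multipliers
(model richness is irrelevant downstream, where only rate ratios and
topology matter); `simulateRatePosterior()` multiplies true rates by
lognormal noise (posterior means converge to
$r\,e^{\sigma^2/2}$ — the common factor cancels in fold changes);
`synthStructure()` writes a one-atom-per-residue PDB with groove
residues seated under 4 Å from a straight peptide and all others beyond
8 Å.  All generators are seed-deterministic.

These generators reproduce the *statistical structure* the pipeline
assumes, not real MHC data: there is no recombination within trees, no
rate variation among branches, no indel process beyond planted gap
columns, no coalescent-exact branch lengths, and no realistic sequence
composition.  Passing recovery tests therefore demonstrates correctness
of the inference chain under its own assumptions — not robustness to
everything real posteriors contain.

## Numerical conventions and test scales

Tie-breaks are by lowest index everywhere (MCC trees, maximizing
quartets, nearest neighbours).  Fragment coordinates are 1-based
inclusive alignment columns.  Gap characters are `-` and `.`.  The
prior-odds factor is exposed but fixed at 1/2 by default.  The test
suite exercises calibration at sizes a laptop handles comfortably: 500
trees x 50 seeded replicates for the Bayes-factor calibration (maximum
K below 1 under monophyly and above 100 under two-lineage TSP), 1,000
random six-tip trees against a brute-force bipartition oracle, 1,000
posterior states for rate recovery (planted multipliers 0.5/1/4
recovered within ±0.15 on the log2 scale), 60-column conversion tracts
over 50 replicates with 1,000 permutations, and 150-residue synthetic
structures for the distance regression.

## Worked example

```{r example}
sim <- simulatePosteriorSample("tsp", n_lineages = 2, epsilon = 0.02,
                               n_trees = 500, seed = 42)
taxa <- taxonTable(sim$sample)
maxBayesFactor(sim$sample,
               taxa$raw[taxa$species_code == "Homo"],
               taxa$raw[taxa$species_code == "Mamu"])
```

The two human alleles never form a clade in any of the 500 sampled
trees for the best quartet, so the Bayes factor is the regularized lower
bound $\frac{500/501}{1/501}\cdot\frac12 = 250$ and is printed with a
`>` prefix.

## Known limitations

The pipeline consumes posterior samples; it does not run MCMC, assess
convergence beyond scalar ESS, or date TSP in absolute time.  The
gene-conversion detector is a simplified within-alignment (global inner)
screen, not a full GENECONV reimplementation, and cannot see conversion
from outside the alignment.  The maximum-over-quartets statistic is not
corrected across cells of a comparison table.  Structure mapping assumes
the deposited (mostly human) structures represent the fold of all mapped
alleles.
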