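test_that("monophyly genealogies keep every species' alleles monophyletic", {
  sim <- simulatePosteriorSample("monophyly", n_trees = 30, epsilon = 0,
                                 seed = 71)
  x <- sim$sample
  taxa <- taxonTable(x)
  combos <- utils::combn(c("Homo", "Patr", "Mamu"), 2)
  for (k in seq_len(ncol(combos))) {
    a <- taxa$raw[taxa$species_code == combos[1, k]][1:2]
    b <- taxa$raw[taxa$species_code == combos[2, k]][1:2]
    cnt <- countTopologies(x, c(a, b))
    expect_equal(nMono(cnt), 30L)
  }
})

test_that("tsp genealogies make cross-lineage allele pairs non-monophyletic", {
  sim <- simulatePosteriorSample("tsp", n_lineages = 2, n_trees = 30,
                                 epsilon = 0, seed = 72)
  tr <- sim$truth
  expect_true(all(c(1L, 2L) %in% tr$lineage))
  pick <- function(sp, lin) tr$tip[tr$species == sp & tr$lineage == lin][1]
  q <- c(pick("Homo", 1), pick("Homo", 2), pick("Mamu", 1), pick("Mamu", 2))
  cnt <- countTopologies(sim$sample, q)
  expect_equal(nNonmono(cnt), 30L)
  # same-lineage pairs still look monophyletic-like across species:
  # alleles cluster by lineage, so a within-lineage quartet is resolved
  q2 <- c(pick("Homo", 1), tr$tip[tr$species == "Homo" & tr$lineage == 1][2],
          pick("Mamu", 1), tr$tip[tr$species == "Mamu" & tr$lineage == 1][2])
  expect_equal(nMono(countTopologies(sim$sample, q2)), 30L)
})

test_that("topology noise perturbs close to the requested fraction of trees", {
  sim <- simulatePosteriorSample("monophyly", n_alleles_per_species = 3,
                                 n_trees = 1000, epsilon = 0.1, seed = 73)
  frac <- mean(sim$perturbed)
  expect_lt(abs(frac - 0.1), 0.03)
  # perturbed trees differ topologically from the base tree
  base <- treeList(sim$sample)[[which(!sim$perturbed)[1]]]
  some <- which(sim$perturbed)[1:20]
  rf <- vapply(treeList(sim$sample)[some], phangorn::RF.dist, numeric(1), base)
  expect_true(all(rf > 0))
})

test_that("generators are seed-deterministic", {
  a <- simulatePosteriorSample("tsp", n_trees = 10, epsilon = 0.2, seed = 74)
  b <- simulatePosteriorSample("tsp", n_trees = 10, epsilon = 0.2, seed = 74)
  expect_identical(lapply(treeList(a$sample), ape::write.tree),
                   lapply(treeList(b$sample), ape::write.tree))
  c <- simulatePosteriorSample("tsp", n_trees = 10, epsilon = 0.2, seed = 75)
  expect_false(identical(lapply(treeList(a$sample), ape::write.tree),
                         lapply(treeList(c$sample), ape::write.tree)))
  s1 <- simulateAlignment(geneconv_tree(), n_columns = 100, seed = 76)
  s2 <- simulateAlignment(geneconv_tree(), n_columns = 100, seed = 76)
  expect_identical(s1$alignment, s2$alignment)
  r1 <- simulateRatePosterior(c(1, 2), n_states = 5, seed = 77)
  expect_identical(r1, simulateRatePosterior(c(1, 2), n_states = 5, seed = 77))
  p1 <- synthStructure(20, 5, groove_positions = 3, seed = 78)
  expect_identical(p1$lines, synthStructure(20, 5, groove_positions = 3,
                                            seed = 78)$lines)
  expect_error(simulatePosteriorSample("monophyly", epsilon = 0.6),
               "epsilon")
  expect_error(simulatePosteriorSample("tsp", n_lineages = 1), "n_lineages")
})

test_that("planted rate classes elevate divergence and gappy columns define the baseline", {
  tree <- geneconv_tree()
  sim <- simulateAlignment(tree, n_columns = 600,
                           site_classes = data.frame(start = 301, end = 600,
                                                     rate = 4),
                           gappy_columns = 1:40,
                           backbone_ids = c("D", "Ds"), seed = 79)
  expect_equal(sim$rates[c(1, 300, 301)], c(1, 1, 4))
  mask <- identifyBaselineSites(sim$alignment, c("D", "Ds"))
  expect_equal(which(mask), 1:40)
  # substitution load scales with the multiplier: compare mismatch
  # fractions of a divergent pair between the 1x and 4x blocks
  m <- sim$alignment
  mm <- function(cols) mean(m["X1", cols] != m["Y1", cols])
  expect_gt(mm(301:600), mm(41:300))
  expect_error(simulateAlignment(tree, 100,
                                 site_classes = data.frame(start = c(1, 5),
                                                           end = c(10, 20),
                                                           rate = 2)),
               "disjoint")
})

test_that("injected conversion tracts copy the donor exactly over the tract", {
  sim <- simulateAlignment(geneconv_tree(), n_columns = 200, seed = 80)
  inj <- injectGeneConversion(sim$alignment, "D", "A", 50, 120)
  m <- inj$alignment
  expect_true(all(m["A", 50:120] == m["D", 50:120]))
  tract_d <- mean(m["A", 50:120] != m["D", 50:120])
  flank_d <- mean(m["A", -(50:120)] != m["D", -(50:120)])
  expect_equal(tract_d, 0)
  expect_gt(flank_d, 0.1)
  expect_error(injectGeneConversion(sim$alignment, "D", "A", 0, 10), "bounds")
  expect_error(injectGeneConversion(sim$alignment, "D", "ZZ", 1, 10), "ZZ")
})

test_that("rate posteriors are noiseless at sigma zero and unbiased up to the lognormal factor", {
  truth <- c(0.5, 1, 4)
  clean <- simulateRatePosterior(truth, n_states = 10, noise_sigma = 0,
                                 seed = 81)
  expect_true(all(t(clean) == truth))
  noisy <- simulateRatePosterior(rep(2, 30), n_states = 1000,
                                 noise_sigma = 0.2, seed = 82)
  target <- 2 * exp(0.2^2 / 2)
  expect_true(all(abs(colMeans(noisy) - target) / target < 0.02))
})

test_that("synthetic structures seat groove residues under 4 A and others over 8 A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  groove <- c(10, 25, 40, 55)
  synthStructure(80, 9, groove_positions = groove, seed = 83, path = f)
  pdb <- readStructure(f)
  d <- minDistanceToPeptide(pdb, "A", "C")
  expect_true(all(d$min_dist[d$resno %in% groove] < 4))
  expect_true(all(d$min_dist[!d$resno %in% groove] > 8))
  expect_equal(nrow(d), 80L)
  expect_equal(length(chainSequence(pdb, "A")), 80L)
  expect_error(synthStructure(10, 5, groove_positions = 11), "subset")
})
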