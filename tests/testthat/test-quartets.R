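test_that("induced quartet topologies classify correctly after unrooting", {
  q <- c("a1", "a2", "b1", "b2")
  expect_equal(quartetTopology(ape::read.tree(text = "((a1,a2),(b1,b2));"), q),
               "monophyletic")
  expect_equal(quartetTopology(ape::read.tree(text = "((a1,b1),(a2,b2));"), q),
               "nonmonophyletic")
  # rooted caterpillar resolves after unrooting
  expect_equal(quartetTopology(ape::read.tree(text = "(a1,(b1,(a2,b2)));"), q),
               "nonmonophyletic")
  expect_equal(quartetTopology(ape::read.tree(text = "(a1,a2,b1,b2);"), q),
               "uninformative")
  # extra tips do not disturb the induced quartet
  big <- ape::read.tree(text = "(((a1,x),a2),((b1,y),b2));")
  expect_equal(quartetTopology(big, q), "monophyletic")
  expect_error(quartetTopology(big, c("a1", "a2", "b1", "zz")), "zz")
})

test_that("exactly one of the three unrooted resolutions is monophyletic", {
  res <- vapply(quartet_resolutions(), function(s)
    quartetTopology(ape::read.tree(text = s), c("a1", "a2", "b1", "b2")),
    character(1))
  expect_equal(sum(res == "monophyletic"), 1L)
  expect_equal(sum(res == "nonmonophyletic"), 2L)
})

test_that("topology tallies agree across methods, the brute-force oracle, and tree order", {
  set.seed(101)
  trees <- lapply(1:200, function(i) {
    t <- ape::rtree(6, tip.label = c("a1", "a2", "b1", "b2", "c1", "c2"))
    if (i %% 5 == 0) t <- ape::di2multi(t, tol = 0.6)  # some polytomies
    t
  })
  x <- TreeSample(trees)
  q <- c("a1", "a2", "b1", "b2")
  fast <- countTopologies(x, q)
  slow <- countTopologies(x, q, method = "prune")
  expect_equal(nMono(fast), nMono(slow))
  expect_equal(nNonmono(fast), nNonmono(slow))
  expect_equal(nUninformative(fast), nUninformative(slow))
  oracle <- table(factor(vapply(trees, brute_quartet, character(1), q),
                         levels = c("monophyletic", "nonmonophyletic",
                                    "uninformative")))
  expect_equal(nMono(fast), unname(oracle[["monophyletic"]]))
  expect_equal(nNonmono(fast), unname(oracle[["nonmonophyletic"]]))
  expect_equal(nUninformative(fast), unname(oracle[["uninformative"]]))
  # permutation invariance of the sample
  xp <- TreeSample(trees[sample(length(trees))])
  perm <- countTopologies(xp, q)
  expect_equal(nMono(perm), nMono(fast))
  expect_equal(nNonmono(perm), nNonmono(fast))
})

test_that("Bayes factors follow the posterior-odds formula with the 1/2 prior factor", {
  even <- bayesFactor(QuartetCount(nMono = 50, nNonmono = 50))
  expect_equal(kValue(even), 0.5)
  expect_false(isLowerBound(even))
  # zero non-monophyletic count regularized to 1/(n+1)
  upper <- bayesFactor(QuartetCount(nMono = 100, nNonmono = 0))
  expect_equal(kValue(upper), (1 / 101) / (100 / 101) * 0.5)
  expect_equal(kValue(upper), 1 / 200)
  expect_true(isLowerBound(upper))
  expect_error(bayesFactor(QuartetCount(nMono = 0, nNonmono = 0,
                                        nUninformative = 10)),
               "no informative trees")
})

test_that("K is monotone in the non-monophyly count and reciprocal pairs multiply to 1/4", {
  n <- 60L
  ks <- vapply(1:(n - 1), function(m)
    kValue(bayesFactor(QuartetCount(nMono = n - m, nNonmono = m))),
    numeric(1))
  expect_true(all(diff(ks) > 0))
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    k1 <- kValue(bayesFactor(QuartetCount(nMono = a, nNonmono = b)))
    k2 <- kValue(bayesFactor(QuartetCount(nMono = b, nNonmono = a)))
    expect_equal(k1 * k2, 0.25)
  }
})

test_that("quartet enumeration is exhaustive up to a seeded cap and respects exclusions", {
  expect_equal(nrow(enumerateQuartets(c("h1", "h2"), c("m1", "m2"))), 1L)
  q9 <- enumerateQuartets(paste0("h", 1:3), paste0("m", 1:3), cap = 100)
  expect_equal(nrow(q9), 9L)
  qx <- enumerateQuartets(paste0("h", 1:4), paste0("m", 1:4),
                          excluded = c("h4", "m1"))
  expect_false(any(c("h4", "m1") %in% unlist(qx)))
  expect_equal(nrow(qx), choose(3, 2)^2)
  # capped subsampling is deterministic under the seed
  qa <- enumerateQuartets(paste0("h", 1:6), paste0("m", 1:6), cap = 50, seed = 9)
  qb <- enumerateQuartets(paste0("h", 1:6), paste0("m", 1:6), cap = 50, seed = 9)
  expect_equal(nrow(qa), 50L)
  expect_identical(qa, qb)
  expect_error(enumerateQuartets(c("h1", "h2"), "m1"),
               class = "tspscan_not_enough_alleles")
})

test_that("the maximum Bayes factor reduces to the single-quartet value and hits exact calibration", {
  sim <- simulatePosteriorSample("monophyly", n_alleles_per_species = 2,
                                 n_trees = 50, epsilon = 0, seed = 13)
  x <- sim$sample
  one <- maxBayesFactor(x, c("Homo_a01", "Homo_a02"),
                        c("Mamu_a01", "Mamu_a02"))
  direct <- bayesFactor(countTopologies(x, c("Homo_a01", "Homo_a02",
                                             "Mamu_a01", "Mamu_a02")))
  expect_equal(kValue(one), kValue(direct))
  expect_equal(one@nQuartetsTested, 1L)
  # noise-free monophyly: every quartet fully monophyletic, so
  # K = (1/(n+1))/(n/(n+1)) * 1/2 = 1/(2n) exactly
  sim6 <- simulatePosteriorSample("monophyly", n_trees = 50, epsilon = 0,
                                  seed = 14)
  all6 <- maxBayesFactor(sim6$sample,
                         taxonTable(sim6$sample)$raw[taxonTable(sim6$sample)$species_code == "Homo"],
                         taxonTable(sim6$sample)$raw[taxonTable(sim6$sample)$species_code == "Mamu"])
  expect_equal(kValue(all6), 1 / (2 * 50))
  expect_true(isLowerBound(all6))
})

test_that("the Bayes factor matrix separates planted TSP from monophyly and blanks thin cells", {
  groups <- list(human = "Homo", owm = "Mamu")
  tspS <- simulatePosteriorSample("tsp", n_trees = 300, epsilon = 0.02,
                                  seed = 21)$sample
  monoS <- simulatePosteriorSample("monophyly", n_trees = 300, epsilon = 0.02,
                                   seed = 22)$sample
  bm <- bfMatrix(list(exon2 = tspS, exon3 = monoS),
                 data.frame(groupA = "human", groupB = "owm"), groups)
  expect_equal(nrow(bm), 2L)
  expect_gt(bm$K[bm$region == "exon2"], 100)
  expect_lt(bm$K[bm$region == "exon3"], 1)
  # a comparison with one usable B allele renders blank
  thin <- simulatePosteriorSample("monophyly",
                                  n_alleles_per_species = c(Homo = 3, Patr = 2,
                                                            Gogo = 2, Popy = 2,
                                                            Mamu = 1),
                                  n_trees = 20, seed = 23)$sample
  bm2 <- bfMatrix(list(exon2 = thin),
                  data.frame(groupA = "human", groupB = "owm"), groups)
  expect_true(is.na(bm2$K))
  expect_equal(bm2$note, "insufficient alleles")
  expect_error(bfMatrix(list(exon2 = thin),
                        data.frame(groupA = "human", groupB = "nope"), groups),
               "unknown group key")
})

test_that("gene-conversion exclusions propagate into the Bayes factor matrix", {
  groups <- list(human = "Homo", owm = "Mamu")
  x <- simulatePosteriorSample("monophyly",
                               n_alleles_per_species = c(Homo = 2, Patr = 2,
                                                         Gogo = 2, Popy = 2,
                                                         Mamu = 3),
                               n_trees = 20, seed = 24)$sample
  full <- bfMatrix(list(e2 = x), data.frame(groupA = "human", groupB = "owm"),
                   groups)
  expect_equal(full$n_quartets, choose(2, 2) * choose(3, 2))
  excl <- bfMatrix(list(e2 = x), data.frame(groupA = "human", groupB = "owm"),
                   groups, exclusions = list(e2 = c("Mamu_a01", "Mamu_a02")))
  expect_true(is.na(excl$K))
})
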