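test_that("taxon labels parse into species code and allele name and round-trip", {
  tab <- parseTaxonLabels(c("HLA-B*07:02", "Patr_B*01:01", "Gogo-C*03",
                            "oddball", "Ab_x"))
  expect_equal(tab$species_code, c("HLA", "Patr", "Gogo", "unknown", "unknown"))
  expect_equal(tab$allele_name[1:3], c("B*07:02", "B*01:01", "C*03"))
  # unmatched labels fall through whole
  expect_equal(tab$allele_name[4], "oddball")
  matched <- !is.na(tab$separator)
  expect_equal(paste0(tab$species_code[matched], tab$separator[matched],
                      tab$allele_name[matched]), tab$raw[matched])
  # species table demotes unlisted codes; groups assign keys
  tab2 <- parseTaxonLabels(c("Patr_B*01", "Mamu_B*01", "Zzzz_B*01"),
                           species_table = c("Patr", "Mamu"),
                           groups = list(apes = "Patr", OWM = "Mamu"))
  expect_equal(tab2$species_code, c("Patr", "Mamu", "unknown"))
  expect_equal(tab2$group, c("apes", "OWM", NA))
})

test_that("newick and nexus samples read in file order with label resolution", {
  nwk <- rep("((Homo_a1:1,Homo_a2:1):1,(Mamu_a1:1,Mamu_a2:1):1);", 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(nwk, f)
  x <- readTreeSamples(f)
  expect_s4_class(x, "TreeSample")
  expect_equal(nTrees(x), 3L)
  expect_equal(sort(tipNames(x)),
               sort(c("Homo_a1", "Homo_a2", "Mamu_a1", "Mamu_a2")))
  expect_equal(provenance(x)$state_index, 1:3)

  # nexus with translate block round-trips through the ape writer
  fn <- withr::local_tempfile(fileext = ".nex")
  writeTreeSample(x, fn, format = "nexus")
  y <- readTreeSamples(fn)
  expect_equal(nTrees(y), 3L)
  expect_equal(sort(tipNames(y)), sort(tipNames(x)))
})

test_that("malformed or tip-inconsistent trees are rejected naming the tree", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((a:1,b:1):1,c:1);", "((a:1,b:1:1,c;"), f)
  expect_error(readTreeSamples(f), "tree 2")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((a:1,b:1):1,c:1);", "(a:1,b:1);"), f2)
  expect_error(readTreeSamples(f2), "tree 2")
})

test_that("burn-in removes floor(f*n) leading trees and keeps provenance", {
  sim <- simulatePosteriorSample("monophyly", n_alleles_per_species = 2,
                                 n_trees = 40, seed = 3)
  x <- sim$sample
  expect_equal(nTrees(applyBurnin(x, 0.10)), 36L)
  expect_equal(provenance(applyBurnin(x, 0.10))$state_index, 5:40)
  expect_equal(nTrees(applyBurnin(x, 0)), 40L)
  x7 <- TreeSample(treeList(x)[1:7])
  expect_equal(nTrees(applyBurnin(x7, 0.5)), 4L)
  expect_error(applyBurnin(x, 1), "burnin_fraction")
  expect_error(applyBurnin(x, -0.1), "burnin_fraction")
})

test_that("replicate combination concatenates and checks tip sets", {
  s1 <- simulatePosteriorSample("monophyly", n_alleles_per_species = 2,
                                n_trees = 100, seed = 1)$sample
  s2 <- simulatePosteriorSample("monophyly", n_alleles_per_species = 2,
                                n_trees = 100, seed = 2)$sample
  both <- combineReplicates(list(s1, s2))
  expect_equal(nTrees(both), 200L)
  expect_identical(combineReplicates(list(s1)), s1)
  s3 <- simulatePosteriorSample("monophyly", n_alleles_per_species = 3,
                                n_trees = 10, seed = 1)$sample
  expect_error(combineReplicates(list(s1, s3)), "replicates 1 and 2")
})

test_that("burn-in then combination over k equal replicates yields k*(n - floor(f*n)) trees", {
  reps <- lapply(1:8, function(s)
    simulatePosteriorSample("monophyly", n_alleles_per_species = 2,
                            n_trees = 50, seed = s)$sample)
  trimmed <- lapply(reps, applyBurnin, burnin_fraction = 0.10)
  expect_equal(nTrees(combineReplicates(trimmed)), 8L * (50L - 5L))
  expect_equal(length(unique(provenance(combineReplicates(trimmed))$replicate_id)), 1L)
})

test_that("the MCC tree maximizes the product of clade frequencies and is a sample member", {
  # identical trees: clade product 1, log score 0
  x <- sample_from_newick(rep("((a,b),((c,d),e));", 10))
  mcc <- mccTree(x)
  expect_equal(attr(mcc, "logCladeScore"), 0)
  expect_equal(phangorn::RF.dist(mcc, treeList(x)[[1]]), 0)

  # 9 copies of T1 vs 1 of T2: clade frequencies 0.9 beat 0.1
  x2 <- sample_from_newick(c(rep("((a,b),((c,d),e));", 9),
                             "((a,c),((b,d),e));"))
  mcc2 <- mccTree(x2)
  expect_equal(attr(mcc2, "index"), 1L)
  expect_equal(phangorn::RF.dist(mcc2, treeList(x2)[[1]]), 0)

  # noise-free simulated sample: recovers the generating topology,
  # and the selected tree is always a member of the sample
  sim <- simulatePosteriorSample("monophyly", n_trees = 25, epsilon = 0,
                                 seed = 7)
  mcc3 <- mccTree(sim$sample)
  expect_equal(phangorn::RF.dist(mcc3, treeList(sim$sample)[[1]]), 0)
  sim2 <- simulatePosteriorSample("monophyly", n_trees = 30, epsilon = 0.3,
                                  seed = 8)
  mcc4 <- mccTree(sim2$sample)
  idx <- attr(mcc4, "index")
  expect_true(idx >= 1 && idx <= 30)
  expect_equal(phangorn::RF.dist(mcc4, treeList(sim2$sample)[[idx]]), 0)
})

test_that("ESS matches theory for iid and AR(1) series and handles constants", {
  expect_equal(essValue(rep(3.14, 50)), 50)
  set.seed(42)
  iid <- rnorm(10000)
  expect_lt(abs(essValue(iid) - 10000) / 10000, 0.15)
  set.seed(43)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 10000))
  theory <- 10000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(essValue(ar) - theory) / theory, 0.25)
  expect_error(essValue(rnorm(5)), "length")
})

test_that("newick serialization round-trips topologies exactly", {
  sim <- simulatePosteriorSample("tsp", n_trees = 15, epsilon = 0.2, seed = 5)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeTreeSample(sim$sample, f)
  back <- readTreeSamples(f)
  rf <- mapply(function(a, b) phangorn::RF.dist(a, b),
               treeList(back), treeList(sim$sample))
  expect_true(all(rf == 0))
})
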