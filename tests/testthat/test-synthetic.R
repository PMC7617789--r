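test_that("generateLabelField places small non-touching seed clones", {
  g <- generateLabelField(40, 40, fraction = 0.12, cloneSeedSize = 3,
                          seed = 3)
  expect_true(all(g$patchSizes >= 1 & g$patchSizes <= 3))
  # labeled components of the emitted field are exactly the patches
  inverted <- LabelField(1L - labelMatrix(g$field))
  comp <- voidSizes(findVoids(inverted, minSize = 1))
  expect_true(all(comp <= 3))
  expect_equal(sum(comp), sum(g$patchSizes))
  expect_equal(g$realizedFraction, mean(labelMatrix(g$field)))
  expect_gte(g$realizedFraction, 0.12 - 3 / 1600)

  empty <- generateLabelField(10, 10, fraction = 0, cloneSeedSize = 2)
  expect_equal(labeledFraction(empty$field), 0)

  expect_error(generateLabelField(12, 12, fraction = 0.9, cloneSeedSize = 3,
                                  seed = 1),
               "achieved")
})

test_that("cloneSeedSize 1 reduces to i.i.d. Bernoulli labeling", {
  g <- generateLabelField(100, 100, fraction = 0.3, seed = 9)
  n <- sum(labelMatrix(g$field))
  expect_lt(abs(n - 3000), 3 * sqrt(1e4 * 0.3 * 0.7))
})

test_that("generateCloneCounts matches its target VAFs in the deep-depth limit", {
  spec <- exampleTreeSpec(nMutations = 10, depthMean = 1e6)
  sim <- generateCloneCounts(spec, seed = 2)
  # pooled per clone and sample: the law of large numbers pins VAF to cf/2
  alt <- rowsum(altCounts(sim$counts), sim$truth$assignments)
  dep <- rowsum(totalDepth(sim$counts), sim$truth$assignments)
  pooledVaf <- alt / dep
  truthVaf <- spec@cf[rownames(pooledVaf), ] / 2
  expect_lt(max(abs(pooledVaf - truthVaf)), 1e-3)
  # zero cell fraction implies zero alt reads
  expect_true(all(alt[truthVaf == 0] == 0))
})

test_that("generated counts respect alt <= depth and seed determinism", {
  spec <- generateTreeScenario(4, 5, seed = 17, depthMean = 30,
                               depthDispersion = 0.3)
  a <- generateCloneCounts(spec, seed = 5)
  b <- generateCloneCounts(spec, seed = 5)
  expect_identical(altCounts(a$counts), altCounts(b$counts))
  expect_identical(totalDepth(a$counts), totalDepth(b$counts))
  expect_true(all(altCounts(a$counts) <= totalDepth(a$counts)))
  expect_true(all(rowSums(totalDepth(a$counts)) > 0))
})

test_that("generateTreeScenario emits pigeonhole-consistent, separable truths", {
  for (K in c(1, 3, 5)) {
    spec <- generateTreeScenario(K, 6, minCfSeparation = 0.15, seed = 60 + K)
    expect_s4_class(spec, "SyntheticCloneSpec")  # validity audits pigeonhole
    cf <- spec@cf
    if (K > 1) {
      seps <- combn(K, 2, function(ij) max(abs(cf[ij[1], ] - cf[ij[2], ])))
      expect_true(all(seps >= 0.15))
      # every ancestor-descendant pair nests on the noise-free CFs
      anc <- function(i) {
        out <- integer(0); p <- spec@parent[i]
        while (!is.na(p)) { out <- c(out, p); p <- spec@parent[p] }
        out
      }
      for (i in seq_len(K)) for (p in anc(i))
        expect_true(nestingTest(cf[i, ], cf[p, ], epsilon = 1e-9) %in%
                      c("strong", "weak"))
    }
  }
  expect_error(generateTreeScenario(8, 2, minCfSeparation = 0.5,
                                    seed = 1, maxTries = 10),
               "infeasible separation")
})

test_that("truth sidecar files are written and parse back", {
  sim <- generateCloneCounts(exampleTreeSpec(nMutations = 3), seed = 1)
  dir <- tempfile()
  writeTruth(sim$truth, dir)
  asg <- read.delim(file.path(dir, "truth_assignments.tsv"))
  expect_equal(nrow(asg), 18)
  ph <- ape::read.tree(file.path(dir, "truth_tree.nwk"))
  expect_setequal(c(ph$tip.label, ph$node.label),
                  c("root", "A", "B", "A1", "A2", "B1"))
})
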