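test_that("VariantCountMatrix validity and long/AD table readers", {
  expect_error(VariantCountMatrix(matrix(5, 1, 2), matrix(4, 1, 2)),
               "alt must not exceed depth")
  expect_error(VariantCountMatrix(matrix(0, 1, 2), matrix(0, 1, 2)),
               "zero depth")

  vcm <- VariantCountMatrix(matrix(1:4, 2, 2), matrix(10L, 2, 2))
  path <- tempfile(fileext = ".tsv")
  writeVariantCounts(vcm, path)
  back <- readVariantCounts(path)
  expect_equal(altCounts(back), altCounts(vcm))
  expect_equal(totalDepth(back), totalDepth(vcm))

  ad <- tempfile(fileext = ".tsv")
  writeLines(c("mutation_id\tsA\tsB", "m1\t18,2\t5,5", "m2\t10,0\t0,10"), ad)
  v2 <- readVcfLikeCounts(ad)
  expect_equal(unname(altCounts(v2)), matrix(c(2L, 0L, 5L, 10L), 2, 2))
  expect_equal(unname(totalDepth(v2)), matrix(c(20L, 10L, 10L, 10L), 2, 2))
  expect_equal(rawVAF(v2)["m1", "sB"], 0.5)
})

test_that("single mutation: one cluster with the conjugate posterior mean", {
  vcm <- VariantCountMatrix(matrix(c(3L, 10L), 1, 2),
                            matrix(c(10L, 40L), 1, 2))
  cc <- gibbsCluster(vcm, burnIn = 10, nSamples = 10, seed = 1)
  expect_equal(nClusters(cc), 1L)
  expect_equal(unname(clusterTheta(cc)[1, ]),
               c((1 + 3) / (2 + 10), (1 + 10) / (2 + 40)))
  # default schedule mirrors the published one
  expect_equal(eval(formals(gibbsCluster)$burnIn), 5000)
  expect_equal(eval(formals(gibbsCluster)$nSamples), 5000)
})

# two well-separated clusters at depth 1000: recovery must be unambiguous
.makeTwoCluster <- function(seed = 4) {
  theta <- rbind(c(0.45, 0.40, 0.45, 0.40, 0.45, 0.40),
                 c(0.05, 0.10, 0.05, 0.10, 0.05, 0.10))
  set.seed(seed)
  truthLab <- rep(1:2, each = 50)
  dep <- matrix(1000L, 100, 6)
  alt <- matrix(rbinom(600, 1000, theta[truthLab, ]), 100, 6)
  list(vcm = VariantCountMatrix(alt, dep), truth = truthLab)
}

test_that("well-separated clones are recovered exactly (ARI = 1)", {
  d <- .makeTwoCluster()
  cc <- gibbsCluster(d$vcm, burnIn = 100, nSamples = 100, seed = 2)
  expect_equal(nClusters(cc), 2L)
  ari <- mclust::adjustedRandIndex(clusterAssignments(cc), d$truth)
  expect_equal(ari, 1)
  # posterior theta hugs the pooled VAF at high depth under the flat prior
  for (k in 1:2) {
    mem <- clusterAssignments(cc) == k
    pooled <- colSums(altCounts(d$vcm)[mem, ]) /
      colSums(totalDepth(d$vcm)[mem, ])
    expect_lt(max(abs(clusterTheta(cc)[k, ] - pooled)), 0.01)
  }
})

test_that("row order is exchangeable: permuting mutations permutes labels only", {
  d <- .makeTwoCluster()
  cc1 <- gibbsCluster(d$vcm, burnIn = 80, nSamples = 80, seed = 3)
  perm <- sample(seq_len(nrow(d$vcm)))
  vcm2 <- VariantCountMatrix(altCounts(d$vcm)[perm, ],
                             totalDepth(d$vcm)[perm, ])
  cc2 <- gibbsCluster(vcm2, burnIn = 80, nSamples = 80, seed = 3)
  part <- function(cc) {
    asg <- clusterAssignments(cc)
    unname(lapply(split(names(asg), asg), sort))
  }
  expect_setequal(part(cc1), part(cc2))
})

test_that("with alpha near 0 identical rows collapse into one cluster", {
  vcm <- VariantCountMatrix(matrix(20L, 30, 3), matrix(100L, 30, 3))
  cc <- gibbsCluster(vcm, burnIn = 50, nSamples = 50, concentration = 1e-8,
                     seed = 5)
  expect_equal(nClusters(cc), 1L)
})

test_that("parameter recovery on synthetic clone trees (reduced schedule)", {
  for (K in 2:3) {
    spec <- generateTreeScenario(K, 6, minCfSeparation = 0.15,
                                 seed = 40 + K, depthMean = 150)
    sim <- generateCloneCounts(spec, seed = 40 + K)
    cc <- gibbsCluster(sim$counts, burnIn = 200, nSamples = 200,
                       seed = 40 + K)
    ari <- mclust::adjustedRandIndex(
      clusterAssignments(cc), sim$truth$assignments[names(clusterAssignments(cc))])
    expect_gte(ari, 0.9)
    expect_lte(thetaRMSE(cc, sim$truth), 0.05)
  }
})

test_that("filterClusters applies the size threshold and logs removals", {
  cc <- makeClustering(c(49, 50, 120))
  expect_message(out <- filterClusters(cc, 50), "removed 1 of 3")
  expect_equal(nClusters(out), 2L)
  expect_setequal(unname(clusterSizes(out)), c(50L, 120L))
  expect_true(all(is.na(
    clusterAssignments(out)[seq_len(49)])))  # dropped members flagged NA

  id <- suppressMessages(filterClusters(cc, 1))
  expect_equal(nClusters(id), 3L)
})

test_that("computeCF applies the diploid heterozygous mapping with clipping", {
  expect_equal(computeCF(c(0, 0.3, 0.5, 0.6)), c(0, 0.6, 1, 1))
  expect_error(computeCF(1.2), "\\[0, 1\\]")
})
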