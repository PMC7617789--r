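test_that("nestingTest evaluates the pigeonhole predicate", {
  expect_equal(nestingTest(c(0.3, 0.4), c(0.8, 0.9)), "strong")
  expect_equal(nestingTest(c(0.1, 0.2), c(0.3, 0.4)), "weak")
  expect_equal(nestingTest(c(0.3, 0.2), c(0.2, 0.6)), "independent")
  # child detected where the parent is absent counts against nesting
  expect_equal(nestingTest(c(0.2, 0.3), c(0.6, 0.005)), "independent")
  expect_error(nestingTest(c(0.1, 0.2), c(0.3, 0.4, 0.5)), "sample index")
})

test_that("prefilterClusters drops clusters below the median-VAF floor", {
  theta <- rbind(c(0.05, 0.08, 0.12), c(0.2, 0.3, 0.25), c(0.09, 0.09, 0.09))
  cc <- makeClustering(c(60, 60, 60), nSamples = 3, theta = theta)
  expect_message(out <- prefilterClusters(cc, 0.1), "removed 2 of 3")
  expect_equal(nClusters(out), 1L)
  expect_equal(unname(clusterTheta(out)[1, 1]), 0.2)
  id <- suppressMessages(prefilterClusters(cc, 0))
  expect_equal(nClusters(id), 3L)
})

test_that("buildTree recovers the unique linear chain from nested CFs", {
  cf <- rbind(top = c(1.0, 1.0), mid = c(0.6, 0.7), leaf = c(0.3, 0.4))
  tr <- buildTree(cf)
  e <- treeEdges(tr)
  expect_equal(treeRoots(tr), "top")
  expect_equal(e$parent[e$child == "mid"], "top")
  expect_equal(e$parent[e$child == "leaf"], "mid")
  expect_equal(e$evidence, c("strong", "strong"))  # CF sums exceed 1 somewhere
  expect_true(all(pigeonholeAudit(tr)$ok))

  single <- buildTree(matrix(c(0.5, 0.5), 1, 2,
                             dimnames = list("only", NULL)))
  expect_equal(treeRoots(single), "only")
  expect_equal(nrow(treeEdges(single)), 0L)
})

test_that("buildTree output is an enumerated nesting-consistent forest of maximal nesting", {
  scenarios <- list(
    chain = rbind(a = c(1, 1), b = c(0.6, 0.7), c = c(0.3, 0.4)),
    fiveClone = exampleTreeSpec()@cf[1:5, ])
  for (K in 2:5)
    scenarios[[sprintf("random%d", K)]] <-
      generateTreeScenario(K, 6, seed = 70 + K)@cf
  for (nm in names(scenarios)) {
    cf <- pmin(scenarios[[nm]], 1)
    tr <- buildTree(cf, epsilon = 1e-9)
    forests <- enumerateForests(cf, epsilon = 1e-9)
    key <- function(par) paste(ifelse(is.na(par), ".", par), collapse = "|")
    built <- tr@parent
    expect_true(key(built) %in% vapply(forests, key, character(1)),
                info = nm)
    maxEdges <- max(vapply(forests, function(p) sum(!is.na(p)), integer(1)))
    expect_equal(sum(!is.na(built)), maxEdges, info = nm)
  }
})

test_that("buildTree is invariant to the input order of clusters", {
  cf <- exampleTreeSpec()@cf
  tr1 <- buildTree(cf, epsilon = 1e-9)
  perm <- c(4, 1, 6, 2, 5, 3)
  tr2 <- buildTree(cf[perm, ], epsilon = 1e-9)
  edges <- function(tr) {
    e <- treeEdges(tr)
    sort(paste(e$child, e$parent))
  }
  expect_equal(edges(tr2), edges(tr1))
})

test_that("noise-free CFs from the six-clone scenario give exact topology", {
  spec <- exampleTreeSpec()
  tr <- buildTree(spec@cf, epsilon = 1e-9)
  e <- treeEdges(tr)
  got <- setNames(e$parent, e$child)
  expect_equal(got[c("A", "B", "A1", "A2", "B1")],
               c(A = "root", B = "root", A1 = "A", A2 = "A", B1 = "B"))
  expect_true(all(pigeonholeAudit(tr, 0)$ok))
  # newick export round-trips through ape with the same tip set
  nwk <- cloneTreeNewick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(c(ph$tip.label, ph$node.label),
                  c("root", "A", "B", "A1", "A2", "B1"))
})

test_that("contradictory strong nestings are reported, not silently resolved", {
  cf <- rbind(x = c(0.9, 0.6), y = c(0.6, 0.9))
  expect_equal(nestingTest(cf["x", ], cf["y", ]), "independent")
  # mutual strong nesting needs CFs equal within epsilon; it is flagged,
  # resolved by total CF and recorded rather than silently dropped
  expect_warning(tr <- buildTree(rbind(x = c(0.9, 0.9), y = c(0.9, 0.9)),
                                 epsilon = 0), "mutually strong-nested")
  expect_warning(buildTree(rbind(x = c(0.9, 0.9), y = c(0.88, 0.88)),
                           epsilon = 0.05), "mutually strong-nested")
})

test_that("mapClonesToSites reports per-site composition and lineage territories", {
  cf <- rbind(A  = c(0.9, 0.8, 0.0, 0.0),
              A1 = c(0.5, 0.3, 0.0, 0.0),
              B  = c(0.0, 0.0, 0.9, 0.8),
              B1 = c(0.0, 0.0, 0.4, 0.2))
  colnames(cf) <- sprintf("s%d", 1:4)
  tr <- buildTree(cf, epsilon = 1e-9)
  sites <- data.frame(sample_id = sprintf("s%d", 1:4),
                      site_label = c("left", "left", "right", "right"))
  mp <- mapClonesToSites(tr, sites)
  expect_setequal(mp$territories$A, "left")
  expect_setequal(mp$territories$B, "right")
  expect_length(intersect(mp$territories$A, mp$territories$B), 0)
  expect_true(all(mp$composition$cf > 0.01))

  # a clone present nowhere above the floor has an empty territory
  trGhost <- new("CloneTree", ids = c("X", "Z"),
                 parent = c(NA_character_, NA_character_),
                 evidence = c(NA_character_, NA_character_),
                 cf = matrix(c(0.5, 0.004, 0.6, 0.004), 2, 2,
                             dimnames = list(c("X", "Z"), c("s1", "s2"))),
                 nMutations = c(1L, 1L), independent = data.frame(),
                 audit = data.frame(), epsilon = 0.05, presenceFloor = 0.01)
  sites2 <- data.frame(sample_id = c("s1", "s2"),
                       site_label = c("dorsal", "ventral"))
  mp2 <- mapClonesToSites(trGhost, sites2)
  expect_length(mp2$territories$Z, 0)
  expect_error(mapClonesToSites(tr, sites2), "cover all samples")
})
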