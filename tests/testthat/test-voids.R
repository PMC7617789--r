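test_that("findVoids: degenerate fields and manual component enumeration", {
  allLab <- LabelField(matrix(1L, 6, 6))
  expect_length(voidSizes(findVoids(allLab)), 0)

  allUnlab <- LabelField(matrix(0L, 4, 7))
  expect_equal(voidSizes(findVoids(allUnlab)), 28L)

  # hand-built 5x5 mask (closed boundary): one unlabeled triple and one
  # singleton; min_size 2 keeps only the triple
  lab <- matrix(1L, 5, 5)
  lab[1, 1] <- 0L; lab[1, 2] <- 0L; lab[2, 2] <- 0L   # component of 3
  lab[4, 4] <- 0L                                     # component of 1
  f <- LabelField(lab, boundary = "closed")
  expect_equal(voidSizes(findVoids(f, minSize = 2)), 3L)
  expect_setequal(voidSizes(findVoids(f, minSize = 1)), c(3L, 1L))
})

test_that("findVoids honours periodic wrap and connectivity", {
  lab <- matrix(1L, 4, 4)
  lab[1, 1] <- 0L; lab[1, 4] <- 0L  # adjacent only across the column wrap
  expect_equal(voidSizes(findVoids(LabelField(lab), minSize = 1)), 2L)
  fClosed <- LabelField(lab, boundary = "closed")
  expect_equal(voidSizes(findVoids(fClosed, minSize = 1)), c(1L, 1L))

  # 8-connectivity joins diagonals that 4-connectivity keeps apart
  lab2 <- matrix(1L, 4, 4)
  lab2[2, 2] <- 0L; lab2[3, 3] <- 0L
  f2 <- LabelField(lab2, boundary = "closed")
  expect_equal(voidSizes(findVoids(f2, connectivity = 4, minSize = 1)),
               c(1L, 1L))
  expect_equal(voidSizes(findVoids(f2, connectivity = 8, minSize = 1)), 2L)
})

test_that("void sizes are invariant under periodic lattice translation", {
  set.seed(5)
  lab <- matrix(rbinom(400, 1, 0.5), 20, 20)
  base <- sort(voidSizes(findVoids(LabelField(lab), minSize = 1)))
  for (shift in list(c(3, 0), c(0, 7), c(11, 5))) {
    rolled <- lab[(seq_len(20) + shift[1] - 1) %% 20 + 1,
                  (seq_len(20) + shift[2] - 1) %% 20 + 1]
    expect_equal(sort(voidSizes(findVoids(LabelField(rolled), minSize = 1))),
                 base)
  }
})

test_that("exceedanceCurve: direct counting, shape invariants, empty input", {
  d <- exceedanceCurve(c(2, 2, 4, 8))
  expect_equal(exceedanceTable(d),
               data.frame(size = c(2L, 4L, 8L),
                          exceedance = c(1, 0.5, 0.25)))
  expect_equal(exceedanceTable(exceedanceCurve(2))$exceedance, 1)

  empty <- exceedanceCurve(c(1, 1), minSize = 2)
  expect_s4_class(empty, "VoidDistribution")
  expect_length(voidSizes(empty), 0)

  set.seed(8)
  tb <- exceedanceTable(exceedanceCurve(sample(2:60, 200, replace = TRUE)))
  expect_true(all(diff(tb$exceedance) <= 0))
  expect_equal(tb$exceedance[1], 1)
  expect_true(all(tb$exceedance > 0 & tb$exceedance <= 1))
})

test_that("fitPowerLaw recovers exact power laws to machine precision", {
  # counts chosen so P(S >= s) = (s/2)^-1 exactly at s = 2, 4, ..., 64
  sizes1 <- rep(c(2, 4, 8, 16, 32, 64), c(32, 16, 8, 4, 2, 2))
  fit1 <- fitPowerLaw(exceedanceCurve(sizes1))
  expect_equal(fit1@exponent, -1, tolerance = 1e-12)
  expect_equal(fit1@rSquared, 1, tolerance = 1e-12)

  # P(S >= s) proportional to s^-2
  sizes2 <- rep(c(2, 4, 8, 16, 32), c(192, 48, 12, 3, 1))
  fit2 <- fitPowerLaw(exceedanceCurve(sizes2))
  expect_equal(fit2@exponent, -2, tolerance = 1e-12)

  expect_error(fitPowerLaw(exceedanceCurve(c(2, 4)), c(2, 10)),
               "at least 3 distinct sizes")
})

test_that("compareToModel reproduces the log-scale R^2 definition", {
  obs <- new("VoidDistribution", sizes = integer(0), minSize = 2L,
             table = data.frame(size = c(2, 20, 200),
                                exceedance = c(1, 0.1, 0.01)))
  identicalModel <- list(obs, obs)
  expect_equal(compareToModel(obs, identicalModel)$rSquared, 1)

  model <- new("VoidDistribution", sizes = integer(0), minSize = 2L,
               table = data.frame(size = c(2, 20, 200),
                                  exceedance = 10^c(0, -1.1, -1.9)))
  cmp <- compareToModel(obs, list(model))
  expect_equal(cmp$rSquared, 1 - 0.02 / 2, tolerance = 1e-10)

  # no overlapping support is an explicit error
  far <- new("VoidDistribution", sizes = integer(0), minSize = 2L,
             table = data.frame(size = c(1000, 2000),
                                exceedance = c(1, 0.5)))
  expect_error(compareToModel(far, list(model)), "support")
})

test_that("expanding fitter clones leave an excess of large voids", {
  # pre-takeover regime: sparse fitter seeds whose expansion outruns the
  # neutral coarsening scale, so unlabeled mutant clones show up as an
  # increased fraction of large voids
  pTail <- function(mode, fitter, seed) {
    ens <- voterEnsemble(128, 128, 0.5, 15, 100, seed = seed, mode = mode,
                         fitterFraction = fitter)
    vapply(ens$replicates,
           function(r) mean(r$voidSizes >= 200), numeric(1))
  }
  nn <- pTail("non_neutral", 0.002, seed = 801)
  ne <- pTail("neutral", 0, seed = 802)
  tt <- t.test(nn, ne, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("exceedance curves survive a TSV round trip", {
  d <- exceedanceCurve(c(2, 2, 3, 9, 9, 40))
  path <- tempfile(fileext = ".tsv")
  writeExceedance(d, path)
  d2 <- readExceedance(path)
  expect_equal(exceedanceTable(d2), exceedanceTable(d))
})
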