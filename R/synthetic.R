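#' Generate a mosaic label field of small contiguous seed clones
#'
#' Emulates the sparse labeling pattern a few days after induction, when
#' each labeled clone is a small contiguous family of cells. Labels are
#' placed as non-overlapping, non-touching contiguous patches grown by a
#' random walk from a seed cell until the target fraction is reached;
#' \code{cloneSeedSize = 1} reduces to i.i.d. Bernoulli labeling. Because
#' patches never touch, every labeled component at generation time has size
#' between 1 and \code{cloneSeedSize}.
#'
#' @param nRows,nCols lattice dimensions.
#' @param fraction target labeled fraction in [0, 1].
#' @param cloneSeedSize cells per seed clone (>= 1).
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @param boundary boundary mode (adjacency honours periodic wrap).
#' @return A list: \code{field} (\linkS4class{LabelField}),
#'   \code{realizedFraction}, \code{nPatches}, \code{patchSizes}.
#' @examples
#' g <- generateLabelField(40, 40, fraction = 0.1, cloneSeedSize = 3, seed = 1)
#' g$realizedFraction
#' @export
generateLabelField <- function(nRows, nCols, fraction, cloneSeedSize = 1L,
                               seed = NULL, boundary = "periodic-both") {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (cloneSeedSize < 1) stop("cloneSeedSize must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- nRows * nCols

  if (cloneSeedSize == 1L) {
    lab <- matrix(rbinom(N, 1L, fraction), nRows, nCols)
    return(list(field = LabelField(lab, boundary = boundary),
                realizedFraction = mean(lab),
                nPatches = sum(lab), patchSizes = rep(1L, sum(lab))))
  }

  target <- round(fraction * N)
  lab <- matrix(0L, nRows, nCols)
  blocked <- matrix(FALSE, nRows, nCols)  # labeled or adjacent to labeled
  code <- .boundaryCode(boundary)
  neigh <- function(r, c) .latticeNeighbours(r, c, nRows, nCols, code)

  count <- 0L
  patchSizes <- integer(0)
  while (count < target) {
    free <- which(!blocked)
    if (!length(free))
      stop(sprintf(
        "cannot reach label fraction %g with cloneSeedSize %d: achieved %g",
        fraction, cloneSeedSize, count / N))
    cell <- free[sample.int(length(free), 1L)]
    patch <- cell
    while (length(patch) < cloneSeedSize) {
      # random-walk growth: extend from a random patch member
      cand <- unique(unlist(lapply(patch, function(i) {
        rc <- .idx2rc(i, nRows)
        neigh(rc[1L], rc[2L])
      })))
      cand <- setdiff(cand[!blocked[cand]], patch)
      if (!length(cand)) break
      patch <- c(patch, cand[sample.int(length(cand), 1L)])
    }
    lab[patch] <- 1L
    count <- count + length(patch)
    patchSizes <- c(patchSizes, length(patch))
    halo <- unique(unlist(lapply(patch, function(i) {
      rc <- .idx2rc(i, nRows)
      neigh(rc[1L], rc[2L])
    })))
    blocked[c(patch, halo)] <- TRUE
  }

  list(field = LabelField(lab, boundary = boundary),
       realizedFraction = mean(lab), nPatches = length(patchSizes),
       patchSizes = patchSizes)
}

.idx2rc <- function(i, nRows) c((i - 1L) %% nRows + 1L, (i - 1L) %/% nRows + 1L)

.latticeNeighbours <- function(r, c, nRows, nCols, code) {
  rr <- r + c(-1L, 1L, 0L, 0L)
  cc <- c + c(0L, 0L, -1L, 1L)
  if (code == 0L) {
    rr <- (rr - 1L) %% nRows + 1L
    cc <- (cc - 1L) %% nCols + 1L
  } else if (code == 1L) {
    cc <- (cc - 1L) %% nCols + 1L
  }
  ok <- rr >= 1L & rr <= nRows & cc >= 1L & cc <= nCols
  rr[ok] + (cc[ok] - 1L) * nRows
}

#' Construct a SyntheticCloneSpec
#'
#' @param parent integer parent index per clone (NA for roots).
#' @param cf clones x samples target cell-fraction matrix; must be
#'   pigeonhole-consistent (children never sum above their parent in any
#'   sample).
#' @param nMutations mutations per clone (scalar recycled).
#' @param depthMean per-sample mean depth (scalar recycled).
#' @param depthDispersion negative-binomial dispersion d with variance
#'   mu + d * mu^2; 0 (default) gives fixed depth.
#' @return A \linkS4class{SyntheticCloneSpec}.
#' @export
syntheticCloneSpec <- function(parent, cf, nMutations, depthMean,
                               depthDispersion = 0) {
  cf <- as.matrix(cf)
  if (is.null(rownames(cf))) rownames(cf) <- sprintf("clone%d", seq_len(nrow(cf)))
  if (is.null(colnames(cf))) colnames(cf) <- sprintf("s%d", seq_len(ncol(cf)))
  if (length(nMutations) == 1L) nMutations <- rep(nMutations, nrow(cf))
  new("SyntheticCloneSpec", parent = as.integer(parent), cf = cf,
      nMutations = as.integer(nMutations), depthMean = as.numeric(depthMean),
      depthDispersion = as.numeric(depthDispersion))
}

setMethod("show", "SyntheticCloneSpec", function(object) {
  cat(sprintf(
    "SyntheticCloneSpec: %d clones x %d samples, %d mutations total\n",
    nrow(object@cf), ncol(object@cf), sum(object@nMutations)))
})

#' Simulate a multi-sample variant count matrix from a clone tree
#'
#' For mutation m of clone c in sample s the total depth is drawn from the
#' per-sample depth model (negative binomial; dispersion 0 gives fixed
#' depth) and the mutant reads as Binomial(depth, cf[c, s] / 2) under the
#' diploid heterozygous assumption, mirroring the generative structure the
#' VAF clustering assumes. No sequencing-error model is applied: mutant
#' reads arise only from true carriers.
#'
#' @param spec a \linkS4class{SyntheticCloneSpec}.
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @return A list: \code{counts} (\linkS4class{VariantCountMatrix}) and
#'   \code{truth} (assignments, clone CF matrix, parent vector).
#' @examples
#' out <- generateCloneCounts(exampleTreeSpec(nMutations = 10), seed = 1)
#' out$counts
#' @export
generateCloneCounts <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SyntheticCloneSpec"))
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(spec@cf); S <- ncol(spec@cf)
  mu <- rep(spec@depthMean, length.out = S)
  disp <- rep(spec@depthDispersion, length.out = S)
  M <- sum(spec@nMutations)
  cloneOf <- rep(seq_len(K), spec@nMutations)
  mutIds <- sprintf("m%04d", seq_len(M))

  dep <- matrix(0L, M, S)
  for (s in seq_len(S)) {
    dep[, s] <- if (disp[s] == 0) rep(as.integer(round(mu[s])), M)
    else rnbinom(M, size = 1 / disp[s], mu = mu[s])
  }
  # the clustering input forbids all-zero-depth mutations; redraw such rows
  while (any(zero <- rowSums(dep) == 0)) {
    for (s in seq_len(S)) {
      if (disp[s] > 0)
        dep[zero, s] <- rnbinom(sum(zero), size = 1 / disp[s], mu = mu[s])
    }
    if (all(disp == 0)) break
  }

  p <- pmin(spec@cf[cloneOf, , drop = FALSE] / 2, 0.5)
  alt <- matrix(rbinom(M * S, as.vector(dep), as.vector(p)), M, S)
  dimnames(alt) <- dimnames(dep) <- list(mutIds, colnames(spec@cf))

  list(counts = VariantCountMatrix(alt, dep),
       truth = list(assignments = stats::setNames(rownames(spec@cf)[cloneOf],
                                                  mutIds),
                    cf = spec@cf, parent = spec@parent,
                    cloneIds = rownames(spec@cf)))
}

#' Draw a random ground-truth clone-tree scenario
#'
#' Generates a random rooted clone tree and a pigeonhole-consistent CF
#' matrix: the root occupies \code{rootCf} of every sample, and each child
#' receives a random share of its parent's cell fraction per sample, boosted
#' in a clone-specific "home" sample so that distinct clones peak in
#' distinct microbiopsies. Draws are retried until (i) every pair of clones
#' differs by at least \code{minCfSeparation} in some sample and (ii) every
#' pair of non-ancestral clones has crossing CF profiles, so the pigeonhole
#' analysis can tell them apart.
#'
#' @param nClones number of clones (>= 1).
#' @param nSamples number of microbiopsies.
#' @param minCfSeparation minimum CF separation between any two clones in at
#'   least one sample (default 0.15).
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @param nMutationsPerClone mutations per clone (default 100).
#' @param depthMean,depthDispersion depth model (defaults 100, 0).
#' @param rootCf root cell fraction per sample (scalar or length nSamples).
#' @param maxTries retry budget before declaring the separation infeasible.
#' @return A \linkS4class{SyntheticCloneSpec}.
#' @export
generateTreeScenario <- function(nClones, nSamples, minCfSeparation = 0.15,
                                 seed = NULL, nMutationsPerClone = 100,
                                 depthMean = 100, depthDispersion = 0,
                                 rootCf = 1, maxTries = 500) {
  if (nClones < 1) stop("nClones must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  parent <- c(NA_integer_,
              if (nClones > 1)
                vapply(2:nClones, function(i)
                  sample.int(i - 1L, 1L), integer(1)))
  home <- ((seq_len(nClones) - 1L) %% nSamples) + 1L

  for (try in seq_len(maxTries)) {
    cf <- matrix(0, nClones, nSamples,
                 dimnames = list(sprintf("clone%d", seq_len(nClones)),
                                 sprintf("s%d", seq_len(nSamples))))
    cf[1L, ] <- rep(rootCf, length.out = nSamples)
    for (p in seq_len(nClones)) {
      kids <- which(!is.na(parent) & parent == p)
      if (!length(kids)) next
      for (s in seq_len(nSamples)) {
        w <- runif(length(kids), 0.10, 0.35) + 0.50 * (home[kids] == s)
        tot <- sum(w)
        if (tot > 0.9) w <- w * 0.9 / tot
        cf[kids, s] <- w * cf[p, s]
      }
    }
    if (.scenarioOk(cf, parent, minCfSeparation))
      return(syntheticCloneSpec(parent, cf, nMutationsPerClone, depthMean,
                                depthDispersion))
  }
  stop(sprintf(
    "infeasible separation: no scenario with %d clones over %d samples met minCfSeparation = %g in %d tries",
    nClones, nSamples, minCfSeparation, maxTries))
}

.scenarioOk <- function(cf, parent, minSep) {
  K <- nrow(cf)
  if (K == 1L) return(TRUE)
  anc <- function(i) {
    out <- integer(0)
    p <- parent[i]
    while (!is.na(p)) { out <- c(out, p); p <- parent[p] }
    out
  }
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    if (max(abs(cf[i, ] - cf[j, ])) < minSep) return(FALSE)
    related <- j %in% anc(i) || i %in% anc(j)
    if (!related) {
      # non-ancestral pairs must cross so they read as independent
      if (!(any(cf[i, ] > cf[j, ]) && any(cf[j, ] > cf[i, ]))) return(FALSE)
    }
  }
  TRUE
}

#' A fixed six-clone demonstration scenario
#'
#' A hand-specified two-lineage tree over six microbiopsies: a ubiquitous
#' founder, two major lineages confined to complementary halves of the
#' samples, two subclones under the first lineage and one under the second.
#' Used in examples and as the shipped clone demo; all pairwise CF profiles
#' are separable and the topology is recoverable from noise-free CFs.
#'
#' @param nMutations mutations per clone (default 50).
#' @param depthMean,depthDispersion depth model (defaults 100, 0).
#' @return A \linkS4class{SyntheticCloneSpec} with clones
#'   root, A, B, A1, A2, B1 and parent structure
#'   root -> (A, B), A -> (A1, A2), B -> B1.
#' @export
exampleTreeSpec <- function(nMutations = 50, depthMean = 100,
                            depthDispersion = 0) {
  cf <- rbind(
    root = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    A    = c(0.85, 0.80, 0.75, 0.05, 0.05, 0.05),
    B    = c(0.05, 0.05, 0.05, 0.85, 0.80, 0.75),
    A1   = c(0.60, 0.10, 0.10, 0.00, 0.00, 0.00),
    A2   = c(0.10, 0.55, 0.10, 0.00, 0.00, 0.00),
    B1   = c(0.00, 0.00, 0.00, 0.60, 0.10, 0.10))
  colnames(cf) <- sprintf("s%d", 1:6)
  syntheticCloneSpec(parent = c(NA, 1L, 1L, 2L, 2L, 3L), cf = cf,
                     nMutations = nMutations, depthMean = depthMean,
                     depthDispersion = depthDispersion)
}

#' Write ground-truth sidecar files for a synthetic scenario
#'
#' Writes \code{truth_assignments.tsv}, \code{truth_cf.tsv} and
#' \code{truth_tree.nwk} next to the simulated counts.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generateCloneCounts}} output.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(mutation_id = names(truth$assignments),
               clone = unname(truth$assignments)),
    file.path(dir, "truth_assignments.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(clone = rownames(truth$cf), truth$cf, check.names = FALSE),
    file.path(dir, "truth_cf.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  ids <- truth$cloneIds
  parent <- ifelse(is.na(truth$parent), NA_character_, ids[truth$parent])
  tr <- new("CloneTree", ids = ids, parent = parent,
            evidence = ifelse(is.na(parent), NA_character_, "strong"),
            cf = truth$cf, nMutations = rep(1L, length(ids)),
            independent = data.frame(), audit = data.frame(),
            epsilon = 0, presenceFloor = 0)
  writeLines(cloneTreeNewick(tr), file.path(dir, "truth_tree.nwk"))
  invisible(dir)
}
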