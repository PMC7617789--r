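#' Construct a VariantCountMatrix
#'
#' @param alt,depth integer matrices (mutations x samples) of mutant and
#'   total read counts. Dimnames give mutation and sample identifiers;
#'   defaults (\code{m1..}, \code{s1..}) are generated when absent.
#' @return A \linkS4class{VariantCountMatrix}.
#' @examples
#' vcm <- VariantCountMatrix(matrix(5, 2, 3), matrix(20, 2, 3))
#' @export
VariantCountMatrix <- function(alt, depth) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  if (!identical(dim(alt), dim(depth)))
    stop("alt and depth must have identical dimensions")
  storage.mode(alt) <- "integer"
  storage.mode(depth) <- "integer"
  rn <- rownames(alt) %||% rownames(depth) %||%
    sprintf("m%d", seq_len(nrow(alt)))
  cn <- colnames(alt) %||% colnames(depth) %||%
    sprintf("s%d", seq_len(ncol(alt)))
  dimnames(alt) <- dimnames(depth) <- list(rn, cn)
  new("VariantCountMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(alt = alt, depth = depth)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn VariantCountMatrix mutant read counts.
#' @param x a VariantCountMatrix.
#' @export
altCounts <- function(x) SummarizedExperiment::assay(x, "alt")

#' @describeIn VariantCountMatrix total read depths.
#' @export
totalDepth <- function(x) SummarizedExperiment::assay(x, "depth")

#' @describeIn VariantCountMatrix raw per-mutation VAFs (NA at zero depth).
#' @export
rawVAF <- function(x) {
  a <- altCounts(x); d <- totalDepth(x)
  v <- a / d
  v[d == 0] <- NA_real_
  v
}

#' Read variant counts from a long-form TSV
#'
#' Expects columns \code{mutation_id}, \code{sample_id}, \code{alt},
#' \code{depth}; missing mutation/sample combinations get depth 0.
#'
#' @param path TSV path.
#' @return A \linkS4class{VariantCountMatrix}.
#' @export
readVariantCounts <- function(path) {
  d <- utils::read.delim(path, colClasses = c(
    mutation_id = "character", sample_id = "character"))
  need <- c("mutation_id", "sample_id", "alt", "depth")
  if (!all(need %in% names(d)))
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  alt <- stats::xtabs(alt ~ mutation_id + sample_id, d)
  dep <- stats::xtabs(depth ~ mutation_id + sample_id, d)
  VariantCountMatrix(unclass(alt)[, , drop = FALSE],
                     unclass(dep)[, , drop = FALSE])
}

#' @rdname readVariantCounts
#' @param vcm a VariantCountMatrix to write (long form).
#' @export
writeVariantCounts <- function(vcm, path) {
  a <- altCounts(vcm); d <- totalDepth(vcm)
  long <- data.frame(
    mutation_id = rep(rownames(a), ncol(a)),
    sample_id = rep(colnames(a), each = nrow(a)),
    alt = as.vector(a), depth = as.vector(d))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a simplified multi-sample VCF-like AD table
#'
#' Accepts a TSV whose first column is \code{mutation_id} and whose
#' remaining columns hold per-sample allelic depths as \code{"ref,alt"}
#' strings (the VCF AD convention); total depth = ref + alt.
#'
#' @param path TSV path.
#' @return A \linkS4class{VariantCountMatrix}.
#' @export
readVcfLikeCounts <- function(path) {
  d <- utils::read.delim(path, colClasses = "character",
                         check.names = FALSE)
  if (names(d)[1L] != "mutation_id")
    stop("first column must be mutation_id")
  samples <- names(d)[-1L]
  parse1 <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed AD field (expected 'ref,alt'): ",
                       col[which(bad)[1L]])
    t(vapply(parts, as.integer, integer(2)))
  }
  ads <- lapply(d[samples], parse1)
  alt <- vapply(ads, function(m) m[, 2L], integer(nrow(d)))
  ref <- vapply(ads, function(m) m[, 1L], integer(nrow(d)))
  alt <- matrix(alt, nrow = nrow(d), dimnames = list(d$mutation_id, samples))
  dep <- matrix(ref, nrow = nrow(d)) + alt
  dimnames(dep) <- dimnames(alt)
  VariantCountMatrix(alt, dep)
}

#' Cluster mutations into clones by a Dirichlet-process mixture
#'
#' Collapsed Gibbs sampling of a Dirichlet-process mixture in which mutation
#' m in cluster c has \code{alt[m,s] ~ Binomial(depth[m,s], theta[c,s])}
#' independently across samples and \code{theta[c,s] ~ Beta(a, b)}. The
#' number of clusters is unconstrained and varies along the chain. The
#' default schedule is 5,000 burn-in followed by 5,000 posterior sampling
#' iterations; reduced schedules are configuration, not a change of model.
#'
#' Hard assignments come from the posterior similarity matrix: mutations are
#' linked by average-linkage hierarchical clustering on 1 - co-assignment
#' probability and cut at 0.5, which is robust to label switching. The MAP
#' iteration's assignment is kept in the diagnostics as an alternative.
#' Per-cluster VAFs are conjugate posterior means
#' \code{(a + sum alt) / (a + b + sum depth)} over cluster members.
#'
#' @param counts a \linkS4class{VariantCountMatrix}.
#' @param burnIn,nSamples Gibbs schedule (defaults 5000 and 5000).
#' @param concentration DP concentration alpha (default 1).
#' @param betaPrior length-2 (a, b) Beta base-measure parameters
#'   (default c(1, 1)).
#' @param thin keep every thin-th post-burn-in iteration (default 1).
#' @param assignment \code{"consensus"} (default) or \code{"map"}.
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @return A \linkS4class{CloneClustering}. A chain that never separates
#'   clusters is not an error; inspect \code{diagnostics(x)$kTrace}.
#' @examples
#' spec <- exampleTreeSpec(nMutations = 20)
#' cc <- gibbsCluster(generateCloneCounts(spec, seed = 1)$counts,
#'                    burnIn = 50, nSamples = 50, seed = 1)
#' @export
gibbsCluster <- function(counts, burnIn = 5000, nSamples = 5000,
                         concentration = 1, betaPrior = c(1, 1), thin = 1,
                         assignment = c("consensus", "map"), seed = NULL) {
  stopifnot(is(counts, "VariantCountMatrix"))
  assignment <- match.arg(assignment)
  if (burnIn < 1 || nSamples < 1) stop("burnIn and nSamples must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  if (length(betaPrior) != 2L || any(betaPrior <= 0))
    stop("betaPrior must be two positive numbers")
  if (!is.null(seed)) set.seed(seed)

  alt <- altCounts(counts); dep <- totalDepth(counts)
  M <- nrow(alt)
  fit <- dp_gibbs_cpp(alt, dep, concentration, betaPrior[1L], betaPrior[2L],
                      as.integer(burnIn), as.integer(nSamples),
                      as.integer(thin))

  cl <- if (assignment == "map") {
    fit$map_assign + 1L
  } else if (M == 1L) {
    1L
  } else {
    h <- stats::hclust(stats::as.dist(1 - fit$psm), method = "average")
    stats::cutree(h, h = 0.5)
  }
  names(cl) <- rownames(alt)

  .buildClustering(cl, alt, dep, betaPrior, diagnostics = list(
    kTrace = fit$k_trace, nKept = fit$n_kept, psm = fit$psm,
    mapAssignments = stats::setNames(fit$map_assign + 1L, rownames(alt)),
    mapLogScore = fit$map_log_score,
    schedule = c(burnIn = burnIn, nSamples = nSamples, thin = thin),
    concentration = concentration, betaPrior = betaPrior,
    assignment = assignment))
}

# assemble a CloneClustering from a hard assignment; clusters ordered by
# descending size, then first-member index (canonical relabeling)
.buildClustering <- function(cl, alt, dep, betaPrior, diagnostics) {
  first <- tapply(seq_along(cl), cl, min)
  sizes <- tapply(seq_along(cl), cl, length)
  ord <- order(-sizes, first)
  old <- names(first)[ord]
  newIdx <- stats::setNames(seq_along(old), old)
  cl2 <- unname(newIdx[as.character(cl)])
  names(cl2) <- names(cl)
  K <- length(old)
  ids <- sprintf("c%d", seq_len(K))
  theta <- matrix(0, K, ncol(alt), dimnames = list(ids, colnames(alt)))
  nm <- integer(K)
  for (k in seq_len(K)) {
    mem <- which(cl2 == k)
    nm[k] <- length(mem)
    A <- colSums(alt[mem, , drop = FALSE])
    D <- colSums(dep[mem, , drop = FALSE])
    theta[k, ] <- (betaPrior[1L] + A) / (betaPrior[1L] + betaPrior[2L] + D)
  }
  new("CloneClustering", assignments = cl2, clusterIds = ids, theta = theta,
      cf = computeCF(theta), nMutations = nm, diagnostics = diagnostics)
}

#' @describeIn gibbsCluster mutation -> cluster assignment vector.
#' @param x a CloneClustering.
#' @export
clusterAssignments <- function(x) x@assignments

#' @describeIn gibbsCluster cluster x sample VAF estimates.
#' @export
clusterTheta <- function(x) x@theta

#' @describeIn gibbsCluster cluster x sample mutant cell fractions.
#' @export
clusterCF <- function(x) x@cf

#' @describeIn gibbsCluster mutations per cluster (named).
#' @export
clusterSizes <- function(x) stats::setNames(x@nMutations, x@clusterIds)

#' @describeIn gibbsCluster number of clusters.
#' @export
nClusters <- function(x) length(x@clusterIds)

#' @describeIn gibbsCluster sampler diagnostics list.
#' @export
diagnostics <- function(x) x@diagnostics

#' @describeIn gibbsCluster mutation ids per cluster.
#' @export
clusterMutations <- function(x) {
  lapply(stats::setNames(seq_along(x@clusterIds), x@clusterIds),
         function(k) names(x@assignments)[!is.na(x@assignments) &
                                            x@assignments == k])
}

setMethod("show", "CloneClustering", function(object) {
  cat(sprintf("CloneClustering: %d clusters over %d mutations x %d samples\n",
              nClusters(object), length(object@assignments),
              ncol(object@theta)))
  if (nClusters(object))
    cat("  sizes:", paste(sprintf("%s=%d", object@clusterIds,
                                  object@nMutations), collapse = ", "), "\n")
})

#' Convert VAF estimates to mutant cell fractions
#'
#' Under the diploid heterozygous assumption a mutation present in a
#' fraction f of cells is read at VAF f/2, so \code{cf = min(2 * theta, 1)}.
#'
#' @param theta VAF value(s) in [0, 1].
#' @return Cell fraction(s), clipped at 1.
#' @examples
#' computeCF(c(0, 0.3, 0.5, 0.6))
#' @export
computeCF <- function(theta) {
  if (any(theta < 0 | theta > 1, na.rm = TRUE))
    stop("theta must lie in [0, 1]")
  pmin(2 * theta, 1)
}

#' Drop small mutation clusters
#'
#' Removes clusters with fewer than \code{minClusterSize} mutations (default
#' 50, the downstream-analysis threshold); dropped mutations keep an NA
#' assignment and the removal is logged via \code{message}.
#'
#' @param clustering a \linkS4class{CloneClustering}.
#' @param minClusterSize minimum cluster size kept.
#' @return The filtered \linkS4class{CloneClustering}.
#' @export
filterClusters <- function(clustering, minClusterSize = 50) {
  stopifnot(is(clustering, "CloneClustering"))
  keep <- clustering@nMutations >= minClusterSize
  nDropMut <- sum(clustering@nMutations[!keep])
  message(sprintf(
    "filterClusters: removed %d of %d clusters (< %d mutations; %d mutations dropped)",
    sum(!keep), length(keep), minClusterSize, nDropMut))
  .subsetClustering(clustering, keep)
}

.subsetClustering <- function(clustering, keep) {
  keptIdx <- which(keep)
  map <- rep(NA_integer_, length(keep))
  map[keptIdx] <- seq_along(keptIdx)
  asg <- clustering@assignments
  asg[] <- ifelse(is.na(asg), NA_integer_, map[asg])
  initialize(clustering,
             assignments = asg,
             clusterIds = clustering@clusterIds[keptIdx],
             theta = clustering@theta[keptIdx, , drop = FALSE],
             cf = clustering@cf[keptIdx, , drop = FALSE],
             nMutations = clustering@nMutations[keptIdx])
}

#' Write clustering outputs
#'
#' Writes \code{clusters.tsv} (cluster_id, mutation_id), \code{theta.tsv},
#' \code{cf.tsv} and \code{diagnostics.json} into a directory.
#'
#' @param clustering a \linkS4class{CloneClustering}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeClustering <- function(clustering, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asg <- clustering@assignments
  memb <- data.frame(
    cluster_id = ifelse(is.na(asg), NA_character_,
                        clustering@clusterIds[asg]),
    mutation_id = names(asg))
  utils::write.table(memb, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .writeMat <- function(m, f) {
    df <- data.frame(cluster_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  .writeMat(clustering@theta, "theta.tsv")
  .writeMat(clustering@cf, "cf.tsv")
  d <- clustering@diagnostics
  jsonlite::write_json(
    list(k_trace = d$kTrace, n_kept = d$nKept,
         schedule = as.list(d$schedule), concentration = d$concentration,
         beta_prior = d$betaPrior, assignment = d$assignment,
         cluster_sizes = as.list(clusterSizes(clustering))),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cluster x sample matrix written by \code{writeClustering}
#'
#' @param path TSV with a \code{cluster_id} column followed by sample
#'   columns.
#' @return A numeric matrix with cluster_id rownames.
#' @export
readClusterMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
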