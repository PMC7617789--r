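#' @import methods
NULL

.BOUNDARIES <- c("periodic-both", "periodic-cols-reflecting-rows", "closed")

.boundaryCode <- function(boundary) {
  match(match.arg(boundary, .BOUNDARIES), .BOUNDARIES) - 1L
}

#' LabelField: the mosaic-labeled basal cell layer
#'
#' A 2D lattice of basal cells in which each cell carries a heritable label
#' bit (mosaic lineage label) and a genotype bit (normal vs. fitter mutant).
#' Cells are stored as integer codes \code{2 * genotype + label}, i.e.
#' 0 = unlabeled normal, 1 = labeled normal, 2 = unlabeled fitter,
#' 3 = labeled fitter.
#'
#' @slot grid integer matrix of cell codes in 0..3.
#' @slot boundary one of \code{"periodic-both"} (closed tube in both axes,
#'   the default for tracheal simulations),
#'   \code{"periodic-cols-reflecting-rows"} (circumferentially periodic,
#'   closed proximo-distally) or \code{"closed"} (e.g. a digitized image
#'   patch).
#' @slot time elapsed simulation time in Monte-Carlo sweeps.
#'
#' @export
setClass("LabelField",
  representation(grid = "matrix", boundary = "character", time = "numeric"))

setValidity("LabelField", function(object) {
  g <- object@grid
  if (!is.numeric(g) || length(dim(g)) != 2L)
    return("grid must be a 2D numeric matrix")
  if (nrow(g) < 2L || ncol(g) < 2L)
    return("grid must be at least 2x2")
  if (!all(g %in% 0:3))
    return("grid codes must be integers in 0..3")
  if (length(object@boundary) != 1L || !object@boundary %in% .BOUNDARIES)
    return(sprintf("boundary must be one of: %s",
                   paste(.BOUNDARIES, collapse = ", ")))
  if (length(object@time) != 1L || is.na(object@time) || object@time < 0)
    return("time must be a single non-negative number")
  TRUE
})

#' VoidDistribution: sizes of unlabeled cell clusters
#'
#' The multiset of void sizes (connected clusters of unlabeled cells, in
#' cells) retained at a minimum-size threshold, together with the empirical
#' cumulative exceedance curve P(S >= s) evaluated at each distinct retained
#' size.
#'
#' @slot sizes integer vector of retained void sizes.
#' @slot minSize minimum void size retained (default 2: regions larger than
#'   one cell).
#' @slot table data.frame with columns \code{size} and \code{exceedance}.
#'
#' @export
setClass("VoidDistribution",
  representation(sizes = "integer", minSize = "integer", table = "data.frame"))

setValidity("VoidDistribution", function(object) {
  tb <- object@table
  if (length(object@sizes) && any(object@sizes < object@minSize))
    return("all retained sizes must be >= minSize")
  if (nrow(tb)) {
    if (!all(c("size", "exceedance") %in% names(tb)))
      return("table must have columns size, exceedance")
    if (is.unsorted(tb$size, strictly = TRUE))
      return("table sizes must be strictly increasing")
    if (any(diff(tb$exceedance) > 1e-12))
      return("exceedance must be non-increasing in size")
    if (abs(tb$exceedance[1L] - 1) > 1e-12)
      return("exceedance at the smallest retained size must be 1")
  }
  TRUE
})

#' PowerLawFit: log-log regression of an exceedance curve
#'
#' Least-squares fit of log10 P(S >= s) against log10 s over a size range.
#'
#' @slot exponent fitted slope (around -1 under neutral competition in 2D).
#' @slot rSquared coefficient of determination of the regression.
#' @slot intercept fitted intercept on the log10 scale.
#' @slot fitRange numeric length-2, inclusive size range used.
#' @slot nPoints number of distinct sizes entering the fit.
#'
#' @export
setClass("PowerLawFit",
  representation(exponent = "numeric", rSquared = "numeric",
                 intercept = "numeric", fitRange = "numeric",
                 nPoints = "integer"))

#' VariantCountMatrix: somatic variant read counts across microbiopsies
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{alt} (mutant reads)
#' and \code{depth} (total reads), rows = mutations, columns = samples
#' (microbiopsies).
#'
#' @export
setClass("VariantCountMatrix", contains = "SummarizedExperiment")

setValidity("VariantCountMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("alt", "depth") %in% an))
    return("assays 'alt' and 'depth' are required")
  alt <- SummarizedExperiment::assay(object, "alt")
  dep <- SummarizedExperiment::assay(object, "depth")
  if (any(alt < 0) || any(dep < 0))
    return("counts must be non-negative")
  if (any(alt > dep))
    return("alt must not exceed depth")
  if (nrow(dep) && any(rowSums(dep) == 0))
    return("mutations with zero depth in every sample are not allowed")
  TRUE
})

#' CloneClustering: a Dirichlet-process clustering of mutations into clones
#'
#' Result of \code{\link{gibbsCluster}}: a hard consensus assignment of
#' mutations to clusters, per-cluster per-sample VAF estimates (posterior
#' means) and derived mutant cell fractions, plus sampler diagnostics.
#'
#' @slot assignments named integer vector, mutation -> cluster index
#'   (NA once a mutation's cluster has been filtered out).
#' @slot clusterIds character vector of cluster identifiers.
#' @slot theta clusters x samples matrix of VAF estimates in [0, 1].
#' @slot cf clusters x samples matrix of mutant cell fractions,
#'   \code{min(2 * theta, 1)} under the diploid heterozygous assumption.
#' @slot nMutations integer vector of cluster sizes.
#' @slot diagnostics list: K trace, posterior similarity matrix, MAP
#'   assignment alternative, iteration schedule, prior settings.
#'
#' @export
setClass("CloneClustering",
  representation(assignments = "integer", clusterIds = "character",
                 theta = "matrix", cf = "matrix", nMutations = "integer",
                 diagnostics = "list"))

setValidity("CloneClustering", function(object) {
  k <- length(object@clusterIds)
  if (nrow(object@theta) != k || nrow(object@cf) != k ||
      length(object@nMutations) != k)
    return("theta, cf and nMutations must have one row/entry per cluster")
  if (length(object@theta) && (any(object@theta < 0) || any(object@theta > 1)))
    return("theta must lie in [0, 1]")
  if (length(object@cf) && (any(object@cf < 0) || any(object@cf > 1)))
    return("cf must lie in [0, 1]")
  TRUE
})

#' CloneTree: a pigeonhole-principle clone phylogeny
#'
#' A rooted forest over mutation clusters. Each edge carries the nesting
#' evidence grade: \code{"strong"} when the child and parent cell fractions
#' sum to more than 100\% in at least one shared microbiopsy (they must
#' overlap, hence nest), otherwise \code{"weak"}.
#'
#' @slot ids cluster identifiers (node names).
#' @slot parent character vector, parent id per node (NA for roots).
#' @slot evidence character vector, "strong"/"weak" per node (NA for roots).
#' @slot cf clusters x samples cell-fraction matrix used for the inference.
#' @slot nMutations mutations per cluster (used as branch lengths).
#' @slot independent data.frame of cluster pairs judged not nested.
#' @slot audit data.frame from \code{\link{pigeonholeAudit}}.
#' @slot epsilon,presenceFloor tolerances used.
#'
#' @export
setClass("CloneTree",
  representation(ids = "character", parent = "character",
                 evidence = "character", cf = "matrix",
                 nMutations = "integer", independent = "data.frame",
                 audit = "data.frame", epsilon = "numeric",
                 presenceFloor = "numeric"))

setValidity("CloneTree", function(object) {
  n <- length(object@ids)
  if (length(object@parent) != n || length(object@evidence) != n)
    return("parent and evidence must have one entry per node")
  if (anyDuplicated(object@ids))
    return("node ids must be unique")
  ok <- is.na(object@parent) | object@parent %in% object@ids
  if (!all(ok))
    return("every non-root parent must be a node id")
  # acyclicity: walking up from any node must terminate
  for (i in seq_len(n)) {
    seen <- character(0)
    p <- object@parent[i]
    while (!is.na(p)) {
      if (p %in% seen) return("parent links contain a cycle")
      seen <- c(seen, p)
      p <- object@parent[match(p, object@ids)]
    }
  }
  TRUE
})

#' SyntheticCloneSpec: ground truth for simulated multi-site read counts
#'
#' A clone tree with per-clone, per-sample target mutant cell fractions and
#' a per-sample sequencing depth model, from which
#' \code{\link{generateCloneCounts}} draws a \linkS4class{VariantCountMatrix}.
#'
#' @slot parent integer vector, parent index per clone (NA for roots).
#' @slot cf clones x samples target cell-fraction matrix in [0, 1];
#'   pigeonhole-consistent by construction (children never sum above their
#'   parent in any sample).
#' @slot nMutations mutations per clone.
#' @slot depthMean per-sample mean sequencing depth.
#' @slot depthDispersion per-sample negative-binomial dispersion d
#'   (variance = mu + d * mu^2); 0 draws a fixed depth equal to the mean.
#'
#' @export
setClass("SyntheticCloneSpec",
  representation(parent = "integer", cf = "matrix", nMutations = "integer",
                 depthMean = "numeric", depthDispersion = "numeric"))

setValidity("SyntheticCloneSpec", function(object) {
  k <- length(object@parent)
  if (nrow(object@cf) != k || length(object@nMutations) != k)
    return("cf and nMutations must have one row/entry per clone")
  if (any(object@cf < 0) || any(object@cf > 1))
    return("cell fractions must lie in [0, 1]")
  if (any(object@nMutations < 1))
    return("every clone needs at least one mutation")
  s <- ncol(object@cf)
  if (!length(object@depthMean) %in% c(1L, s) ||
      !length(object@depthDispersion) %in% c(1L, s))
    return("depthMean/depthDispersion must have length 1 or n_samples")
  if (any(object@depthMean <= 0) || any(object@depthDispersion < 0))
    return("depthMean must be positive, depthDispersion non-negative")
  ok <- is.na(object@parent) |
    (object@parent >= 1 & object@parent <= k & object@parent != seq_len(k))
  if (!all(ok)) return("parent indices out of range")
  viol <- .pigeonholeViolations(object@cf, object@parent, eps = 1e-9)
  if (nrow(viol))
    return(sprintf(
      "pigeonhole violation: children of clone %d exceed its CF in sample %d",
      viol$parent[1L], viol$sample[1L]))
  TRUE
})

# children CF sums may not exceed the parent CF in any sample
.pigeonholeViolations <- function(cf, parent, eps) {
  out <- data.frame(parent = integer(0), sample = integer(0),
                    childSum = numeric(0), parentCf = numeric(0))
  for (p in unique(parent[!is.na(parent)])) {
    kids <- which(!is.na(parent) & parent == p)
    csum <- colSums(cf[kids, , drop = FALSE])
    bad <- which(csum > cf[p, ] + eps)
    if (length(bad))
      out <- rbind(out, data.frame(parent = p, sample = bad,
                                   childSum = csum[bad],
                                   parentCf = cf[p, bad]))
  }
  out
}
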