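#' Pigeonhole nesting test between two clone clusters
#'
#' Tests whether cluster A is nested within (is a subclone of) cluster B
#' from their per-sample mutant cell fractions. Let M be the member samples
#' of B (cf_B above the presence floor). A is nested in B when cf_A <= cf_B
#' + epsilon in every member sample and A is absent (cf_A <= floor)
#' elsewhere. The evidence is \emph{strong} when cf_A + cf_B > 100\% in at
#' least one member sample (the two clusters must then share cells, so the
#' smaller is inside the larger); otherwise it is \emph{weak}. When cf_A
#' exceeds cf_B in some samples and falls below it in others, the clusters
#' are independent and not nested. A sample where only the putative child is
#' detected counts as evidence against nesting.
#'
#' @param cfA,cfB numeric cell-fraction vectors over the same samples
#'   (capped at 1 internally).
#' @param epsilon noise tolerance on the CF comparisons (default 0.05).
#' @param presenceFloor CF below which a clone is considered absent
#'   (default 0.01).
#' @return \code{"strong"}, \code{"weak"} or \code{"independent"}.
#' @examples
#' nestingTest(c(0.3, 0.4), c(0.8, 0.9))  # strong (sums exceed 100%)
#' nestingTest(c(0.1, 0.2), c(0.3, 0.4))  # weak
#' nestingTest(c(0.3, 0.2), c(0.2, 0.6))  # independent (crossing)
#' @export
nestingTest <- function(cfA, cfB, epsilon = 0.05, presenceFloor = 0.01) {
  if (length(cfA) != length(cfB))
    stop("cfA and cfB must share the sample index")
  if (!is.null(names(cfA)) && !is.null(names(cfB)) &&
      !identical(names(cfA), names(cfB)))
    stop("cfA and cfB must share the sample index (names differ)")
  if (epsilon < 0) stop("epsilon must be non-negative")
  cfA <- pmin(cfA, 1); cfB <- pmin(cfB, 1)
  member <- cfB > presenceFloor
  if (!any(member)) return("independent")
  inside <- all(cfA[member] <= cfB[member] + epsilon)
  absentOutside <- all(cfA[!member] <= presenceFloor)
  if (inside && absentOutside) {
    if (any(cfA[member] + cfB[member] > 1)) "strong" else "weak"
  } else {
    "independent"
  }
}

#' Drop clusters below a median-VAF threshold
#'
#' Only clusters with a median VAF of at least \code{minMedianVaf} (default
#' 0.1) across samples with nonzero depth enter the phylogenetic analysis.
#'
#' @param clustering a \linkS4class{CloneClustering}.
#' @param minMedianVaf threshold on the per-cluster median VAF.
#' @param sampleDepths optional per-sample total depths (per cluster use is
#'   the column sums of the member depths); samples with zero depth are
#'   excluded from the median. By default all samples count.
#' @return The filtered \linkS4class{CloneClustering}.
#' @export
prefilterClusters <- function(clustering, minMedianVaf = 0.1,
                              sampleDepths = NULL) {
  stopifnot(is(clustering, "CloneClustering"))
  med <- apply(clustering@theta, 1L, function(v) {
    if (!is.null(sampleDepths)) v <- v[sampleDepths > 0]
    stats::median(v)
  })
  keep <- med >= minMedianVaf
  message(sprintf(
    "prefilterClusters: removed %d of %d clusters (median VAF < %g)",
    sum(!keep), length(keep), minMedianVaf))
  .subsetClustering(clustering, keep)
}

#' Build a clone phylogeny by the pigeonhole principle
#'
#' Clusters are sorted by descending total cell fraction and attached, in
#' turn, to the smallest (lowest total CF) already-placed cluster in which
#' they nest with strong or weak evidence; clusters nesting in none become
#' additional roots, so the result is a rooted forest (multiple trees across
#' anatomical compartments are expected). Contradictory strong nestings
#' (each of two clusters strongly nested in the other with unequal CFs at
#' epsilon = 0) are a data inconsistency and raise an error; with a positive
#' epsilon near-identical clusters are resolved by total CF and recorded.
#'
#' @param x a \linkS4class{CloneClustering} or a clusters x samples CF
#'   matrix with cluster ids as rownames.
#' @param nMutations mutations per cluster (taken from the clustering when
#'   \code{x} is one; used as branch lengths).
#' @param epsilon CF noise tolerance (default 0.05).
#' @param presenceFloor CF presence floor (default 0.01).
#' @return A \linkS4class{CloneTree}.
#' @examples
#' cf <- rbind(root = c(1, 1), mid = c(0.6, 0.7), leaf = c(0.3, 0.4))
#' buildTree(cf)
#' @export
buildTree <- function(x, nMutations = NULL, epsilon = 0.05,
                      presenceFloor = 0.01) {
  if (is(x, "CloneClustering")) {
    cf <- clusterCF(x)
    if (is.null(nMutations)) nMutations <- x@nMutations
  } else {
    cf <- as.matrix(x)
  }
  if (!nrow(cf)) stop("at least one cluster is required")
  if (is.null(rownames(cf))) rownames(cf) <- sprintf("c%d", seq_len(nrow(cf)))
  if (is.null(nMutations)) nMutations <- rep(1L, nrow(cf))
  cf <- pmin(cf, 1)

  ids <- rownames(cf)
  K <- length(ids)
  rel <- matrix(NA_character_, K, K, dimnames = list(ids, ids))
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    rel[i, j] <- nestingTest(cf[i, ], cf[j, ], epsilon, presenceFloor)

  # contradictory strong nestings
  bad <- which(rel == "strong" & t(rel) == "strong", arr.ind = TRUE)
  bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
  if (nrow(bad)) {
    unequal <- apply(bad, 1L, function(ij)
      max(abs(cf[ij[1L], ] - cf[ij[2L], ])) > epsilon)
    if (epsilon == 0 && any(unequal))
      stop("data inconsistency: clusters ", ids[bad[which(unequal)[1L], 1L]],
           " and ", ids[bad[which(unequal)[1L], 2L]],
           " are each strongly nested in the other with unequal CFs",
           call. = FALSE)
    warning("mutually strong-nested cluster pair(s) at epsilon = ", epsilon,
            "; resolved by total CF and recorded in the tree")
  }

  tot <- rowSums(cf)
  ord <- order(-tot, ids)
  parent <- stats::setNames(rep(NA_character_, K), ids)
  evidence <- stats::setNames(rep(NA_character_, K), ids)
  placed <- character(0)
  for (i in ord) {
    id <- ids[i]
    hosts <- placed[rel[id, placed] %in% c("strong", "weak")]
    if (length(hosts)) {
      h <- hosts[order(tot[hosts], hosts)][1L]
      parent[id] <- h
      evidence[id] <- rel[id, h]
    }
    placed <- c(placed, id)
  }

  indep <- which(rel == "independent" & t(rel) == "independent",
                 arr.ind = TRUE)
  indep <- indep[indep[, 1L] < indep[, 2L], , drop = FALSE]
  independent <- data.frame(a = ids[indep[, 1L]], b = ids[indep[, 2L]])

  tree <- new("CloneTree", ids = ids, parent = unname(parent[ids]),
              evidence = unname(evidence[ids]), cf = cf,
              nMutations = as.integer(nMutations),
              independent = independent,
              audit = data.frame(), epsilon = epsilon,
              presenceFloor = presenceFloor)
  tree@audit <- pigeonholeAudit(tree, epsilon)
  tree
}

#' Audit a clone tree for pigeonhole consistency
#'
#' For every parent p with children C and every sample s, the children's
#' cell fractions must satisfy sum_C cf_c(s) <= cf_p(s) + |C| * epsilon.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param epsilon tolerance (defaults to the tree's own epsilon).
#' @return A data.frame of per-(parent, sample) checks with an \code{ok}
#'   column; zero rows with \code{ok = FALSE} means the audit passes.
#' @export
pigeonholeAudit <- function(tree, epsilon = tree@epsilon) {
  out <- data.frame(parent = character(0), sample = character(0),
                    childSum = numeric(0), parentCf = numeric(0),
                    nChildren = integer(0), ok = logical(0))
  samples <- colnames(tree@cf) %||% sprintf("s%d", seq_len(ncol(tree@cf)))
  for (p in tree@ids) {
    kids <- tree@ids[!is.na(tree@parent) & tree@parent == p]
    if (!length(kids)) next
    csum <- colSums(tree@cf[kids, , drop = FALSE])
    out <- rbind(out, data.frame(
      parent = p, sample = samples, childSum = unname(csum),
      parentCf = unname(tree@cf[p, ]), nChildren = length(kids),
      ok = unname(csum <= tree@cf[p, ] + length(kids) * epsilon)))
  }
  out
}

#' @describeIn buildTree edge table (child, parent, evidence).
#' @param tree a CloneTree.
#' @export
treeEdges <- function(tree) {
  i <- !is.na(tree@parent)
  data.frame(child = tree@ids[i], parent = tree@parent[i],
             evidence = tree@evidence[i])
}

#' @describeIn buildTree ids of the root clusters.
#' @export
treeRoots <- function(tree) tree@ids[is.na(tree@parent)]

setMethod("show", "CloneTree", function(object) {
  nr <- sum(is.na(object@parent))
  cat(sprintf("CloneTree: %d clusters, %d root(s), %d edge(s)\n",
              length(object@ids), nr, sum(!is.na(object@parent))))
  e <- treeEdges(object)
  if (nrow(e))
    cat(paste(sprintf("  %s -> %s (%s)", e$child, e$parent, e$evidence),
              collapse = "\n"), "\n")
  if (nrow(object@audit) && !all(object@audit$ok))
    cat("  WARNING: pigeonhole audit reports violations\n")
})

#' Newick export of a clone tree
#'
#' Cluster ids become tip/node labels and per-cluster mutation counts become
#' branch lengths. A forest yields one newick string per root.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @return Character vector of newick strings.
#' @export
cloneTreeNewick <- function(tree) {
  bl <- stats::setNames(tree@nMutations, tree@ids)
  rec <- function(id) {
    kids <- tree@ids[!is.na(tree@parent) & tree@parent == id]
    core <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", id)
    else id
    paste0(core, ":", bl[[id]])
  }
  vapply(treeRoots(tree), function(r) paste0(rec(r), ";"), character(1))
}

#' @rdname cloneTreeNewick
#' @param path base path: newick lines go to \code{path}, the edge-evidence
#'   sidecar to \code{paste0(path, ".edges.tsv")}.
#' @export
writeCloneTree <- function(tree, path) {
  writeLines(cloneTreeNewick(tree), path)
  utils::write.table(treeEdges(tree), paste0(path, ".edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map clones to anatomical sites
#'
#' Joins a clone tree with a site map and reports, per sample, the clones
#' present above the floor with their CFs and lineage (root ancestor), plus
#' each lineage's territory: the set of sites where any of its members is
#' present. Major lineages occupying largely exclusive territories show up
#' as disjoint site sets.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param sites data.frame with columns \code{sample_id},
#'   \code{site_label} (and optional \code{x}, \code{y}); must cover every
#'   sample of the CF matrix.
#' @param presenceFloor CF above which a clone counts as present.
#' @return A list: \code{composition} (sample_id, site_label, cluster, cf,
#'   lineage) and \code{territories} (named list of site-label sets per root
#'   lineage).
#' @export
mapClonesToSites <- function(tree, sites, presenceFloor = 0.01) {
  stopifnot(is(tree, "CloneTree"))
  need <- c("sample_id", "site_label")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  samples <- colnames(tree@cf)
  if (!all(samples %in% sites$sample_id))
    stop("sites must cover all samples; missing: ",
         paste(setdiff(samples, sites$sample_id), collapse = ", "))

  lineage <- stats::setNames(tree@ids, tree@ids)
  for (i in seq_along(tree@ids)) {
    p <- tree@parent[i]
    id <- tree@ids[i]
    while (!is.na(p)) {
      id <- p
      p <- tree@parent[match(p, tree@ids)]
    }
    lineage[tree@ids[i]] <- id
  }

  comp <- do.call(rbind, lapply(samples, function(s) {
    pres <- tree@ids[tree@cf[, s] > presenceFloor]
    if (!length(pres)) return(NULL)
    data.frame(sample_id = s,
               site_label = sites$site_label[match(s, sites$sample_id)],
               cluster = pres, cf = unname(tree@cf[pres, s]),
               lineage = unname(lineage[pres]))
  }))
  if (is.null(comp))
    comp <- data.frame(sample_id = character(0), site_label = character(0),
                       cluster = character(0), cf = numeric(0),
                       lineage = character(0))

  terr <- lapply(stats::setNames(treeRoots(tree), treeRoots(tree)),
                 function(r) sort(unique(comp$site_label[comp$lineage == r])))
  list(composition = comp, territories = terr)
}

#' Read a site map TSV (sample_id, site_label, optional x, y)
#' @param path TSV path.
#' @return data.frame.
#' @export
readSiteMap <- function(path) {
  d <- utils::read.delim(path, colClasses = c(sample_id = "character"))
  if (!all(c("sample_id", "site_label") %in% names(d)))
    stop("site map needs columns sample_id, site_label")
  d
}
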