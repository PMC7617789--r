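# Independent oracles used across the suite. These re-derive expected
# behaviour by brute force and must stay independent of the implementation
# paths they check.

# Exact one-event transition distribution of the labeled count on a 2x2
# periodic lattice with von Neumann offsets: enumerate all 4 sites x 4
# neighbour slots (wrapped slots can coincide), each with probability 1/16.
enumerateTransition2x2 <- function(lab) {
  stopifnot(identical(dim(lab), c(2L, 2L)))
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  probs <- setNames(numeric(5), 0:4)
  for (r in 1:2) for (c in 1:2) for (k in 1:4) {
    rr <- ((r - 1L + offs[[k]][1L]) %% 2L) + 1L
    cc <- ((c - 1L + offs[[k]][2L]) %% 2L) + 1L
    nxt <- lab
    nxt[r, c] <- lab[rr, cc]
    key <- as.character(sum(nxt))
    probs[key] <- probs[key] + 1 / 16
  }
  probs
}

# Monte-Carlo distribution of the labeled count after one elementary event,
# nEvents independent single-event draws from the same start field.
mcTransition2x2 <- function(lab, nEvents, seed) {
  set.seed(seed)
  f0 <- LabelField(lab)
  counts <- setNames(numeric(5), 0:4)
  for (i in seq_len(nEvents)) {
    f1 <- elementaryEvent(f0)
    key <- as.character(sum(labelMatrix(f1)))
    counts[key] <- counts[key] + 1
  }
  counts / nEvents
}

# Exhaustive enumeration of all rooted forests over <= 5 clusters that are
# consistent with the pairwise nesting relation: each cluster's parent is
# either none or a cluster it nests in (strong or weak), and parent links
# are acyclic.
enumerateForests <- function(cf, epsilon = 0, presenceFloor = 0.01) {
  ids <- rownames(cf)
  K <- length(ids)
  hosts <- lapply(seq_len(K), function(i) {
    ok <- vapply(seq_len(K), function(j) {
      if (i == j) return(FALSE)
      nestingTest(cf[i, ], cf[j, ], epsilon, presenceFloor) != "independent"
    }, logical(1))
    c(NA_integer_, which(ok))
  })
  grids <- do.call(expand.grid, hosts)
  keep <- apply(grids, 1L, function(par) {
    for (i in seq_len(K)) {
      seen <- integer(0)
      p <- par[i]
      while (!is.na(p)) {
        if (p %in% seen) return(FALSE)
        seen <- c(seen, p)
        p <- par[p]
      }
    }
    TRUE
  })
  lapply(which(keep), function(r) {
    par <- as.integer(grids[r, ])
    ifelse(is.na(par), NA_character_, ids[par])
  })
}

# Map inferred clusters to true clones by majority vote of their members.
majorityCloneMap <- function(clustering, truthAssignments) {
  asg <- clusterAssignments(clustering)
  ids <- clustering@clusterIds
  vapply(seq_along(ids), function(k) {
    mem <- names(asg)[!is.na(asg) & asg == k]
    names(which.max(table(truthAssignments[mem])))
  }, character(1)) |> setNames(ids)
}

# RMSE between inferred cluster VAFs and the true clone VAFs (cf / 2),
# after majority-mapping clusters to clones.
thetaRMSE <- function(clustering, truth) {
  mp <- majorityCloneMap(clustering, truth$assignments)
  th <- clusterTheta(clustering)
  tru <- truth$cf[mp, , drop = FALSE] / 2
  sqrt(mean((th - tru)^2))
}

# Synthetic CloneClustering with given cluster sizes (for filter tests).
makeClustering <- function(sizes, nSamples = 2, theta = NULL) {
  K <- length(sizes)
  ids <- sprintf("c%d", seq_len(K))
  asg <- rep(seq_len(K), sizes)
  names(asg) <- sprintf("m%d", seq_along(asg))
  if (is.null(theta))
    theta <- matrix(seq(0.1, 0.4, length.out = K), K, nSamples,
                    dimnames = list(ids, sprintf("s%d", seq_len(nSamples))))
  new("CloneClustering", assignments = asg, clusterIds = ids,
      theta = theta, cf = computeCF(theta), nMutations = as.integer(sizes),
      diagnostics = list())
}
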