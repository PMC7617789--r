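#' Voter-model dynamics of the basal cell layer
#'
#' In the neutral model, stochastic loss of a basal cell through
#' differentiation is compensated by the duplication of a uniformly chosen
#' neighbour. In the non-neutral model a small fraction of fitter mutant
#' cells wins contested replacements: the replacing neighbour is drawn with
#' probability proportional to its genotype weight (normal = 1, fitter =
#' \code{selection}). With \code{selection = Inf} a fitter neighbour always
#' wins, fitter cells compete neutrally with each other, and a fitter site
#' with no fitter neighbour cannot be displaced by a normal lineage (the
#' loss event is a no-op), so the fitter area fraction never decreases.
#'
#' @param field a \linkS4class{LabelField}.
#' @param nEvents number of elementary loss/replacement events.
#' @param neighborhood 4 (von Neumann, default) or 8 (Moore).
#' @param mode \code{"neutral"} or \code{"non_neutral"}.
#' @param selection relative replacement weight of fitter cells
#'   (> 1; default \code{Inf}). Ignored in neutral mode.
#' @param seed optional integer; if given, \code{set.seed} is called first.
#' @return The field after \code{nEvents} events (time unchanged; use
#'   \code{\link{runSimulation}} for sweep bookkeeping).
#' @examples
#' f <- seedLabels(16, 16, labelFraction = 0.5, seed = 1)
#' f1 <- elementaryEvent(f, seed = 2)
#' @export
elementaryEvent <- function(field, nEvents = 1, neighborhood = 4,
                            mode = c("neutral", "non_neutral"),
                            selection = Inf, seed = NULL) {
  mode <- match.arg(mode)
  .checkDynamicsConfig(neighborhood, mode, selection)
  stopifnot(is(field, "LabelField"))
  if (!is.null(seed)) set.seed(seed)
  g <- voter_run(field@grid, as.numeric(nEvents), as.integer(neighborhood),
                 .boundaryCode(field@boundary), mode == "non_neutral",
                 selection)
  initialize(field, grid = g)
}

.checkDynamicsConfig <- function(neighborhood, mode, selection) {
  if (!neighborhood %in% c(4, 8))
    stop("neighborhood must be 4 (von Neumann) or 8 (Moore)")
  if (mode == "non_neutral" && !(selection > 1))
    stop("non-neutral mode requires selection > 1")
  invisible(TRUE)
}

#' Run a voter-model simulation
#'
#' Advances a \linkS4class{LabelField} by \code{nSweeps} Monte-Carlo sweeps
#' (1 sweep = nRows * nCols elementary events, random sequential update) and
#' returns snapshots at the requested sweep times.
#'
#' @inheritParams elementaryEvent
#' @param nSweeps total number of sweeps (0 returns the initial state).
#' @param snapshotSweeps sweep times at which to record snapshots
#'   (default: final sweep only). Must be within \code{[0, nSweeps]}.
#' @return A list of \linkS4class{LabelField} snapshots, one per requested
#'   time, named by sweep; reproducible bit-for-bit under a fixed seed.
#' @examples
#' f <- seedLabels(32, 32, labelFraction = 0.5, seed = 1)
#' snaps <- runSimulation(f, nSweeps = 10, snapshotSweeps = c(5, 10), seed = 1)
#' @export
runSimulation <- function(field, nSweeps, snapshotSweeps = nSweeps,
                          neighborhood = 4,
                          mode = c("neutral", "non_neutral"),
                          selection = Inf, seed = NULL) {
  mode <- match.arg(mode)
  .checkDynamicsConfig(neighborhood, mode, selection)
  stopifnot(is(field, "LabelField"))
  if (nSweeps < 0) stop("nSweeps must be non-negative")
  snapshotSweeps <- sort(unique(as.numeric(snapshotSweeps)))
  if (any(snapshotSweeps < 0) || any(snapshotSweeps > nSweeps))
    stop("snapshot times must lie in [0, nSweeps]")
  if (!is.null(seed)) set.seed(seed)

  N <- prod(dim(field))
  out <- vector("list", length(snapshotSweeps))
  names(out) <- as.character(snapshotSweeps)
  cur <- field@grid
  last <- 0
  for (i in seq_along(snapshotSweeps)) {
    t <- snapshotSweeps[i]
    if (t > last) {
      cur <- voter_run(cur, (t - last) * N, as.integer(neighborhood),
                       .boundaryCode(field@boundary), mode == "non_neutral",
                       selection)
      last <- t
    }
    out[[i]] <- initialize(field, grid = cur, time = field@time + t)
  }
  out
}

#' Run a replicate ensemble of voter-model simulations
#'
#' Seeds, simulates and summarizes \code{nReplicates} independent lattices;
#' replicate r uses seed \code{seed + r}, so the ensemble is reproducible and
#' embarrassingly parallel in principle. This is the workhorse behind the
#' ensemble void-size statistics (the study compares data against 200 such
#' simulations).
#'
#' @inheritParams runSimulation
#' @param nRows,nCols lattice dimensions.
#' @param labelFraction Bernoulli labeling fraction at sweep 0.
#' @param fitterFraction fraction of cells seeded as fitter mutants (0 for
#'   the neutral model).
#' @param nReplicates number of independent replicates.
#' @param seed base integer seed.
#' @param minVoidSize passed to \code{\link{findVoids}} on each final field.
#' @param boundary lattice boundary mode.
#' @return A list with per-replicate elements: \code{voidSizes} (integer
#'   vector), \code{initialLabeled}, \code{finalLabeled},
#'   \code{finalFitter}; plus \code{params}.
#' @export
voterEnsemble <- function(nRows, nCols, labelFraction, nSweeps, nReplicates,
                          seed, mode = c("neutral", "non_neutral"),
                          fitterFraction = 0, selection = Inf,
                          neighborhood = 4, boundary = "periodic-both",
                          minVoidSize = 2) {
  mode <- match.arg(mode)
  if (mode == "neutral" && fitterFraction != 0)
    stop("neutral mode requires fitterFraction = 0")
  .checkDynamicsConfig(neighborhood, mode, selection)
  res <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    set.seed(seed + r)
    f <- seedLabels(nRows, nCols, labelFraction = labelFraction,
                    boundary = boundary)
    if (fitterFraction > 0)
      f <- seedGenotypes(f, fitterFraction)
    fin <- runSimulation(f, nSweeps, mode = mode, selection = selection,
                         neighborhood = neighborhood)[[1L]]
    vd <- findVoids(fin, connectivity = neighborhood, minSize = minVoidSize)
    res[[r]] <- list(voidSizes = voidSizes(vd),
                     initialLabeled = labeledFraction(f),
                     finalLabeled = labeledFraction(fin),
                     finalFitter = fitterFraction(fin))
  }
  list(replicates = res,
       params = list(nRows = nRows, nCols = nCols,
                     labelFraction = labelFraction, nSweeps = nSweeps,
                     nReplicates = nReplicates, seed = seed, mode = mode,
                     fitterFraction = fitterFraction, selection = selection,
                     neighborhood = neighborhood, boundary = boundary,
                     minVoidSize = minVoidSize))
}
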