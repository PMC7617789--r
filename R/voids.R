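#' Identify voids (connected clusters of unlabeled cells)
#'
#' Finds connected components of unlabeled cells under the stated
#' connectivity, honouring the field's boundary (components wrap across
#' periodic edges), and drops components smaller than \code{minSize}
#' (default 2: only regions larger than one cell are analyzed).
#'
#' @param field a \linkS4class{LabelField}.
#' @param connectivity 4 or 8; defaults to the canonical simulation
#'   neighbourhood (4).
#' @param minSize smallest void size retained.
#' @return A \linkS4class{VoidDistribution}.
#' @examples
#' f <- seedLabels(64, 64, labelFraction = 0.5, seed = 1)
#' findVoids(f)
#' @export
findVoids <- function(field, connectivity = 4, minSize = 2) {
  stopifnot(is(field, "LabelField"))
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  sizes <- void_sizes_cpp(field@grid, as.integer(connectivity),
                          .boundaryCode(field@boundary))
  exceedanceCurve(sizes, minSize = minSize)
}

#' Cumulative exceedance curve of void sizes
#'
#' Builds the empirical curve P(S >= s) = (# voids of size >= s) / (#
#' retained voids), evaluated at each distinct retained size. An input that
#' is empty after filtering yields an explicit empty distribution.
#'
#' @param sizes integer vector of void sizes.
#' @param minSize smallest size retained (default 2).
#' @return A \linkS4class{VoidDistribution}.
#' @examples
#' exceedanceTable(exceedanceCurve(c(2, 2, 4, 8)))
#' @export
exceedanceCurve <- function(sizes, minSize = 2) {
  sizes <- as.integer(sizes[sizes >= minSize])
  if (!length(sizes))
    return(new("VoidDistribution", sizes = integer(0),
               minSize = as.integer(minSize),
               table = data.frame(size = integer(0), exceedance = numeric(0))))
  s <- sort(unique(sizes))
  n <- length(sizes)
  exceed <- vapply(s, function(x) sum(sizes >= x) / n, numeric(1))
  new("VoidDistribution", sizes = sizes, minSize = as.integer(minSize),
      table = data.frame(size = s, exceedance = exceed))
}

#' @describeIn exceedanceCurve retained void sizes of a VoidDistribution.
#' @param x a \linkS4class{VoidDistribution}.
#' @export
voidSizes <- function(x) x@sizes

#' @describeIn exceedanceCurve the (size, exceedance) table.
#' @export
exceedanceTable <- function(x) x@table

setMethod("show", "VoidDistribution", function(object) {
  cat(sprintf("VoidDistribution: %d voids >= %d cells",
              length(object@sizes), object@minSize))
  if (length(object@sizes))
    cat(sprintf("; sizes %d..%d", min(object@sizes), max(object@sizes)))
  cat("\n")
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: exponent %.3f (R^2 = %.3f) over sizes [%g, %g], %d points\n",
    object@exponent, object@rSquared, object@fitRange[1L],
    object@fitRange[2L], object@nPoints))
})

#' Fit a power law to an exceedance curve
#'
#' Least-squares regression of log10 P(S >= s) on log10 s over distinct
#' sizes inside \code{fitRange}. Under neutral competition in 2D the
#' cumulative void-size distribution follows a power law with exponent
#' around -1; non-neutral expansions bend the curve towards heavier tails.
#'
#' @param dist a \linkS4class{VoidDistribution}.
#' @param fitRange inclusive size range (default c(2, 100)).
#' @return A \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(dist, fitRange = c(2, 100)) {
  stopifnot(is(dist, "VoidDistribution"))
  tb <- dist@table
  tb <- tb[tb$size >= fitRange[1L] & tb$size <= fitRange[2L] &
             tb$exceedance > 0, , drop = FALSE]
  if (nrow(tb) < 3L)
    stop("power-law fit requires at least 3 distinct sizes in fitRange (got ",
         nrow(tb), ")")
  fit <- stats::lm(log10(exceedance) ~ log10(size), data = tb)
  y <- log10(tb$exceedance)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  new("PowerLawFit",
      exponent = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2,
      fitRange = as.numeric(fitRange), nPoints = nrow(tb))
}

#' Score observed void data against a model ensemble
#'
#' Evaluates each ensemble replicate's exceedance curve at the observed
#' distinct sizes by log-log linear interpolation, averages across
#' replicates, and reports R^2 = 1 - SS_res / SS_tot computed on log10
#' exceedance values (observed vs. ensemble mean). Observed sizes covered by
#' fewer than \code{minCoverage} of the replicate curves are excluded from
#' R^2 and reported in \code{excludedSizes}.
#'
#' @param observed a \linkS4class{VoidDistribution}.
#' @param ensemble a list of \linkS4class{VoidDistribution} replicates.
#' @param minCoverage minimum fraction of replicate curves that must span an
#'   observed size for it to enter the comparison (default 0.5).
#' @return A list: \code{rSquared}; \code{curve} (data.frame with size,
#'   observed and ensemble mean/sd log10 exceedance); \code{excludedSizes};
#'   \code{nEnsemble}.
#' @export
compareToModel <- function(observed, ensemble, minCoverage = 0.5) {
  stopifnot(is(observed, "VoidDistribution"))
  if (!length(ensemble)) stop("ensemble must be non-empty")
  obs <- observed@table
  if (!nrow(obs)) stop("observed distribution is empty")

  logs <- log10(obs$size)
  interp <- vapply(ensemble, function(d) {
    tb <- exceedanceTable(d)
    tb <- tb[tb$exceedance > 0, , drop = FALSE]
    if (nrow(tb) < 2L) return(rep(NA_real_, length(logs)))
    out <- stats::approx(log10(tb$size), log10(tb$exceedance), xout = logs,
                         rule = 1)$y
    out
  }, numeric(length(logs)))
  interp <- matrix(interp, nrow = length(logs))

  coverage <- rowMeans(!is.na(interp))
  keep <- coverage >= minCoverage
  if (!any(keep))
    stop("no overlapping size support between observed data and ensemble")

  mu <- rowMeans(interp, na.rm = TRUE)
  sdv <- apply(interp, 1L, stats::sd, na.rm = TRUE)
  obsLog <- log10(obs$exceedance)
  ssRes <- sum((obsLog[keep] - mu[keep])^2)
  ssTot <- sum((obsLog[keep] - mean(obsLog[keep]))^2)
  r2 <- 1 - ssRes / ssTot

  list(rSquared = r2,
       curve = data.frame(size = obs$size, observedLog10 = obsLog,
                          modelMeanLog10 = mu, modelSdLog10 = sdv,
                          coverage = coverage, used = keep),
       excludedSizes = obs$size[!keep],
       nEnsemble = length(ensemble))
}

#' Read/write exceedance curves and fits
#'
#' Curves are two-column TSVs (\code{size}, \code{exceedance}); fits are
#' JSON with exponent, r_squared, fit_range and n_voids.
#'
#' @param path file path.
#' @return \code{readExceedance} returns a \linkS4class{VoidDistribution}
#'   rebuilt from the tabulated curve (distinct sizes, counts recovered from
#'   the exceedance steps).
#' @export
readExceedance <- function(path) {
  tb <- utils::read.delim(path)
  stopifnot(all(c("size", "exceedance") %in% names(tb)))
  d <- new("VoidDistribution", sizes = integer(0),
           minSize = if (nrow(tb)) as.integer(min(tb$size)) else 2L,
           table = tb[order(tb$size), c("size", "exceedance")])
  d
}

#' @rdname readExceedance
#' @param dist a \linkS4class{VoidDistribution}.
#' @export
writeExceedance <- function(dist, path) {
  utils::write.table(exceedanceTable(dist), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readExceedance
#' @param fit a \linkS4class{PowerLawFit}.
#' @param nVoids optional void count to record.
#' @export
writePowerLawFit <- function(fit, path, nVoids = NA_integer_) {
  jsonlite::write_json(
    list(exponent = fit@exponent, r_squared = fit@rSquared,
         intercept = fit@intercept, fit_range = fit@fitRange,
         n_points = fit@nPoints, n_voids = nVoids),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
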