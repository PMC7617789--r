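#' Construct a LabelField
#'
#' @param labels 0/1 matrix (or logical) of mosaic lineage labels.
#' @param genotypes 0/1 matrix of genotypes (0 normal, 1 fitter); a scalar is
#'   recycled. Default all-normal.
#' @param boundary boundary mode, see \linkS4class{LabelField}.
#' @param time elapsed time in Monte-Carlo sweeps.
#' @return A \linkS4class{LabelField}.
#' @examples
#' f <- LabelField(matrix(rbinom(100, 1, 0.3), 10, 10))
#' labeledFraction(f)
#' @export
LabelField <- function(labels, genotypes = 0L,
                       boundary = c("periodic-both",
                                    "periodic-cols-reflecting-rows",
                                    "closed"),
                       time = 0) {
  labels <- .asBitMatrix(labels, "labels")
  if (length(genotypes) == 1L)
    genotypes <- matrix(as.integer(genotypes), nrow(labels), ncol(labels))
  genotypes <- .asBitMatrix(genotypes, "genotypes")
  if (!identical(dim(labels), dim(genotypes)))
    stop("labels and genotypes must have the same dimensions")
  new("LabelField", grid = 2L * genotypes + labels,
      boundary = match.arg(boundary), time = as.numeric(time))
}

.asBitMatrix <- function(m, what) {
  if (is.logical(m)) m[] <- as.integer(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric or logical matrix")
  if (!all(m %in% c(0, 1)))
    stop(what, " must contain only 0/1 values")
  storage.mode(m) <- "integer"
  m
}

#' @describeIn LabelField matrix of label bits (1 = labeled).
#' @param x a LabelField.
#' @export
labelMatrix <- function(x) x@grid %% 2L

#' @describeIn LabelField matrix of genotype bits (1 = fitter).
#' @export
genotypeMatrix <- function(x) x@grid %/% 2L

#' @describeIn LabelField fraction of labeled cells.
#' @export
labeledFraction <- function(x) mean(x@grid %% 2L)

#' @describeIn LabelField fraction of fitter-mutant cells.
#' @export
fitterFraction <- function(x) mean(x@grid %/% 2L)

#' @describeIn LabelField boundary mode string.
#' @export
fieldBoundary <- function(x) x@boundary

#' @describeIn LabelField elapsed time in sweeps.
#' @export
fieldTime <- function(x) x@time

setMethod("dim", "LabelField", function(x) dim(x@grid))

setMethod("show", "LabelField", function(object) {
  cat(sprintf(
    "LabelField: %d x %d cells (%s), t = %g sweeps\n",
    nrow(object@grid), ncol(object@grid), object@boundary, object@time))
  cat(sprintf("  labeled fraction: %.4f; fitter fraction: %.4f\n",
              labeledFraction(object), fitterFraction(object)))
})

#' Seed a mosaic labeling pattern
#'
#' Emulates the tamoxifen-induced mosaic labeling of the basal layer at the
#' start of a lineage-tracing experiment.
#'
#' @param nRows,nCols lattice dimensions.
#' @param mode \code{"bernoulli"} for i.i.d. labels at \code{labelFraction};
#'   \code{"clustered"} for small contiguous seed clones (delegates to
#'   \code{\link{generateLabelField}}); \code{"from_mask"} to copy a supplied
#'   0/1 matrix.
#' @param labelFraction target labeled fraction in [0, 1].
#' @param mask 0/1 matrix for \code{mode = "from_mask"}.
#' @param cloneSeedSize patch size for \code{mode = "clustered"}.
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @param boundary boundary mode of the returned field.
#' @return A \linkS4class{LabelField} at time 0.
#' @examples
#' f <- seedLabels(64, 64, labelFraction = 0.5, seed = 1)
#' @export
seedLabels <- function(nRows, nCols,
                       mode = c("bernoulli", "clustered", "from_mask"),
                       labelFraction = NULL, mask = NULL, cloneSeedSize = 3L,
                       seed = NULL,
                       boundary = "periodic-both") {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "from_mask") {
    if (is.null(mask)) stop("mode 'from_mask' requires a mask")
    if (!all(mask %in% c(0, 1)))
      stop("mask must contain only 0/1 values")
    if (!missing(nRows) &&
        !identical(dim(mask), as.integer(c(nRows, nCols))))
      stop("mask dimensions do not match nRows/nCols")
    return(LabelField(mask, boundary = boundary))
  }
  if (is.null(labelFraction) || labelFraction < 0 || labelFraction > 1)
    stop("labelFraction must lie in [0, 1]")
  if (mode == "bernoulli") {
    lab <- matrix(rbinom(nRows * nCols, 1L, labelFraction), nRows, nCols)
    return(LabelField(lab, boundary = boundary))
  }
  generateLabelField(nRows, nCols, fraction = labelFraction,
                     cloneSeedSize = cloneSeedSize,
                     boundary = boundary)$field
}

#' Seed fitter-mutant genotypes
#'
#' Assigns each cell the fitter genotype independently with probability
#' \code{fitterFraction}, leaving labels untouched: a small fraction of
#' fitter mutant clones distributed randomly in the system.
#'
#' @param field a \linkS4class{LabelField}.
#' @param fitterFraction probability in [0, 1].
#' @param seed optional integer; if given, \code{set.seed} is called.
#' @return The field with genotypes redrawn.
#' @export
seedGenotypes <- function(field, fitterFraction, seed = NULL) {
  stopifnot(is(field, "LabelField"))
  if (fitterFraction < 0 || fitterFraction > 1)
    stop("fitterFraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rbinom(prod(dim(field)), 1L, fitterFraction),
              nrow(field@grid), ncol(field@grid))
  LabelField(labelMatrix(field), g, boundary = field@boundary,
             time = field@time)
}

#' Read/write label fields as integer CSV matrices
#'
#' Fields are stored as plain CSV matrices of cell codes
#' \code{2 * genotype + label} (0 = unlabeled normal ... 3 = labeled fitter),
#' without headers.
#'
#' @param path file path.
#' @param boundary,time metadata to attach on read (not stored in the CSV).
#' @return \code{readLabelField} returns a \linkS4class{LabelField};
#'   \code{writeLabelField} returns \code{path} invisibly.
#' @export
readLabelField <- function(path, boundary = "periodic-both", time = 0) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  new("LabelField", grid = m, boundary = boundary, time = as.numeric(time))
}

#' @rdname readLabelField
#' @param field a \linkS4class{LabelField} to write.
#' @export
writeLabelField <- function(field, path) {
  stopifnot(is(field, "LabelField"))
  utils::write.table(field@grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
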