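#' Build a signal dictionary over a parameter grid
#'
#' Simulates one signal evolution per grid atom through the pulse train.
#' "Si" mode uses the single-spin simulator with instantaneous pulses; "Mu"
#' mode runs the slab ensemble through the discretized RF waveforms and
#' returns the signals of one slice position (see \code{\link{simulateMu}}).
#'
#' @param grid a \linkS4class{ParamGrid}
#' @param train a \linkS4class{PulseTrain}
#' @param mode "Si" or "Mu"
#' @param ensemble a \linkS4class{SlabEnsemble} (required for Mu)
#' @param sliceIndex slice position in 1..nZencodes (required for Mu)
#' @param hardPulseMaxDeg maximum rotation per hard-pulse sub-step, degrees
#' @return a \linkS4class{SignalDictionary}
#' @export
buildDictionary <- function(grid, train, mode = c("Si", "Mu"), ensemble = NULL,
                            sliceIndex = NULL, hardPulseMaxDeg = 2) {
  mode <- match.arg(mode)
  thetaMat <- as.matrix(grid@atoms[, c("t1", "t2", "delta", "b1")])
  if (mode == "Si") {
    tl <- buildEventTimeline(train, instantAll = TRUE)
    out <- .runBloch(tl, thetaMat, 0, matrix(1 + 0i, 1, 1))
    sig <- matrix(as.complex(out), tl$nq, nrow(thetaMat))
    sliceIndex <- NA_integer_
    ensemble <- NULL
  } else {
    if (is.null(ensemble) || is.null(sliceIndex))
      stop("Mu mode requires an ensemble and a sliceIndex")
    sel <- any(vapply(train@block@pulses,
                      function(p) p@selective && p@duration > 0, logical(1)))
    w <- zencodeWeights(ensemble)[, sliceIndex, drop = FALSE]
    if (!sel) {
      tl <- buildEventTimeline(train, slabWidth = ensemble@slabWidth,
                               hardPulseMaxDeg = hardPulseMaxDeg)
      out <- .runBloch(tl, thetaMat, 0, matrix(1 + 0i, 1, 1))
      sig <- sum(w) * matrix(as.complex(out), tl$nq, nrow(thetaMat))
    } else {
      tl <- buildEventTimeline(train, slabWidth = ensemble@slabWidth,
                               hardPulseMaxDeg = hardPulseMaxDeg)
      out <- .runBloch(tl, thetaMat, subspinPositions(ensemble), w)
      sig <- matrix(as.complex(out), tl$nq, nrow(thetaMat))
    }
    sliceIndex <- as.integer(sliceIndex)
  }
  new("SignalDictionary", atomSignals = sig, grid = grid, mode = mode,
      sliceIndex = sliceIndex, atomNorms = sqrt(colSums(abs(sig)^2)),
      train = train, ensemble = ensemble)
}

#' Truncated SVD of the dictionary contrast dimension
#'
#' Computes the singular value decomposition of the nContrasts x nAtoms atom
#' matrix and keeps the first d1 components; the left singular vectors are
#' the temporal basis of the subspace-constrained reconstruction. All
#' singular values are retained so the captured-energy fraction can be
#' evaluated at any order.
#'
#' @param dict a \linkS4class{SignalDictionary}
#' @param d1 truncation order, 1 <= d1 <= nContrasts
#' @return a \linkS4class{ContrastSubspace}
#' @export
computeSubspace <- function(dict, d1 = 12) {
  nq <- nrow(dict@atomSignals)
  if (d1 < 1 || d1 > nq) stop("d1 must lie in [1, nContrasts]")
  sv <- svd(dict@atomSignals)
  d1 <- as.integer(d1)
  new("ContrastSubspace", basis = sv$u[, seq_len(d1), drop = FALSE],
      singularValues = sv$d, vFactor = sv$v[, seq_len(d1), drop = FALSE],
      d1 = d1)
}

#' Fraction of squared singular-value energy in the leading components
#'
#' @param x a \linkS4class{ContrastSubspace} or \linkS4class{PhaseSubspace}
#' @param d number of leading components
#' @return numeric in [0, 1], non-decreasing in d
#' @export
setGeneric("energyFraction", function(x, d) standardGeneric("energyFraction"))

#' @rdname energyFraction
#' @export
setMethod("energyFraction", "ContrastSubspace", function(x, d) {
  s2 <- x@singularValues^2
  sum(s2[seq_len(min(d, length(s2)))]) / sum(s2)
})

#' @rdname energyFraction
#' @export
setMethod("energyFraction", "PhaseSubspace", function(x, d) {
  s2 <- x@sTilde^2
  sum(s2[seq_len(min(d, length(s2)))]) / sum(s2)
})

#' Save / load a dictionary container
#'
#' Serializes the dictionary (atom signals, grid axes, mode, slice index,
#' train configuration) to a single binary container file.
#'
#' @param dict a \linkS4class{SignalDictionary}
#' @param path file path
#' @export
saveDictionary <- function(dict, path) saveRDS(dict, path)

#' @rdname saveDictionary
#' @export
loadDictionary <- function(path) {
  d <- readRDS(path)
  if (!is(d, "SignalDictionary")) stop("file does not contain a dictionary")
  d
}

setMethod("show", "SignalDictionary", function(object) {
  cat(sprintf("SignalDictionary (%s): %d contrasts x %d atoms%s\n",
              object@mode, nrow(object@atomSignals), ncol(object@atomSignals),
              if (!is.na(object@sliceIndex))
                sprintf(", slice %d", object@sliceIndex) else ""))
})

setMethod("show", "ContrastSubspace", function(object) {
  cat(sprintf("ContrastSubspace: d1 = %d of %d contrasts, energy %.4f\n",
              object@d1, nrow(object@basis),
              energyFraction(object, object@d1)))
})
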