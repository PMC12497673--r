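# Synthetic k-space generation under the off-resonance readout model: the
# echo-state magnetization of each voxel is constant over a readout except
# for the B0 phase exp(-i 2 pi Delta_v tau_p) accrued at its off-resonance
# (within-readout relaxation is neglected, a documented fidelity limit of
# the signal model). Each sample of contrast q and coil c is
#   Y[q, c, p] = sum_v C[c, v] M[q, v] exp(-i 2 pi Delta_v tau_p)
#                * exp(-i 2 pi k_p . r_v / N)  (+ complex Gaussian noise).

#' Simulate echo-state images for every voxel of a parameter map
#'
#' Runs the single-spin simulator for each distinct masked tissue-parameter
#' combination and fills an nContrasts x nVoxels matrix (column-major voxel
#' order); masked-out voxels are zero.
#'
#' @param pmap a \linkS4class{ParamMap}
#' @param train a \linkS4class{PulseTrain}
#' @return complex matrix, nContrasts x nVoxels
#' @export
simulateVoxelSignals <- function(pmap, train) {
  nq <- nContrasts(train)
  nv <- length(pmap@mask)
  M <- matrix(0 + 0i, nq, nv)
  sel <- which(pmap@mask)
  if (!length(sel)) return(M)
  key <- paste(pmap@t1[sel], pmap@t2[sel], pmap@delta[sel], pmap@b1[sel])
  uk <- !duplicated(key)
  thetaMat <- cbind(pmap@t1[sel][uk], pmap@t2[sel][uk],
                    pmap@delta[sel][uk], pmap@b1[sel][uk])
  tl <- buildEventTimeline(train, instantAll = TRUE)
  sig <- matrix(as.complex(.runBloch(tl, thetaMat, 0, matrix(1 + 0i, 1, 1))),
                nq, nrow(thetaMat))
  M[, sel] <- sig[, match(key, key[uk])] *
    rep(pmap@i0[sel], each = nq)
  M
}

#' Synthesize undersampled multi-coil k-space data
#'
#' Applies the forward acquisition model to a digital phantom: single-spin
#' echo-state signals per contrast, coil weighting, per-sample off-resonance
#' phase over the readout, exact non-uniform Fourier encoding along the
#' scheduled interleaves, and optional i.i.d. complex Gaussian noise with a
#' stored seed. With \code{noiseSd = 0} the synthesis is deterministic.
#'
#' @param pmap a \linkS4class{ParamMap}
#' @param train a \linkS4class{PulseTrain}
#' @param op a \linkS4class{SamplingOperator}
#' @param coils a \linkS4class{CoilMaps}
#' @param noiseSd complex-noise standard deviation per real/imaginary part
#' @param seed RNG seed used when noise is drawn
#' @return a \linkS4class{KSpaceData}
#' @export
synthesizeKspace <- function(pmap, train, op, coils, noiseSd = 0, seed = 1L) {
  M <- simulateVoxelSignals(pmap, train)
  synthesizeFromSignals(M, pmap@delta, op, coils, noiseSd = noiseSd,
                        seed = seed)
}

#' @rdname synthesizeKspace
#' @param signals complex matrix of echo-state signals, nContrasts x nVoxels
#' @param deltaMap off-resonance map (matrix or vector, Hz)
#' @export
synthesizeFromSignals <- function(signals, deltaMap, op, coils, noiseSd = 0,
                                  seed = 1L) {
  nq <- nrow(signals)
  nv <- prod(op@gridShape)
  if (ncol(signals) != nv) stop("signals do not match the operator grid")
  cm <- matrix(coils@maps, nv)  # nv x nCoils
  nc <- ncol(cm)
  tau <- op@trajectory@tau
  ns <- length(tau)
  apc <- op@schedule@armsPerContrast
  # within-readout phase, sample x voxel (exact, no subspace truncation)
  W <- exp(-2i * pi * outer(tau / 1000, as.numeric(deltaMap)))
  Y <- array(0 + 0i, dim = c(nq, nc, ns * apc))
  for (q in seq_len(nq)) {
    arms <- op@schedule@armIndex[q, ] + 1L
    E <- do.call(rbind, lapply(arms, function(a) op@armMatrices[[a]] * W))
    X <- cm * signals[q, ]               # nv x nCoils
    Y[q, , ] <- t(E %*% X)
  }
  seed <- as.integer(seed)
  if (noiseSd > 0) {
    set.seed(seed)
    n <- length(Y)
    Y <- Y + noiseSd * (rnorm(n) + 1i * rnorm(n))
  }
  new("KSpaceData", samples = Y, trajectory = op@trajectory,
      schedule = op@schedule, noiseSd = noiseSd,
      seed = if (noiseSd > 0) seed else NA_integer_)
}

#' Save / load a k-space container
#'
#' Serializes samples, trajectory, schedule and acquisition metadata to a
#' single binary container file.
#' @param kdata a \linkS4class{KSpaceData}
#' @param path file path
#' @export
saveKSpace <- function(kdata, path) saveRDS(kdata, path)

#' @rdname saveKSpace
#' @export
loadKSpace <- function(path) {
  k <- readRDS(path)
  if (!is(k, "KSpaceData")) stop("file does not contain k-space data")
  k
}

setMethod("show", "KSpaceData", function(object) {
  d <- dim(object@samples)
  cat(sprintf("KSpaceData: %d contrasts x %d coils x %d samples, noise sd %g\n",
              d[1], d[2], d[3], object@noiseSd))
})
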