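# Per-contrast non-uniform Fourier encoding.
#
# Image coordinates are 0-based and FOV-centered (r = index - N/2 in pixel
# units), k is in cycles/FOV, and the forward phase convention is
# exp(-i 2 pi k . r / N). The operator is an exact non-uniform DFT: each of
# the nArmsFull rotated interleaves gets one precomputed nSamples x nVoxels
# matrix, and a contrast's forward map stacks the matrices of its scheduled
# arms. Exactness makes the adjoint the conjugate transpose by construction.

.voxelCoords <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]
  x <- (seq_len(nx) - 1) - nx / 2
  y <- (seq_len(ny) - 1) - ny / 2
  list(x = rep(x, times = ny), y = rep(y, each = nx))
}

# exact non-uniform DFT matrix for arbitrary k rows (cycles/FOV)
.dftMatrix <- function(k, gridShape) {
  r <- .voxelCoords(gridShape)
  nx <- gridShape[1]; ny <- gridShape[2]
  exp(-2i * pi * (outer(k[, 1], r$x / nx) + outer(k[, 2], r$y / ny)))
}

#' Build the per-contrast sampling operator
#'
#' Precomputes the exact non-uniform DFT matrix of every rotated interleave
#' (arm a is the base spiral rotated by 2 pi a / nArmsFull) on the given
#' image grid; the forward and adjoint maps of each contrast stack/sum the
#' matrices of the arms in its schedule.
#'
#' @param traj a \linkS4class{SpiralTrajectory}
#' @param schedule an \linkS4class{UndersamplingSchedule}
#' @param gridShape integer length-2 image grid shape
#' @return a \linkS4class{SamplingOperator}
#' @export
buildOperator <- function(traj, schedule, gridShape) {
  if (schedule@nArmsFull != traj@nArmsFull)
    stop("schedule and trajectory disagree on the number of arms")
  gridShape <- as.integer(gridShape)
  if (max(sqrt(rowSums(traj@kCoords^2))) > min(gridShape) / 2 + 1e-9)
    stop("trajectory exceeds the Nyquist extent of the image grid")
  arms <- lapply(0:(traj@nArmsFull - 1L), function(a) {
    .dftMatrix(rotateArm(traj, 2 * pi * a / traj@nArmsFull)@kCoords, gridShape)
  })
  new("SamplingOperator", gridShape = gridShape, trajectory = traj,
      schedule = schedule, armMatrices = arms)
}

#' Number of k-space samples per contrast of an operator
#' @param op a \linkS4class{SamplingOperator}
#' @export
samplesPerContrast <- function(op) {
  op@schedule@armsPerContrast * nrow(op@trajectory@kCoords)
}

#' Radial density-compensation weights of a contrast's samples
#'
#' Sample weights proportional to the local k-space cell area of the
#' constant-pitch spiral (|k| with a half-cell floor at the center),
#' normalized to unit mean, repeated per scheduled arm. Used to
#' precondition the conjugate-gradient normal equations; for consistent
#' (noiseless, full-rank) systems the weighted and unweighted least-squares
#' solutions coincide while convergence improves markedly.
#'
#' @param op a \linkS4class{SamplingOperator}
#' @export
dcfWeights <- function(op) {
  r <- sqrt(rowSums(op@trajectory@kCoords^2))
  w <- r + max(r) / (2 * length(r))
  w <- w / mean(w)
  rep(w, op@schedule@armsPerContrast)
}

#' Within-readout time offsets of a contrast's samples (ms)
#'
#' Sample p of every scheduled arm is acquired tau_p after the echo state;
#' the offsets repeat per arm.
#' @param op a \linkS4class{SamplingOperator}
#' @export
sampleTimes <- function(op) rep(op@trajectory@tau, op@schedule@armsPerContrast)

#' Forward non-uniform Fourier map of one contrast
#'
#' @param op a \linkS4class{SamplingOperator}
#' @param x complex matrix (image on the grid) or vector of length nVoxels,
#'   or a matrix with nVoxels rows (one column per field to transform)
#' @param q contrast index (1-based)
#' @return complex matrix, samplesPerContrast x ncol(x)
#' @export
opForward <- function(op, x, q) {
  x <- .asVoxelMatrix(op, x)
  arms <- op@schedule@armIndex[q, ] + 1L
  do.call(rbind, lapply(arms, function(a) op@armMatrices[[a]] %*% x))
}

#' Adjoint non-uniform Fourier map of one contrast
#'
#' @param op a \linkS4class{SamplingOperator}
#' @param y complex matrix, samplesPerContrast x nFields (or vector)
#' @param q contrast index (1-based)
#' @return complex matrix, nVoxels x nFields
#' @export
opAdjoint <- function(op, y, q) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  arms <- op@schedule@armIndex[q, ] + 1L
  ns <- nrow(op@trajectory@kCoords)
  acc <- matrix(0 + 0i, prod(op@gridShape), ncol(y))
  for (i in seq_along(arms)) {
    rows <- ((i - 1L) * ns + 1L):(i * ns)
    acc <- acc + crossprod(Conj(op@armMatrices[[arms[i]]]),
                           y[rows, , drop = FALSE])
  }
  acc
}

.asVoxelMatrix <- function(op, x) {
  nv <- prod(op@gridShape)
  if (is.matrix(x) && all(dim(x) == op@gridShape)) return(matrix(as.complex(x), nv, 1))
  if (is.matrix(x) && nrow(x) == nv) return(x)
  if (length(x) == nv) return(matrix(as.complex(x), nv, 1))
  stop("image does not match the operator grid")
}

setMethod("show", "SamplingOperator", function(object) {
  cat(sprintf(
    "SamplingOperator: grid %dx%d, %d arms precomputed, %d samples/contrast\n",
    object@gridShape[1], object@gridShape[2], length(object@armMatrices),
    samplesPerContrast(object)))
})
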