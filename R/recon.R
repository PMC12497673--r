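# Linear reconstructions solved by conjugate gradient on the normal
# equations (zero initialization, relative-residual stopping). The forward
# acquisition model shared by all solvers maps voxel images to scheduled
# k-space samples through coil weighting, an optional truncated phase
# subspace for within-readout off-resonance, and the per-contrast
# non-uniform DFT.

#' Truncated SVD of the within-readout off-resonance phase matrix
#'
#' Forms exp(-i 2 pi Delta_v tau_p) (sample x voxel) for the given
#' off-resonance map and sample times and keeps the leading d2 components.
#' If d2 is NULL, the smallest order whose squared singular-value energy
#' reaches \code{energyTol} is chosen, capped at \code{maxD2}. For very
#' large voxel counts the left basis is computed on a regular voxel
#' subsample and the right factor by projection (exact when the subsample
#' spans the map's off-resonance range).
#'
#' @param deltaMap off-resonance map, Hz (matrix or vector)
#' @param tau within-readout sample times, ms (tau[1] = 0)
#' @param d2 truncation order, or NULL for automatic selection
#' @param energyTol energy fraction target for automatic d2
#' @param maxD2 cap for automatic d2
#' @param maxVoxelsExact largest voxel count decomposed without subsampling
#' @return a \linkS4class{PhaseSubspace}
#' @export
phaseSubspace <- function(deltaMap, tau, d2 = NULL, energyTol = 0.999,
                          maxD2 = 16L, maxVoxelsExact = 16384L) {
  delta <- as.numeric(deltaMap)
  nv <- length(delta)
  sub <- if (nv > maxVoxelsExact)
    seq.int(1L, nv, length.out = maxVoxelsExact) else seq_len(nv)
  W <- exp(-2i * pi * outer(tau / 1000, delta[sub]))
  sv <- svd(W)
  s2 <- sv$d^2
  if (is.null(d2)) {
    d2 <- which(cumsum(s2) / sum(s2) >= energyTol)[1]
    if (is.na(d2)) d2 <- length(s2)
    d2 <- min(d2, maxD2)
  }
  d2 <- as.integer(max(1L, d2))
  u <- sv$u[, seq_len(d2), drop = FALSE]
  if (nv > length(sub)) {
    Wf <- exp(-2i * pi * outer(tau / 1000, delta))
    v <- crossprod(Conj(Wf), u) %*% diag(1 / sv$d[seq_len(d2)], d2)
  } else {
    v <- sv$v[, seq_len(d2), drop = FALSE]
  }
  new("PhaseSubspace", uTilde = u, sTilde = sv$d, vTilde = v, d2 = d2)
}

# uTilde rows expanded to the stacked samples of a contrast (repeat per arm)
.expandPhaseBasis <- function(phase, op) {
  ns <- nrow(op@trajectory@kCoords)
  apc <- op@schedule@armsPerContrast
  phase@uTilde[rep(seq_len(ns), apc), , drop = FALSE]
}

# forward model for contrast q: image (nv vector) -> samples (np vector),
# fields batched as columns
.forwardContrast <- function(op, cm, q, img, phase, uExp) {
  if (is.null(phase)) {
    X <- cm * img
    return(opForward(op, X, q))  # np x nc
  }
  d2 <- phase@d2; nc <- ncol(cm)
  X <- matrix(0 + 0i, nrow(cm), nc * d2)
  for (w in seq_len(d2)) {
    pw <- phase@sTilde[w] * Conj(phase@vTilde[, w]) * img
    X[, (w - 1L) * nc + seq_len(nc)] <- cm * pw
  }
  G <- opForward(op, X, q)  # np x (nc*d2)
  np <- nrow(G)
  Y <- matrix(0 + 0i, np, nc)
  for (w in seq_len(d2))
    Y <- Y + G[, (w - 1L) * nc + seq_len(nc), drop = FALSE] * uExp[, w]
  Y
}

# adjoint for contrast q: samples (np x nc) -> image (nv vector)
.adjointContrast <- function(op, cm, q, Yq, phase, uExp) {
  if (is.null(phase)) {
    B <- opAdjoint(op, Yq, q)  # nv x nc
    return(rowSums(Conj(cm) * B))
  }
  d2 <- phase@d2; nc <- ncol(cm)
  H <- matrix(0 + 0i, nrow(Yq), nc * d2)
  for (w in seq_len(d2))
    H[, (w - 1L) * nc + seq_len(nc)] <- Yq * Conj(uExp[, w])
  B <- opAdjoint(op, H, q)  # nv x (nc*d2)
  acc <- complex(nrow(cm))
  for (w in seq_len(d2)) {
    t0 <- rowSums(Conj(cm) * B[, (w - 1L) * nc + seq_len(nc), drop = FALSE])
    acc <- acc + phase@sTilde[w] * phase@vTilde[, w] * t0
  }
  acc
}

#' Conjugate gradient on the normal equations
#'
#' Minimizes ||A x - b||^2 by CG applied to A^H A x = A^H b for a linear
#' operator given as forward/adjoint closures over arbitrary complex arrays.
#'
#' @param applyNormal function(x) returning A^H A x
#' @param rhs A^H b
#' @param maxIter iteration cap
#' @param tol relative residual tolerance
#' @return list with \code{x}, \code{residuals} (norm per iteration),
#'   \code{converged}
#' @export
cgSolve <- function(applyNormal, rhs, maxIter = 40L, tol = 1e-6) {
  x <- rhs * 0
  r <- rhs
  p <- r
  rs <- sum(Re(Conj(r) * r))
  b0 <- sqrt(rs)
  res <- numeric(0)
  converged <- b0 == 0
  if (!converged) for (it in seq_len(maxIter)) {
    Ap <- applyNormal(p)
    alpha <- rs / sum(Re(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- sum(Re(Conj(r) * r))
    res <- c(res, sqrt(rsNew))
    if (sqrt(rsNew) / b0 < tol) { converged <- TRUE; break }
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  if (!converged)
    warning(sprintf("CG did not reach tolerance %.1e in %d iterations", tol,
                    maxIter))
  list(x = x, residuals = res, converged = converged)
}

.coilMatrix <- function(coils, op) {
  cm <- matrix(coils@maps, prod(op@gridShape))
  if (nrow(cm) != prod(op@gridShape))
    stop("coil maps do not match the operator grid")
  cm
}

#' SENSE reconstruction with optional B0 compensation
#'
#' Reconstructs each contrast image independently by conjugate-gradient
#' least squares of the coil-weighted non-uniform Fourier model; with a
#' phase subspace the within-readout off-resonance phase is part of the
#' forward model, compensating blurring from extended readouts.
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param coils a \linkS4class{CoilMaps}
#' @param op a \linkS4class{SamplingOperator}
#' @param phase a \linkS4class{PhaseSubspace} or NULL for plain SENSE
#' @param maxIter,tol conjugate-gradient controls
#' @param dcf logical, precondition with radial density-compensation
#'   weights (see \code{\link{dcfWeights}})
#' @return complex matrix of contrast images, nContrasts x nVoxels
#' @export
senseB0 <- function(kdata, coils, op, phase = NULL, maxIter = 40L,
                    tol = 1e-6, dcf = TRUE) {
  Y <- kdata@samples
  nq <- dim(Y)[1]
  cm <- .coilMatrix(coils, op)
  uExp <- if (is.null(phase)) NULL else .expandPhaseBasis(phase, op)
  w <- if (dcf) dcfWeights(op) else rep(1, samplesPerContrast(op))
  out <- matrix(0 + 0i, nq, nrow(cm))
  for (q in seq_len(nq)) {
    Yq <- t(Y[q, , , drop = TRUE])
    if (dim(Y)[2] == 1L) Yq <- matrix(Y[q, 1, ], ncol = 1)
    rhs <- .adjointContrast(op, cm, q, Yq * w, phase, uExp)
    normalOp <- function(x)
      .adjointContrast(op, cm, q,
                       .forwardContrast(op, cm, q, x, phase, uExp) * w,
                       phase, uExp)
    out[q, ] <- cgSolve(normalOp, rhs, maxIter, tol)$x
  }
  out
}

# full forward: sigma/delta coefficients (d1 x nv) -> Y (nq x nc x np)
.forwardComponents <- function(op, cm, U, coeff, phase, uExp) {
  nq <- nrow(U)
  np <- samplesPerContrast(op)
  nc <- ncol(cm)
  Y <- array(0 + 0i, dim = c(nq, nc, np))
  for (q in seq_len(nq)) {
    img <- as.vector(U[q, , drop = FALSE] %*% coeff)
    Y[q, , ] <- t(.forwardContrast(op, cm, q, img, phase, uExp))
  }
  Y
}

.adjointComponents <- function(op, cm, U, Y, phase, uExp) {
  nq <- nrow(U); d1 <- ncol(U)
  nv <- nrow(cm)
  coeff <- matrix(0 + 0i, d1, nv)
  for (q in seq_len(nq)) {
    Yq <- t(Y[q, , , drop = TRUE])
    if (dim(Y)[2] == 1L) Yq <- matrix(Y[q, 1, ], ncol = 1)
    aq <- .adjointContrast(op, cm, q, Yq, phase, uExp)
    coeff <- coeff + outer(Conj(U[q, ]), aq)
  }
  coeff
}

#' Subspace-constrained reconstruction
#'
#' Jointly estimates d1 component images in the truncated temporal basis of
#' the dictionary: all contrasts are coupled through the basis, so
#' interleaves missed by one contrast are informed by the others. Solved by
#' conjugate gradient on the normal equations.
#'
#' @inheritParams senseB0
#' @param subspace a \linkS4class{ContrastSubspace}
#' @param dcf logical, precondition with density-compensation weights
#' @return a \linkS4class{ComponentImages}
#' @export
scr <- function(kdata, coils, op, subspace, maxIter = 40L, tol = 1e-6,
                dcf = TRUE) {
  scrB0(kdata, coils, op, subspace, phase = NULL, maxIter = maxIter,
        tol = tol, dcf = dcf)
}

#' Subspace-constrained reconstruction with B0 compensation
#'
#' As \code{\link{scr}}, with the truncated phase subspace of the
#' off-resonance map inserted into the forward model so that phase accrued
#' over extended readouts is accounted for during reconstruction.
#'
#' @inheritParams scr
#' @param phase a \linkS4class{PhaseSubspace}, or NULL to omit compensation
#' @return a \linkS4class{ComponentImages}
#' @export
scrB0 <- function(kdata, coils, op, subspace, phase, maxIter = 40L,
                  tol = 1e-6, dcf = TRUE) {
  Y <- kdata@samples
  U <- subspace@basis
  if (dim(Y)[1] != nrow(U)) stop("contrast counts of data and basis differ")
  cm <- .coilMatrix(coils, op)
  uExp <- if (is.null(phase)) NULL else .expandPhaseBasis(phase, op)
  w <- if (dcf) dcfWeights(op) else rep(1, samplesPerContrast(op))
  weight <- function(Y) {
    Yw <- Y
    for (q in seq_len(dim(Y)[1]))
      Yw[q, , ] <- sweep(matrix(Y[q, , ], dim(Y)[2]), 2, w, `*`)
    Yw
  }
  rhs <- .adjointComponents(op, cm, U, weight(Y), phase, uExp)
  normalOp <- function(x)
    .adjointComponents(op, cm, U,
                       weight(.forwardComponents(op, cm, U, x, phase, uExp)),
                       phase, uExp)
  fit <- cgSolve(normalOp, rhs, maxIter, tol)
  new("ComponentImages", coefficients = fit$x, subspace = subspace)
}

#' Compose contrast images from component images
#'
#' @param subspace a \linkS4class{ContrastSubspace}
#' @param components a \linkS4class{ComponentImages} or a d1 x nVoxels matrix
#' @return complex matrix, nContrasts x nVoxels
#' @export
composeContrasts <- function(subspace, components) {
  coeff <- if (is(components, "ComponentImages")) components@coefficients
           else components
  subspace@basis %*% coeff
}

setMethod("show", "ComponentImages", function(object) {
  cat(sprintf("ComponentImages: %d components x %d voxels\n",
              nrow(object@coefficients), ncol(object@coefficients)))
})

setMethod("show", "PhaseSubspace", function(object) {
  cat(sprintf("PhaseSubspace: d2 = %d of %d samples, energy %.5f\n",
              object@d2, nrow(object@uTilde),
              energyFraction(object, object@d2)))
})
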