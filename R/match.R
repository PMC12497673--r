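# Dictionary matching with interpolation refinement.
#
# Stage 1 assigns each voxel the atom maximizing the normalized match metric
# |<d, y>| / ||d|| (invariant to any global complex scale of y). Stage 2
# refines the nonlinear parameters off-grid, coordinate-wise: along each grid
# axis a quadratic is fitted to the metric at the winning node and its two
# neighbors and the parabola vertex is taken (clamped to the neighbor
# interval; the grid value is kept at edges, at excluded neighbors, or when
# the metric is locally flat). T1/T2 are interpolated on the log scale
# matching their grid spacing. Proton density is re-estimated by simulating
# the refined atom and projecting the data onto it.

.simulateThetaMatrix <- function(thetaMat, train, mode, ensemble, sliceIndex,
                                 hardPulseMaxDeg = 2) {
  if (mode == "Si") {
    tl <- buildEventTimeline(train, instantAll = TRUE)
    return(matrix(as.complex(.runBloch(tl, thetaMat, 0, matrix(1 + 0i, 1, 1))),
                  tl$nq, nrow(thetaMat)))
  }
  sel <- any(vapply(train@block@pulses,
                    function(p) p@selective && p@duration > 0, logical(1)))
  w <- zencodeWeights(ensemble)[, sliceIndex, drop = FALSE]
  tl <- buildEventTimeline(train, slabWidth = ensemble@slabWidth,
                           hardPulseMaxDeg = hardPulseMaxDeg)
  if (!sel) {
    out <- .runBloch(tl, thetaMat, 0, matrix(1 + 0i, 1, 1))
    return(sum(w) * matrix(as.complex(out), tl$nq, nrow(thetaMat)))
  }
  out <- .runBloch(tl, thetaMat, subspinPositions(ensemble), w)
  matrix(as.complex(out), tl$nq, nrow(thetaMat))
}

#' Match measured signal evolutions to a dictionary
#'
#' Per voxel, finds the dictionary atom maximizing the normalized complex
#' correlation with the measured contrast series, estimates the complex
#' proton density as the least-squares scale of the winning atom, and (by
#' default) refines T1, T2, off-resonance and B1 off-grid by coordinate-wise
#' quadratic interpolation of the match metric, re-estimating the proton
#' density at the refined parameters. All-zero voxels are flagged invalid.
#'
#' @param signals complex matrix, nContrasts x nVoxels
#' @param dict a \linkS4class{SignalDictionary}
#' @param refine logical, apply interpolation refinement
#' @param refineIters additional interpolation passes in which the metric is
#'   evaluated on re-simulated atoms around the current off-grid estimate
#'   with a halving step, sharpening the vertex estimate along correlated
#'   parameter ridges (0 disables)
#' @param blockSize atoms per block in the correlation search (memory bound)
#' @param subspace a \linkS4class{ContrastSubspace}, or NULL. When the
#'   signals come from a subspace-constrained reconstruction they live in
#'   the span of the temporal basis; supplying that basis matches data and
#'   atoms in the compressed domain (atoms projected onto the subspace), so
#'   the truncation residual of the basis does not bias the fit.
#' @return a list with per-voxel vectors \code{t1}, \code{t2}, \code{delta},
#'   \code{b1}, complex \code{i0}, \code{metric} (normalized correlation of
#'   the winning node), \code{atom} (grid atom index) and logical
#'   \code{valid}
#' @export
matchDictionary <- function(signals, dict, refine = TRUE, refineIters = 3L,
                            blockSize = 8192L, subspace = NULL) {
  if (!is.matrix(signals)) signals <- matrix(signals, ncol = 1)
  nq <- nrow(dict@atomSignals)
  if (nrow(signals) != nq)
    stop("signal length must equal the dictionary contrast count")
  CU <- if (is.null(subspace)) NULL else Conj(t(subspace@basis))
  D <- dict@atomSignals
  norms <- dict@atomNorms
  if (!is.null(CU)) {
    signals <- CU %*% signals
    D <- CU %*% D
    norms <- sqrt(colSums(abs(D)^2))
    if (any(norms == 0)) stop("dictionary atom orthogonal to the subspace")
  }
  nr <- nrow(D)
  nv <- ncol(signals)
  na <- ncol(D)
  Dn <- D / rep(norms, each = nr)

  valid <- colSums(abs(signals)) > 0
  best <- integer(nv)
  bestRaw <- complex(nv)     # <dn, y> of the winner
  bestMet <- numeric(nv)
  ynorm <- sqrt(colSums(abs(signals)^2))

  for (a0 in seq(1L, na, by = blockSize)) {
    aIdx <- a0:min(na, a0 + blockSize - 1L)
    G <- crossprod(Conj(Dn[, aIdx, drop = FALSE]), signals)  # block x nv
    A <- abs(G)
    top <- max.col(t(A), ties.method = "first")
    met <- A[cbind(top, seq_len(nv))]
    upd <- met > bestMet
    if (any(upd)) {
      best[upd] <- aIdx[top[upd]]
      bestMet[upd] <- met[upd]
      bestRaw[upd] <- G[cbind(top[upd], which(upd))]
    }
  }
  best[!valid] <- NA_integer_

  atoms <- dict@grid@atoms
  res <- list(
    t1 = ifelse(valid, atoms$t1[best], NA_real_),
    t2 = ifelse(valid, atoms$t2[best], NA_real_),
    delta = ifelse(valid, atoms$delta[best], NA_real_),
    b1 = ifelse(valid, atoms$b1[best], NA_real_),
    i0 = ifelse(valid, bestRaw / norms[best], 0 + 0i),
    metric = ifelse(valid, bestMet / pmax(ynorm, .Machine$double.eps), 0),
    atom = best, valid = valid)

  if (refine && any(valid)) {
    res <- .interpolateRefine(res, signals, dict, Dn, CU)
    if (refineIters > 0)
      res <- .localPolish(res, signals, dict, iters = refineIters, CU = CU)
  }
  res
}

# metric |<dn_a, y_v>| for per-voxel atom indices (NA -> NA)
.metricAt <- function(Dn, signals, atomIds) {
  ok <- !is.na(atomIds)
  out <- rep(NA_real_, length(atomIds))
  if (any(ok))
    out[ok] <- abs(colSums(Conj(Dn[, atomIds[ok], drop = FALSE]) *
                           signals[, ok, drop = FALSE]))
  out
}

.interpolateRefine <- function(res, signals, dict, Dn, CU = NULL) {
  grid <- dict@grid
  idxArr <- .gridIndexArray(grid)
  dims <- dim(idxArr)
  atoms <- grid@atoms
  vsel <- which(res$valid)
  aid <- res$atom[vsel]
  sig <- signals[, vsel, drop = FALSE]
  axCols <- c("it1", "it2", "idelta", "ib1")
  axVals <- list(log(grid@t1Values), log(grid@t2Values),
                 grid@deltaValues, grid@b1Values)
  pos <- as.matrix(atoms[aid, axCols])      # current node per voxel
  refined <- matrix(0, length(vsel), 4)     # axis coordinates (value scale)
  m0 <- .metricAt(Dn, sig, aid)

  for (ax in 1:4) {
    vals <- axVals[[ax]]
    i <- pos[, ax]
    refined[, ax] <- vals[i]
    if (dims[ax] < 3) next
    neighborId <- function(shift) {
      p <- pos
      p[, ax] <- p[, ax] + shift
      inb <- p[, ax] >= 1 & p[, ax] <= dims[ax]
      out <- rep(NA_integer_, nrow(p))
      out[inb] <- idxArr[p[inb, , drop = FALSE]]
      out
    }
    idLo <- neighborId(-1L); idHi <- neighborId(1L)
    mLo <- .metricAt(Dn, sig, idLo)
    mHi <- .metricAt(Dn, sig, idHi)
    ok <- !is.na(mLo) & !is.na(mHi)
    denom <- mLo - 2 * m0 + mHi
    interior <- ok & denom < -.Machine$double.eps & m0 >= pmax(mLo, mHi)
    off <- rep(0, length(m0))
    off[interior] <- 0.5 * (mLo[interior] - mHi[interior]) / denom[interior]
    off <- pmin(1, pmax(-1, off))
    # asymmetric node spacing: interpolate on the axis value scale
    stepLo <- vals[pmax(i - 1, 1)] - vals[i]
    stepHi <- vals[pmin(i + 1, dims[ax])] - vals[i]
    refined[, ax] <- vals[i] + ifelse(off < 0, -off * stepLo, off * stepHi)
  }

  t1r <- exp(refined[, 1]); t2r <- exp(refined[, 2])
  t2r <- pmin(t2r, t1r)  # keep the physical ordering after refinement
  thetaMat <- cbind(t1r, t2r, refined[, 3], refined[, 4])
  sim <- .simulateThetaMatrix(thetaMat, dict@train, dict@mode, dict@ensemble,
                              dict@sliceIndex)
  if (!is.null(CU)) sim <- CU %*% sim
  nrm2 <- colSums(abs(sim)^2)
  proj <- colSums(Conj(sim) * sig)
  i0 <- proj / nrm2
  ynorm <- sqrt(colSums(abs(sig)^2))
  res$t1[vsel] <- t1r
  res$t2[vsel] <- t2r
  res$delta[vsel] <- refined[, 3]
  res$b1[vsel] <- refined[, 4]
  res$i0[vsel] <- i0
  res$metric[vsel] <- abs(proj) / pmax(sqrt(nrm2) * ynorm,
                                       .Machine$double.eps)
  res
}

# iterated coordinate-wise quadratic interpolation on re-simulated atoms:
# starting from the grid-pass estimate, each pass probes +-h along every
# axis (log scale for t1/t2), takes the clamped parabola vertex, and halves
# h; estimates stay inside the grid ranges and keep t2 <= t1
.localPolish <- function(res, signals, dict, iters = 2L, CU = NULL) {
  grid <- dict@grid
  vsel <- which(res$valid)
  sig <- signals[, vsel, drop = FALSE]
  ynorm <- sqrt(colSums(abs(sig)^2))
  nv <- length(vsel)

  X <- cbind(log(res$t1[vsel]), log(res$t2[vsel]),
             res$delta[vsel], res$b1[vsel])
  lims <- rbind(range(log(grid@t1Values)), range(log(grid@t2Values)),
                range(grid@deltaValues), range(grid@b1Values))
  stepOf <- function(v) if (length(v) > 1) mean(diff(v)) else 0
  h0 <- c(stepOf(log(grid@t1Values)), stepOf(log(grid@t2Values)),
          stepOf(grid@deltaValues), stepOf(grid@b1Values)) / 2

  toTheta <- function(X) {
    t1 <- exp(X[, 1]); t2 <- pmin(exp(X[, 2]), t1)
    cbind(t1, t2, X[, 3], X[, 4])
  }
  metricOf <- function(X) {
    sim <- .simulateThetaMatrix(toTheta(X), dict@train, dict@mode,
                                dict@ensemble, dict@sliceIndex)
    if (!is.null(CU)) sim <- CU %*% sim
    nrm <- sqrt(colSums(abs(sim)^2))
    abs(colSums(Conj(sim) * sig)) / pmax(nrm * ynorm, .Machine$double.eps)
  }

  m0 <- metricOf(X)
  for (it in seq_len(iters)) {
    h <- h0 / 2^(it - 1)
    for (ax in which(h0 > 0)) {
      Xlo <- X; Xlo[, ax] <- pmax(X[, ax] - h[ax], lims[ax, 1])
      Xhi <- X; Xhi[, ax] <- pmin(X[, ax] + h[ax], lims[ax, 2])
      mLo <- metricOf(Xlo)
      mHi <- metricOf(Xhi)
      denom <- mLo - 2 * m0 + mHi
      ok <- denom < -.Machine$double.eps & m0 >= pmax(mLo, mHi) - 1e-12
      off <- rep(0, nv)
      off[ok] <- 0.5 * (mLo[ok] - mHi[ok]) / denom[ok]
      off <- pmin(1, pmax(-1, off))
      # move toward the better side when the center is not the local max
      off[!ok & mHi > m0 & mHi >= mLo] <- 1
      off[!ok & mLo > m0 & mLo > mHi] <- -1
      Xn <- X
      Xn[, ax] <- X[, ax] + off * h[ax]
      Xn[, ax] <- pmin(pmax(Xn[, ax], lims[ax, 1]), lims[ax, 2])
      mN <- metricOf(Xn)
      take <- mN >= m0
      X[take, ax] <- Xn[take, ax]
      m0[take] <- mN[take]
    }
  }

  theta <- toTheta(X)
  sim <- .simulateThetaMatrix(theta, dict@train, dict@mode, dict@ensemble,
                              dict@sliceIndex)
  if (!is.null(CU)) sim <- CU %*% sim
  nrm2 <- colSums(abs(sim)^2)
  proj <- colSums(Conj(sim) * sig)
  res$t1[vsel] <- theta[, 1]
  res$t2[vsel] <- theta[, 2]
  res$delta[vsel] <- theta[, 3]
  res$b1[vsel] <- theta[, 4]
  res$i0[vsel] <- proj / nrm2
  res$metric[vsel] <- abs(proj) / pmax(sqrt(nrm2) * ynorm,
                                       .Machine$double.eps)
  res
}

#' Pack per-voxel match results into parameter maps
#'
#' @param res result list from \code{\link{matchDictionary}} computed on the
#'   masked voxels of \code{mask} (in column-major order)
#' @param mask logical matrix of fitted voxels
#' @return a \linkS4class{ParamMap}
#' @export
matchToParamMap <- function(res, mask) {
  shape <- dim(mask)
  fill <- function(vals, default) {
    m <- matrix(default, shape[1], shape[2])
    m[mask] <- vals
    m
  }
  ok <- res$valid
  new("ParamMap",
      i0 = fill(ifelse(ok, res$i0, 0 + 0i), 0 + 0i),
      t1 = fill(ifelse(ok, res$t1, NA_real_), NA_real_),
      t2 = fill(ifelse(ok, res$t2, NA_real_), NA_real_),
      delta = fill(ifelse(ok, res$delta, NA_real_), NA_real_),
      b1 = fill(ifelse(ok, res$b1, NA_real_), NA_real_),
      mask = fill(ok, FALSE))
}
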