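# Two-pass off-resonance estimation. The echo-state signal is periodic in
# the off-resonance with period 1/TRp (1000/trp_ms in Hz), so the
# off-resonance returned by dictionary matching is wrapped into the
# +-1000/(2 trp) band; a spatial unwrapping step recovers the smooth map
# needed for B0-compensated reconstruction of extended readouts.

#' Off-resonance wrap period of a train, Hz
#'
#' The fitted off-resonance aliases with period 1/TRp (from
#' |Delta . TRp| > pi with Delta in angular units); expressed in Hz this is
#' 1000 / trp_ms, i.e. 33.33 Hz at TRp 30 ms.
#' @param train a \linkS4class{PulseTrain}
#' @export
wrapPeriod <- function(train) 1000 / trpMs(train)

#' Initial (wrapped) off-resonance map from uncompensated reconstruction
#'
#' First pass of the two-step compensation: subspace-constrained
#' reconstruction without B0 compensation, followed by dictionary matching;
#' the off-resonance component of the fit is returned, flagged wrapped.
#'
#' @param kdata a \linkS4class{KSpaceData}
#' @param coils a \linkS4class{CoilMaps}
#' @param op a \linkS4class{SamplingOperator}
#' @param dict a \linkS4class{SignalDictionary} whose off-resonance axis
#'   spans at least one wrap period
#' @param subspace a \linkS4class{ContrastSubspace}
#' @param mask logical matrix of voxels to fit
#' @param maxIter,tol conjugate-gradient controls
#' @return list with \code{b0} (a \linkS4class{B0Map}), \code{fit} (the
#'   match result) and \code{images} (reconstructed contrast images)
#' @export
estimateB0Initial <- function(kdata, coils, op, dict, subspace, mask,
                              maxIter = 40L, tol = 1e-6) {
  span <- diff(range(dict@grid@deltaValues))
  if (span + 1e-9 < wrapPeriod(dict@train))
    stop("dictionary off-resonance axis must span at least one wrap period")
  comp <- scr(kdata, coils, op, subspace, maxIter = maxIter, tol = tol)
  images <- composeContrasts(subspace, comp)
  fit <- matchDictionary(images[, as.vector(mask), drop = FALSE], dict,
                         subspace = subspace)
  delta <- matrix(0, nrow(mask), ncol(mask))
  delta[mask] <- fit$delta
  period <- wrapPeriod(dict@train)
  delta[mask] <- (fit$delta + period / 2) %% period - period / 2
  b0 <- new("B0Map", delta = delta, wrapped = TRUE, mask = mask)
  list(b0 = b0, fit = fit, images = images)
}

#' Unwrap a wrapped off-resonance map
#'
#' Quality-guided region growing: within each connected component of the
#' mask, growth starts from the highest-quality voxel (its wrapped value is
#' kept as the anchor) and each voxel added is shifted by the integer
#' multiple of the wrap period that brings it closest to the mean of its
#' already-unwrapped neighbors. Voxels are admitted in decreasing quality
#' order, so reliable regions set the reference before noisy ones.
#' Disconnected components are unwrapped independently; their relative
#' global multiples are not resolved.
#'
#' @param wrapped a \linkS4class{B0Map} with \code{wrapped = TRUE}
#' @param train the \linkS4class{PulseTrain} defining the wrap period
#' @param quality numeric matrix of per-voxel confidence (typically the
#'   proton-density magnitude); defaults to 1 everywhere
#' @return a \linkS4class{B0Map} with \code{wrapped = FALSE}
#' @export
unwrapB0 <- function(wrapped, train, quality = NULL) {
  if (!wrapped@wrapped) return(wrapped)
  mask <- wrapped@mask
  if (!any(mask)) stop("mask is empty")
  period <- wrapPeriod(train)
  delta <- wrapped@delta
  if (is.null(quality)) quality <- matrix(1, nrow(mask), ncol(mask))
  nx <- nrow(mask); ny <- ncol(mask)

  comp <- .connectedComponents(mask)
  out <- delta
  for (cid in seq_len(max(comp, na.rm = TRUE))) {
    vox <- which(comp == cid)
    if (length(vox) == 1L) next
    settled <- logical(length(delta))
    seed <- vox[which.max(quality[vox])]
    settled[seed] <- TRUE
    frontier <- setdiff(.neighbors4(seed, nx, ny), which(!mask))
    frontier <- frontier[mask[frontier] & comp[frontier] == cid]
    while (length(frontier)) {
      v <- frontier[which.max(quality[frontier])]
      nb <- .neighbors4(v, nx, ny)
      nb <- nb[settled[nb]]
      ref <- mean(out[nb])
      k <- round((ref - delta[v]) / period)
      out[v] <- delta[v] + k * period
      settled[v] <- TRUE
      frontier <- frontier[frontier != v]
      newNb <- .neighbors4(v, nx, ny)
      newNb <- newNb[mask[newNb] & comp[newNb] == cid & !settled[newNb]]
      frontier <- union(frontier, newNb)
    }
  }
  new("B0Map", delta = out, wrapped = FALSE, mask = mask)
}

# 4-connected neighbor linear indices
.neighbors4 <- function(v, nx, ny) {
  i <- ((v - 1L) %% nx) + 1L
  j <- ((v - 1L) %/% nx) + 1L
  nb <- c(if (i > 1L) v - 1L, if (i < nx) v + 1L,
          if (j > 1L) v - nx, if (j < ny) v + nx)
  nb
}

# label 4-connected components of a logical mask (0/NA outside)
.connectedComponents <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(NA_integer_, nx, ny)
  cid <- 0L
  for (v0 in which(mask)) {
    if (!is.na(comp[v0])) next
    cid <- cid + 1L
    queue <- v0
    comp[v0] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- .neighbors4(v, nx, ny)
      nb <- nb[mask[nb] & is.na(comp[nb])]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

setMethod("show", "B0Map", function(object) {
  rng <- range(object@delta[object@mask])
  cat(sprintf("B0Map (%s): [%.2f, %.2f] Hz over %d voxels\n",
              if (object@wrapped) "wrapped" else "unwrapped",
              rng[1], rng[2], sum(object@mask)))
})
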