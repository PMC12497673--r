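#' Digital multi-tube relaxometry phantom
#'
#' Builds a 2D parameter map of disk-shaped tubes with assigned (T1, T2),
#' mimicking a standard relaxometry test object with calibrated tubes; the
#' tube values here are synthetic defaults in the spirit of such phantoms.
#' Off-resonance is a low-order radial/linear polynomial and the transmit
#' field a smooth radial profile, both over FOV-centered coordinates
#' normalized by half the matrix size.
#'
#' @param gridShape integer length-2 (default 32 x 32)
#' @param tubeCenters numeric matrix nTubes x 2, FOV-centered pixel units;
#'   default four tubes on the diagonals
#' @param tubeRadius tube radius in pixels (scalar or per tube)
#' @param t1 per-tube T1 values, ms
#' @param t2 per-tube T2 values, ms
#' @param i0 per-tube complex proton density
#' @param b0Spec named list with entries \code{const}, \code{linx},
#'   \code{liny}, \code{quad} (Hz at unit normalized coordinate):
#'   delta(x, y) = const + linx x + liny y + quad (x^2 + y^2)
#' @param b1Spec named list with entries \code{center}, \code{quad}:
#'   b1(r) = center + quad r^2 (clamped to [0.8, 1.2])
#' @param tubeTaper width (pixels) of the linear proton-density roll-off at
#'   each tube edge. The taper emulates partial-volume amplitude at tube
#'   boundaries and keeps the phantom's spectrum compact; relaxation
#'   parameters are constant within a tube, so edge voxels change only in
#'   amplitude, not signal shape.
#' @return a \linkS4class{ParamMap}
#' @export
makePhantom <- function(gridShape = c(32L, 32L),
                        tubeCenters = NULL, tubeRadius = 5,
                        t1 = c(300, 600, 1000, 1500),
                        t2 = c(50, 80, 120, 200),
                        i0 = NULL,
                        b0Spec = list(const = -5, linx = 0, liny = 0, quad = 20),
                        b1Spec = list(center = 1.04, quad = -0.18),
                        tubeTaper = 1.5) {
  nx <- gridShape[1]; ny <- gridShape[2]
  if (is.null(tubeCenters)) {
    d <- round(nx / 4)
    tubeCenters <- rbind(c(-d, -d), c(d, -d), c(-d, d), c(d, d))
  }
  nT <- nrow(tubeCenters)
  if (length(t1) != nT || length(t2) != nT)
    stop("t1/t2 must have one value per tube")
  if (is.null(i0)) i0 <- rep(1 + 0i, nT)
  tubeRadius <- rep_len(tubeRadius, nT)
  for (i in seq_len(nT)) for (j in seq_len(nT)) {
    if (i < j && sqrt(sum((tubeCenters[i, ] - tubeCenters[j, ])^2)) <
        tubeRadius[i] + tubeRadius[j])
      stop("tubes overlap")
  }
  x <- matrix((seq_len(nx) - 1) - nx / 2, nx, ny)
  y <- matrix((seq_len(ny) - 1) - ny / 2, nx, ny, byrow = TRUE)
  if (any(abs(tubeCenters[, 1]) + tubeRadius > nx / 2) ||
      any(abs(tubeCenters[, 2]) + tubeRadius > ny / 2))
    stop("tubes must fit inside the grid")

  mask <- matrix(FALSE, nx, ny)
  t1m <- t2m <- matrix(NA_real_, nx, ny)
  i0m <- matrix(0 + 0i, nx, ny)
  tube <- matrix(NA_integer_, nx, ny)
  for (i in seq_len(nT)) {
    r <- sqrt((x - tubeCenters[i, 1])^2 + (y - tubeCenters[i, 2])^2)
    w <- pmin(pmax((tubeRadius[i] - r) / max(tubeTaper, 1e-6), 0), 1)
    inT <- w > 0.05
    mask[inT] <- TRUE
    t1m[inT] <- t1[i]; t2m[inT] <- t2[i]
    i0m[inT] <- i0[i] * w[inT]
    tube[inT] <- i
  }
  xn <- x / (nx / 2); yn <- y / (ny / 2)
  r2 <- xn^2 + yn^2
  deltam <- b0Spec$const + b0Spec$linx * xn + b0Spec$liny * yn + b0Spec$quad * r2
  b1m <- pmin(pmax(b1Spec$center + b1Spec$quad * r2, 0.8), 1.2)
  t1m[!mask] <- 1000; t2m[!mask] <- 100  # inert background (zero density)
  pm <- new("ParamMap", i0 = i0m, t1 = t1m, t2 = t2m, delta = deltam,
            b1 = b1m, mask = mask)
  attr(pm, "tube") <- tube
  pm
}

#' Synthetic smooth coil sensitivity maps
#'
#' One Gaussian magnitude lobe per coil, centered on points around the FOV
#' border, with a low-order polynomial phase; the root-sum-of-squares is
#' strictly positive over the grid. A surrogate for measured sensitivities:
#' maps are spatially band-limited by construction.
#'
#' @param nCoils number of coils (>= 1)
#' @param gridShape integer length-2
#' @param smoothness Gaussian width as a fraction of the FOV (default 0.8)
#' @return a \linkS4class{CoilMaps}
#' @export
makeCoilMaps <- function(nCoils, gridShape = c(32L, 32L), smoothness = 0.8) {
  if (nCoils < 1) stop("nCoils must be >= 1")
  nx <- gridShape[1]; ny <- gridShape[2]
  if (nCoils == 1) {
    return(new("CoilMaps",
               maps = array(1 + 0i, dim = c(nx, ny, 1))))
  }
  x <- matrix((seq_len(nx) - 1) - nx / 2, nx, ny) / (nx / 2)
  y <- matrix((seq_len(ny) - 1) - ny / 2, nx, ny, byrow = TRUE) / (ny / 2)
  maps <- array(0 + 0i, dim = c(nx, ny, nCoils))
  ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils
  s2 <- (2 * smoothness)^2
  for (c0 in seq_len(nCoils)) {
    cx <- cos(ang[c0]); cy <- sin(ang[c0])
    mag <- 0.15 + exp(-((x - cx)^2 + (y - cy)^2) / s2)
    ph <- 0.5 * (cx * x + cy * y) + 0.2 * x * y
    maps[, , c0] <- mag * exp(1i * ph)
  }
  new("CoilMaps", maps = maps)
}

#' Tube label matrix of a phantom
#' @param pmap a \linkS4class{ParamMap} built by \code{\link{makePhantom}}
#' @export
tubeLabels <- function(pmap) attr(pmap, "tube")

setMethod("show", "ParamMap", function(object) {
  d <- dim(object@mask)
  cat(sprintf("ParamMap: %d x %d, %d voxels in mask\n",
              d[1], d[2], sum(object@mask)))
})

setMethod("show", "CoilMaps", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoilMaps: %d x %d x %d coils\n", d[1], d[2], d[3]))
})
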