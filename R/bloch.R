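#' Rotate a magnetization vector about a transverse axis
#'
#' Right-handed rotation of (Mx, My, Mz) by \code{flip} degrees about the
#' unit axis at azimuth \code{phaseAxis} degrees in the transverse plane
#' (x = 0, y = 90). Length-preserving.
#'
#' @param m numeric length-3 magnetization vector
#' @param flip rotation angle, degrees
#' @param phaseAxis axis azimuth, degrees
#' @return numeric length-3 vector
#' @examples
#' rotateMagnetization(c(0, 0, 1), 180, 0)  # inversion
#' @export
rotateMagnetization <- function(m, flip, phaseAxis) {
  a <- deg2rad(flip); phi <- deg2rad(phaseAxis)
  ca <- cos(a); sa <- sin(a); cp <- cos(phi); sp <- sin(phi)
  u <- cp * m[1] + sp * m[2]
  v <- -sp * m[1] + cp * m[2]
  vr <- v * ca - m[3] * sa
  mz <- v * sa + m[3] * ca
  c(cp * u - sp * vr, sp * u + cp * vr, mz)
}

#' Free relaxation and precession of a magnetization vector
#'
#' Closed-form Bloch evolution over \code{dt} ms: the transverse component is
#' rotated by \eqn{-2\pi \cdot \mathrm{delta} \cdot dt/1000} (left-handed
#' precession for positive off-resonance) and scaled by \eqn{e^{-dt/T_2}};
#' the longitudinal component recovers toward the equilibrium value 1 with
#' time constant T1.
#'
#' @param m numeric length-3 magnetization vector
#' @param dt interval in ms (>= 0)
#' @param t1,t2 relaxation times in ms
#' @param delta off-resonance in Hz
#' @return numeric length-3 vector
#' @export
relaxPrecess <- function(m, dt, t1, t2, delta) {
  stopifnot(dt >= 0)
  th <- 2 * pi * delta * dt / 1000
  e1 <- exp(-dt / t1); e2 <- exp(-dt / t2)
  c(e2 * (cos(th) * m[1] + sin(th) * m[2]),
    e2 * (-sin(th) * m[1] + cos(th) * m[2]),
    1 + (m[3] - 1) * e1)
}

#' Construct a slab sub-spin ensemble
#'
#' @param nSubspins number of sub-spins along the slice axis
#' @param slabFactor extent multiplier: sub-spins span slabFactor x slabWidth,
#'   so out-of-slab magnetization (and its aliasing into the slices through
#'   the finite z-encode field of view) is represented
#' @param nZencodes number of balanced z-encodes / reconstructed slices
#' @param slabWidth slab width in mm (also the z-encode field of view)
#' @return a \linkS4class{SlabEnsemble}
#' @export
slabEnsemble <- function(nSubspins = 64, slabFactor = 1.8, nZencodes = 8,
                         slabWidth = 132) {
  new("SlabEnsemble", nSubspins = as.integer(nSubspins),
      slabFactor = slabFactor, nZencodes = as.integer(nZencodes),
      slabWidth = slabWidth)
}

#' Sub-spin positions of an ensemble (mm, slice axis, centered)
#' @param ensemble a \linkS4class{SlabEnsemble}
#' @export
subspinPositions <- function(ensemble) {
  n <- ensemble@nSubspins
  extent <- ensemble@slabFactor * ensemble@slabWidth
  ((seq_len(n) - 0.5) / n - 0.5) * extent
}

#' Slice-separation weights from balanced z-encodes
#'
#' One Bloch simulation run yields every sub-spin's signal without
#' z-encoding; each balanced z-encode m then multiplies sub-spin j by
#' \eqn{e^{-i 2 \pi m z_j / F}}, and the inverse discrete Fourier transform
#' across encodes isolates each slice. Both steps are linear in the sub-spin
#' signals, so they collapse into a fixed weight per (sub-spin, slice): the
#' periodic Dirichlet kernel centered on the slice, normalized by the
#' nominal number of sub-spins per slice. The encoded field of view F is the
#' full simulated extent (slabFactor x slab width), so out-of-slab
#' magnetization excited by non-selective pulses is resolved onto the outer
#' slices rather than folded into the slab.
#'
#' @param ensemble a \linkS4class{SlabEnsemble}
#' @return complex matrix, nSubspins x nZencodes
#' @export
zencodeWeights <- function(ensemble) {
  nz <- ensemble@nZencodes
  fov <- ensemble@slabFactor * ensemble@slabWidth
  z <- subspinPositions(ensemble)
  ms <- seq.int(-floor(nz / 2), ceiling(nz / 2) - 1L)
  zs <- slicePositions(ensemble)
  w <- matrix(0 + 0i, length(z), nz)
  for (s in seq_len(nz)) {
    acc <- complex(length(z))
    for (m in ms) acc <- acc + exp(2i * pi * m * (zs[s] - z) / fov)
    w[, s] <- acc / ensemble@nSubspins
  }
  w
}

#' Slice center positions (mm) of an ensemble
#'
#' Slices tile the z-encode field of view (slabFactor x slab width); the
#' central slice sits at z = 0.
#' @param ensemble a \linkS4class{SlabEnsemble}
#' @export
slicePositions <- function(ensemble) {
  nz <- ensemble@nZencodes
  fov <- ensemble@slabFactor * ensemble@slabWidth
  (seq_len(nz) - 1L - floor(nz / 2)) * (fov / nz)
}

#' Index of the central slice (z = 0)
#' @param ensemble a \linkS4class{SlabEnsemble}
#' @export
centralSlice <- function(ensemble) floor(ensemble@nZencodes / 2) + 1L

# run the compiled engine for a theta matrix (t1, t2, delta, b1 columns)
.runBloch <- function(timeline, thetaMat, zpos, weights) {
  out <- bloch_run_cpp(thetaMat, timeline$evType, timeline$evAngle,
                       timeline$evCphi, timeline$evSphi, timeline$evRc,
                       timeline$evGc, timeline$dtMs, timeline$gradAmp,
                       zpos, weights)
  out  # n_q x n_w x n_atoms
}

.thetaMatrix <- function(theta) {
  matrix(c(theta@t1, theta@t2, theta@delta, theta@b1), 1, 4)
}

#' Single-spin signal simulation
#'
#' Simulates the transient response of one spin per voxel through the pulse
#' train: starting from equilibrium, each pulse is applied as an
#' instantaneous rotation (flip scaled by b1) at its center and the
#' magnetization relaxes and precesses over the inter-pulse intervals. The
#' complex transverse signal (Mx + i My), scaled by the complex proton
#' density, is recorded at the echo state of each readout
#' (\code{readoutStartOffset} after the pulse center), giving one value per
#' contrast.
#'
#' @param theta a \linkS4class{TissueParams}
#' @param train a \linkS4class{PulseTrain}
#' @return complex vector of length \code{nContrasts(train)}
#' @export
simulateSi <- function(theta, train) {
  tl <- buildEventTimeline(train, instantAll = TRUE)
  out <- .runBloch(tl, .thetaMatrix(theta), 0, matrix(1 + 0i, 1, 1))
  theta@i0 * as.complex(out)
}

#' Slab-resolved multi-spin signal simulation
#'
#' Simulates every sub-spin of the ensemble through the time-discretized RF
#' envelopes (selective pulses see a position-dependent off-resonance from
#' the slice-select gradient, followed by a rephasing lobe), in a single run
#' without z-encoding; slice signals are then obtained by applying the
#' balanced z-encode phases and the inverse Fourier transform across
#' encodes (see \code{\link{zencodeWeights}}). With non-selective pulses and
#' a homogeneous slab all interior slices reproduce the single-spin result.
#'
#' @param theta a \linkS4class{TissueParams}
#' @param train a \linkS4class{PulseTrain}
#' @param ensemble a \linkS4class{SlabEnsemble}
#' @param hardPulseMaxDeg maximum rotation per hard-pulse sub-step, degrees
#' @param collapseUniform with no slice-selection every sub-spin shares one
#'   history, so the ensemble collapses to a single spin exactly; set FALSE
#'   to force the full per-sub-spin simulation (useful for validation)
#' @return complex matrix, nContrasts x nZencodes (one echo series per slice)
#' @export
simulateMu <- function(theta, train, ensemble, hardPulseMaxDeg = 2,
                       collapseUniform = TRUE) {
  sel <- any(vapply(train@block@pulses, function(p) p@selective && p@duration > 0,
                    logical(1)))
  if (!sel && collapseUniform) {
    # no slice-selection: all sub-spins share one history; collapse exactly
    tl <- buildEventTimeline(train, instantAll = FALSE,
                             slabWidth = ensemble@slabWidth,
                             hardPulseMaxDeg = hardPulseMaxDeg)
    w <- zencodeWeights(ensemble)
    out <- .runBloch(tl, .thetaMatrix(theta), 0, matrix(1 + 0i, 1, 1))
    series <- theta@i0 * as.complex(out)
    return(outer(series, colSums(w)))
  }
  tl <- buildEventTimeline(train, slabWidth = ensemble@slabWidth,
                           hardPulseMaxDeg = hardPulseMaxDeg)
  w <- zencodeWeights(ensemble)
  out <- .runBloch(tl, .thetaMatrix(theta), subspinPositions(ensemble), w)
  theta@i0 * matrix(as.complex(out), tl$nq, ensemble@nZencodes)
}

#' Tissue parameter constructor
#'
#' @param i0 complex apparent proton density
#' @param t1,t2 relaxation times, ms
#' @param delta off-resonance, Hz
#' @param b1 transmit scale
#' @return a \linkS4class{TissueParams}
#' @export
tissueParams <- function(i0 = 1 + 0i, t1 = 1000, t2 = 100, delta = 0, b1 = 1) {
  new("TissueParams", i0 = as.complex(i0), t1 = t1, t2 = t2,
      delta = delta, b1 = b1)
}
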