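#' Design an Archimedean spiral-out readout
#'
#' Analytic constant-pitch (Archimedean) spiral starting at k = 0, reaching
#' |k| = matrix/2 cycles/FOV at the end of the readout, sampled uniformly in
#' time. The number of turns is chosen so that, with all \code{nArms}
#' rotated interleaves acquired, the radial spacing between adjacent turns
#' satisfies the Nyquist limit of 1 cycle/FOV; a coarser configuration
#' raises a warning (undersampling in-plane is legitimate).
#'
#' @param matrix image matrix size (isotropic)
#' @param fov field of view in mm (metadata; k is kept in cycles/FOV)
#' @param nArms interleaves of the fully sampled design
#' @param readoutMs readout duration, ms
#' @param nSamples samples per interleave
#' @param turns number of spiral turns per interleave; the default
#'   matrix / (2 nArms) gives exactly Nyquist inter-turn spacing when all
#'   arms are acquired, larger values oversample radially (denser
#'   per-contrast coverage under arm undersampling)
#' @return a \linkS4class{SpiralTrajectory}
#' @examples
#' tr <- designSpiral(32, 220, 16, 22, 96)
#' max(sqrt(rowSums(tr@kCoords^2)))  # 16 cycles/FOV
#' @export
designSpiral <- function(matrix, fov = 220, nArms = 16, readoutMs = 22,
                         nSamples = 256, turns = NULL) {
  if (nArms < 1) stop("nArms must be >= 1")
  if (readoutMs <= 0) stop("readoutMs must be > 0")
  kmax <- matrix / 2
  # inter-turn spacing = 1 cycle/FOV with all arms at the default
  nTurns <- if (is.null(turns)) kmax / nArms else turns
  if (nTurns * nArms < kmax - 1e-9)
    warning("spiral design does not reach Nyquist spacing with all arms")
  t <- seq(0, 1, length.out = nSamples)
  r <- kmax * t
  th <- 2 * pi * nTurns * t
  k <- cbind(r * cos(th), r * sin(th))
  if (max(sqrt(rowSums(diff(k)^2))) > 1 + 1e-9)
    warning("along-readout sample spacing exceeds 1 cycle/FOV (sub-Nyquist)")
  new("SpiralTrajectory",
      kCoords = k,
      tau = readoutMs * t, readoutMs = readoutMs,
      nArmsFull = as.integer(nArms), matrixSize = as.integer(matrix))
}

#' Rotate a spiral interleave in the k-plane
#'
#' @param traj a \linkS4class{SpiralTrajectory}
#' @param angle rotation angle, radians
#' @return a \linkS4class{SpiralTrajectory} with rotated coordinates and
#'   unchanged sample timing
#' @export
rotateArm <- function(traj, angle) {
  c0 <- cos(angle); s0 <- sin(angle)
  k <- traj@kCoords
  traj@kCoords <- cbind(c0 * k[, 1] - s0 * k[, 2],
                        s0 * k[, 1] + c0 * k[, 2])
  traj
}

#' Golden-ratio interleave schedule across contrasts
#'
#' Each contrast acquires a maximally uniform subset of the interleaves
#' (shot r of contrast q at nominal angular position r * nArms /
#' armsPerContrast), rotated per contrast by a golden-ratio increment: the
#' offset of contrast q (0-based) is \code{round(nArms * frac(q * frac(2 *
#' phi))) mod nArms} with phi the golden ratio. In-plane aliasing is then
#' uniform within every contrast while consecutive contrasts sample
#' complementary arms, so full angular coverage accumulates over a few
#' contrasts at any acceleration. At acceleration 1 every contrast acquires
#' all arms.
#'
#' @param nContrasts number of contrasts
#' @param nArmsFull interleaves in the fully sampled design
#' @param acceleration undersampling factor (>= 1);
#'   \code{armsPerContrast = round(nArmsFull / acceleration)}
#' @return an \linkS4class{UndersamplingSchedule}
#' @examples
#' s <- scheduleArms(48, 16, 16 / 3)
#' s@armsPerContrast  # 3
#' @export
scheduleArms <- function(nContrasts, nArmsFull, acceleration = 1) {
  if (acceleration < 1) stop("acceleration must be >= 1")
  nArmsFull <- as.integer(nArmsFull)
  apc <- max(1L, as.integer(round(nArmsFull / acceleration)))
  if (apc >= nArmsFull) {
    arm <- matrix(rep(0:(nArmsFull - 1L), each = nContrasts),
                  nContrasts, nArmsFull)
    apc <- nArmsFull
  } else {
    phi <- (1 + sqrt(5)) / 2
    inc <- 2 * phi - floor(2 * phi)  # frac(2 * golden ratio)
    q <- 0:(nContrasts - 1L)
    offset <- round(nArmsFull * ((q * inc) %% 1))
    base <- round((0:(apc - 1L)) * nArmsFull / apc)
    arm <- matrix(as.integer(outer(offset, base, `+`) %% nArmsFull),
                  nContrasts, apc)
  }
  new("UndersamplingSchedule", nArmsFull = nArmsFull,
      acceleration = acceleration, armsPerContrast = apc, armIndex = arm)
}

setMethod("show", "SpiralTrajectory", function(object) {
  cat(sprintf(
    "SpiralTrajectory: %d samples, readout %g ms, kmax %g cycles/FOV, %d arms full\n",
    nrow(object@kCoords), object@readoutMs,
    max(sqrt(rowSums(object@kCoords^2))), object@nArmsFull))
})

setMethod("show", "UndersamplingSchedule", function(object) {
  cat(sprintf(
    "UndersamplingSchedule: %d contrasts x %d arms (of %d), acceleration %.3g\n",
    nrow(object@armIndex), object@armsPerContrast, object@nArmsFull,
    object@acceleration))
})
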