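# Discretization of a pulse train into the flat event timeline consumed by
# the compiled Bloch engine. Selective pulses are expanded with the
# hard-pulse approximation (rotation per sub-step capped at hardPulseMaxDeg,
# free precession under the slice-select gradient interleaved symmetrically);
# non-selective or zero-duration pulses are single instantaneous rotations at
# the pulse center. After each selective pulse a rephasing lobe of half the
# slice-select moment is applied, as on the scanner.

deg2rad <- function(x) x * pi / 180

# choose the number of envelope samples so no sub-step rotates by more than
# maxDeg at nominal B1
.envelopeSamples <- function(flipDeg, tbw, maxDeg) {
  n <- 65L
  for (i in 1:20) {
    env <- sincEnvelope(n, tbw)
    ang <- flipDeg * env / sum(env)
    m <- max(abs(ang))
    if (m <= maxDeg) break
    n <- as.integer(ceiling(n * m / maxDeg)) + 1L
  }
  n
}

# registry helpers: map values to small lookup tables
.classIndex <- function(registry, value) {
  hit <- which(abs(registry$values - value) < 1e-12)
  if (length(hit)) return(list(reg = registry, idx = hit[1] - 1L))
  registry$values <- c(registry$values, value)
  list(reg = registry, idx = length(registry$values) - 1L)
}

#' @keywords internal
#' @noRd
buildEventTimeline <- function(train, slabWidth = NULL, instantAll = FALSE,
                               hardPulseMaxDeg = 2) {
  blk <- train@block
  trp <- blk@trp
  offset <- train@readoutStartOffset
  pulses <- rep(blk@pulses, times = train@nBlocks)

  durs <- vapply(pulses, function(p)
    if (instantAll || !p@selective) 0 else p@duration, numeric(1))
  if (any(offset < durs / 2))
    stop("readoutStartOffset must be >= half of every pulse duration")
  if (any(trp - offset < durs / 2))
    stop("trp too short for readout offset plus pulse duration")

  evType <- integer(0); evAngle <- numeric(0)
  evCphi <- numeric(0); evSphi <- numeric(0)
  evRc <- integer(0); evGc <- integer(0)
  dtReg <- list(values = numeric(0))
  gradReg <- list(values = numeric(0))

  addEv <- function(type, angle = 0, phi = 0, rc = -1L, gc = -1L) {
    evType[[length(evType) + 1L]] <<- type
    evAngle[[length(evAngle) + 1L]] <<- angle
    evCphi[[length(evCphi) + 1L]] <<- cos(phi)
    evSphi[[length(evSphi) + 1L]] <<- sin(phi)
    evRc[[length(evRc) + 1L]] <<- rc
    evGc[[length(evGc) + 1L]] <<- gc
  }
  dtClass <- function(dt) {
    if (dt <= 0) return(-1L)
    r <- .classIndex(dtReg, dt); dtReg <<- r$reg; r$idx
  }
  gradClass <- function(gDt) {  # gDt in Hz/mm * ms; table stores rad/mm
    if (gDt == 0) return(-1L)
    r <- .classIndex(gradReg, 2 * pi * gDt / 1000); gradReg <<- r$reg; r$idx
  }

  np <- length(pulses)
  for (i in seq_len(np)) {
    p <- pulses[[i]]
    phi <- deg2rad(p@phaseAxis)
    dur <- durs[i]
    if (dur == 0) {
      addEv(1L, angle = deg2rad(p@flipAngle), phi = phi)
    } else {
      if (is.null(slabWidth))
        stop("selective pulses require a slab width (supply an ensemble)")
      n <- .envelopeSamples(p@flipAngle, p@timeBandwidth, hardPulseMaxDeg)
      env <- sincEnvelope(n, p@timeBandwidth)
      angles <- deg2rad(p@flipAngle) * env / sum(env)
      dt <- dur / n
      gHzPerMm <- 1000 * p@timeBandwidth / dur / slabWidth  # pulse BW / slab
      rcH <- dtClass(dt / 2)
      gcH <- gradClass(gHzPerMm * dt / 2)
      for (k in seq_len(n))
        addEv(1L, angle = angles[k], phi = phi, rc = rcH, gc = gcH)
      # rephasing lobe: minus half the slice-select moment, instantaneous
      addEv(0L, gc = gradClass(-gHzPerMm * dur / 2))
    }
    # free evolution to the echo state, record, then to the next pulse
    addEv(0L, rc = dtClass(offset - dur / 2))
    addEv(2L)
    if (i < np) {
      durNext <- durs[i + 1]
      addEv(0L, rc = dtClass(trp - offset - durNext / 2))
    }
  }

  list(evType = evType, evAngle = evAngle, evCphi = evCphi, evSphi = evSphi,
       evRc = evRc, evGc = evGc, dtMs = dtReg$values, gradAmp = gradReg$values,
       nq = sum(evType == 2L),
       anySelective = any(durs > 0))
}
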