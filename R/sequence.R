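#' Create an RF pulse
#'
#' @param flipAngle flip angle in degrees, in (0, 360)
#' @param phaseAxis rotation-axis azimuth in degrees (x = 0, y = 90)
#' @param duration pulse duration in ms; 0 models the pulse as an
#'   instantaneous rotation at its center
#' @param selective logical, slab-selective (played under a slice-select
#'   gradient, with a windowed-sinc envelope)
#' @param timeBandwidth time-bandwidth product of the selective envelope
#' @param envelopeSamples number of envelope samples for selective pulses;
#'   if NULL, chosen automatically when the timeline is discretized
#' @return an \linkS4class{RFPulse}
#' @export
rfPulse <- function(flipAngle, phaseAxis, duration = 0, selective = FALSE,
                    timeBandwidth = 16, envelopeSamples = NULL) {
  env <- numeric(0)
  if (selective && duration > 0) {
    n <- if (is.null(envelopeSamples)) 129L else as.integer(envelopeSamples)
    env <- sincEnvelope(n, timeBandwidth)
  }
  new("RFPulse", flipAngle = flipAngle, phaseAxis = phaseAxis,
      duration = duration, envelope = env, selective = selective,
      timeBandwidth = if (selective) timeBandwidth else NA_real_)
}

#' Hamming-windowed sinc envelope
#'
#' Surrogate for a Shinnar-Le Roux selective pulse: a sinc of the requested
#' time-bandwidth product under a Hamming window, sampled uniformly. The
#' slab-profile physics (selectivity, edge roll-off), not the exact SLR
#' shape, is the modeling target.
#'
#' @param n number of samples
#' @param tbw time-bandwidth product
#' @return numeric vector of amplitudes (arbitrary units, positive integral)
#' @export
sincEnvelope <- function(n, tbw = 16) {
  t <- seq(-0.5, 0.5, length.out = n)
  x <- pi * tbw * t
  s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  w <- 0.54 + 0.46 * cos(2 * pi * t)
  s * w
}

#' Build the optimized four-pulse block
#'
#' The repeated unit of the transient-state train: flip angles
#' (30, 175, 30, 175) degrees about axes (x, y, y, x), i.e. phase azimuths
#' (0, 90, 90, 0) degrees, separated by the inter-pulse time TRp.
#'
#' @param trp inter-pulse repetition time in ms (> 0)
#' @param selectiveExcitation logical, play the 30-degree pulses slab-selectively
#' @param selectiveInversion logical, play the 175-degree pulses slab-selectively
#' @param pulseDuration duration in ms of selective pulses (0 = instantaneous
#'   for non-selective pulses)
#' @param timeBandwidth time-bandwidth product of selective pulses
#' @return a \linkS4class{SequenceBlock}
#' @examples
#' blk <- buildOptimizedBlock(30)
#' blockDuration(blk)  # 120 ms
#' @export
buildOptimizedBlock <- function(trp, selectiveExcitation = FALSE,
                                selectiveInversion = FALSE,
                                pulseDuration = 1.2, timeBandwidth = 16) {
  if (!(is.numeric(trp) && length(trp) == 1L && trp > 0))
    stop("trp must be a single positive number (ms)")
  flips <- c(30, 175, 30, 175)
  axes <- c(0, 90, 90, 0)
  sel <- c(selectiveExcitation, selectiveInversion,
           selectiveExcitation, selectiveInversion)
  pulses <- lapply(seq_len(4), function(i) {
    rfPulse(flips[i], axes[i],
            duration = if (sel[i]) pulseDuration else 0,
            selective = sel[i], timeBandwidth = timeBandwidth)
  })
  new("SequenceBlock", pulses = pulses, trp = trp)
}

#' Assemble a pulse train
#'
#' @param block a \linkS4class{SequenceBlock}
#' @param nBlocks number of block repetitions (>= 1)
#' @param delay inter-train delay in ms (>= 0)
#' @param readoutStartOffset ms from each pulse center to the first readout
#'   sample; the echo state is defined there and within-readout time offsets
#'   count from it
#' @return a \linkS4class{PulseTrain}
#' @examples
#' tr <- buildPulseTrain(buildOptimizedBlock(30), nBlocks = 12, delay = 3000)
#' nContrasts(tr)       # 48
#' trainDuration(tr)    # 1440 ms
#' @export
buildPulseTrain <- function(block, nBlocks, delay, readoutStartOffset = 2) {
  if (!(is.numeric(nBlocks) && length(nBlocks) == 1L && nBlocks >= 1))
    stop("nBlocks must be >= 1")
  if (!(is.numeric(delay) && length(delay) == 1L && delay >= 0))
    stop("delay must be >= 0")
  new("PulseTrain", block = block, nBlocks = as.integer(nBlocks),
      interTrainDelay = delay, readoutStartOffset = readoutStartOffset)
}

#' @describeIn buildOptimizedBlock total block duration (4 x trp), ms
#' @param block a \linkS4class{SequenceBlock}
#' @export
blockDuration <- function(block) 4 * block@trp

#' Number of contrasts of a pulse train
#'
#' One readout follows every pulse, so the train yields 4 x nBlocks contrasts.
#' @param train a \linkS4class{PulseTrain}
#' @export
nContrasts <- function(train) 4L * train@nBlocks

#' Active duration of a pulse train (excluding the inter-train delay), ms
#' @param train a \linkS4class{PulseTrain}
#' @export
trainDuration <- function(train) train@nBlocks * blockDuration(train@block)

#' Fraction of the repetition spent in the recovery delay
#'
#' The delay between trains ensures magnetization recovery but acquires no
#' data; this returns delay / (train duration + delay), in [0, 1).
#'
#' @param train a \linkS4class{PulseTrain}
#' @return numeric fraction
#' @examples
#' tr <- buildPulseTrain(buildOptimizedBlock(30), 12, 3000)
#' deadTimeFraction(tr)  # 3000 / 4440
#' @export
deadTimeFraction <- function(train) {
  train@interTrainDelay / (trainDuration(train) + train@interTrainDelay)
}

#' @rdname nContrasts
#' @export
trpMs <- function(train) train@block@trp

setMethod("show", "SequenceBlock", function(object) {
  p <- vapply(object@pulses, function(x)
    sprintf("%g°@%g°%s", x@flipAngle, x@phaseAxis,
            if (x@selective) "(sel)" else ""), character(1))
  cat("SequenceBlock:", paste(p, collapse = ", "),
      sprintf("| TRp %g ms\n", object@trp))
})

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf(
    "PulseTrain: %d blocks (%d contrasts), TRp %g ms, train %g ms + delay %g ms\n",
    object@nBlocks, nContrasts(object), trpMs(object),
    trainDuration(object), object@interTrainDelay))
})
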