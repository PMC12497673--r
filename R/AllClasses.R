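#' @import methods
NULL

#' RF pulse description
#'
#' A single radio-frequency pulse of the train: nominal flip angle, the
#' azimuth of its rotation axis in the transverse plane, its duration and
#' (for slab-selective pulses) a sampled amplitude envelope with a given
#' time-bandwidth product. A zero duration means the pulse is modeled as an
#' instantaneous rotation at its center time.
#'
#' @slot flipAngle numeric, degrees, in (0, 360)
#' @slot phaseAxis numeric, degrees, azimuth of the rotation axis (x = 0, y = 90)
#' @slot duration numeric, ms (0 for instantaneous)
#' @slot envelope numeric vector, sampled amplitude waveform (arbitrary units,
#'   uniform dwell); empty for hard/instantaneous pulses
#' @slot selective logical, slab-selective pulse played with a slice-select gradient
#' @slot timeBandwidth numeric, time-bandwidth product (selective pulses only)
#' @export
setClass("RFPulse",
  representation(flipAngle = "numeric", phaseAxis = "numeric",
                 duration = "numeric", envelope = "numeric",
                 selective = "logical", timeBandwidth = "numeric"),
  prototype(envelope = numeric(0), selective = FALSE, timeBandwidth = NA_real_))

setValidity("RFPulse", function(object) {
  msg <- character(0)
  if (!(object@flipAngle > 0 && object@flipAngle < 360))
    msg <- c(msg, "flipAngle must lie in (0, 360) degrees")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (object@selective && object@duration > 0 && length(object@envelope) == 0)
    msg <- c(msg, "selective finite-duration pulse requires an envelope")
  if (length(msg)) msg else TRUE
})

#' Four-pulse sequence block
#'
#' The repeated unit of the pulse train: exactly four RF pulses separated by
#' the inter-pulse repetition time TRp.
#'
#' @slot pulses list of 4 \linkS4class{RFPulse}
#' @slot trp numeric, inter-pulse repetition time in ms
#' @export
setClass("SequenceBlock",
  representation(pulses = "list", trp = "numeric"))

setValidity("SequenceBlock", function(object) {
  msg <- character(0)
  if (length(object@pulses) != 4L)
    msg <- c(msg, "a sequence block holds exactly 4 pulses")
  if (!all(vapply(object@pulses, is, logical(1), class2 = "RFPulse")))
    msg <- c(msg, "pulses must all be RFPulse objects")
  if (!(length(object@trp) == 1L && object@trp > 0))
    msg <- c(msg, "trp must be a single positive number (ms)")
  if (length(msg) == 0 &&
      any(vapply(object@pulses, function(p) p@duration, numeric(1)) >= object@trp))
    msg <- c(msg, "trp must exceed every pulse duration")
  if (length(msg)) msg else TRUE
})

#' Pulse train
#'
#' A repeated four-pulse block, the delay between trains, and the offset
#' from each pulse center to the first readout sample. The number of
#' contrasts is 4 x nBlocks (one readout per pulse).
#'
#' @slot block \linkS4class{SequenceBlock}
#' @slot nBlocks integer, number of block repetitions
#' @slot interTrainDelay numeric, ms
#' @slot readoutStartOffset numeric, ms from pulse center to the first
#'   readout sample (the time at which the echo "state" is defined)
#' @export
setClass("PulseTrain",
  representation(block = "SequenceBlock", nBlocks = "integer",
                 interTrainDelay = "numeric", readoutStartOffset = "numeric"))

setValidity("PulseTrain", function(object) {
  msg <- character(0)
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@interTrainDelay < 0) msg <- c(msg, "interTrainDelay must be >= 0")
  if (object@readoutStartOffset < 0)
    msg <- c(msg, "readoutStartOffset must be >= 0")
  if (object@readoutStartOffset >= object@block@trp)
    msg <- c(msg, "readoutStartOffset must be smaller than trp")
  if (length(msg)) msg else TRUE
})

#' Tissue parameter vector
#'
#' The six-parameter voxel model: complex apparent proton density (real and
#' imaginary part), longitudinal and transverse relaxation times, off-resonance
#' and relative transmit field.
#'
#' @slot i0 complex apparent proton density (arbitrary units)
#' @slot t1 numeric, ms
#' @slot t2 numeric, ms
#' @slot delta numeric, off-resonance in Hz
#' @slot b1 numeric, transmit scale (1 = nominal flip angle)
#' @export
setClass("TissueParams",
  representation(i0 = "complex", t1 = "numeric", t2 = "numeric",
                 delta = "numeric", b1 = "numeric"))

setValidity("TissueParams", function(object) {
  msg <- character(0)
  if (object@t1 <= 0) msg <- c(msg, "t1 must be > 0")
  if (object@t2 <= 0) msg <- c(msg, "t2 must be > 0")
  if (object@b1 <= 0) msg <- c(msg, "b1 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Slab sub-spin ensemble
#'
#' Geometry of the slab-resolved (multi-spin) simulation: sub-spins placed
#' uniformly along the slice axis over slabFactor times the slab width, and
#' the number of balanced z-encodes used to separate slices by inverse
#' Fourier transform.
#'
#' @slot nSubspins integer
#' @slot slabFactor numeric, extent multiplier (sub-spins cover slabFactor x slab width)
#' @slot nZencodes integer, number of z-encodes (slices)
#' @slot slabWidth numeric, slab width in mm (the z-encode field of view)
#' @export
setClass("SlabEnsemble",
  representation(nSubspins = "integer", slabFactor = "numeric",
                 nZencodes = "integer", slabWidth = "numeric"))

setValidity("SlabEnsemble", function(object) {
  msg <- character(0)
  if (object@nSubspins < 1L) msg <- c(msg, "nSubspins must be >= 1")
  if (object@slabFactor <= 0) msg <- c(msg, "slabFactor must be > 0")
  if (object@nZencodes < 1L) msg <- c(msg, "nZencodes must be >= 1")
  if (object@nSubspins < object@nZencodes)
    msg <- c(msg, "nSubspins must be >= nZencodes")
  if (object@slabWidth <= 0) msg <- c(msg, "slabWidth must be > 0 (mm)")
  if (length(msg)) msg else TRUE
})

#' Tissue-parameter grid for dictionary generation
#'
#' T1 and T2 axes are log-spaced, off-resonance and transmit-scale axes are
#' linear; atoms are the Cartesian product with combinations t2 > t1 removed.
#'
#' @slot t1Values numeric, ms
#' @slot t2Values numeric, ms
#' @slot deltaValues numeric, Hz
#' @slot b1Values numeric
#' @slot atoms data.frame with columns t1, t2, delta, b1 and the axis indices
#'   it1, it2, idelta, ib1 (proton density fixed at 1 + 0i)
#' @export
setClass("ParamGrid",
  representation(t1Values = "numeric", t2Values = "numeric",
                 deltaValues = "numeric", b1Values = "numeric",
                 atoms = "data.frame"))

#' Simulated signal dictionary
#'
#' One complex signal evolution (length = number of contrasts) per grid atom,
#' simulated either with a single spin per voxel ("Si") or with the slab
#' ensemble at one slice position ("Mu").
#'
#' @slot atomSignals complex matrix, nContrasts x nAtoms
#' @slot grid \linkS4class{ParamGrid}
#' @slot mode character, "Si" or "Mu"
#' @slot sliceIndex integer, slice position for Mu mode (NA for Si)
#' @slot atomNorms numeric, Euclidean norm per atom
#' @slot train \linkS4class{PulseTrain} used for simulation
#' @slot ensemble the \linkS4class{SlabEnsemble} used in Mu mode (NULL for Si)
#' @export
setClass("SignalDictionary",
  representation(atomSignals = "matrix", grid = "ParamGrid", mode = "character",
                 sliceIndex = "integer", atomNorms = "numeric",
                 train = "PulseTrain", ensemble = "ANY"))

setValidity("SignalDictionary", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("Si", "Mu")) msg <- c(msg, "mode must be 'Si' or 'Mu'")
  if (!is.complex(object@atomSignals)) msg <- c(msg, "atomSignals must be complex")
  if (ncol(object@atomSignals) != length(object@atomNorms))
    msg <- c(msg, "atomNorms length must equal number of atoms")
  if (length(msg) == 0 && any(object@atomNorms == 0))
    msg <- c(msg, "dictionary contains zero-norm atoms")
  if (length(msg)) msg else TRUE
})

#' Truncated contrast subspace
#'
#' Truncated SVD of the dictionary's contrast-by-atom matrix; the first d1
#' left singular vectors span the temporal subspace used by the
#' subspace-constrained reconstruction.
#'
#' @slot basis complex matrix, nContrasts x d1 (orthonormal columns)
#' @slot singularValues numeric, all singular values (non-increasing), kept in
#'   full so energy fractions can be evaluated at any order
#' @slot vFactor complex matrix, nAtoms x d1
#' @slot d1 integer, truncation order
#' @export
setClass("ContrastSubspace",
  representation(basis = "matrix", singularValues = "numeric",
                 vFactor = "matrix", d1 = "integer"))

setValidity("ContrastSubspace", function(object) {
  msg <- character(0)
  if (object@d1 < 1L || object@d1 > nrow(object@basis))
    msg <- c(msg, "d1 must lie in [1, nContrasts]")
  if (ncol(object@basis) != object@d1)
    msg <- c(msg, "basis must have d1 columns")
  if (is.unsorted(rev(object@singularValues)))
    msg <- c(msg, "singular values must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Spiral readout trajectory
#'
#' A single spiral-out interleave: k-space coordinates in cycles/FOV, the
#' within-readout time offset of every sample (tau, ms, tau[1] = 0), and the
#' number of interleaves that together sample k-space at the Nyquist rate.
#'
#' @slot kCoords numeric matrix, nSamples x 2, cycles/FOV
#' @slot tau numeric, ms, strictly increasing from 0
#' @slot readoutMs numeric, readout duration in ms
#' @slot nArmsFull integer, interleaves in the fully sampled design
#' @slot matrixSize integer, nominal image matrix
#' @export
setClass("SpiralTrajectory",
  representation(kCoords = "matrix", tau = "numeric", readoutMs = "numeric",
                 nArmsFull = "integer", matrixSize = "integer"))

setValidity("SpiralTrajectory", function(object) {
  msg <- character(0)
  if (ncol(object@kCoords) != 2L) msg <- c(msg, "kCoords must be nSamples x 2")
  if (nrow(object@kCoords) != length(object@tau))
    msg <- c(msg, "tau length must match kCoords rows")
  if (length(object@tau) && object@tau[1] != 0)
    msg <- c(msg, "first sample must be at tau = 0")
  if (length(object@tau) > 1 && any(diff(object@tau) <= 0))
    msg <- c(msg, "tau must be strictly increasing")
  if (length(msg) == 0 &&
      max(sqrt(rowSums(object@kCoords^2))) > object@matrixSize / 2 + 1e-9)
    msg <- c(msg, "|k| must not exceed matrix/2 cycles/FOV")
  if (length(msg)) msg else TRUE
})

#' Golden-ratio undersampling schedule
#'
#' For each contrast, the interleaves acquired. Arms are selected by
#' incrementing a golden-ratio rotation across shots and contrasts, giving
#' near-uniform angular coverage at any acceleration.
#'
#' @slot nArmsFull integer
#' @slot acceleration numeric
#' @slot armsPerContrast integer
#' @slot armIndex integer matrix, nContrasts x armsPerContrast, 0-based arm ids
#' @export
setClass("UndersamplingSchedule",
  representation(nArmsFull = "integer", acceleration = "numeric",
                 armsPerContrast = "integer", armIndex = "matrix"))

setValidity("UndersamplingSchedule", function(object) {
  msg <- character(0)
  if (object@armsPerContrast < 1L) msg <- c(msg, "armsPerContrast must be >= 1")
  if (ncol(object@armIndex) != object@armsPerContrast)
    msg <- c(msg, "armIndex must have armsPerContrast columns")
  if (length(msg) == 0 &&
      (min(object@armIndex) < 0L || max(object@armIndex) >= object@nArmsFull))
    msg <- c(msg, "arm indices must lie in [0, nArmsFull)")
  if (length(msg)) msg else TRUE
})

#' Non-uniform Fourier sampling operator
#'
#' The per-contrast encoding operator F: an exact non-uniform DFT from the
#' FOV-centered image grid to the k-space samples of the interleaves
#' scheduled for that contrast. Per-arm DFT matrices are precomputed once.
#'
#' @slot gridShape integer vector length 2
#' @slot trajectory \linkS4class{SpiralTrajectory}
#' @slot schedule \linkS4class{UndersamplingSchedule}
#' @slot armMatrices list of complex nSamples x nVoxels matrices, one per arm
#' @export
setClass("SamplingOperator",
  representation(gridShape = "integer", trajectory = "SpiralTrajectory",
                 schedule = "UndersamplingSchedule", armMatrices = "list"))

#' Voxel-wise parameter maps
#'
#' Per-voxel tissue parameters over a 2D grid plus the valid-voxel mask.
#' Masked-out voxels carry zero proton density.
#'
#' @slot i0 complex matrix (apparent proton density)
#' @slot t1 numeric matrix, ms
#' @slot t2 numeric matrix, ms
#' @slot delta numeric matrix, Hz
#' @slot b1 numeric matrix
#' @slot mask logical matrix
#' @export
setClass("ParamMap",
  representation(i0 = "matrix", t1 = "matrix", t2 = "matrix",
                 delta = "matrix", b1 = "matrix", mask = "matrix"))

setValidity("ParamMap", function(object) {
  dims <- lapply(list(object@i0, object@t1, object@t2, object@delta,
                      object@b1, object@mask), dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    return("all parameter maps and the mask must share one shape")
  if (any(object@i0[!object@mask] != 0))
    return("masked voxels must have zero proton density")
  TRUE
})

#' Coil sensitivity maps
#'
#' @slot maps complex array, nx x ny x nCoils
#' @export
setClass("CoilMaps", representation(maps = "array"))

setValidity("CoilMaps", function(object) {
  if (length(dim(object@maps)) != 3L) return("maps must be nx x ny x nCoils")
  if (!is.complex(object@maps)) return("maps must be complex")
  TRUE
})

#' Acquired/synthesized k-space data
#'
#' Complex samples indexed contrast x coil x sample, plus references to the
#' trajectory/schedule that generated the sample positions and timing.
#'
#' @slot samples complex array, nContrasts x nCoils x nSamplesSelected
#' @slot trajectory \linkS4class{SpiralTrajectory}
#' @slot schedule \linkS4class{UndersamplingSchedule}
#' @slot noiseSd numeric
#' @slot seed integer (NA if no noise drawn)
#' @export
setClass("KSpaceData",
  representation(samples = "array", trajectory = "SpiralTrajectory",
                 schedule = "UndersamplingSchedule", noiseSd = "numeric",
                 seed = "integer"))

setValidity("KSpaceData", function(object) {
  if (length(dim(object@samples)) != 3L)
    return("samples must be nContrasts x nCoils x nSamples")
  if (!all(is.finite(Re(object@samples)) & is.finite(Im(object@samples))))
    return("samples must be finite")
  expected <- object@schedule@armsPerContrast * nrow(object@trajectory@kCoords)
  if (dim(object@samples)[3] != expected)
    return("sample count inconsistent with schedule and trajectory")
  TRUE
})

#' Truncated phase subspace for B0 compensation
#'
#' Truncated SVD of the within-readout off-resonance phase matrix
#' exp(-i 2 pi Delta_v tau_p), indexed sample x voxel.
#'
#' @slot uTilde complex matrix, nSamples x d2 (orthonormal columns)
#' @slot sTilde numeric, all singular values (non-increasing)
#' @slot vTilde complex matrix, nVoxels x d2
#' @slot d2 integer
#' @export
setClass("PhaseSubspace",
  representation(uTilde = "matrix", sTilde = "numeric", vTilde = "matrix",
                 d2 = "integer"))

#' Component (subspace coefficient) images
#'
#' @slot coefficients complex matrix, d1 x nVoxels
#' @slot subspace \linkS4class{ContrastSubspace}
#' @export
setClass("ComponentImages",
  representation(coefficients = "matrix", subspace = "ContrastSubspace"))

#' Off-resonance map
#'
#' @slot delta numeric matrix, Hz
#' @slot wrapped logical, TRUE if values are confined to the +-1/(2 TRp) band
#' @slot mask logical matrix
#' @export
setClass("B0Map",
  representation(delta = "matrix", wrapped = "logical", mask = "matrix"))
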