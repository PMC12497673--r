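---
title: "Transient-state bSSFP multi-parameter mapping: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient-state bSSFP multi-parameter mapping: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

The sequence modeled here is a transient-state balanced SSFP train: an
optimized block of four RF pulses (30° about x, 175° about y, 30° about y,
175° about x) separated by TRp = 30 ms, repeated 12 times (1440 ms), with a
spiral readout after every pulse and a 3 s recovery delay between trains.
Each of the 48 readouts is a *contrast* q; because the magnetization never
reaches steady state, the complex echo-state series across contrasts encodes
the six voxel parameters

θ = (Re I0, Im I0, T1, T2, Δ, B1),

where I0 is the apparent proton density (a complex linear scale), T1 and T2
are relaxation times in ms, Δ is off-resonance in Hz, and B1 a
dimensionless transmit scale (1 = nominal flip angle). The echo state is
defined `readoutStartOffset` (default 2 ms) after the pulse center; the
within-readout clock τ counts from it, with τ₁ = 0. That offset convention
is internal: any consistent value works because synthesis, reconstruction
and fitting all share the same timeline.

Conventions used everywhere: right-handed rotations about transverse axes,
left-handed precession for positive Δ (a transverse phase factor
e^{-i 2π Δ t}), equilibrium magnetization normalized to 1, and I0 applied as
a complex scale to the recorded transverse signal.

## Single-spin and slab-resolved simulation

`simulateSi()` treats pulses as instantaneous rotations — the standard
dictionary-generation approximation. `simulateMu()` resolves the excited
slab: sub-spins are distributed along the slice axis over 1.8× the slab
width (production default 5000, desk default 64), selective pulses are
discretized with a hard-pulse approximation (at most 2° rotation per
sub-step, configurable; symmetric interleaving of precession under the
slice-select gradient; a rephasing lobe of half the select moment after
each pulse), and the selective envelope is a Hamming-windowed sinc of
time-bandwidth 16 standing in for the scanner's SLR design — the slab-edge
physics, not the proprietary waveform, is the modeling target. Balanced
z-encodes are linear in the sub-spin signals, so encode-then-inverse-DFT
collapses to one fixed Dirichlet weight per (sub-spin, slice)
(`zencodeWeights()`); the encoded field of view equals the simulated
extent, so out-of-slab magnetization excited by non-selective inversion
pulses lands on the outer slices instead of folding into the slab. When no
pulse is selective every sub-spin shares one history and the ensemble
collapses to a single spin exactly; the implementation takes that fast path
unless asked not to.

The off-resonance wrap period follows from the TRp-periodic evolution:
signals at Δ and Δ + 1000/TRp Hz differ only by the readout-offset phase,
which is a contrast-independent factor absorbed into I0. Fitted Δ is
therefore confined to ±16.67 Hz at TRp 30 ms and must be spatially
unwrapped.

# Acquisition model

In-plane encoding is a stack-of-spirals: an analytic constant-pitch
Archimedean interleave reaching |k| = matrix/2 cycles/FOV at the end of the
readout, rotated into `nArms` interleaves (16 by default, the count
consistent with the acceleration set {2, 4, 5.33, 8} yielding
{8, 4, 3, 2} interleaves per contrast). The slice direction is fully
sampled, so an inverse Fourier transform decouples slices and all
reconstruction is 2D per slice. Undersampling skips interleaves per
contrast: each contrast acquires a maximally uniform subset rotated by a
golden-ratio increment per contrast, so aliasing is uniform within a
contrast and complementary across neighboring contrasts. (The published
description fixes only the golden-ratio character of the per-contrast
rotation, not the exact indexing; the uniform-subset rule is this package's
reading, chosen because clustered subsets make per-contrast aliasing
strongly anisotropic.)

During the extended (22 ms) readouts the only off-resonance effect modeled
is the phase e^{-i 2π Δ_v τ_p}; within-readout relaxation is neglected — a
documented fidelity limit of the signal model. The encoding operator is an
exact non-uniform DFT with precomputed per-interleave matrices (image
coordinates FOV-centered, k in cycles/FOV, forward phase
e^{-i 2π k·r/N}); at the package's problem sizes dense BLAS products are
faster and simpler than gridded approximations, and the adjoint is exact by
construction.

# Reconstruction

All solvers minimize a least-squares data fit by conjugate gradient on the
normal equations (zero start, relative-residual stop; defaults 40
iterations, 1e-6). Radial density-compensation weighting preconditions the
normal equations by default; for consistent full-rank systems it leaves the
solution unchanged while removing the slow convergence caused by the
center-heavy spiral density.

* `senseB0()` reconstructs each contrast independently from its coil-weighted
  samples; with a phase subspace supplied, the B0 phase during the readout
  is part of the forward model.
* `scr()` constrains all contrasts to d1 temporal components U from the
  truncated SVD of the dictionary (default d1 = 12, which captures ≥ 99% of
  the squared singular-value energy of the slab-resolved dictionary) and
  solves jointly for the component images.
* `scrB0()` adds the second SVD: the within-readout phase matrix
  e^{-iΔτ} (sample × voxel) truncated to d2 components. d2 defaults to the
  smallest order holding 99.9% of the phase-matrix energy, capped at 16;
  published settings for this order are not available, so the energy rule
  makes the choice reproducible. For very large maps the phase SVD uses a
  regular voxel subsample for the left basis and projects for the right one.

Two practical notes established on the synthetic testbed. First, at high
acceleration the part of the true signal outside the d1-dimensional basis
aliases into the component images; CG iteration count acts as a mild
regularizer there (the default 40 is a good operating point, and fits on
subspace-reconstructed images are performed in the compressed domain —
dictionary atoms projected onto the same basis — so the truncation residual
cannot bias the match systematically). Second, recovery statements about
"exact" reconstruction are only meaningful on the operator's row space: a
spiral disk never samples the k-space corners of a rectangular grid, so the
test suite projects ground truth onto the observable subspace (computed
densely on small toys) before asserting 1e-5/1e-6-level agreement.

# Dictionary fitting

`matchDictionary()` implements match-then-interpolate fitting. Stage 1
maximizes the normalized complex correlation |⟨d, y⟩|/‖d‖ over the grid —
invariant to the complex scale of y, which becomes the I0 estimate of the
winner. Stage 2 refines each nonlinear parameter coordinate-wise by a
quadratic fit of the metric at the winning node and its grid neighbors
(log scale for T1/T2, vertex clamped to the neighbor interval, grid value
kept at edges or where the metric is flat). Because the published
refinement procedure's details (automatic step selection for a target
interpolation accuracy) are not available, the package adds a documented
iterated variant of the same idea: up to `refineIters` (default 3)
further coordinate passes evaluate the metric on re-simulated atoms around
the current off-grid estimate with a halving step. This sharpens recovery
along the correlated T1–B1 ridge of the four-pulse train from several
percent to a few tenths of a percent at negligible cost, while remaining a
match-then-interpolate scheme. A small number of voxels on strong ridges
can still lock into a wrong basin of the correlation landscape — medians
are the robust summary, and the limitation is inherited by any
single-start grid search.

Default grid semantics: T1 ∈ [100, 2500] ms and T2 ∈ [20, 300] ms
log-spaced, Δ ∈ [-200, 200] Hz and B1 ∈ [0.8, 1.2] linear, combinations
with T2 > T1 excluded (physically motivated; the measurement model is
near-degenerate there anyway). Two different grids serve two different
purposes: the *basis* grid spans the full Δ range (matching how the
temporal subspace is built for reconstruction), while the *fit* grid
confines Δ to one wrap band — atoms a wrap period apart are identical up
to an absorbable phase, so a wide fit axis only creates ambiguous
duplicates. Fixed default step counts (pipeline defaults: 28/24/15/5 for
fitting, 12/10/11/5 for the basis) replace the unavailable automatic
selection rule; both are config overrides.

# Two-pass off-resonance pipeline

`runPipeline()` chains: uncompensated subspace reconstruction → dictionary
fit → wrapped Δ map → spatial unwrap → phase subspace → B0-compensated
reconstruction (per-contrast SENSE or subspace-constrained, by `method`) →
final fit; maps are written as NIfTI with a JSON provenance log. The
unwrapping algorithm is a quality-guided region growing written for this
package (the published appendix describing the original algorithm is not
available): per connected mask component, growth starts at the
highest-quality voxel (proton-density magnitude), admits voxels in
decreasing quality order, and shifts each by the integer number of wrap
periods closest to the mean of its settled neighbors. Each component is
anchored to its own seed; inter-component multiples are unresolved, which
is irrelevant when every component's seed sits where the true field is
in-band, and is flagged as a limitation otherwise. The final fitted Δ is
re-referenced to the unwrapped map by adding the per-voxel integer number
of wrap periods.

# The synthetic testbed

`makePhantom()` builds a four-tube disk phantom in the spirit of a
standard relaxometry test object — T1 = {300, 600, 1000, 1500} ms,
T2 = {50, 80, 120, 200} ms are package-defined synthetic values, since the
calibrated tube values of the physical phantom are not published. Proton
density rolls off linearly over 1.5 px at tube edges, emulating partial
volume while keeping relaxation constant within a tube (edge voxels change
amplitude, not signal shape) and keeping the phantom's spectrum compact on
the small grids used here. The default off-resonance field is a radial
polynomial spanning roughly -5 to +35 Hz across the field of view with
tube values inside the wrap band (so the default pipeline exercises
fitting and compensation but not unwrapping, which has its own dedicated
ramps); the default transmit field is a radial profile within [0.8, 1.04],
kept off the grid edge because dictionary estimates clamp there. Coil maps
are Gaussian-lobe magnitudes with low-order polynomial phase — smooth,
band-limited, strictly positive in root-sum-of-squares, standing in for
measured sensitivities (sensitivity calibration itself is out of scope).
Noise, when requested, is i.i.d. complex Gaussian per sample with a stored
seed.

What the testbed does *not* emulate: gradient imperfections and eddy
currents, concomitant fields, within-readout relaxation, magnetization
transfer (a candidate explanation for in vivo T1 underestimation by this
family of sequences), motion, and realistic coil noise correlation.
Passing tests therefore demonstrate correctness of the algorithms under
the stated signal model, not scanner-grade validation.

# Problem sizes and numerical choices

Default desk-scale sizes, chosen once as the smallest configurations that
leave the studied effects clearly visible: 32×32 image grids with 16-arm,
3-turn, 320-sample spiral planes (the multi-turn arms reproduce the dense
per-contrast radial coverage that the published 256-matrix acquisition has
and that single-turn toy spirals lack); 4 synthetic coils; 64 sub-spins and
8 z-encodes for the slab ensemble; a ~8 400-atom slab-resolved dictionary
for the subspace energy computation; ~46 000-atom single-spin fit
dictionaries. Degenerate inputs are handled explicitly: all-zero voxels are
flagged invalid and masked, empty masks abort the pipeline with a staged
diagnostic, single-voxel mask components pass through unwrapping unchanged,
and zero data reconstructs to exactly zero. Ties in the correlation search
break toward the first atom; Δ fit axes should stay strictly inside one
wrap band to avoid exact-alias ties at the endpoints.
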