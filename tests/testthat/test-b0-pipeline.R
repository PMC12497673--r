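# First-pass estimation, unwrapping and the two-pass orchestration on
# reduced problem sizes (16x16 grids, small fit dictionaries).

smallPipelineConfig <- function(...) {
  base <- list(
    trajectory = list(matrix = 16, nSamples = 96, turns = 2),
    coils = list(n = 2, smoothness = 0.5),
    phantom = list(tubeCenters = rbind(c(-4, -4), c(4, 4)), tubeRadius = 3,
                   t1 = c(600, 1200), t2 = c(80, 150)),
    basis = list(steps = c(t1 = 8, t2 = 6, delta = 7, b1 = 3)),
    fit = list(steps = c(t1 = 14, t2 = 12, delta = 9, b1 = 3)),
    cg = list(maxIter = 20, tol = 1e-6))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    else base[[nm]] <- over[[nm]]
  }
  pipelineConfig(base)
}

smallB0Setup <- function(b0Spec) {
  cfg <- smallPipelineConfig()
  tr <- buildPulseTrain(buildOptimizedBlock(30), 12, 3000)
  ph <- smallPhantom(b0Spec = b0Spec)
  traj <- suppressWarnings(designSpiral(16, 220, 16, 22, 96, turns = 2))
  op <- buildOperator(traj, scheduleArms(48, 16, 2), c(16, 16))
  coils <- makeCoilMaps(2, c(16, 16), smoothness = 0.5)
  kd <- synthesizeKspace(ph, tr, op, coils)
  g <- makeParamGrid(deltaRange = c(-wrapPeriod(tr) / 2, wrapPeriod(tr) / 2),
                     steps = c(t1 = 10, t2 = 8, delta = 9, b1 = 3))
  dict <- buildDictionary(g, tr, "Si")
  gb <- makeParamGrid(steps = c(t1 = 8, t2 = 6, delta = 7, b1 = 3))
  ss <- computeSubspace(buildDictionary(gb, tr, "Si"), 12)
  list(tr = tr, ph = ph, op = op, coils = coils, kd = kd, dict = dict,
       ss = ss)
}

test_that("first pass recovers small off-resonance and aliases large one", {
  s0 <- smallB0Setup(list(const = 0, linx = 0, liny = 0, quad = 0))
  est <- suppressWarnings(
    estimateB0Initial(s0$kd, s0$coils, s0$op, s0$dict, s0$ss, s0$ph@mask,
                      maxIter = 20))
  expect_true(est$b0@wrapped)
  expect_lt(max(abs(est$b0@delta[s0$ph@mask])), 1.5)

  s10 <- smallB0Setup(list(const = 10, linx = 0, liny = 0, quad = 0))
  est10 <- suppressWarnings(
    estimateB0Initial(s10$kd, s10$coils, s10$op, s10$dict, s10$ss,
                      s10$ph@mask, maxIter = 20))
  expect_lt(median(abs(est10$b0@delta[s10$ph@mask] - 10)), 1.5)

  # +40 Hz lies outside the +-16.67 Hz band: the estimate aliases down
  s40 <- smallB0Setup(list(const = 40, linx = 0, liny = 0, quad = 0))
  est40 <- suppressWarnings(
    estimateB0Initial(s40$kd, s40$coils, s40$op, s40$dict, s40$ss,
                      s40$ph@mask, maxIter = 20))
  vals <- est40$b0@delta[s40$ph@mask]
  expect_true(all(abs(vals) <= 1000 / 60 + 1e-6))
  expect_lt(median(abs(vals - (40 - 1000 / 30))), 1.5)

  # the dictionary's off-resonance axis must cover a wrap period
  gNarrow <- makeParamGrid(deltaRange = c(-5, 5),
                           steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 1))
  dNarrow <- buildDictionary(gNarrow, s0$tr, "Si")
  expect_error(estimateB0Initial(s0$kd, s0$coils, s0$op, dNarrow, s0$ss,
                                 s0$ph@mask), "wrap period")
})

test_that("unwrapping reverses wrapping of smooth ramps up to the anchor", {
  tr <- defaultTrain()
  period <- wrapPeriod(tr)
  expect_equal(period, 1000 / 30)
  nx <- 24
  x <- matrix(((seq_len(nx) - 1) - nx / 2) / (nx / 2), nx, nx)
  mask <- matrix(TRUE, nx, nx)
  quality <- exp(-(x^2 + t(x)^2))   # anchor at the center (in-band truth)
  for (amp in c(40, 60)) {
    truth <- amp * x
    wrapped <- (truth + period / 2) %% period - period / 2
    b0 <- new("B0Map", delta = wrapped, wrapped = TRUE, mask = mask)
    uw <- unwrapB0(b0, tr, quality)
    expect_false(uw@wrapped)
    expect_lt(max(abs(uw@delta - truth)), 1e-9)
    # output differs from input by integer multiples of the wrap period
    k <- (uw@delta - wrapped) / period
    expect_lt(max(abs(k - round(k))), 1e-9)
    # neighbor jumps inside the mask stay below half a period
    expect_lt(max(abs(diff(uw@delta))), period / 2)
  }

  # a map without wraps passes through unchanged
  smooth <- 12 * x
  b0s <- new("B0Map", delta = smooth, wrapped = TRUE, mask = mask)
  expect_equal(unwrapB0(b0s, tr, quality)@delta, smooth)
  # single-voxel mask is left untouched; empty mask is an error
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  b1v <- new("B0Map", delta = matrix(5, 3, 3), wrapped = TRUE, mask = m1)
  expect_equal(unwrapB0(b1v, tr)@delta, matrix(5, 3, 3))
  expect_error(unwrapB0(new("B0Map", delta = matrix(0, 2, 2),
                            wrapped = TRUE, mask = matrix(FALSE, 2, 2)), tr),
               "empty")
  # already-unwrapped maps are returned as-is
  done <- new("B0Map", delta = smooth, wrapped = FALSE, mask = mask)
  expect_identical(unwrapB0(done, tr), done)
})

test_that("disconnected mask components are unwrapped independently", {
  tr <- defaultTrain()
  period <- wrapPeriod(tr)
  delta <- matrix(0, 9, 9)
  mask <- matrix(FALSE, 9, 9)
  mask[2:4, 2:4] <- TRUE     # component A: constant 5 Hz
  mask[6:8, 6:8] <- TRUE     # component B: ramp crossing the band edge
  delta[2:4, 2:4] <- 5
  rampB <- matrix(seq(10, 40, length.out = 9), 3, 3)
  delta[6:8, 6:8] <- (rampB + period / 2) %% period - period / 2
  b0 <- new("B0Map", delta = delta, wrapped = TRUE, mask = mask)
  q <- matrix(0, 9, 9); q[2, 2] <- 2; q[6, 6] <- 2
  q[mask & q == 0] <- 1
  uw <- unwrapB0(b0, tr, q)
  expect_equal(uw@delta[2:4, 2:4], matrix(5, 3, 3))
  # component B is smooth after unwrapping (anchored to its own seed)
  d <- uw@delta[6:8, 6:8]
  expect_lt(max(abs(diff(as.vector(d)))), period / 2)
})

test_that("two-pass pipeline is deterministic and improves the T2 map", {
  cfg <- smallPipelineConfig(method = "scr-b0", acceleration = 2,
                             phantom = list(
                               tubeCenters = rbind(c(-4, -4), c(4, 4)),
                               tubeRadius = 3, t1 = c(600, 1200),
                               t2 = c(80, 150),
                               b0Spec = list(const = -4, linx = 10, liny = 0,
                                             quad = 8)))
  r1 <- suppressWarnings(runPipeline(cfg))
  r2 <- suppressWarnings(runPipeline(cfg))
  expect_identical(r1$maps@t1, r2$maps@t1)
  expect_identical(r1$maps@t2, r2$maps@t2)
  expect_identical(r1$b0@delta, r2$b0@delta)

  # pass 2 (B0-compensated) T2 at least as accurate as pass 1
  msk <- r1$truth@mask
  rmse <- function(t2hat) sqrt(mean((t2hat - r1$truth@t2[msk])^2))
  expect_lte(rmse(r1$fit$t2), rmse(r1$pass1$fit$t2) + 1e-9)

  # maps land near the truth even at this deliberately coarse setting
  # (16x16 grid, 2 coils, 20 CG iterations); accuracy at the full study
  # conditions is asserted in the acceptance suite
  expect_lt(median(abs(r1$maps@t1[msk] - r1$truth@t1[msk]) /
                   r1$truth@t1[msk]), 0.12)
  expect_lt(median(abs(r1$maps@t2[msk] - r1$truth@t2[msk]) /
                   r1$truth@t2[msk]), 0.12)
  expect_lt(median(abs(r1$maps@delta[msk] - r1$truth@delta[msk])), 1.5)
})

test_that("pipeline writes NIfTI maps and a provenance log", {
  outDir <- file.path(tempdir(), "mpssfp-out")
  unlink(outDir, recursive = TRUE)
  cfg <- smallPipelineConfig(method = "scr-b0", acceleration = 2,
                             outDir = outDir)
  r <- suppressWarnings(runPipeline(cfg))
  files <- list.files(outDir)
  for (f in c("t1_ms.nii.gz", "t2_ms.nii.gz", "delta_hz.nii.gz", "b1.nii.gz",
              "i0_magnitude.nii.gz", "i0_phase.nii.gz",
              "b0_unwrapped_hz.nii.gz", "provenance.json"))
    expect_true(f %in% files)
  vol <- as.array(RNifti::readNifti(file.path(outDir, "t1_ms.nii.gz")))
  expect_equal(dim(vol)[1:2], c(16L, 16L))
  volM <- matrix(vol, 16, 16)
  expect_equal(volM[r$maps@mask], r$maps@t1[r$maps@mask], tolerance = 1e-6)
  prov <- jsonlite::read_json(file.path(outDir, "provenance.json"))
  expect_equal(prov$d2, r$info$d2)
  unlink(outDir, recursive = TRUE)
})

test_that("pipeline rejects empty masks and unknown methods with diagnostics", {
  cfg <- smallPipelineConfig(mask = matrix(FALSE, 16, 16))
  expect_error(suppressWarnings(runPipeline(cfg)), "mask is empty")
  cfg2 <- smallPipelineConfig(method = "magic")
  expect_error(runPipeline(cfg2), "method")
  # stage labeling on failure
  cfg3 <- smallPipelineConfig(phantom = list(t1 = c(1, 2, 3)))
  expect_error(suppressWarnings(runPipeline(cfg3)), "phantom")
})
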