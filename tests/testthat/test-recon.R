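# Dense-oracle checks of the CG reconstructions. On spiral samplings the
# encoding never observes image content outside its k-space disk (the grid
# corners), so "exact recovery" statements are asserted against the
# row-space projection of the truth, computed densely per toy problem.

denseEncoding <- function(op, coils, deltaMap, q = 1) {
  cm <- matrix(coils@maps, prod(op@gridShape))
  tau <- op@trajectory@tau
  W <- exp(-2i * pi * outer(tau / 1000, as.numeric(deltaMap)))
  arms <- op@schedule@armIndex[q, ] + 1L
  EW <- do.call(rbind, lapply(arms, function(a) op@armMatrices[[a]] * W))
  do.call(rbind, lapply(seq_len(ncol(cm)), function(c0)
    EW * rep(cm[, c0], each = nrow(EW))))
}

rowSpaceProjector <- function(A, tol = 1e-9) {
  sv <- svd(A)
  r <- sum(sv$d > tol * sv$d[1])
  V <- sv$v[, seq_len(r), drop = FALSE]
  V %*% Conj(t(V))
}

test_that("phase subspace is exact for trivial and complete truncations", {
  tau <- seq(0, 22, length.out = 40)
  # zero off-resonance: rank one, single component reproduces exactly
  ps0 <- phaseSubspace(matrix(0, 4, 4), tau, d2 = 1)
  W0 <- ps0@uTilde %*% (ps0@sTilde[1] * Conj(t(ps0@vTilde)))
  expect_equal(W0, matrix(1 + 0i, 40, 16), tolerance = 1e-12)
  expect_equal(energyFraction(ps0, 1), 1)

  # full decomposition reproduces the phase matrix to machine precision
  set.seed(2)
  delta <- runif(30, -80, 80)
  W <- exp(-2i * pi * outer(tau / 1000, delta))
  psF <- phaseSubspace(delta, tau, d2 = min(40, 30))
  WF <- psF@uTilde %*% (diag(psF@sTilde[1:psF@d2]) %*% Conj(t(psF@vTilde)))
  expect_lt(relErr(WF, W), 1e-10)
})

test_that("phase truncation error equals the tail singular energy", {
  tau <- seq(0, 22, length.out = 48)
  set.seed(5)
  delta <- runif(64, -100, 100)   # 64-voxel toy
  W <- exp(-2i * pi * outer(tau / 1000, delta))
  ps <- phaseSubspace(delta, tau, d2 = 5)
  Wt <- ps@uTilde %*% (diag(ps@sTilde[1:5]) %*% Conj(t(ps@vTilde)))
  expect_equal(sum(abs(W - Wt)^2), sum(ps@sTilde[-(1:5)]^2), tolerance = 1e-8)
  # automatic selection reaches the energy target
  psA <- phaseSubspace(delta, tau)
  expect_gte(energyFraction(psA, psA@d2), 0.999)
})

test_that("voxel-subsampled phase decomposition matches the exact one", {
  tau <- seq(0, 22, length.out = 32)
  delta <- seq(-60, 60, length.out = 500)
  psE <- phaseSubspace(delta, tau, d2 = 6)
  psS <- phaseSubspace(delta, tau, d2 = 6, maxVoxelsExact = 100L)
  W <- exp(-2i * pi * outer(tau / 1000, delta))
  rec <- function(ps) ps@uTilde %*% (diag(ps@sTilde[1:6]) %*% Conj(t(ps@vTilde)))
  expect_lt(relErr(rec(psS), W), 2 * max(relErr(rec(psE), W), 1e-6))
})

test_that("SENSE solution matches the dense pseudo-inverse on a tiny instance", {
  # 8x8 grid, 2 coils, 1 contrast, off-resonance in the model
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  traj <- suppressWarnings(designSpiral(8, 220, 8, 22, 30))
  op <- buildOperator(traj, scheduleArms(4, 8, 1), c(8, 8))
  coils <- makeCoilMaps(2, c(8, 8), smoothness = 0.6)
  delta <- matrix(seq(-20, 20, length.out = 64), 8, 8)
  ph <- makePhantom(c(8, 8), tubeCenters = rbind(c(0, 0)), tubeRadius = 2.5,
                    t1 = 800, t2 = 90,
                    b0Spec = list(const = 0, linx = 0, liny = 0, quad = 0))
  ph@delta <- delta
  kd <- synthesizeKspace(ph, tr, op, coils)
  ps <- phaseSubspace(delta, traj@tau, d2 = 8)

  # dense forward including the truncated phase model, matching the solver
  cm <- matrix(coils@maps, 64)
  armsE <- do.call(rbind, lapply(op@schedule@armIndex[1, ] + 1L,
                                 function(a) op@armMatrices[[a]]))
  ns <- nrow(traj@kCoords)
  uRep <- ps@uTilde[rep(seq_len(ns), op@schedule@armsPerContrast), , drop = FALSE]
  Adense <- do.call(rbind, lapply(1:2, function(c0) {
    Reduce(`+`, lapply(seq_len(ps@d2), function(w)
      (armsE * rep(ps@sTilde[w] * Conj(ps@vTilde[, w]) * cm[, c0],
                   each = nrow(armsE))) * uRep[, w]))
  }))
  y <- c(kd@samples[1, 1, ], kd@samples[1, 2, ])
  sv <- svd(Adense)
  r <- sum(sv$d > 1e-9 * sv$d[1])
  xPinv <- sv$v[, 1:r] %*% ((Conj(t(sv$u[, 1:r])) %*% y) / sv$d[1:r])

  kd1 <- kd
  kd1@samples <- kd@samples[1, , , drop = FALSE]
  xCg <- suppressWarnings(
    senseB0(kd1, coils, op, ps, maxIter = 300, tol = 1e-12, dcf = FALSE))
  expect_lt(relErr(as.vector(xCg[1, ]), as.vector(xPinv)), 1e-6)
})

test_that("identity-encoding limit: uniform coil, full sampling, no off-resonance", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 1, nCoils = 1)
  ph <- smallPhantom()
  M <- simulateVoxelSignals(ph, tr)
  A <- denseEncoding(acq$op, acq$coils, matrix(0, 16, 16))
  P <- rowSpaceProjector(A)
  Mproj <- t(P %*% t(M))  # observable part of the truth
  kd <- synthesizeFromSignals(Mproj, matrix(0, 16, 16), acq$op, acq$coils)
  img <- suppressWarnings(
    senseB0(kd, acq$coils, acq$op, NULL, maxIter = 400, tol = 1e-12))
  expect_lt(relErr(img, Mproj), 1e-6)
})

test_that("complete-basis SCR equals per-contrast SENSE when fully sampled", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)  # 4 contrasts
  traj <- suppressWarnings(designSpiral(8, 220, 8, 22, 40))
  op <- buildOperator(traj, scheduleArms(4, 8, 1), c(8, 8))
  coils <- makeCoilMaps(2, c(8, 8), smoothness = 0.6)
  acq <- list(op = op, coils = coils)
  ph <- makePhantom(c(8, 8), tubeCenters = rbind(c(-2, -2), c(2, 2)),
                    tubeRadius = 1.6, t1 = c(600, 1200), t2 = c(80, 150),
                    b0Spec = list(const = 0, linx = 0, liny = 0, quad = 0))
  kd <- synthesizeKspace(ph, tr, acq$op, acq$coils)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 4)  # d1 = nq
  sense <- suppressWarnings(
    senseB0(kd, acq$coils, acq$op, NULL, maxIter = 300, tol = 1e-12))
  comp <- suppressWarnings(
    scr(kd, acq$coils, acq$op, ss, maxIter = 600, tol = 1e-12))
  expect_lt(relErr(composeContrasts(ss, comp), sense), 1e-6)
})

test_that("B0-compensated SCR collapses to plain SCR at zero off-resonance", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 2)
  ph <- smallPhantom()
  kd <- synthesizeKspace(ph, tr, acq$op, acq$coils)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 4)
  ps <- phaseSubspace(matrix(0, 16, 16), acq$traj@tau, d2 = 1)
  a <- suppressWarnings(scr(kd, acq$coils, acq$op, ss, maxIter = 30,
                            tol = 1e-10))
  b <- suppressWarnings(scrB0(kd, acq$coils, acq$op, ss, ps, maxIter = 30,
                              tol = 1e-10))
  expect_lt(relErr(b@coefficients, a@coefficients), 1e-8)
})

test_that("end-to-end: full sampling, complete bases recover the observable truth", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 1)
  ph <- smallPhantom(b0Spec = list(const = -5, linx = 12, liny = 0, quad = 8))
  M <- simulateVoxelSignals(ph, tr)
  A <- denseEncoding(acq$op, acq$coils, ph@delta)
  P <- rowSpaceProjector(A)
  Mproj <- t(P %*% t(M))
  kd <- synthesizeFromSignals(Mproj, ph@delta, acq$op, acq$coils)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 4)   # complete
  ps <- phaseSubspace(ph@delta, acq$traj@tau, d2 = 20)     # numerically full
  comp <- suppressWarnings(
    scrB0(kd, acq$coils, acq$op, ss, ps, maxIter = 500, tol = 1e-12))
  expect_lt(relErr(composeContrasts(ss, comp), Mproj), 1e-5)
})

test_that("model objective at the truth beats the zero solution", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 2)
  ph <- smallPhantom(b0Spec = list(const = 4, linx = 8, liny = 0, quad = 0))
  M <- simulateVoxelSignals(ph, tr)
  kd <- synthesizeKspace(ph, tr, acq$op, acq$coils)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 4)
  ps <- phaseSubspace(ph@delta, acq$traj@tau, d2 = 10)
  cm <- matrix(acq$coils@maps, 256)
  uExp <- mpssfp:::.expandPhaseBasis(ps, acq$op)
  sigmaTrue <- Conj(t(ss@basis)) %*% M
  obj <- function(sig) {
    Yh <- mpssfp:::.forwardComponents(acq$op, cm, ss@basis, sig, ps, uExp)
    sum(abs(kd@samples - Yh)^2)
  }
  expect_lt(obj(sigmaTrue), obj(sigmaTrue * 0))
})

test_that("the full B0-compensated forward operator passes the adjoint test", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 16 / 3)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 3)
  set.seed(9)
  delta <- matrix(runif(256, -40, 40), 16, 16)
  ps <- phaseSubspace(delta, acq$traj@tau, d2 = 4)
  cm <- matrix(acq$coils@maps, 256)
  uExp <- mpssfp:::.expandPhaseBasis(ps, acq$op)
  U <- ss@basis
  sig <- matrix(complex(real = rnorm(3 * 256), imaginary = rnorm(3 * 256)),
                3, 256)
  np <- samplesPerContrast(acq$op)
  Y <- array(complex(real = rnorm(4 * 2 * np), imaginary = rnorm(4 * 2 * np)),
             dim = c(4, 2, np))
  Fs <- mpssfp:::.forwardComponents(acq$op, cm, U, sig, ps, uExp)
  Fa <- mpssfp:::.adjointComponents(acq$op, cm, U, Y, ps, uExp)
  ip1 <- sum(Conj(Y) * Fs)
  ip2 <- sum(Conj(Fa) * sig)
  expect_lt(abs(ip1 - ip2) / sqrt(sum(abs(sig)^2) * sum(abs(Y)^2)), 1e-6)
})

test_that("normal-equation CG residuals decrease monotonically", {
  tr <- buildPulseTrain(buildOptimizedBlock(30), 1, 0)
  acq <- smallAcq(acceleration = 16 / 3)
  ph <- smallPhantom()
  kd <- synthesizeKspace(ph, tr, acq$op, acq$coils)
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 3)
  cm <- matrix(acq$coils@maps, 256)
  rhs <- mpssfp:::.adjointComponents(acq$op, cm, ss@basis, kd@samples, NULL, NULL)
  fit <- suppressWarnings(cgSolve(function(x)
    mpssfp:::.adjointComponents(acq$op, cm, ss@basis,
      mpssfp:::.forwardComponents(acq$op, cm, ss@basis, x, NULL, NULL),
      NULL, NULL), rhs, maxIter = 25, tol = 1e-12))
  expect_true(all(diff(fit$residuals) <= 1e-9 * fit$residuals[1]))
  # zero data gives the zero solution
  z <- suppressWarnings(scr(kd, acq$coils, acq$op, ss, maxIter = 5, tol = 1e-6))
  kd0 <- kd; kd0@samples[] <- 0 + 0i
  expect_equal(scr(kd0, acq$coils, acq$op, ss)@coefficients,
               0 * z@coefficients)
})

test_that("contrast composition is the basis expansion and a projector", {
  tr <- shortTrain()
  g <- makeParamGrid(deltaRange = c(-15, 15),
                     steps = c(t1 = 4, t2 = 3, delta = 3, b1 = 2))
  ss <- computeSubspace(buildDictionary(g, tr, "Si"), 5)
  expect_equal(composeContrasts(ss, matrix(0 + 0i, 5, 10)),
               matrix(0 + 0i, 12, 10))
  one <- computeSubspace(buildDictionary(g, tr, "Si"), 1)
  img <- composeContrasts(one, matrix(1 + 0i, 1, 7))
  for (q in 1:12) expect_equal(img[q, ], rep(one@basis[q, 1], 7))
  # compose after project is the identity on the subspace
  coefs <- matrix(complex(real = rnorm(5 * 7), imaginary = rnorm(5 * 7)), 5, 7)
  I <- composeContrasts(ss, coefs)
  expect_equal(composeContrasts(ss, Conj(t(ss@basis)) %*% I), I,
               tolerance = 1e-10)
})

test_that("B0 compensation lowers reconstruction error for extended readouts", {
  # fast small-scale version: 22 ms readouts, smooth field within +-100 Hz
  tr <- shortTrain()
  acq <- smallAcq(acceleration = 2)
  ph <- smallPhantom(b0Spec = list(const = 0, linx = 80, liny = 0, quad = 0))
  expect_lte(max(abs(ph@delta[ph@mask])), 100)
  M <- simulateVoxelSignals(ph, tr)
  kd <- synthesizeKspace(ph, tr, acq$op, acq$coils)
  ps <- phaseSubspace(ph@delta, acq$traj@tau)
  msk <- as.vector(ph@mask)
  with0 <- suppressWarnings(senseB0(kd, acq$coils, acq$op, ps, maxIter = 25))
  without <- suppressWarnings(senseB0(kd, acq$coils, acq$op, NULL, maxIter = 25))
  nrmse <- function(img) relErr(img[, msk], M[, msk])
  expect_lt(nrmse(with0), nrmse(without))
})
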