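# Shared fixtures, built once per session and cached. Sizes are desk-scale:
# the default train (12 blocks, TRp 30 ms, 48 contrasts) everywhere, small
# image grids for operator/recon toys, and the full 32x32 phantom pipeline
# only where the end-to-end behavior is under test.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(build()), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

defaultTrain <- function(readoutStartOffset = 2) {
  buildPulseTrain(buildOptimizedBlock(30), nBlocks = 12, delay = 3000,
                  readoutStartOffset = readoutStartOffset)
}

shortTrain <- function() {
  buildPulseTrain(buildOptimizedBlock(30), nBlocks = 3, delay = 3000)
}

testEnsemble <- function() slabEnsemble(64, 1.8, 8, 132)

# independent fine-timestep Bloch integrator (pure R, built differently from
# the package engine: Rodrigues rotation matrices and stepwise relaxation)
oracleBlochSi <- function(t1, t2, delta, b1, train, dtUs = 10) {
  rotmat <- function(flipDeg, axisDeg) {
    a <- flipDeg * pi / 180
    u <- c(cos(axisDeg * pi / 180), sin(axisDeg * pi / 180), 0)
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  }
  evolve <- function(m, dtMs) {
    n <- max(1L, ceiling(dtMs * 1000 / dtUs))
    h <- dtMs / n
    e1 <- exp(-h / t1); e2 <- exp(-h / t2)
    th <- -2 * pi * delta * h / 1000
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    for (i in seq_len(n)) {
      m[1:2] <- e2 * (R %*% m[1:2])
      m[3] <- 1 + (m[3] - 1) * e1
    }
    m
  }
  blk <- train@block
  trp <- blk@trp
  off <- train@readoutStartOffset
  m <- c(0, 0, 1)
  out <- complex(nContrasts(train))
  k <- 0L
  for (b in seq_len(train@nBlocks)) for (p in blk@pulses) {
    m <- as.vector(rotmat(b1 * p@flipAngle, p@phaseAxis) %*% m)
    mr <- evolve(m, off)
    k <- k + 1L
    out[k] <- complex(real = mr[1], imaginary = mr[2])
    m <- evolve(m, trp)
  }
  out
}

# brute-force non-uniform DFT (triple loop style, independent of the
# operator's matrix construction)
bruteDft <- function(img, k, gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]
  xs <- rep((seq_len(nx) - 1) - nx / 2, times = ny)
  ys <- rep((seq_len(ny) - 1) - ny / 2, each = nx)
  v <- as.vector(img)
  vapply(seq_len(nrow(k)), function(p)
    sum(v * exp(-2i * pi * (k[p, 1] * xs / nx + k[p, 2] * ys / ny))),
    complex(1))
}

relErr <- function(x, ref) sqrt(sum(abs(x - ref)^2) / sum(abs(ref)^2))

# small acquisition used across recon tests: 16x16 grid, full spiral set
smallAcq <- function(acceleration = 1, nCoils = 2) {
  traj <- suppressWarnings(designSpiral(16, 220, 16, 22, 96, turns = 2))
  sched <- scheduleArms(48, 16, acceleration)
  op <- buildOperator(traj, sched, c(16, 16))
  coils <- makeCoilMaps(nCoils, c(16, 16), smoothness = 0.5)
  list(traj = traj, op = op, coils = coils)
}

smallPhantom <- function(b0Spec = list(const = 0, linx = 0, liny = 0, quad = 0)) {
  makePhantom(c(16, 16), tubeCenters = rbind(c(-4, -4), c(4, 4)),
              tubeRadius = 3, t1 = c(600, 1200), t2 = c(80, 150),
              b0Spec = b0Spec)
}

# pipeline runs reused by the acceptance suite
fixSensePipeline <- function() fixture("senseAccel2", function()
  suppressWarnings(runPipeline(pipelineConfig(method = "sense",
                                              acceleration = 2))))

fixScrPipeline <- function() fixture("scrAccel533", function()
  suppressWarnings(runPipeline(pipelineConfig(method = "scr-b0",
                                              acceleration = 16 / 3))))

# slab-resolved dictionary over the full stated grid ranges (reduced density)
fixMuSubspace <- function() fixture("muSubspace", function() {
  train <- buildPulseTrain(buildOptimizedBlock(30, selectiveExcitation = TRUE),
                           nBlocks = 12, delay = 3000)
  ens <- testEnsemble()
  g <- makeParamGrid(steps = c(t1 = 14, t2 = 12, delta = 11, b1 = 5))
  d <- buildDictionary(g, train, "Mu", ens, centralSlice(ens))
  computeSubspace(d, 12)
})

tubeMeans <- function(res) {
  tube <- tubeLabels(res$truth)
  msk <- res$truth@mask
  vapply(1:4, function(k) {
    s <- msk & tube == k
    c(t1 = mean(res$maps@t1[s]), t2 = mean(res$maps@t2[s]))
  }, numeric(2))
}
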