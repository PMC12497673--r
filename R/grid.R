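#' Construct a tissue-parameter grid
#'
#' T1 and T2 axes are spaced logarithmically over their ranges, off-resonance
#' and transmit-scale axes linearly. Atoms are the Cartesian product of the
#' four axes with physically inconsistent combinations (t2 > t1) removed;
#' proton density is fixed at 1 + 0i and recovered as a linear scale during
#' matching.
#'
#' @param t1Range,t2Range numeric length-2, ms (defaults 100-2500 and 20-300)
#' @param deltaRange numeric length-2, Hz (default -200 to 200)
#' @param b1Range numeric length-2 (default 0.8-1.2)
#' @param steps named integer vector with entries t1, t2, delta, b1
#'   (>= 2 each, or 1 to pin an axis at its midpoint)
#' @return a \linkS4class{ParamGrid}
#' @examples
#' g <- makeParamGrid(steps = c(t1 = 3, t2 = 2, delta = 3, b1 = 1))
#' g@t1Values  # 100, 500, 2500 (log-spaced)
#' @export
makeParamGrid <- function(t1Range = c(100, 2500), t2Range = c(20, 300),
                          deltaRange = c(-200, 200), b1Range = c(0.8, 1.2),
                          steps = c(t1 = 40, t2 = 40, delta = 41, b1 = 9)) {
  checkRange <- function(r, name, positive = FALSE) {
    if (length(r) != 2L || r[1] > r[2])
      stop(sprintf("%s range must be (low, high) with low <= high", name))
    if (positive && r[1] <= 0)
      stop(sprintf("%s range must be positive", name))
  }
  checkRange(t1Range, "t1", TRUE); checkRange(t2Range, "t2", TRUE)
  checkRange(deltaRange, "delta"); checkRange(b1Range, "b1", TRUE)
  for (nm in c("t1", "t2", "delta", "b1"))
    if (is.na(steps[nm]) || steps[nm] < 1)
      stop("steps must contain t1, t2, delta, b1, each >= 1")

  logSeq <- function(r, n) {
    if (n == 1) return(sqrt(r[1] * r[2]))
    exp(seq(log(r[1]), log(r[2]), length.out = n))
  }
  linSeq <- function(r, n) {
    if (n == 1) return(mean(r))
    seq(r[1], r[2], length.out = n)
  }
  t1v <- logSeq(t1Range, steps[["t1"]])
  t2v <- logSeq(t2Range, steps[["t2"]])
  dv <- linSeq(deltaRange, steps[["delta"]])
  b1v <- linSeq(b1Range, steps[["b1"]])

  atoms <- expand.grid(it1 = seq_along(t1v), it2 = seq_along(t2v),
                       idelta = seq_along(dv), ib1 = seq_along(b1v),
                       KEEP.OUT.ATTRS = FALSE)
  atoms$t1 <- t1v[atoms$it1]
  atoms$t2 <- t2v[atoms$it2]
  atoms$delta <- dv[atoms$idelta]
  atoms$b1 <- b1v[atoms$ib1]
  atoms <- atoms[atoms$t2 <= atoms$t1, , drop = FALSE]
  rownames(atoms) <- NULL
  new("ParamGrid", t1Values = t1v, t2Values = t2v, deltaValues = dv,
      b1Values = b1v, atoms = atoms)
}

#' Number of atoms in a grid
#' @param grid a \linkS4class{ParamGrid}
#' @export
nAtoms <- function(grid) nrow(grid@atoms)

# 4D lookup array: axis indices -> atom column (NA where excluded)
.gridIndexArray <- function(grid) {
  dims <- c(length(grid@t1Values), length(grid@t2Values),
            length(grid@deltaValues), length(grid@b1Values))
  idx <- array(NA_integer_, dims)
  idx[as.matrix(grid@atoms[, c("it1", "it2", "idelta", "ib1")])] <-
    seq_len(nrow(grid@atoms))
  idx
}

setMethod("show", "ParamGrid", function(object) {
  cat(sprintf(
    "ParamGrid: %d atoms | t1 %d in [%g, %g] ms (log), t2 %d in [%g, %g] ms (log),\n  delta %d in [%g, %g] Hz, b1 %d in [%g, %g]\n",
    nAtoms(object),
    length(object@t1Values), min(object@t1Values), max(object@t1Values),
    length(object@t2Values), min(object@t2Values), max(object@t2Values),
    length(object@deltaValues), min(object@deltaValues), max(object@deltaValues),
    length(object@b1Values), min(object@b1Values), max(object@b1Values)))
})
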