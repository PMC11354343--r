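## Low-level lattice operations shared by the solver, gradient and tracer.
## All kernels are applied in correlation form, result[i] = sum_o w[o] * a[i + o],
## with replicate (clamp-to-edge) padding; every kernel used in the package is
## either symmetric or explicitly sign-documented, so the distinction from
## convolution never changes a result silently.

.axisLetters <- c("x", "y", "z")

.faceNames <- function(rank) {
  as.vector(t(outer(.axisLetters[seq_len(rank)], c("0", "1"), paste0)))
}

## Shift an array by an integer offset with replicate padding.
.shiftReplicate <- function(a, offset) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(k) {
    pmin.int(pmax.int(seq_len(d[k]) + offset[k], 1L), d[k])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## Decompose a small dense kernel (odd dims) into integer offsets + weights.
.kernelOffsets <- function(kern) {
  d <- dim(kern)
  stopifnot(all(d %% 2L == 1L))
  nz <- which(kern != 0)
  arr <- arrayInd(nz, d)
  centre <- (d + 1L) / 2L
  list(offsets = sweep(arr, 2L, centre), weights = kern[nz])
}

## Correlation of `a` with a small kernel, replicate padding.  This is the
## default ("shift") backend: one clamped-index subset per non-zero weight.
## Opposite offsets with equal weights are summed pairwise before
## accumulation, so that reflections and transpositions of a symmetric input
## produce bit-identical results (pair sums only rely on the commutativity
## of floating-point addition, never on its associativity).
.stencilApply <- function(a, kern) {
  ko <- .kernelOffsets(kern)
  off <- ko$offsets
  w <- ko$weights
  used <- rep(FALSE, length(w))
  out <- array(0, dim(a))
  for (m in seq_along(w)) {
    if (used[m]) next
    opposite <- apply(off, 1L, function(o) all(o == -off[m, ]))
    partner <- setdiff(which(!used & opposite), m)
    if (length(partner) && w[partner[1]] == w[m]) {
      p <- partner[1]
      out <- out + w[m] * (.shiftReplicate(a, off[m, ]) +
                             .shiftReplicate(a, off[p, ]))
      used[c(m, p)] <- TRUE
    } else {
      out <- out + w[m] * .shiftReplicate(a, off[m, ])
      used[m] <- TRUE
    }
  }
  out
}

## FFT backend: replicate-pad by the kernel radius, circular cross-correlation
## via the DFT, crop back.  Exact up to floating-point round-off; used for
## backend cross-checking and available through solverControl(backend = "fft").
.stencilApplyFFT <- function(a, kern) {
  d <- dim(a)
  r <- (dim(kern) - 1L) / 2L
  dp <- d + 2L * r
  idx <- lapply(seq_along(d), function(k) {
    pmin.int(pmax.int(seq_len(dp[k]) - r[k], 1L), d[k])
  })
  ap <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  ## embed kernel with its centre at the origin, offsets wrapped circularly
  kp <- array(0, dp)
  ko <- .kernelOffsets(kern)
  for (m in seq_along(ko$weights)) {
    pos <- (ko$offsets[m, ] %% dp) + 1L
    kp[matrix(pos, nrow = 1L)] <- kp[matrix(pos, nrow = 1L)] + ko$weights[m]
  }
  cc <- Re(fft(fft(ap) * Conj(fft(kp)), inverse = TRUE)) / prod(dp)
  idx2 <- lapply(seq_along(d), function(k) seq_len(d[k]) + r[k])
  do.call(`[`, c(list(cc), idx2, list(drop = FALSE)))
}

## 1D kernel laid along one axis of a rank-2/3 array.
.axisKernel <- function(w, axis, rank) {
  n <- length(w)
  d <- rep(1L, rank)
  d[axis] <- n
  array(w, d)
}

## Separable filtering: apply a 1D kernel along each requested axis in turn.
.separableFilter <- function(a, w, axes) {
  rank <- length(dim(a))
  for (ax in axes) a <- .stencilApply(a, .axisKernel(w, ax, rank))
  a
}

.gaussianWeights <- function(sigma) {
  if (sigma <= 0) return(1)
  rad <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  w / sum(w)
}

## Multilinear interpolation of one or more component arrays at continuous
## 0-based voxel coordinates (voxel centres at integers).  `P` is an m x rank
## matrix; returns an m x length(comps) matrix.  Corner indices are clamped to
## the lattice (replicate behaviour); callers police out-of-bounds positions.
.interpLinear <- function(comps, P) {
  d <- dim(comps[[1]])
  rank <- length(d)
  m <- nrow(P)
  i0 <- floor(P)
  fr <- P - i0
  strides <- cumprod(c(1L, d[-rank]))
  corners <- as.matrix(expand.grid(rep(list(0:1), rank)))
  out <- matrix(0, m, length(comps))
  for (cc in seq_len(nrow(corners))) {
    w <- rep(1, m)
    idx <- rep(1, m)
    for (k in seq_len(rank)) {
      b <- corners[cc, k]
      w <- w * if (b == 1L) fr[, k] else 1 - fr[, k]
      ik <- pmin.int(pmax.int(i0[, k] + b, 0), d[k] - 1L)
      idx <- idx + ik * strides[k]
    }
    for (j in seq_along(comps)) {
      out[, j] <- out[, j] + w * comps[[j]][idx]
    }
  }
  out
}

## Nearest voxel (0-based) for continuous 0-based coordinates.
.nearestVoxel <- function(P) round(P)

.popSd <- function(x) sqrt(mean((x - mean(x))^2))
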