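# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
# Kernel truncated at 3 sigma; edge rows renormalized (no intensity leak).
gauss_smooth3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  dm <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- dm[ax]
    r <- max(1L, ceiling(3 * s))
    i <- seq_len(n)
    K <- outer(i, i, function(a, b) {
      d <- abs(a - b)
      ifelse(d <= r, exp(-d^2 / (2 * s^2)), 0)
    })
    K <- K / rowSums(K)
    if (ax == 1L) {
      arr <- array(K %*% matrix(arr, dm[1], dm[2] * dm[3]), dm)
    } else if (ax == 2L) {
      a2 <- aperm(arr, c(2, 1, 3))
      a2 <- array(K %*% matrix(a2, dm[2], dm[1] * dm[3]), c(dm[2], dm[1], dm[3]))
      arr <- aperm(a2, c(2, 1, 3))
    } else {
      a3 <- aperm(arr, c(3, 1, 2))
      a3 <- array(K %*% matrix(a3, dm[3], dm[1] * dm[2]), c(dm[3], dm[1], dm[2]))
      arr <- aperm(a3, c(2, 3, 1))
    }
  }
  arr
}

# Gaussian-smooth (sigma = factor/2 voxels) and subsample a volume by an
# integer factor, adjusting the affine so voxel centers stay in place.
# `subsample` can be smaller than `factor` to keep more samples at a given
# smoothing scale (used by the MI registration, where a sparsely sampled
# joint histogram makes the metric unreliable).
pyramid_level <- function(vol, factor, subsample = factor) {
  if (factor <= 1L) return(vol)
  sm <- gauss_smooth3d(vol$data, factor / 2)
  dm <- dim(sm)
  subsample <- max(1L, as.integer(subsample))
  ix <- lapply(dm, function(n) seq(1L, n, by = subsample))
  sub <- sm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  aff <- vol$affine %*% diag(c(subsample, subsample, subsample, 1))
  volume3d(sub, aff, frame = vol$frame, kind = "scalar")
}
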