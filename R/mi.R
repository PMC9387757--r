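# Equal-width bin index in [0, bins-1] over (lo, hi); values outside are
# clipped into the end bins. Degenerate range puts everything in bin 0.
bin_index <- function(x, lo, hi, bins) {
  if (!(hi > lo)) return(integer(length(x)))
  i <- floor((x - lo) / (hi - lo) * bins)
  pmin.int(pmax.int(as.integer(i), 0L), bins - 1L)
}

# MI (nats) between two equal-length intensity vectors given fixed bin ranges.
mi_from_values <- function(x, y, bins, rx, ry) {
  ix <- bin_index(x, rx[1], rx[2], bins)
  iy <- bin_index(y, ry[1], ry[2], bins)
  counts <- tabulate(ix + bins * iy + 1L, nbins = bins * bins)
  p <- counts / sum(counts)
  pj <- matrix(p, bins, bins)
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

percentile_range <- function(x) unname(quantile(x, c(0.01, 0.99), names = FALSE))

#' Mutual information between two volumes on the same grid
#'
#' Joint-histogram MI in nats with `bins` equal-width bins per axis spanning
#' each volume's (1st, 99th) percentile intensity range; values outside the
#' range are clipped into the end bins.
#'
#' @param a,b `ielec_volume`s with identical grid shapes.
#' @param bins Number of histogram bins per axis (>= 2), default 32.
#' @return MI in nats (>= 0 up to numerical slack).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  if (!identical(dim(a$data), dim(b$data)))
    ielec_stop("dim", "volumes must share a grid: (%s) vs (%s)",
               paste(dim(a$data), collapse = ", "),
               paste(dim(b$data), collapse = ", "))
  if (bins < 2L) ielec_stop("dim", "bins must be >= 2")
  x <- as.vector(a$data); y <- as.vector(b$data)
  mi_from_values(x, y, as.integer(bins), percentile_range(x), percentile_range(y))
}
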