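# 26-connected neighbour offsets (vertex adjacency).
.OFFSETS26 <- {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# Candidate voxels (0-based index matrix + world centers + intensities)
# within `radius` mm of world point `center`. All distances in world mm so
# anisotropic voxels are handled correctly.
ball_voxels <- function(vol, center, radius) {
  dm <- dim(vol$data)
  inv3 <- solve(vol$affine)[1:3, 1:3]
  cv <- world_to_voxel(vol, center)
  ext <- radius * sqrt(rowSums(inv3 * inv3))
  lo <- pmax(ceiling(cv - ext - 1e-9), 0)
  hi <- pmin(floor(cv + ext + 1e-9), dm - 1)
  if (any(lo > hi)) return(NULL)
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  colnames(idx) <- NULL
  w <- voxel_to_world(vol, idx)
  d <- row_norms(w - matrix(center, nrow(w), 3, byrow = TRUE))
  keep <- d <= radius + 1e-9
  if (!any(keep)) return(NULL)
  list(idx = idx[keep, , drop = FALSE], world = w[keep, , drop = FALSE],
       dist = d[keep],
       val = vol$data[idx[keep, , drop = FALSE] + 1L])
}

#' Find the brightest voxel near a seed point
#'
#' Returns the voxel with maximal CT intensity among voxels whose centers lie
#' within `radius` mm of the seed. Ties resolve to the voxel closest to the
#' seed, then to lexicographic index order, so the result is deterministic.
#'
#' @param ct Scalar `ielec_volume` (the post-implant CT).
#' @param seed 3-vector, world mm; must map inside the volume.
#' @param radius Search radius in mm (default 5).
#' @return Integer 3-vector of 0-based voxel indices.
#' @export
find_local_peak <- function(ct, seed, radius = 5) {
  if (radius <= 0) ielec_stop("bounds", "radius must be positive")
  seed <- as_points(seed)[1, ]
  dm <- dim(ct$data)
  sv <- world_to_voxel(ct, seed)
  if (any(sv < -0.5) || any(sv > dm - 0.5))
    ielec_stop("bounds", "seed (%.1f, %.1f, %.1f) mm maps outside the volume",
               seed[1], seed[2], seed[3])
  b <- ball_voxels(ct, seed, radius)
  if (is.null(b))
    ielec_stop("bounds", "no voxel centers within %.2f mm of the seed", radius)
  best <- which(b$val == max(b$val))
  if (length(best) > 1L) {
    best <- best[b$dist[best] == min(b$dist[best])]
    if (length(best) > 1L) {
      o <- order(b$idx[best, 1], b$idx[best, 2], b$idx[best, 3])
      best <- best[o[1]]
    }
  }
  as.integer(b$idx[best[1], ])
}

# Shared setup for the two region-growing implementations: the eligible
# candidate set around a peak (intensity floor + world-distance cap).
region_candidates <- function(ct, peak, intensity_floor, max_region_radius) {
  peak_w <- voxel_to_world(ct, peak)
  peak_int <- ct$data[matrix(peak + 1L, 1)]
  b <- ball_voxels(ct, peak_w, max_region_radius)
  keep <- b$val >= intensity_floor * peak_int
  list(idx = b$idx[keep, , drop = FALSE], world = b$world[keep, , drop = FALSE],
       val = b$val[keep], peak_w = peak_w, peak_int = peak_int)
}

# Monotone region growth, fixed-point formulation: iterate admission of any
# eligible voxel with a 26-neighbour already in the region whose intensity is
# >= its own, until nothing changes. Traversal-order independent by
# construction.
region_grow_fixedpoint <- function(cand, peak) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kmap <- key(cand$idx)
  lookup <- setNames(seq_along(kmap), kmap)
  n <- nrow(cand$idx)
  # precompute neighbour index (row of cand) for each voxel/offset, NA if
  # neighbour not eligible
  nbr <- matrix(NA_integer_, n, 26)
  for (o in seq_len(26)) {
    nk <- key(cand$idx + matrix(.OFFSETS26[o, ], n, 3, byrow = TRUE))
    nbr[, o] <- lookup[nk]
  }
  reg <- logical(n)
  reg[lookup[key(matrix(peak, 1))]] <- TRUE
  repeat {
    vint <- ifelse(reg, cand$val, -Inf)
    admit <- rep(FALSE, n)
    for (o in seq_len(26)) {
      has <- !is.na(nbr[, o])
      admit[has] <- admit[has] | (vint[nbr[has, o]] >= cand$val[has])
    }
    newreg <- reg | admit
    if (identical(newreg, reg)) break
    reg <- newreg
  }
  which(reg)
}

# Same admission rule via breadth-first search from the peak: a popped region
# voxel v admits any eligible 26-neighbour n with intensity(n) <= intensity(v).
# Serves as the independent traversal for the order-independence property.
region_grow_bfs <- function(cand, peak) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kmap <- key(cand$idx)
  lookup <- setNames(seq_along(kmap), kmap)
  n <- nrow(cand$idx)
  nbr <- matrix(NA_integer_, n, 26)
  for (o in seq_len(26)) {
    nk <- key(cand$idx + matrix(.OFFSETS26[o, ], n, 3, byrow = TRUE))
    nbr[, o] <- lookup[nk]
  }
  reg <- logical(n)
  start <- lookup[key(matrix(peak, 1))]
  reg[start] <- TRUE
  queue <- c(start)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ns <- nbr[v, ]
    ns <- ns[!is.na(ns)]
    adm <- ns[!reg[ns] & cand$val[ns] <= cand$val[v]]
    if (length(adm)) {
      reg[adm] <- TRUE
      queue <- c(queue, adm)
    }
  }
  which(reg)
}

#' Snap a contact to the center of mass of its CT blob
#'
#' Refines a roughly-placed contact location: finds the brightest voxel near
#' the seed, grows a region of voxels that monotonically decrease in
#' intensity away from that peak (26-connectivity, non-strict decrease, with
#' an intensity floor and a world-radius cap to keep the region on the
#' contact), and returns the intensity-weighted centroid of the region in
#' world mm. The admitted set depends only on intensities, not on traversal
#' order, and the operation is idempotent to well under a voxel.
#'
#' @inheritParams find_local_peak
#' @param intensity_floor Fraction of the peak intensity below which voxels
#'   are never admitted (default 0.25).
#' @param max_region_radius World-mm cap on the region's distance from the
#'   peak (default 5).
#' @param method `"fixedpoint"` (default) or `"bfs"`; both produce the same
#'   region.
#' @return An `ielec_snap`: `center` (mm), `peak_voxel` (0-based),
#'   `region_voxels`, `region_mass`, `moved_mm`.
#' @export
snap_to_center <- function(ct, seed, radius = 5, intensity_floor = 0.25,
                           max_region_radius = 5,
                           method = c("fixedpoint", "bfs")) {
  method <- match.arg(method)
  seed <- as_points(seed)[1, ]
  peak <- find_local_peak(ct, seed, radius)
  cand <- region_candidates(ct, peak, intensity_floor, max_region_radius)
  sel <- if (method == "bfs") region_grow_bfs(cand, peak)
         else region_grow_fixedpoint(cand, peak)
  w <- cand$world[sel, , drop = FALSE]
  v <- cand$val[sel]
  center <- colSums(w * v) / sum(v)
  structure(list(center = center,
                 peak_voxel = as.integer(peak),
                 region_voxels = length(sel),
                 region_mass = sum(v),
                 moved_mm = sqrt(sum((center - seed)^2))),
            class = "ielec_snap")
}

#' @export
print.ielec_snap <- function(x, ...) {
  cat(sprintf("<ielec_snap> center (%.2f, %.2f, %.2f) mm, %d voxels, moved %.2f mm\n",
              x$center[1], x$center[2], x$center[3], x$region_voxels, x$moved_mm))
  invisible(x)
}
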