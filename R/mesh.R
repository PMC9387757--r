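#' Triangulated surface mesh
#'
#' @param vertices V x 3 matrix of mm coordinates.
#' @param triangles T x 3 integer matrix of 1-based vertex indices.
#' @param frame Frame tag.
#' @return An object of class `ielec_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, frame = "mr_subject") {
  v <- as_points(vertices)
  tr <- as.matrix(triangles)
  storage.mode(tr) <- "integer"
  if (ncol(tr) != 3L) ielec_stop("dim", "triangles must be T x 3")
  if (any(tr < 1L) || any(tr > nrow(v)))
    ielec_stop("dim", "triangle indices out of range [1, %d]", nrow(v))
  ab <- v[tr[, 2], ] - v[tr[, 1], ]
  ac <- v[tr[, 3], ] - v[tr[, 1], ]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  areas <- 0.5 * row_norms(cr)
  if (any(areas <= 1e-12))
    ielec_stop("dim", "%d degenerate (zero-area) triangle(s)", sum(areas <= 1e-12))
  structure(list(vertices = v, triangles = tr,
                 frame = match.arg(frame, .FRAMES)),
            class = "ielec_mesh")
}

#' @export
print.ielec_mesh <- function(x, ...) {
  cat(sprintf("<ielec_mesh> %d vertices, %d triangles, frame %s\n",
              nrow(x$vertices), nrow(x$triangles), x$frame))
  invisible(x)
}

# Signed enclosed volume (positive for outward-oriented closed meshes).
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], ]; b <- v[tr[, 2], ]; c_ <- v[tr[, 3], ]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# A mesh is closed iff every undirected edge borders exactly two triangles.
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Read / write an ASCII OFF surface mesh
#'
#' Standard OFF: header line `OFF`, then `V F E`, V vertex lines (x y z), F
#' face lines (`3 i j k`, 0-based). Only triangular faces are supported.
#'
#' @param path File path.
#' @param frame Frame tag attached on read.
#' @return `read_off` returns an `ielec_mesh`.
#' @export
read_off <- function(path, frame = "mr_subject") {
  if (!file.exists(path)) ielec_stop("io", "mesh file not found: %s", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF")
    ielec_stop("format", "not an OFF file (missing OFF header): %s", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  fl <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               nf, byrow = TRUE, ncol = 4)
  if (any(fl[, 1] != 3))
    ielec_stop("format", "non-triangular face in %s", path)
  surface_mesh(verts, fl[, 2:4] + 1L, frame = frame)
}

#' @rdname read_off
#' @param mesh An `ielec_mesh`.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Exact nearest point on a triangulated surface
#'
#' Scans every triangle with the exact point-to-triangle projection
#' (vertex/edge/interior cases) in compiled code; ties resolve to the lowest
#' triangle id.
#'
#' @param p 3-vector mm (or n x 3 matrix for a batch).
#' @param surface An `ielec_mesh`.
#' @return For a single point, a list `point` (3-vector), `triangle` (id),
#'   `distance` (mm); for a batch, a list of `point` matrix, `triangle` and
#'   `distance` vectors.
#' @export
nearest_point_on_mesh <- function(p, surface) {
  single <- is.null(dim(p))
  pts <- as_points(p)
  res <- .c_closest_on_mesh(surface$vertices, surface$triangles, pts)
  if (single)
    list(point = drop(res$point[1, ]), triangle = res$triangle[1],
         distance = res$distance[1])
  else res
}

# Crude inside test adequate for star-shaped (near-spherical) closed meshes:
# sign of (p - nearest point) . (outward triangle normal).
points_inside_mesh <- function(pts, mesh) {
  pts <- as_points(pts)
  res <- nearest_point_on_mesh(pts, mesh)
  tr <- mesh$triangles[res$triangle, , drop = FALSE]
  a <- mesh$vertices[tr[, 1], , drop = FALSE]
  b <- mesh$vertices[tr[, 2], , drop = FALSE]
  c_ <- mesh$vertices[tr[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  rowSums((pts - res$point) * nrm) <= 0
}

#' Smooth a pial surface into a leptomeningeal envelope
#'
#' Iterative Laplacian smoothing with cotangent weights (the discrete
#' mean-curvature normal, so a sphere is a fixed point up to numerical
#' noise) and a per-step uniform re-inflation about the centroid that
#' restores the enclosed volume, so the surface bridges sulci instead of
#' shrinking. A final enclosure pass inflates minimally, if needed, until at
#' least 99% of the input vertices lie inside; its volume cost is the filled
#' sulcal volume, which stays within ~2% for the shallow smoothing targets
#' this operation is meant for.
#'
#' @param pial Closed `ielec_mesh`.
#' @param iterations Smoothing iterations (default 20).
#' @param relaxation Step fraction toward the weighted neighbourhood mean
#'   (default 0.5).
#' @return Smoothed `ielec_mesh` with unchanged vertex count.
#' @export
smooth_to_leptomeningeal <- function(pial, iterations = 20L, relaxation = 0.5) {
  if (!mesh_is_closed(pial))
    ielec_stop("topology", "surface is not closed (boundary edges present)")
  v <- pial$vertices
  tr <- pial$triangles
  nv <- nrow(v)
  cot_weights <- function(v) {
    # per-triangle corner cotangents accumulated onto opposite edges
    w_i <- integer(0); w_j <- integer(0); w <- numeric(0)
    for (corner in 1:3) {
      a <- tr[, corner]
      b <- tr[, corner %% 3 + 1]
      c_ <- tr[, (corner + 1) %% 3 + 1]
      u <- v[b, ] - v[a, ]
      q <- v[c_, ] - v[a, ]
      cr <- cbind(u[, 2] * q[, 3] - u[, 3] * q[, 2],
                  u[, 3] * q[, 1] - u[, 1] * q[, 3],
                  u[, 1] * q[, 2] - u[, 2] * q[, 1])
      ct <- rowSums(u * q) / pmax(row_norms(cr), 1e-12)
      # weight for edge (b, c_), both directions
      w_i <- c(w_i, b, c_); w_j <- c(w_j, c_, b); w <- c(w, ct, ct)
    }
    list(i = w_i, j = w_j, w = pmax(w, 0))
  }
  vol0 <- abs(mesh_volume(pial))
  # weights frozen from the input mesh: the smoothing pair is then a linear
  # operator and its shrink/anti-shrink steps cancel cleanly on a sphere
  cw <- cot_weights(v)
  lap <- function(v) {
    num <- rowsum(v[cw$j, , drop = FALSE] * cw$w, cw$i)
    den <- rowsum(cw$w, cw$i)
    num / as.vector(den) - v
  }
  for (it in seq_len(iterations)) {
    # smoothing step, then an outward anti-shrink step with the same
    # operator (Taubin pair): mesh-irregularity effects cancel to first
    # order, so a sphere is a fixed point; a global rescale then pins the
    # enclosed volume exactly
    v <- v + relaxation * lap(v)
    v <- v - (relaxation + 0.02) * lap(v)
    ctr <- colMeans(v)
    s <- (vol0 / abs(mesh_volume(surface_mesh(v, tr))))^(1 / 3)
    v <- sweep(sweep(sweep(v, 2, ctr), 2, rep(s, 3), `*`), 2, ctr, `+`)
  }
  out <- surface_mesh(v, tr, frame = pial$frame)
  # enclosure guarantee: one minimal uniform inflation so that >= 99% of the
  # original vertices are enclosed (a leptomeningeal envelope wraps the pial
  # surface), then verify
  ctr <- colMeans(v)
  for (k in 1:10) {
    res <- nearest_point_on_mesh(pial$vertices, out)
    inside <- points_inside_mesh(pial$vertices, out)
    sd_out <- ifelse(inside, 0, res$distance)
    need <- stats::quantile(sd_out, 0.99, names = FALSE)
    if (need <= 0) break
    rmean <- mean(row_norms(sweep(v, 2, ctr)))
    v <- sweep(sweep(sweep(v, 2, ctr), 2, rep(1 + (need + 1e-6) / rmean, 3),
                     `*`), 2, ctr, `+`)
    out <- surface_mesh(v, tr, frame = pial$frame)
  }
  out
}

#' Project ECoG contacts onto a brain surface (brain-shift compensation)
#'
#' Craniotomy pressure changes push grid/strip electrodes below the
#' pre-operative pial surface in the post-operative CT. This is compensated
#' by moving each selected contact to the exact nearest point on the
#' leptomeningeal surface mesh. Unselected contacts are untouched. The
#' per-contact shift distances are returned in the `"shift_mm"` attribute; a
#' warning is emitted when two projected contacts end up closer than 1 mm.
#'
#' @param m `ielec_montage` with the selected channels located.
#' @param surface Closed, outward-oriented `ielec_mesh`.
#' @param channels Channel names to project (default: all located).
#' @return The updated montage.
#' @export
project_sensors_onto_brain <- function(m, surface, channels = NULL) {
  if (!mesh_is_closed(surface))
    ielec_stop("topology", "projection surface is not closed")
  if (mesh_volume(surface) <= 0)
    ielec_stop("topology", "projection surface is not outward-oriented")
  cc <- m$contacts
  if (is.null(channels)) channels <- cc$name[cc$status == "located"]
  i <- match(channels, cc$name)
  if (anyNA(i))
    ielec_stop("name", "unknown channel(s): %s",
               paste(channels[is.na(i)], collapse = ", "))
  bad <- channels[cc$status[i] != "located"]
  if (length(bad))
    ielec_stop("state", "cannot project unlocated channel(s): %s",
               paste(bad, collapse = ", "))
  pts <- as.matrix(cc[i, c("x", "y", "z")])
  res <- nearest_point_on_mesh(pts, surface)
  shift <- res$distance
  m$contacts[i, c("x", "y", "z")] <- res$point
  pr <- res$point
  if (length(i) > 1) {
    dmat <- as.matrix(dist(pr))
    diag(dmat) <- Inf
    if (any(dmat < 1))
      warning(sprintf("%d projected contact pair(s) closer than 1 mm",
                      sum(dmat < 1) / 2))
  }
  attr(m, "shift_mm") <- setNames(shift, channels)
  m
}
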