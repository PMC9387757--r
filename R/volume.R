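#' 3D image volume with a voxel-to-world affine
#'
#' The basic image container: a 3D intensity (or integer label) grid together
#' with the 4x4 matrix mapping 0-based voxel indices to world coordinates
#' (scanner RAS, mm) and a coordinate-frame tag.
#'
#' @param data 3D numeric array. For `kind = "label"` all values must be
#'   non-negative integers.
#' @param affine 4x4 voxel-index-to-world-mm matrix; must be invertible and
#'   have bottom row (0, 0, 0, 1).
#' @param frame Frame tag, one of `"ct"`, `"mr_subject"`, `"mr_template"`.
#' @param kind `"scalar"` (intensities) or `"label"` (integer segmentation).
#' @return An object of class `ielec_volume`.
#' @export
volume3d <- function(data, affine, frame, kind = c("scalar", "label")) {
  kind <- match.arg(kind)
  frame <- match.arg(frame, .FRAMES)
  if (length(dim(data)) != 3L)
    ielec_stop("dim", "volume data must have exactly 3 axes, got shape (%s)",
               paste(dim(data), collapse = ", "))
  if (any(dim(data) < 1L))
    ielec_stop("dim", "all volume axes must have length >= 1")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    ielec_stop("dim", "affine must be 4x4")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 0)
    ielec_stop("dim", "affine bottom row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps)
    ielec_stop("dim", "affine is singular (upper-left 3x3 determinant ~ 0)")
  if (kind == "label") {
    if (any(data < 0) || max(abs(data - round(data))) > 0)
      ielec_stop("kind", "label volumes must contain non-negative integers")
    storage.mode(data) <- "integer"
  } else {
    storage.mode(data) <- "double"
  }
  structure(list(data = data, affine = affine, frame = frame, kind = kind),
            class = "ielec_volume")
}

#' @export
print.ielec_volume <- function(x, ...) {
  cat(sprintf("<ielec_volume> %s %s, shape (%s), voxel sizes (%s) mm\n",
              x$frame, x$kind, paste(dim(x$data), collapse = ", "),
              paste(sprintf("%.2f", voxel_sizes(x)), collapse = ", ")))
  invisible(x)
}

# Per-axis world-mm lengths of the voxel edges.
voxel_sizes <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Read a NIfTI-1 volume
#'
#' Reads a (possibly gzipped) NIfTI-1 file without any reorientation. The
#' affine is taken from the sform when its code is valid, otherwise from the
#' qform, matching common neuroimaging convention.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @inheritParams volume3d
#' @return An `ielec_volume`.
#' @export
read_volume <- function(path, frame, kind = c("scalar", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    ielec_stop("io", "NIfTI file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    ielec_stop("dim", "expected a 3D volume, got shape (%s) in %s",
               paste(d, collapse = ", "), path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- rbind(matrix(aff[1:3, ], 3, 4), c(0, 0, 0, 1))
  volume3d(array(as.vector(img), dim = d), aff, frame = frame, kind = kind)
}

#' Write a volume as NIfTI-1
#'
#' @param vol An `ielec_volume`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    ielec_stop("io", "parent directory does not exist: %s", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) ielec_stop("io", "cannot write %s: %s", path,
                                          conditionMessage(e)))
  invisible(path)
}

#' Map continuous voxel indices to world mm
#'
#' Indices are 0-based and may lie outside the grid (affine extrapolation).
#'
#' @param vol An `ielec_volume`.
#' @param idx 3-vector or n x 3 matrix of continuous voxel indices.
#' @return Matching 3-vector or n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, idx) {
  v <- as_points(idx)
  w <- t(vol$affine %*% rbind(t(v), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(idx))) drop(w) else w
}

#' Map world mm to continuous voxel indices
#'
#' Exact inverse of [voxel_to_world()].
#'
#' @param vol An `ielec_volume`.
#' @param xyz 3-vector or n x 3 matrix of world coordinates (mm).
#' @return Continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  p <- as_points(xyz)
  v <- t(solve(vol$affine) %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(xyz))) drop(v) else v
}

# All voxel-center indices of a volume as an n x 3 0-based matrix
# (column-major order, matching as.vector(vol$data)).
voxel_grid <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
}

# Sample a volume at world-mm points (n x 3), trilinear or nearest.
sample_volume <- function(vol, world, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  vox <- world_to_voxel(vol, as_points(world))
  if (interp == "linear")
    .c_sample_trilinear(as.double(vol$data), dim(vol$data), vox, fill)
  else
    .c_sample_nearest(as.double(vol$data), dim(vol$data), vox, fill)
}

#' Resample a volume onto another volume's grid
#'
#' Pulls `moving` onto `target`'s voxel grid through a world-to-world affine:
#' each target voxel center is mapped to world mm, through the inverse of
#' `world_map`, into `moving`'s voxel space and sampled there. Out-of-bounds
#' samples fill with 0 (air). Label volumes always use nearest-neighbour
#' interpolation so no new label ids can appear.
#'
#' @param moving,target `ielec_volume`s; `world_map$source` must equal
#'   `moving$frame` and `world_map$target` must equal `target$frame`.
#' @param world_map An [affine_transform()] mapping moving world to target world.
#' @param interp `"linear"` or `"nearest"`.
#' @return An `ielec_volume` on `target`'s grid, in `target`'s frame, with
#'   `moving`'s kind.
#' @export
resample <- function(moving, target, world_map, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (world_map$source != moving$frame || world_map$target != target$frame)
    ielec_stop("frame",
               "world_map maps %s -> %s but volumes are moving=%s, fixed=%s",
               world_map$source, world_map$target, moving$frame, target$frame)
  if (moving$kind == "label") interp <- "nearest"
  dm <- dim(target$data)
  tw <- voxel_to_world(target, voxel_grid(dm))
  mw <- t(solve(world_map$matrix) %*% rbind(t(tw), 1))[, 1:3, drop = FALSE]
  vals <- sample_volume(moving, mw, interp = interp, fill = 0)
  if (moving$kind == "label") vals <- as.integer(round(vals))
  volume3d(array(vals, dm), target$affine, frame = target$frame,
           kind = moving$kind)
}
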