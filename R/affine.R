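#' World-to-world affine transform between tagged frames
#'
#' @param matrix 4x4 homogeneous matrix (mm); bottom row must be exactly
#'   (0, 0, 0, 1) and the matrix invertible.
#' @param source,target Frame tags of the input and output spaces.
#' @return An object of class `ielec_affine`.
#' @export
affine_transform <- function(matrix, source, target) {
  m <- unname(as.matrix(matrix))
  if (!all(dim(m) == c(4L, 4L)))
    ielec_stop("dim", "transform matrix must be 4x4")
  if (!identical(as.numeric(m[4, ]), c(0, 0, 0, 1)))
    ielec_stop("dim", "transform bottom row must be exactly (0, 0, 0, 1)")
  if (abs(det(m)) <= .Machine$double.eps)
    ielec_stop("dim", "transform matrix is singular")
  source <- match.arg(source, .FRAMES)
  target <- match.arg(target, .FRAMES)
  structure(list(matrix = m, source = source, target = target),
            class = "ielec_affine")
}

#' @export
print.ielec_affine <- function(x, ...) {
  cat(sprintf("<ielec_affine> %s -> %s\n", x$source, x$target))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity transform between two frames
#' @inheritParams affine_transform
#' @export
identity_transform <- function(source, target = source)
  affine_transform(diag(4), source, target)

#' Compose two affine transforms
#'
#' `compose(a, b)` is the map "first b, then a"; requires
#' `a$source == b$target`.
#'
#' @param a,b `ielec_affine` objects.
#' @return The composed `ielec_affine` mapping `b$source` to `a$target`.
#' @export
compose <- function(a, b) {
  if (a$source != b$target)
    ielec_stop("frame", "cannot compose: a maps %s -> %s but b maps %s -> %s",
               a$source, a$target, b$source, b$target)
  affine_transform(a$matrix %*% b$matrix, b$source, a$target)
}

#' Invert an affine transform (swaps source and target)
#' @param a An `ielec_affine`.
#' @export
invert <- function(a) affine_transform(solve(a$matrix), a$target, a$source)

#' Apply an affine transform to points
#' @param a An `ielec_affine`.
#' @param points 3-vector or n x 3 matrix (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_affine <- function(a, points) {
  p <- as_points(points)
  out <- t(a$matrix %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(points))) drop(out) else out
}

#' Serialize / read an affine transform as JSON
#'
#' The on-disk form is `{"matrix": [16 numbers, row-major], "source": tag,
#' "target": tag}`.
#'
#' @param a An `ielec_affine`.
#' @param path File path.
#' @return `read_transform` returns an `ielec_affine`.
#' @export
write_transform <- function(a, path) {
  jsonlite::write_json(list(matrix = as.vector(t(a$matrix)),
                            source = a$source, target = a$target),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) ielec_stop("io", "transform file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(j$matrix, 4, 4, byrow = TRUE), j$source, j$target)
}
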