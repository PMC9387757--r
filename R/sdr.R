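#' Dense diffeomorphic deformation field
#'
#' Paired forward/backward displacement fields on the fixed volume's grid.
#' The forward field follows the resampling convention: for a fixed-grid
#' point `x` (world mm), `x + forward(x)` is the matching location in
#' pre-affine-aligned moving space. The backward field is its inverse:
#' `y + backward(y)` carries an aligned-moving-space point back to fixed
#' space. Point warping in the moving-to-fixed direction (e.g. subject
#' contacts to template space) therefore applies `pre_affine` and then the
#' backward displacement; see [apply_point_registration()].
#'
#' @param grid_affine 4x4 field-voxel to fixed-world matrix.
#' @param forward,backward 4D arrays (nx, ny, nz, 3) of displacements in mm.
#' @param pre_affine `ielec_affine` applied before the field
#'   (moving world -> fixed world).
#' @return An object of class `ielec_deformation`.
#' @export
deformation_field <- function(grid_affine, forward, backward, pre_affine) {
  if (!identical(dim(forward), dim(backward)))
    ielec_stop("dim", "forward and backward fields must share a grid shape")
  if (length(dim(forward)) != 4L || dim(forward)[4] != 3L)
    ielec_stop("dim", "displacement fields must be (nx, ny, nz, 3) arrays")
  structure(list(grid_affine = unname(as.matrix(grid_affine)),
                 forward = forward, backward = backward,
                 pre_affine = pre_affine),
            class = "ielec_deformation")
}

#' @export
print.ielec_deformation <- function(x, ...) {
  cat(sprintf("<ielec_deformation> %s -> %s, grid (%s), max |fwd| %.2f mm\n",
              x$pre_affine$source, x$pre_affine$target,
              paste(dim(x$forward)[1:3], collapse = ", "),
              sqrt(max(rowSums(matrix(x$forward, ncol = 3)^2)))))
  invisible(x)
}

# Sample a (nx,ny,nz,3) displacement array at world points (n x 3).
# Returns list(disp = n x 3 mm, inside = logical).
sample_field <- function(field_arr, grid_affine, world) {
  dm <- dim(field_arr)[1:3]
  vox <- t(solve(grid_affine) %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
  inside <- vox[, 1] >= 0 & vox[, 1] <= dm[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= dm[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= dm[3] - 1
  disp <- vapply(1:3, function(k)
    .c_sample_trilinear(as.double(field_arr[, , , k]), dm, vox, 0),
    numeric(nrow(world)))
  list(disp = matrix(disp, ncol = 3), inside = inside)
}

# World-space image gradient (n x 3, intensity per mm) of values laid out on
# a volume grid, by central differences converted through the affine.
grid_gradient_world <- function(vals, dm, affine) {
  a <- array(vals, dm)
  gv <- array(0, c(dm, 3))
  n1 <- dm[1]; n2 <- dm[2]; n3 <- dm[3]
  if (n1 > 2) gv[2:(n1 - 1), , , 1] <- (a[3:n1, , ] - a[1:(n1 - 2), , ]) / 2
  if (n2 > 2) gv[, 2:(n2 - 1), , 2] <- (a[, 3:n2, ] - a[, 1:(n2 - 2), ]) / 2
  if (n3 > 2) gv[, , 2:(n3 - 1), 3] <- (a[, , 3:n3] - a[, , 1:(n3 - 2)]) / 2
  matrix(gv, ncol = 3) %*% solve(affine[1:3, 1:3])
}

# Clamp to (1st, 99th) percentile and rescale into (0, 1).
normalize_intensity <- function(vol) {
  r <- percentile_range(as.vector(vol$data))
  d <- pmin(pmax(vol$data, r[1]), r[2])
  if (r[2] > r[1]) d <- (d - r[1]) / (r[2] - r[1])
  volume3d(d, vol$affine, frame = vol$frame, kind = "scalar")
}

#' Symmetric diffeomorphic registration (greedy demons scheme)
#'
#' Nonlinear registration for same-modality volumes (subject MR to template
#' MR), run after an affine pre-alignment. Volumes are rescaled into (0, 1)
#' by their 1st-99th percentiles and matched by sum-of-squared differences.
#' At each iteration a symmetric demons force (average of fixed and warped
#' moving gradients) is computed, capped at one voxel, smoothed with a
#' Gaussian of width `field_sigma` mm, and composed into the forward
#' displacement field; the backward field is maintained as its fixed-point
#' inverse so the pair stays a discrete diffeomorphism.
#'
#' @param moving,fixed Scalar `ielec_volume`s.
#' @param pre_affine `ielec_affine` moving world -> fixed world (identity if
#'   omitted).
#' @param level_iters Iterations per pyramid level, coarse to fine.
#' @param field_sigma Gaussian width (mm) applied to each update field.
#' @param pyramid_factors Subsampling factors matching `level_iters`.
#' @return An `ielec_deformation` on the fixed grid, with attributes
#'   `ssd_affine` and `ssd_final` (fixed-frame SSD before/after the field).
#' @export
compute_sdr_registration <- function(moving, fixed, pre_affine = NULL,
                                     level_iters = c(30L, 30L, 25L),
                                     field_sigma = 2,
                                     pyramid_factors = c(4L, 2L, 1L)) {
  if (moving$kind != "scalar" || fixed$kind != "scalar")
    ielec_stop("kind", "SDR registration requires scalar volumes")
  if (length(level_iters) != length(pyramid_factors))
    ielec_stop("dim", "level_iters and pyramid_factors lengths differ")
  if (is.null(pre_affine))
    pre_affine <- affine_transform(diag(4), moving$frame, fixed$frame)
  mn <- normalize_intensity(moving)
  fn <- normalize_intensity(fixed)
  inv_pre <- solve(pre_affine$matrix)

  Farr <- NULL
  grid_aff <- NULL
  ssd0 <- ssd1 <- NA_real_
  for (li in seq_along(pyramid_factors)) {
    f <- pyramid_factors[li]
    fx <- pyramid_level(fn, f)
    mv <- pyramid_level(mn, f)
    dm <- dim(fx$data)
    W <- voxel_to_world(fx, voxel_grid(dm))
    fvals <- as.vector(fx$data)
    gF <- grid_gradient_world(fvals, dm, fx$affine)
    vs <- voxel_sizes(fx)
    sig_vox <- field_sigma / vs
    inv_mv <- solve(mv$affine)

    if (is.null(Farr)) {
      Fm <- matrix(0, nrow(W), 3)
    } else {
      Fm <- sample_field(Farr, grid_aff, W)$disp
    }

    warp_vals <- function(Fm) {
      pm <- W + Fm
      mw <- t(inv_pre %*% rbind(t(pm), 1))[, 1:3, drop = FALSE]
      vox <- t(inv_mv %*% rbind(t(mw), 1))[, 1:3, drop = FALSE]
      .c_sample_trilinear(as.double(mv$data), dim(mv$data), vox, 0)
    }

    if (li == 1L) ssd0 <- mean((fvals - warp_vals(matrix(0, nrow(W), 3)))^2)

    for (it in seq_len(level_iters[li])) {
      mvals <- warp_vals(Fm)
      dif <- fvals - mvals
      gM <- grid_gradient_world(mvals, dm, fx$affine)
      g <- 0.5 * (gF + gM)
      den <- rowSums(g * g) + dif * dif
      coef <- ifelse(den > 1e-9, dif / den, 0)
      u <- g * coef
      # cap update at one voxel
      un <- row_norms(u)
      cap <- min(vs)
      sc <- ifelse(un > cap, cap / un, 1)
      u <- u * sc
      for (k in 1:3)
        u[, k] <- as.vector(gauss_smooth3d(array(u[, k], dm), sig_vox))
      # compose: F'(x) = u(x) + F(x + u(x))
      Fu <- sample_field(array(Fm, c(dm, 3)), fx$affine, W + u)$disp
      Fm <- u + Fu
    }
    Farr <- array(Fm, c(dm, 3))
    grid_aff <- fx$affine
    if (li == length(pyramid_factors)) ssd1 <- mean((fvals - warp_vals(Fm))^2)
  }

  # backward field by fixed-point inversion of the forward field
  dm <- dim(Farr)[1:3]
  W <- voxel_to_world(volume3d(array(0, dm), grid_aff, fixed$frame), voxel_grid(dm))
  Bm <- -matrix(Farr, ncol = 3)
  for (it in 1:20)
    Bm <- -sample_field(Farr, grid_aff, W + Bm)$disp
  out <- deformation_field(grid_aff, Farr, array(Bm, c(dm, 3)), pre_affine)
  attr(out, "ssd_affine") <- ssd0
  attr(out, "ssd_final") <- ssd1
  out
}

#' Map points through a registration result
#'
#' For an affine result the homogeneous matrix (or its inverse, for
#' `direction = "backward"`) is applied. For a deformation field,
#' `direction = "forward"` maps moving-frame points into the fixed frame:
#' the pre-affine is applied and the sampled displacement added;
#' `direction = "backward"` is the inverse mapping. Points falling outside
#' the field grid get the affine-only mapping and are flagged in the
#' `"outside"` attribute of the result.
#'
#' @param points 3-vector or n x 3 matrix, mm, in the moving frame
#'   (`"forward"`) or fixed frame (`"backward"`).
#' @param result An `ielec_registration`, `ielec_affine`, or
#'   `ielec_deformation`.
#' @param direction `"forward"` (moving to fixed) or `"backward"`.
#' @return Mapped points (same shape as input); attribute `"outside"` is a
#'   logical vector for field-based mapping.
#' @export
apply_point_registration <- function(points, result,
                                     direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  p <- as_points(points)
  if (!all(is.finite(p))) ielec_stop("dim", "points must be finite")
  if (inherits(result, "ielec_registration")) result <- result$affine
  if (inherits(result, "ielec_affine")) {
    a <- if (direction == "forward") result else invert(result)
    out <- apply_affine(a, p)
    out <- matrix(out, ncol = 3)
  } else if (inherits(result, "ielec_deformation")) {
    if (direction == "forward") {
      q0 <- apply_affine(result$pre_affine, p)
      q0 <- matrix(q0, ncol = 3)
      s <- sample_field(result$backward, result$grid_affine, q0)
      out <- q0 + ifelse(matrix(s$inside, nrow(q0), 3), s$disp, 0)
      attr(out, "outside") <- !s$inside
    } else {
      s <- sample_field(result$forward, result$grid_affine, p)
      q <- p + ifelse(matrix(s$inside, nrow(p), 3), s$disp, 0)
      out <- matrix(apply_affine(invert(result$pre_affine), q), ncol = 3)
      attr(out, "outside") <- !s$inside
    }
    if (any(!s$inside))
      warning(sprintf("%d point(s) outside the deformation grid mapped affine-only",
                      sum(!s$inside)))
  } else {
    ielec_stop("dim", "unsupported registration result of class %s",
               paste(class(result), collapse = "/"))
  }
  if (is.null(dim(points))) {
    o <- attr(out, "outside")
    out <- drop(unclass(out)[1, , drop = FALSE])
    attr(out, "outside") <- o
  }
  out
}

#' Compare linear and diffeomorphic point mapping accuracy
#'
#' Euclidean error of an affine mapping and of a deformation-field mapping
#' against reference (template-space) positions.
#'
#' @param points n x 3 mm, moving frame.
#' @param linear `ielec_affine` moving -> fixed.
#' @param field `ielec_deformation`.
#' @param reference n x 3 mm ground-truth fixed-frame positions.
#' @return list with `per_point` (data.frame: linear_mm, sdr_mm) and `mean`
#'   (named numeric of the two mean errors).
#' @export
compare_linear_vs_sdr <- function(points, linear, field, reference) {
  p <- as_points(points); ref <- as_points(reference)
  if (nrow(p) != nrow(ref))
    ielec_stop("dim", "points (%d) and reference (%d) lengths differ",
               nrow(p), nrow(ref))
  lp <- matrix(apply_affine(linear, p), ncol = 3)
  sp <- matrix(apply_point_registration(p, field, "forward"), ncol = 3)
  le <- row_norms(lp - ref)
  se <- row_norms(sp - ref)
  list(per_point = data.frame(linear_mm = le, sdr_mm = se),
       mean = c(linear_mm = mean(le), sdr_mm = mean(se)))
}

#' Forward-backward round-trip error of a deformation field
#'
#' Diagnostic for the diffeomorphism property: maps fixed-frame points
#' through the forward then backward displacement and reports the distance
#' back to the start.
#'
#' @param field An `ielec_deformation`.
#' @param points n x 3 fixed-frame points, mm.
#' @return Numeric vector of round-trip distances (mm).
#' @export
roundtrip_error <- function(field, points) {
  p <- as_points(points)
  f <- sample_field(field$forward, field$grid_affine, p)
  y <- p + f$disp
  b <- sample_field(field$backward, field$grid_affine, y)
  row_norms(y + b$disp - p)
}

#' Serialize / read a deformation field
#'
#' The displacement fields are written as NIfTI volumes (one 3-component
#' file each for forward and backward, stored as three scalar volumes with
#' suffixes) plus a JSON sidecar holding the pre-affine and grid affine.
#'
#' @param field An `ielec_deformation`.
#' @param prefix Output path prefix; files `<prefix>_fwd<k>.nii.gz`,
#'   `<prefix>_bwd<k>.nii.gz` (k = 1..3) and `<prefix>.json` are written.
#' @return `read_deformation` returns an `ielec_deformation`.
#' @export
write_deformation <- function(field, prefix) {
  dm <- dim(field$forward)[1:3]
  for (k in 1:3) {
    write_volume(volume3d(field$forward[, , , k], field$grid_affine,
                          field$pre_affine$target),
                 sprintf("%s_fwd%d.nii.gz", prefix, k))
    write_volume(volume3d(field$backward[, , , k], field$grid_affine,
                          field$pre_affine$target),
                 sprintf("%s_bwd%d.nii.gz", prefix, k))
  }
  jsonlite::write_json(list(grid_affine = as.vector(t(field$grid_affine)),
                            pre_affine = as.vector(t(field$pre_affine$matrix)),
                            source = field$pre_affine$source,
                            target = field$pre_affine$target,
                            shape = dm),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_deformation
#' @export
read_deformation <- function(prefix) {
  jp <- paste0(prefix, ".json")
  if (!file.exists(jp)) ielec_stop("io", "deformation sidecar not found: %s", jp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  ga <- matrix(j$grid_affine, 4, 4, byrow = TRUE)
  pre <- affine_transform(matrix(j$pre_affine, 4, 4, byrow = TRUE),
                          j$source, j$target)
  dm <- as.integer(j$shape)
  fwd <- array(0, c(dm, 3)); bwd <- array(0, c(dm, 3))
  for (k in 1:3) {
    fwd[, , , k] <- read_volume(sprintf("%s_fwd%d.nii.gz", prefix, k),
                                j$target)$data
    bwd[, , , k] <- read_volume(sprintf("%s_bwd%d.nii.gz", prefix, k),
                                j$target)$data
  }
  deformation_field(ga, fwd, bwd, pre)
}
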