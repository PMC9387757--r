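# Rotation about x, y, z (intrinsic, applied as Rx %*% Ry %*% Rz).
rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# 12-parameter vector -> 4x4 matrix. Layout: translation mm (1:3), Euler
# angles rad about `center` (4:6), log-scales (7:9), shears xy/xz/yz (10:12).
params_to_matrix <- function(p, center) {
  A <- rot3(p[4], p[5], p[6]) %*% diag(exp(p[7:9])) %*%
    rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[1:3] + center - A %*% center
  M
}

# Intensity center of mass in world mm (negative intensities clamped to 0).
intensity_com <- function(vol) {
  w <- pmax(as.vector(vol$data), 0)
  g <- voxel_to_world(vol, voxel_grid(dim(vol$data)))
  colSums(g * w) / sum(w)
}

# Active parameter indices per stage.
.STAGE_PARAMS <- list(translation = 1:3, rigid = 1:6, affine = 1:12)

#' Affine CT-to-MR registration by mutual-information maximization
#'
#' Coarse-to-fine registration over a Gaussian pyramid. At each level the
#' volumes are smoothed (sigma = factor/2 voxels) and subsampled, then a
#' derivative-free coordinate-descent search refines the current parameter
#' vector stage by stage (translation; + Euler rotations about the fixed
#' volume's center; + log-scales and shears). Without `initial`, the seed
#' aligns the two volumes' intensity centers of mass; a manual pre-alignment
#' can be supplied for the rare poses (e.g. near 90 degrees) where the MI
#' landscape defeats the automatic seed.
#'
#' @param moving,fixed Scalar-kind `ielec_volume`s (e.g. CT and MR).
#' @param initial Optional `ielec_affine` seeding the search
#'   (moving world -> fixed world).
#' @param stages Ordered subset of `c("translation", "rigid", "affine")`.
#' @param pyramid_factors Strictly decreasing integers ending at 1.
#' @param bins Histogram bins for MI (default 32).
#' @param max_eval Evaluation budget per stage per pyramid level.
#' @param tol Step floor of the coordinate search, in scaled parameter units
#'   (mm / degrees / percent-scale).
#' @return A `ielec_registration` with elements `affine` (the
#'   moving-world-to-fixed-world map), `mi_trace` (data.frame of accepted-step
#'   MI values: level, eval, mi) and `converged` (logical per level).
#' @export
compute_affine_registration <- function(moving, fixed, initial = NULL,
                                        stages = c("translation", "rigid", "affine"),
                                        pyramid_factors = c(4L, 2L, 1L),
                                        bins = 32L, max_eval = 300L, tol = 1e-2) {
  if (moving$kind != "scalar" || fixed$kind != "scalar")
    ielec_stop("kind", "affine registration requires scalar volumes")
  stages <- match.arg(stages, names(.STAGE_PARAMS), several.ok = TRUE)
  pf <- as.integer(pyramid_factors)
  if (any(diff(pf) >= 0) || pf[length(pf)] != 1L)
    ielec_stop("dim", "pyramid_factors must be strictly decreasing and end at 1")

  if (is.null(initial)) {
    B <- diag(4)
    B[1:3, 4] <- intensity_com(fixed) - intensity_com(moving)
  } else {
    if (initial$source != moving$frame || initial$target != fixed$frame)
      ielec_stop("frame", "initial maps %s -> %s, expected %s -> %s",
                 initial$source, initial$target, moving$frame, fixed$frame)
    B <- initial$matrix
  }

  center <- voxel_to_world(fixed, (dim(fixed$data) - 1) / 2)
  # Scaled units per parameter: 1 mm, 1 degree, 1% log-scale, 0.01 shear.
  scale <- c(rep(1, 3), rep(pi / 180, 3), rep(0.01, 6))

  p <- rep(0, 12)
  trace_lvl <- integer(0); trace_eval <- integer(0); trace_mi <- numeric(0)
  converged <- logical(length(pf))

  for (li in seq_along(pf)) {
    f <- pf[li]
    # smooth at the pyramid scale but subsample at most 2x: the MI joint
    # histogram needs tens of thousands of samples to be a trustworthy
    # objective, and 64^3/4^3 = 4096 is not enough
    ss <- min(f, 2L)
    fx <- pyramid_level(fixed, f, subsample = ss)
    mv <- pyramid_level(moving, f, subsample = ss)
    tw <- voxel_to_world(fx, voxel_grid(dim(fx$data)))
    fvals <- as.vector(fx$data)
    rfix <- percentile_range(fvals)
    rmov <- percentile_range(as.vector(mv$data))
    inv_aff_mv <- solve(mv$affine)
    # coarser levels get fewer bins for the same reason
    bins_l <- max(8L, as.integer(round(bins / ss)))

    mvdata <- as.double(mv$data)
    eval_mi <- function(pv) {
      M <- params_to_matrix(pv * scale, center) %*% B
      W2V <- inv_aff_mv %*% solve(M)   # fixed world -> moving voxel
      vals <- .c_sample_affine(mvdata, dim(mv$data), tw, W2V, 0)
      mi_from_values(fvals, vals, bins_l, rfix, rmov)
    }

    ps <- p / scale
    if (li == 1L) {
      # Field-of-view overlap guard: the seeded map must land a sensible
      # fraction of fixed voxels inside the moving volume.
      M0 <- params_to_matrix(p, center) %*% B
      mw <- t(solve(M0) %*% rbind(t(tw), 1))[, 1:3, drop = FALSE]
      vox <- t(inv_aff_mv %*% rbind(t(mw), 1))[, 1:3, drop = FALSE]
      dmv <- dim(mv$data)
      inside <- vox[, 1] >= 0 & vox[, 1] <= dmv[1] - 1 &
        vox[, 2] >= 0 & vox[, 2] <= dmv[2] - 1 &
        vox[, 3] >= 0 & vox[, 3] <= dmv[3] - 1
      if (mean(inside) < 0.10)
        ielec_stop("overlap",
                   paste("fields of view barely overlap after seeding",
                         "(%.1f%% of fixed voxels map into the moving volume);",
                         "supply a manual pre-alignment via `initial`"),
                   100 * mean(inside))
    }

    nev <- 0L
    level_converged <- TRUE
    cur <- eval_mi(ps); nev <- nev + 1L
    trace_lvl <- c(trace_lvl, li); trace_eval <- c(trace_eval, nev)
    trace_mi <- c(trace_mi, cur)

    if (f <= 2L && any(c("rigid", "affine") %in% stages)) {
      # Rotation information lives at fine scales: at the heavily smoothed
      # coarsest level a 10-15 degree pose change barely moves the image and
      # the MI optimum there can sit degrees off, so rotation search only
      # starts once the smoothing scale drops to 2 voxels. An exhaustive
      # Euler-angle sweep around the current estimate (wide at the first
      # rotation level, narrow afterwards) puts the descent in the right
      # basin; a pure local search can stall several degrees away.
      first_rot <- li == match(TRUE, pf <= 2L)
      ang <- if (first_rot) seq(-13.5, 13.5, by = 3) else seq(-3, 3, by = 1)
      cand <- as.matrix(expand.grid(ang, ang, ang))
      base <- ps
      best <- NULL
      for (ci in seq_len(nrow(cand))) {
        if (all(cand[ci, ] == 0)) next
        pc <- base
        pc[4:6] <- base[4:6] + cand[ci, ]
        v <- eval_mi(pc); nev <- nev + 1L
        if (v > cur + 1e-12) {
          cur <- v; best <- pc
        }
      }
      if (!is.null(best)) {
        ps <- best
        trace_lvl <- c(trace_lvl, li); trace_eval <- c(trace_eval, nev)
        trace_mi <- c(trace_mi, cur)
      }
    }

    stages_l <- if (f <= 2L) stages else intersect(stages, "translation")
    if (!length(stages_l)) stages_l <- stages[1]
    for (st in stages_l) {
      active <- .STAGE_PARAMS[[st]]
      step <- 2 * f
      stage_ev <- 0L
      while (step >= tol && stage_ev < max_eval) {
        improved <- FALSE
        for (i in active) {
          if (stage_ev >= max_eval) break
          for (sgn in c(1, -1)) {
            if (stage_ev >= max_eval) break
            cand <- ps
            cand[i] <- cand[i] + sgn * step
            v <- eval_mi(cand); nev <- nev + 1L; stage_ev <- stage_ev + 1L
            if (v > cur + 1e-12) {
              ps <- cand; cur <- v; improved <- TRUE
              trace_lvl <- c(trace_lvl, li); trace_eval <- c(trace_eval, nev)
              trace_mi <- c(trace_mi, cur)
              # line acceleration: keep walking this direction while it helps
              while (stage_ev < max_eval) {
                cand <- ps
                cand[i] <- cand[i] + sgn * step
                v <- eval_mi(cand); nev <- nev + 1L; stage_ev <- stage_ev + 1L
                if (v > cur + 1e-12) {
                  ps <- cand; cur <- v
                  trace_lvl <- c(trace_lvl, li)
                  trace_eval <- c(trace_eval, nev)
                  trace_mi <- c(trace_mi, cur)
                } else break
              }
              break
            }
          }
        }
        if (!improved) step <- step / 2
      }
      if (stage_ev >= max_eval && step >= tol) level_converged <- FALSE
    }

    if (li == length(pf)) {
      # final-level polish: coordinate moves stall on the coupled
      # rotation/translation/scale ridges of the MI surface, so finish with
      # a derivative-free simplex search over the last stage's parameters
      active <- .STAGE_PARAMS[[stages_l[length(stages_l)]]]
      opt <- stats::optim(ps[active], function(pa) {
        pc <- ps
        pc[active] <- pa
        -eval_mi(pc)
      }, method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-10))
      nev <- nev + opt$counts[["function"]]
      if (-opt$value > cur + 1e-12) {
        ps[active] <- opt$par
        cur <- -opt$value
        trace_lvl <- c(trace_lvl, li); trace_eval <- c(trace_eval, nev)
        trace_mi <- c(trace_mi, cur)
      }
    }

    converged[li] <- level_converged
    p <- ps * scale
  }

  structure(list(
    affine = affine_transform(params_to_matrix(p, center) %*% B,
                              moving$frame, fixed$frame),
    mi_trace = data.frame(level = trace_lvl, eval = trace_eval, mi = trace_mi),
    converged = converged,
    params = p
  ), class = "ielec_registration")
}

#' @export
print.ielec_registration <- function(x, ...) {
  cat(sprintf("<ielec_registration> %s -> %s, final MI %.4f nats, levels converged: %s\n",
              x$affine$source, x$affine$target, tail(x$mi_trace$mi, 1),
              paste(x$converged, collapse = ", ")))
  invisible(x)
}
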