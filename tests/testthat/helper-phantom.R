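# Shared fixtures, built in code and cached for the session so the expensive
# phantom/registration objects are generated once.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_phantom <- function(seed = 7L) {
  cached(paste0("phantom_", seed), make_phantom(phantom_spec(seed = seed)))
}

# n points uniform in a ball of given radius (seeded by the caller)
runif_ball <- function(n, radius) {
  m <- matrix(rnorm(3 * n), n, 3)
  m <- m / sqrt(rowSums(m^2))
  m * radius * runif(n)^(1 / 3)
}

rownorms <- function(m) sqrt(rowSums(m * m))

# A lone Gaussian blob CT on an identity-affine grid, for localization units.
blob_volume <- function(center, sigma = 1.5, shape = c(24L, 24L, 24L),
                        amplitude = 1000, background = 40, extra = NULL) {
  g <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                             z = 0:(shape[3] - 1)))
  v <- background + amplitude * exp(-rowSums(sweep(g, 2, center)^2) / (2 * sigma^2))
  if (!is.null(extra))
    v <- v + extra$amplitude *
      exp(-rowSums(sweep(g, 2, extra$center)^2) / (2 * extra$sigma^2))
  volume3d(array(v, shape), diag(4), frame = "ct")
}

# Run the end-to-end pipeline on the default phantom once and cache the
# result (output dir + phantom + jittered seeds used).
pipeline_fixture <- function() {
  cached("pipeline", {
    ph <- default_phantom()
    dir <- file.path(tempdir(), "ielec-phantom")
    write_phantom(ph, dir)
    set.seed(99L)
    pos <- montage_positions(ph$montage_truth)
    jit <- runif_ball(nrow(pos), 2)
    write_electrodes_tsv(montage(rownames(pos), pos + jit),
                         file.path(dir, "seeds.tsv"))
    out <- file.path(tempdir(), "ielec-out1")
    cfg <- list(seed = 1L,
                paths = list(ct = file.path(dir, "ct.nii.gz"),
                             mr = file.path(dir, "mr.nii.gz"),
                             template = file.path(dir, "template.nii.gz"),
                             seg = file.path(dir, "seg.nii.gz"),
                             lut = file.path(dir, "lut.txt"),
                             electrodes = file.path(dir, "seeds.tsv"),
                             surface = file.path(dir, "lepto.off"),
                             out_dir = out),
                project = list(channels = paste0("G", 1:16)))
    res <- suppressMessages(run_pipeline(cfg))
    list(phantom = ph, dir = dir, out = out, cfg = cfg, result = res)
  })
}

# Template-space ground truth for a set of subject-frame points.
template_truth <- function(ph, points) {
  ielec:::invert_deform_points(points, ph$spec)
}

# Independent point-to-triangle distance oracle, vectorized over all
# triangles: minimum over the three vertices, the three clamped edge
# projections, and the unconstrained plane foot where its barycentric
# coordinates are admissible (Gram normal equations) — a different
# derivation from the compiled kernel's region walk.
oracle_nearest <- function(p, mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)
  d2min <- pmin(rowSums((pm - a)^2), rowSums((pm - b)^2), rowSums((pm - c_)^2))
  for (e in list(list(a, b), list(b, c_), list(c_, a))) {
    d <- e[[2]] - e[[1]]
    s <- rowSums((pm - e[[1]]) * d) / rowSums(d * d)
    s <- pmin(pmax(s, 0), 1)
    q <- e[[1]] + d * s
    d2min <- pmin(d2min, rowSums((pm - q)^2))
  }
  e1 <- b - a; e2 <- c_ - a
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  r1 <- rowSums((pm - a) * e1); r2 <- rowSums((pm - a) * e2)
  det <- g11 * g22 - g12^2
  u <- (g22 * r1 - g12 * r2) / det
  w <- (g11 * r2 - g12 * r1) / det
  ok <- det > 1e-12 & u >= 0 & w >= 0 & u + w <= 1
  if (any(ok)) {
    q <- a[ok, , drop = FALSE] + e1[ok, , drop = FALSE] * u[ok] +
      e2[ok, , drop = FALSE] * w[ok]
    d2min[ok] <- pmin(d2min[ok], rowSums((pm[ok, , drop = FALSE] - q)^2))
  }
  list(distance = sqrt(min(d2min)))
}
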