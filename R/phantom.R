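#' Specification of a synthetic head phantom
#'
#' Defines the geometry, intensity model and noise of the deterministic
#' phantom the pipeline is validated on: a spherical head with a bright-CT /
#' dark-MR skull shell, an sEEG shaft of Gaussian contact blobs in the CT,
#' an ECoG grid depressed below a spherical leptomeningeal surface
#' (brain shift), concentric segmentation label shells, and a template MR
#' related to the subject MR by a known smooth sinusoidal deformation.
#'
#' CT intensities are quantized to integers (Hounsfield-like); the sEEG
#' shaft is axis-aligned with voxel-center contacts so equally bright
#' contact peaks tie exactly and the documented distance tie-break of
#' [find_local_peak()] resolves them.
#'
#' @param shape Grid shape in voxels (default 64^3).
#' @param voxel_size Isotropic voxel size, mm (default 1).
#' @param head_radius Outer skull semi-axis along x, mm.
#' @param head_axes Relative semi-axes of the ellipsoidal skull (the
#'   asymmetry, together with a smooth directional modulation of the skull
#'   intensity, is what makes head rotation identifiable to the
#'   registration, as it is for real heads).
#' @param skull_thickness Skull shell thickness, mm.
#' @param brain_radius Brain (and leptomeningeal sphere) radius, mm.
#' @param seeg List: `name` prefix, `n` contacts, `pitch` in voxels (integer,
#'   so contacts stay voxel-aligned), and the CT voxel indices of the shaft
#'   line: `y`, `z`, and `x0` (index of contact 1).
#' @param ecog List: `name` prefix, `rows`, `cols`, `pitch` mm,
#'   `depression` mm (inward brain-shift displacement).
#' @param blob_sigma Contact blob Gaussian sigma, mm.
#' @param psf_sigma Scanner point-spread emulation: Gaussian sigma (mm)
#'   applied to the noise-free MR, CT and template volumes. Real scanners do
#'   not produce step-function edges; perfectly sharp analytic boundaries
#'   interact with trilinear resampling to create spurious similarity optima
#'   no real acquisition would show.
#' @param blob_amplitude Contact blob amplitude, CT intensity units.
#' @param noise_sigma_mr,noise_sigma_ct Additive Gaussian noise sigma.
#' @param deform_amplitude,deform_wavelength Amplitude (mm) and wavelength
#'   (mm) of the subject-to-template sinusoidal deformation.
#' @param pial_dent Inward sulcal dent amplitude of the pial surface, mm
#'   (shallow by construction: the leptomeningeal envelope must bridge them
#'   while changing the enclosed volume by at most ~2 percent).
#' @param label_bands Outer radii (mm) of the concentric label bands.
#' @param ct_misalign `NULL` for a seeded random rigid CT pose
#'   (rotation 5-15 degrees, translation 5-20 mm), or a list
#'   `(angle_deg, axis, translation)` for an explicit pose.
#' @param seed Integer seed for all randomness.
#' @return A `ielec_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size = 1,
                         head_radius = 29, head_axes = c(1, 0.93, 0.87),
                         skull_thickness = 2, brain_radius = 22.5,
                         seeg = list(name = "LPM", n = 10L, pitch = 4,
                                     y = 40, z = 31, x0 = 14),
                         ecog = list(name = "G", rows = 4L, cols = 4L,
                                     pitch = 10, depression = 3),
                         blob_sigma = 0.9, blob_amplitude = 1000,
                         psf_sigma = 0.6,
                         noise_sigma_mr = 5, noise_sigma_ct = 0,
                         deform_amplitude = 3, deform_wavelength = 40,
                         pial_dent = 0.8,
                         label_bands = c(6, 11.6, 18.2, 23.6),
                         ct_misalign = NULL, seed = 42L) {
  sp <- list(shape = as.integer(shape), voxel_size = voxel_size,
             head_radius = head_radius, head_axes = head_axes,
             skull_thickness = skull_thickness,
             brain_radius = brain_radius, seeg = seeg, ecog = ecog,
             blob_sigma = blob_sigma, blob_amplitude = blob_amplitude,
             psf_sigma = psf_sigma,
             noise_sigma_mr = noise_sigma_mr, noise_sigma_ct = noise_sigma_ct,
             deform_amplitude = deform_amplitude,
             deform_wavelength = deform_wavelength,
             pial_dent = pial_dent, label_bands = label_bands,
             ct_misalign = ct_misalign, seed = as.integer(seed))
  geom <- c(head_radius, head_axes, skull_thickness, brain_radius, blob_sigma,
            blob_amplitude, seeg$pitch, ecog$pitch)
  if (any(geom <= 0)) ielec_stop("spec", "all geometric quantities must be positive")
  if (brain_radius >= (head_radius - skull_thickness) * min(head_axes))
    ielec_stop("spec", "brain must fit inside the skull")
  class(sp) <- "ielec_phantom_spec"
  sp
}

# ---- analytic phantom fields, all in MR world mm -------------------------

phantom_center <- function(sp) (sp$shape - 1) / 2 * sp$voxel_size

# radius from head center for n x 3 points
.prad <- function(q, c0) row_norms(q - matrix(c0, nrow(q), 3, byrow = TRUE))

# Normalized ellipsoidal skull coordinate (1 = outer skull surface) and the
# smooth directional modulation of skull intensity. The ellipticity plus the
# modulation break the rotational symmetry of the head, as skull anatomy
# does for real heads; the interior is kept free of texture so contact blob
# peaks stay exactly tied on the CT grid.
.skull_coords <- function(q, sp) {
  c0 <- phantom_center(sp)
  dq <- q - matrix(c0, nrow(q), 3, byrow = TRUE)
  ax <- sp$head_radius * sp$head_axes
  u <- sqrt((dq[, 1] / ax[1])^2 + (dq[, 2] / ax[2])^2 + (dq[, 3] / ax[3])^2)
  r <- row_norms(dq)
  d <- dq / pmax(r, 1e-9)
  mod <- 1 + 0.4 * (1.5 * d[, 1] * d[, 2] + 1.2 * d[, 2] * d[, 3] +
                      0.9 * d[, 1] * d[, 3] + 0.6 * (d[, 1]^2 - d[, 2]^2))
  list(u = u, r = r, mod = mod)
}

mr_analytic <- function(q, sp) {
  sc <- .skull_coords(q, sp)
  t_rel <- sp$skull_thickness / sp$head_radius
  fat_rel <- 1.5 / sp$head_radius
  v <- numeric(nrow(q))
  v[sc$u >= 1 & sc$u < 1 + fat_rel] <- 250
  sk <- sc$u >= 1 - t_rel & sc$u < 1
  v[sk] <- 80 * sc$mod[sk]
  v[sc$u < 1 - t_rel & sc$r >= sp$brain_radius] <- 150   # CSF gap
  br <- sc$r < sp$brain_radius
  if (any(br)) {
    qb <- q[br, , drop = FALSE]
    v[br] <- 420 +
      160 * sin(2 * pi * qb[, 1] / 13) * sin(2 * pi * qb[, 2] / 16) *
        sin(2 * pi * qb[, 3] / 11) +
      120 * (1 - sc$r[br] / sp$brain_radius)
  }
  v
}

ct_analytic <- function(q, sp, contacts) {
  sc <- .skull_coords(q, sp)
  t_rel <- sp$skull_thickness / sp$head_radius
  fat_rel <- 1.5 / sp$head_radius
  v <- numeric(nrow(q))
  v[sc$u >= 1 & sc$u < 1 + fat_rel] <- 30
  sk <- sc$u >= 1 - t_rel & sc$u < 1
  v[sk] <- 800 * sc$mod[sk]
  v[sc$u < 1 - t_rel] <- 40
  s2 <- 2 * sp$blob_sigma^2
  dmin2 <- rep(Inf, nrow(q))
  for (k in seq_len(nrow(contacts))) {
    d2 <- rowSums((q - matrix(contacts[k, ], nrow(q), 3, byrow = TRUE))^2)
    dmin2 <- pmin(dmin2, d2)
    near <- d2 < (5 * sp$blob_sigma)^2
    v[near] <- v[near] + sp$blob_amplitude * exp(-d2[near] / s2)
  }
  # Faint soft-tissue texture correlated with the MR (what couples CT and MR
  # mutual information away from the skull), suppressed within 5 mm of any
  # contact where the metal blob dominates. The margin exceeds the snap
  # region radius plus the scanner-PSF kernel reach, so every contact's
  # neighbourhood stays texture-free and symmetric: peak intensities tie
  # exactly and region centroids are unbiased.
  br <- sc$r < sp$brain_radius & dmin2 > 25
  if (any(br)) {
    qb <- q[br, , drop = FALSE]
    v[br] <- v[br] + 0.12 *
      (160 * sin(2 * pi * qb[, 1] / 13) * sin(2 * pi * qb[, 2] / 16) *
         sin(2 * pi * qb[, 3] / 11) +
       120 * (1 - sc$r[br] / sp$brain_radius))
  }
  v
}

# Concentric label shells: boundaries depend only on the radius from the
# head center, so label margins around the contacts are invariant to the
# seeded CT pose rotation.
seg_analytic <- function(q, sp) {
  c0 <- phantom_center(sp)
  r <- .prad(q, c0)
  b <- sp$label_bands
  id <- integer(nrow(q))
  id[r < b[1]] <- 10L                        # Thalamus
  id[r >= b[1] & r < b[2]] <- 17L            # Hippocampus
  id[r >= b[2] & r < b[3]] <- 2L             # Cerebral white matter
  id[r >= b[3] & r < b[4]] <- 3L             # Cerebral cortex
  id
}

phantom_lut <- function() {
  df <- data.frame(
    id = c(0L, 2L, 3L, 10L, 17L),
    name = c("Unknown", "Cerebral-White-Matter", "Cerebral-Cortex",
             "Thalamus", "Hippocampus"),
    r = c(0L, 245L, 205L, 0L, 220L),
    g = c(0L, 245L, 62L, 118L, 216L),
    b = c(0L, 245L, 78L, 14L, 20L),
    a = 0L, stringsAsFactors = FALSE)
  class(df) <- c("ielec_lut", "data.frame")
  df
}

# sinusoidal template deformation d(q): template(q) = subject(q + d(q))
deform_analytic <- function(q, sp) {
  c0 <- phantom_center(sp)
  A <- sp$deform_amplitude
  w <- 2 * pi / sp$deform_wavelength
  x <- q[, 1] - c0[1]; y <- q[, 2] - c0[2]; z <- q[, 3] - c0[3]
  cbind(A * sin(w * y) * cos(w * z),
        A * sin(w * z) * cos(w * x),
        A * sin(w * x) * cos(w * y))
}

# x solving x + d(x) = p (template-space location of subject point p)
invert_deform_points <- function(p, sp) {
  x <- p
  for (i in 1:30) x <- p - deform_analytic(x, sp)
  x
}

# ---- meshes ---------------------------------------------------------------

# Icosphere: subdivided icosahedron scaled to unit radius.
icosphere <- function(subdivisions = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid <- new.env()
    nf <- matrix(0L, 0, 3)
    getmid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c_); ca <- getmid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# spherical angles of unit vectors
.sph_angles <- function(u) list(theta = acos(pmin(pmax(u[, 3], -1), 1)),
                                phi = atan2(u[, 2], u[, 1]))

phantom_meshes <- function(sp) {
  ico <- icosphere(3L)
  c0 <- phantom_center(sp)
  R <- sp$brain_radius
  lepto_v <- sweep(ico$vertices * R, 2, c0, `+`)
  ang <- .sph_angles(ico$vertices)
  dent <- sp$pial_dent * pmax(0, sin(4 * ang$theta) * sin(4 * ang$phi))
  pial_v <- sweep(ico$vertices * (R - dent), 2, c0, `+`)
  list(pial = surface_mesh(pial_v, ico$triangles, frame = "mr_subject"),
       lepto = surface_mesh(lepto_v, ico$triangles, frame = "mr_subject"))
}

# ---- contact layout -------------------------------------------------------

# The sEEG shaft is laid out on CT voxel centers (integer indices along the
# CT x axis): equally bright contact blobs then sample identically on the CT
# grid, peak-voxel intensities tie exactly, and find_local_peak's distance
# tie-break resolves neighbouring contacts deterministically. The ECoG grid
# is anatomy-relative (on the leptomeningeal sphere in the MR frame).
phantom_contacts <- function(sp, ct_aff, ct_to_mr) {
  c0 <- phantom_center(sp)
  se <- sp$seeg
  seeg_idx <- cbind(se$x0 + (seq_len(se$n) - 1) * se$pitch, se$y, se$z)
  seeg_ctw <- t(ct_aff %*% rbind(t(seeg_idx), 1))[, 1:3, drop = FALSE]
  seeg_mr <- t(ct_to_mr %*% rbind(t(seeg_ctw), 1))[, 1:3, drop = FALSE]
  seeg_names <- paste0(se$name, seq_len(se$n))
  # ghost blobs one pitch beyond each shaft end (the shaft tip and cable
  # leave metal artifact there too): every real contact then has identical
  # neighbourhoods, so the scanner PSF cannot break the exact intensity
  # ties between contact peaks that the snap tie-break relies on
  ghost_idx <- rbind(c(se$x0 - se$pitch, se$y, se$z),
                     c(se$x0 + se$n * se$pitch, se$y, se$z))
  ghost_ctw <- t(ct_aff %*% rbind(t(ghost_idx), 1))[, 1:3, drop = FALSE]
  ghost_mr <- t(ct_to_mr %*% rbind(t(ghost_ctw), 1))[, 1:3, drop = FALSE]
  ec <- sp$ecog
  R <- sp$brain_radius
  si <- (seq_len(ec$rows) - (ec$rows + 1) / 2) * ec$pitch
  sj <- (seq_len(ec$cols) - (ec$cols + 1) / 2) * ec$pitch
  g <- expand.grid(si = si, sj = sj)
  h <- sqrt(R^2 - g$si^2 - g$sj^2)
  dirs <- cbind(g$si, g$sj, h) / R              # unit vectors (on sphere)
  pre <- sweep(dirs * R, 2, c0, `+`)            # on the leptomeningeal sphere
  post <- sweep(dirs * (R - ec$depression), 2, c0, `+`)  # brain-shifted
  ecog_names <- paste0(ec$name, seq_len(ec$rows * ec$cols))
  list(names = c(seeg_names, ecog_names),
       true = rbind(seeg_mr, post),             # where the blobs are (MR frame)
       blobs = rbind(seeg_mr, post, ghost_mr),  # incl. shaft-end artifacts
       ecog_names = ecog_names, seeg_names = seeg_names,
       ecog_preshift = pre)
}

# ---- the generator --------------------------------------------------------

#' Generate a synthetic head phantom bundle
#'
#' Produces every input the localization pipeline needs, with ground truth
#' for all of them, fully deterministically for a given spec and seed:
#' subject MR, misaligned CT with contact blobs, segmentation + LUT, pial
#' and leptomeningeal meshes, true contact montage (and pre-shift ECoG
#' positions), the true CT-to-MR rigid transform, a template MR, and the
#' true subject-to-template deformation field.
#'
#' @param sp A [phantom_spec()].
#' @return A `ielec_phantom` list with elements `mr`, `ct`, `seg`, `lut`,
#'   `pial`, `lepto`, `montage_truth`, `grid_truth_preshift`,
#'   `true_ct_to_mr`, `template_mr`, `true_subject_to_template`,
#'   `truth_labels`, `spec`.
#' @export
make_phantom <- function(sp = phantom_spec()) {
  if (!inherits(sp, "ielec_phantom_spec")) ielec_stop("spec", "not a phantom spec")
  c0 <- phantom_center(sp)

  with_seed(sp$seed, {
    # CT pose: rotation about the head center + world translation
    mis <- sp$ct_misalign
    if (is.null(mis)) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 5, 15)
      tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      tr <- tdir * runif(1, 5, 20)
      mis <- list(angle_deg = ang, axis = ax, translation = tr)
    }
    ax <- mis$axis / sqrt(sum(mis$axis^2))
    th <- mis$angle_deg * pi / 180
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R3 <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    Tm <- diag(4)
    Tm[1:3, 1:3] <- R3
    Tm[1:3, 4] <- mis$translation + c0 - R3 %*% c0
    true_ct_to_mr <- affine_transform(Tm, "ct", "mr_subject")

    mr_aff <- diag(4) * c(rep(sp$voxel_size, 3), 1)
    # CT grid origin chosen so the head sits centered in the CT field of view
    ct_aff <- mr_aff
    ct_aff[1:3, 4] <- solve(Tm)[1:3, 1:3] %*% (-mis$translation)

    cts <- phantom_contacts(sp, ct_aff, Tm)
    if (any(.prad(cts$true, c0) >= sp$head_radius))
      ielec_stop("spec", "contacts outside the head")

    grid <- voxel_grid(sp$shape) * sp$voxel_size
    n <- nrow(grid)

    psf <- sp$psf_sigma / sp$voxel_size
    mrv <- gauss_smooth3d(array(mr_analytic(grid, sp), sp$shape), psf)
    if (sp$noise_sigma_mr > 0) mrv <- mrv + rnorm(n, 0, sp$noise_sigma_mr)
    mr <- volume3d(array(mrv, sp$shape), mr_aff, "mr_subject")

    ctw <- t(ct_aff %*% rbind(t(voxel_grid(sp$shape)), 1))[, 1:3]
    ctq <- t(Tm %*% rbind(t(ctw), 1))[, 1:3]
    ctv <- gauss_smooth3d(array(ct_analytic(ctq, sp, cts$blobs), sp$shape), psf)
    if (sp$noise_sigma_ct > 0) ctv <- ctv + rnorm(n, 0, sp$noise_sigma_ct)
    ct <- volume3d(array(round(ctv), sp$shape), ct_aff, "ct")

    seg <- volume3d(array(seg_analytic(grid, sp), sp$shape), mr_aff,
                    "mr_subject", kind = "label")

    tmplv <- gauss_smooth3d(array(mr_analytic(grid + deform_analytic(grid, sp),
                                              sp), sp$shape), psf)
    if (sp$noise_sigma_mr > 0) tmplv <- tmplv + rnorm(n, 0, sp$noise_sigma_mr)
    template_mr <- volume3d(array(tmplv, sp$shape), mr_aff, "mr_template")

    dm <- sp$shape
    fwd <- array(deform_analytic(grid, sp), c(dm, 3))
    binv <- invert_deform_points(grid + matrix(fwd, ncol = 3), sp) -
      (grid + matrix(fwd, ncol = 3))
    true_field <- deformation_field(mr_aff, fwd, array(binv, c(dm, 3)),
                                    affine_transform(diag(4), "mr_subject",
                                                     "mr_template"))

    meshes <- phantom_meshes(sp)
    montage_truth <- montage(cts$names, cts$true, frame = "mr_subject")
    grid_truth_preshift <- montage(cts$ecog_names, cts$ecog_preshift,
                                   frame = "mr_subject")

    lut <- phantom_lut()
    # generating labels: sEEG at true positions, ECoG at pre-shift positions
    eval_pos <- rbind(cts$true[seq_along(cts$seeg_names), , drop = FALSE],
                      cts$ecog_preshift)
    truth_labels <- data.frame(
      name = cts$names,
      label = lut_name(lut, seg_analytic(eval_pos, sp)),
      stringsAsFactors = FALSE)

    structure(list(mr = mr, ct = ct, seg = seg, lut = lut,
                   pial = meshes$pial, lepto = meshes$lepto,
                   montage_truth = montage_truth,
                   grid_truth_preshift = grid_truth_preshift,
                   true_ct_to_mr = true_ct_to_mr,
                   template_mr = template_mr,
                   true_subject_to_template = true_field,
                   truth_labels = truth_labels,
                   spec = sp),
              class = "ielec_phantom")
  })
}

#' @export
print.ielec_phantom <- function(x, ...) {
  cat(sprintf("<ielec_phantom> %s grid, %d contacts, seed %d\n",
              paste(x$spec$shape, collapse = "x"),
              nrow(x$montage_truth$contacts), x$spec$seed))
  invisible(x)
}

#' Write a phantom bundle to a directory
#'
#' Writes all volumes (NIfTI), meshes (OFF), montages (electrodes.tsv), the
#' LUT, the true transforms, and a manifest JSON listing every file with its
#' MD5 checksum.
#'
#' @param bundle An `ielec_phantom`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_phantom <- function(bundle, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    ielec_stop("io", "cannot write to directory %s", dir)
  p <- function(f) file.path(dir, f)
  write_volume(bundle$mr, p("mr.nii.gz"))
  write_volume(bundle$ct, p("ct.nii.gz"))
  write_volume(bundle$seg, p("seg.nii.gz"))
  write_volume(bundle$template_mr, p("template.nii.gz"))
  write_off(bundle$pial, p("pial.off"))
  write_off(bundle$lepto, p("lepto.off"))
  write_electrodes_tsv(bundle$montage_truth, p("electrodes.tsv"))
  write_electrodes_tsv(bundle$grid_truth_preshift, p("electrodes_preshift.tsv"))
  write_transform(bundle$true_ct_to_mr, p("ct_to_mr.json"))
  write_deformation(bundle$true_subject_to_template, p("subject_to_template"))
  writeLines(c("# synthetic phantom color LUT",
               sprintf("%-4d %-28s %3d %3d %3d %3d", bundle$lut$id,
                       bundle$lut$name, bundle$lut$r, bundle$lut$g,
                       bundle$lut$b, bundle$lut$a)),
             p("lut.txt"))
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    spec = bundle$spec[setdiff(names(bundle$spec), "ct_misalign")],
    files = lapply(setNames(files, files),
                   function(f) list(md5 = unname(tools::md5sum(p(f))))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}

#' Discrepancy between two affine transforms at a point
#'
#' Reports how far apart two transforms are: the translation discrepancy at
#' a reference point (mm) and the angle (degrees) between their rotation
#' parts (polar decomposition of the relative 3x3 block).
#'
#' @param a,b `ielec_affine` objects with matching frames.
#' @param at Reference point, world mm (e.g. the head center).
#' @return list(translation_mm, rotation_deg).
#' @export
transform_discrepancy <- function(a, b, at) {
  D <- solve(a$matrix) %*% b$matrix
  p <- as.numeric(D %*% c(at, 1))[1:3]
  trans <- sqrt(sum((p - at)^2))
  sv <- svd(D[1:3, 1:3])
  Rm <- sv$u %*% t(sv$v)
  ang <- acos(pmin(pmax((sum(diag(Rm)) - 1) / 2, -1), 1)) * 180 / pi
  list(translation_mm = trans, rotation_deg = ang)
}
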