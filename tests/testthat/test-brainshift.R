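test_that("nearest_point_on_mesh handles foot, edge and vertex cases", {
  # one triangle in the z = 0 plane
  mesh_v <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, -4))
  mesh_t <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  mesh <- surface_mesh(mesh_v, mesh_t, frame = "mr_subject")
  r <- nearest_point_on_mesh(c(1, 1, 2), mesh)
  expect_equal(r$point, c(1, 1, 0))          # orthogonal foot
  expect_equal(r$distance, 2)
  expect_identical(r$triangle, 1L)

  # point nearest the shared edge between triangles 1 and 2: deterministic
  # lower triangle id
  r2 <- nearest_point_on_mesh(c(2, -1, 1), mesh)
  expect_equal(r2$point, c(2, 0, 0))
  expect_identical(r2$triangle, 1L)

  r3 <- nearest_point_on_mesh(c(6, -1, 1), mesh)
  expect_equal(r3$point, c(4, 0, 0))         # vertex case
})

test_that("compiled nearest-point kernel matches the independent oracle", {
  ph <- default_phantom()
  mesh <- ph$lepto
  set.seed(41)
  pts <- matrix(rnorm(50 * 3, 31.5, 12), ncol = 3)
  res <- nearest_point_on_mesh(pts, mesh)
  for (i in seq_len(nrow(pts))) {
    o <- oracle_nearest(pts[i, ], mesh)
    expect_lt(abs(res$distance[i] - o$distance), 1e-9)
  }
})

test_that("leptomeningeal smoothing fills dents without shrinking", {
  ph <- default_phantom()
  c0 <- (ph$spec$shape - 1) / 2
  # sphere is (nearly) a fixed point
  sm <- smooth_to_leptomeningeal(ph$lepto)
  expect_lt(max(rownorms(sm$vertices - ph$lepto$vertices)),
            5e-3 * ph$spec$brain_radius)
  expect_identical(nrow(sm$vertices), nrow(ph$lepto$vertices))

  # dented sphere: radial spread strictly reduced, >= 99% of input enclosed
  smp <- smooth_to_leptomeningeal(ph$pial)
  rin <- rownorms(sweep(ph$pial$vertices, 2, c0))
  rout <- rownorms(sweep(smp$vertices, 2, c0))
  expect_lt(sd(rout), sd(rin))
  expect_gte(mean(ielec:::points_inside_mesh(ph$pial$vertices, smp)), 0.99)
  expect_lt(abs(ielec:::mesh_volume(smp) / ielec:::mesh_volume(ph$pial) - 1),
            0.04)

  # open hemisphere is rejected
  keep <- rowSums(matrix(ph$lepto$vertices[t(ph$lepto$triangles), 3] - c0[3],
                         ncol = 3) > 0) == 3
  open_mesh <- surface_mesh(ph$lepto$vertices, ph$lepto$triangles[keep, ])
  expect_error(smooth_to_leptomeningeal(open_mesh),
               class = "ielec_topology_error")
})

test_that("projection moves contacts to the surface exactly and idempotently", {
  ph <- default_phantom()
  pre <- montage_positions(ph$grid_truth_preshift)
  proj <- suppressWarnings(
    project_sensors_onto_brain(ph$montage_truth, ph$lepto,
                               channels = rownames(pre)))
  pp <- montage_positions(proj, rownames(pre))
  # on-mesh to numerical precision
  expect_lt(max(nearest_point_on_mesh(pp, ph$lepto)$distance), 1e-6)
  # recovers the pre-shift truth
  expect_lt(mean(rownorms(pp - pre)), 0.2)
  expect_lt(max(rownorms(pp - pre)), 0.2 + 1e-9)
  # shifts are the grid depression (up to mesh facet depth)
  expect_equal(unname(attr(proj, "shift_mm")),
               rep(ph$spec$ecog$depression, 16), tolerance = 0.05)
  # idempotent
  proj2 <- suppressWarnings(
    project_sensors_onto_brain(proj, ph$lepto, channels = rownames(pre)))
  expect_lt(max(rownorms(montage_positions(proj2, rownames(pre)) - pp)), 1e-9)
  # inter-contact distance structure matches the physical (pre-shift) grid
  # geometry within 15% — projection undoes the depression's compression
  d_true <- dist(pre)
  d_post <- dist(pp)
  expect_lt(max(abs(d_post / d_true - 1)), 0.15)

  # a contact already on a triangle stays put
  tri1 <- ph$lepto$triangles[1, ]
  onmesh <- colMeans(ph$lepto$vertices[tri1, ])
  m <- mark_contact(montage(c("X1", "X2")), "X1", onmesh)
  pm <- project_sensors_onto_brain(m, ph$lepto, channels = "X1")
  expect_lt(sqrt(sum((montage_positions(pm, "X1") - onmesh)^2)), 1e-9)
  expect_identical(pm$contacts$status[2], "unlocated")   # untouched
  expect_error(project_sensors_onto_brain(m, ph$lepto, channels = "X2"),
               "X2", class = "ielec_state_error")
})

test_that("a contact at the sphere center projects radially", {
  ph <- default_phantom()
  c0 <- (ph$spec$shape - 1) / 2
  off <- c0 + c(3, 0, 0)   # along +x from the center
  m <- mark_contact(montage("C1"), "C1", off)
  pm <- project_sensors_onto_brain(m, ph$lepto, channels = "C1")
  p <- drop(montage_positions(pm, "C1"))
  u <- (p - c0) / sqrt(sum((p - c0)^2))
  # direction preserved up to the facet resolution of the mesh
  expect_gt(sum(u * c(1, 0, 0)), 0.99)
  expect_equal(sqrt(sum((p - c0)^2)), ph$spec$brain_radius, tolerance = 0.1)
})

test_that("OFF meshes round-trip", {
  ph <- default_phantom()
  f <- tempfile(fileext = ".off")
  write_off(ph$pial, f)
  back <- read_off(f)
  expect_equal(back$vertices, ph$pial$vertices, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$triangles, ph$pial$triangles, ignore_attr = TRUE)
  writeLines("NOFF", f)
  expect_error(read_off(f), class = "ielec_format_error")
})
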