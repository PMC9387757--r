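test_that("mutual information matches an independent entropy oracle", {
  set.seed(2)
  vol <- volume3d(array(rexp(20^3, 1 / 100), c(20, 20, 20)), diag(4), "ct")
  mi_self <- mutual_information(vol, vol, bins = 32)
  # oracle: marginal entropy from a directly built histogram with the same
  # binning rule (1st-99th percentile range, clipped end bins)
  x <- as.vector(vol$data)
  r <- unname(quantile(x, c(0.01, 0.99)))
  i <- pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * 32), 0), 31)
  p <- as.vector(table(factor(i, levels = 0:31))) / length(i)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi_self, h, tolerance = 1e-12)
  expect_gte(mi_self, 0)

  const <- volume3d(array(7, dim(vol$data)), diag(4), "ct")
  expect_equal(mutual_information(vol, const), 0)

  set.seed(3)
  perm <- volume3d(array(sample(x), dim(vol$data)), diag(4), "ct")
  expect_lt(mutual_information(vol, perm), mi_self)

  other <- volume3d(array(rnorm(20^3, 500, 100), c(20, 20, 20)), diag(4),
                    "mr_subject")
  expect_lt(abs(mutual_information(vol, other) -
                  mutual_information(other, vol)), 1e-9)
  small <- volume3d(array(0, c(5, 5, 5)), diag(4), "ct")
  expect_error(mutual_information(vol, small), class = "ielec_dim_error")
})

test_that("self-registration returns the identity", {
  ph <- default_phantom()
  reg <- compute_affine_registration(ph$mr, ph$mr, max_eval = 60)
  d <- transform_discrepancy(reg$affine, identity_transform("mr_subject"),
                             (ph$spec$shape - 1) / 2)
  expect_lt(d$translation_mm, 0.1)
  expect_lt(d$rotation_deg, 0.1)
})

test_that("MI trace is monotone and the result beats the seed", {
  ph <- default_phantom()
  reg <- cached("reg_default",
                compute_affine_registration(ph$ct, ph$mr,
                                            stages = c("translation", "rigid")))
  by_level <- split(reg$mi_trace$mi, reg$mi_trace$level)
  for (v in by_level) expect_true(all(diff(v) >= -1e-9))
  # the result beats its seed, compared on the final level's metric
  # (levels use different grids and bin counts, so MI values are only
  # comparable within a level)
  final <- by_level[[length(by_level)]]
  expect_gte(tail(final, 1), final[1] - 1e-9)
})

test_that("rigid ground-truth misalignment is recovered on the phantom", {
  ph <- default_phantom()
  reg <- cached("reg_default",
                compute_affine_registration(ph$ct, ph$mr,
                                            stages = c("translation", "rigid")))
  d <- transform_discrepancy(reg$affine, ph$true_ct_to_mr,
                             (ph$spec$shape - 1) / 2)
  expect_lt(d$translation_mm, 0.5)   # 0.5 voxel at 1 mm voxels
  expect_lt(d$rotation_deg, 1)
})

test_that("registration is covariant under pre-composed rigid maps", {
  ph <- default_phantom()
  reg <- cached("reg_default",
                compute_affine_registration(ph$ct, ph$mr,
                                            stages = c("translation", "rigid")))
  # pre-rotate the moving volume by a known rigid map T (header-level):
  # registering T-moved CT must recover result composed with T^-1
  th <- 6 * pi / 180
  Tm <- diag(4)
  Tm[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Tm[1:3, 4] <- c(4, -3, 2)
  ct2 <- volume3d(ph$ct$data, solve(Tm) %*% ph$ct$affine, "ct")
  reg2 <- compute_affine_registration(ct2, ph$mr,
                                      stages = c("translation", "rigid"))
  expected <- reg$affine$matrix %*% Tm
  d <- transform_discrepancy(reg2$affine,
                             affine_transform(expected, "ct", "mr_subject"),
                             (ph$spec$shape - 1) / 2)
  expect_lt(d$translation_mm, 0.5)
  expect_lt(d$rotation_deg, 1)
})

test_that("non-overlapping fields of view raise an overlap error", {
  ph <- default_phantom()
  far <- diag(4); far[1:3, 4] <- c(500, 0, 0)
  expect_error(
    compute_affine_registration(ph$ct, ph$mr,
                                initial = affine_transform(far, "ct", "mr_subject")),
    "pre-alignment", class = "ielec_overlap_error")
  seg <- ph$seg
  expect_error(compute_affine_registration(seg, ph$mr),
               class = "ielec_kind_error")
})
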