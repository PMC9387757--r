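test_that("NIfTI write/read round-trips data and affine", {
  aff <- rbind(c(0, -1.5, 0, 10), c(1.5, 0, 0, -20), c(0, 0, 2, -5),
               c(0, 0, 0, 1))
  set.seed(1)
  vol <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)), aff, "mr_subject")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "mr_subject")
  expect_lt(max(abs(back$affine - aff)), 1e-5)
  expect_lt(max(abs(back$data - vol$data)), 1e-6)

  lab <- volume3d(array(sample(0:5, 60, TRUE), c(3, 4, 5)), diag(4),
                  "mr_subject", kind = "label")
  f2 <- tempfile(fileext = ".nii")
  write_volume(lab, f2)
  back2 <- read_volume(f2, "mr_subject", kind = "label")
  expect_identical(back2$data, lab$data)
})

test_that("sform is preferred; qform is the fallback when sform code is 0", {
  skip_if_not_installed("oro.nifti")
  # independent header writer: qform-only file with 2 mm voxels and offsets
  img <- oro.nifti::nifti(array(as.numeric(1:27), c(3, 3, 3)),
                          datatype = 16)
  img@pixdim <- c(1, 2, 2, 2, 0, 0, 0, 0)
  img@qform_code <- 2
  img@sform_code <- 0
  img@quatern_b <- 0; img@quatern_c <- 0; img@quatern_d <- 0
  img@qoffset_x <- -10; img@qoffset_y <- -11; img@qoffset_z <- -12
  f <- tempfile()
  oro.nifti::writeNIfTI(img, f)
  vol <- read_volume(paste0(f, ".nii.gz"), "mr_subject")
  expect_equal(vol$affine[1:3, 1:3], diag(c(2, 2, 2)), tolerance = 1e-6)
  expect_equal(vol$affine[1:3, 4], c(-10, -11, -12), tolerance = 1e-6)

  # both headers valid, deliberately different: sform must win
  img2 <- RNifti::asNifti(array(as.numeric(1:27), c(3, 3, 3)))
  saff <- diag(c(3, 3, 3, 1)); saff[1:3, 4] <- c(1, 2, 3)
  RNifti::qform(img2) <- structure(diag(4), code = 1L)
  RNifti::sform(img2) <- structure(saff, code = 2L)
  f2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img2, f2)
  vol2 <- read_volume(f2, "mr_subject")
  expect_equal(vol2$affine, saff, tolerance = 1e-5)
})

test_that("read_volume rejects missing files and 4D images", {
  expect_error(read_volume(tempfile(), "ct"), class = "ielec_io_error")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), f)
  expect_error(read_volume(f, "ct"), "4, 4, 4, 3", class = "ielec_dim_error")
  expect_error(write_volume(blob_volume(c(5, 5, 5)),
                            file.path(tempfile(), "x", "y.nii")),
               class = "ielec_io_error")
})

test_that("volume3d validates its invariants", {
  expect_error(volume3d(array(0, c(2, 2)), diag(4), "ct"),
               class = "ielec_dim_error")
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(volume3d(array(0, c(2, 2, 2)), sing, "ct"),
               class = "ielec_dim_error")
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(volume3d(array(0, c(2, 2, 2)), bad, "ct"),
               class = "ielec_dim_error")
  expect_error(volume3d(array(0.5, c(2, 2, 2)), diag(4), "ct", kind = "label"),
               class = "ielec_kind_error")
})

test_that("voxel/world mapping matches hand computations and inverts", {
  vol <- volume3d(array(0, c(8, 8, 8)), diag(4), "ct")
  expect_equal(voxel_to_world(vol, c(3, 4, 5)), c(3, 4, 5))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  vol2 <- volume3d(array(0, c(12, 12, 12)), aff, "ct")
  expect_equal(voxel_to_world(vol2, c(5, 5, 5)), c(0, 0, 0))
  expect_equal(world_to_voxel(vol, c(3, 4, 5)), c(3, 4, 5))

  set.seed(42)
  for (i in 1:10) {
    A <- diag(4)
    repeat {
      A[1:3, 1:3] <- matrix(rnorm(9), 3)
      if (abs(det(A[1:3, 1:3])) > 0.1) break
    }
    A[1:3, 4] <- rnorm(3, 0, 20)
    v <- volume3d(array(0, c(4, 4, 4)), A, "ct")
    x <- matrix(rnorm(30, 0, 10), 10, 3)
    expect_lt(max(abs(world_to_voxel(v, voxel_to_world(v, x)) - x)), 1e-9)
  }
})

test_that("resample: identity, integer translation against roll oracle, labels", {
  set.seed(5)
  vol <- volume3d(array(rnorm(16^3), c(16, 16, 16)), diag(4), "ct")
  idm <- identity_transform("ct")
  expect_equal(resample(vol, vol, idm)$data, vol$data, tolerance = 1e-12)

  # pure +2 voxel translation along x with nearest interpolation: the
  # interior must equal the rolled array
  shift <- diag(4); shift[1, 4] <- 2
  mp <- affine_transform(shift, "ct", "ct")
  out <- resample(vol, vol, mp, interp = "nearest")
  rolled <- vol$data
  rolled[3:16, , ] <- vol$data[1:14, , ]
  expect_equal(out$data[3:16, , ], rolled[3:16, , ])

  lab <- volume3d(array(sample(c(0L, 3L, 7L), 16^3, TRUE), c(16, 16, 16)),
                  diag(4), "ct", kind = "label")
  halfvox <- diag(4); halfvox[1:3, 4] <- 0.5
  outl <- resample(lab, lab, affine_transform(halfvox, "ct", "ct"),
                   interp = "linear")   # forced to nearest for labels
  expect_true(all(outl$data %in% c(0L, 3L, 7L)))

  mr <- volume3d(vol$data, diag(4), "mr_subject")
  expect_error(resample(vol, mr, idm), class = "ielec_frame_error")
})

test_that("compose/invert obey group laws and frame checks", {
  set.seed(9)
  mk <- function(src, tgt) {
    A <- diag(4); A[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    A[1:3, 4] <- rnorm(3, 0, 5)
    affine_transform(A, src, tgt)
  }
  a <- mk("ct", "mr_subject")
  expect_lt(max(abs(compose(a, invert(a))$matrix - diag(4))), 1e-12)
  b <- mk("mr_subject", "mr_template")
  c_ <- mk("mr_template", "mr_template")
  lhs <- compose(compose(c_, b), a)
  rhs <- compose(c_, compose(b, a))
  expect_lt(max(abs(lhs$matrix - rhs$matrix)), 1e-9)
  x <- c(3, -2, 7)
  expect_equal(apply_affine(compose(b, a), x),
               apply_affine(b, apply_affine(a, x)), tolerance = 1e-9)
  expect_error(compose(a, b), class = "ielec_frame_error")

  f <- tempfile(fileext = ".json")
  write_transform(a, f)
  a2 <- read_transform(f)
  expect_equal(a2$matrix, a$matrix, tolerance = 1e-12)
  expect_identical(a2$source, "ct")
})
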