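test_that("find_local_peak finds the brightest voxel and breaks ties by distance", {
  # single bright voxel 2 mm from the seed
  v <- array(10, c(20, 20, 20))
  v[13, 11, 11] <- 500
  ct <- volume3d(v, diag(4), "ct")
  expect_equal(find_local_peak(ct, c(10, 10, 10), radius = 5), c(12L, 10L, 10L))

  # two equal maxima at 1 mm and 3 mm: the closer one wins
  v2 <- array(10, c(20, 20, 20))
  v2[12, 11, 11] <- 500
  v2[14, 11, 11] <- 500
  ct2 <- volume3d(v2, diag(4), "ct")
  expect_equal(find_local_peak(ct2, c(10, 10, 10), radius = 5),
               c(11L, 10L, 10L))

  # phantom blob with offset seed, validated by a brute-force ball scan
  ct3 <- blob_volume(c(11.3, 10.6, 12.2))
  seed <- c(11.3, 10.6, 12.2) + c(2, -1.5, 1.5)
  pk <- find_local_peak(ct3, seed, radius = 5)
  g <- as.matrix(expand.grid(0:23, 0:23, 0:23))
  inball <- rownorms(sweep(g, 2, seed)) <= 5
  cand <- g[inball, ]
  best <- cand[which.max(ct3$data[cand + 1]), ]
  expect_equal(pk, as.integer(best))

  expect_error(find_local_peak(ct3, c(100, 0, 0)), class = "ielec_bounds_error")
  expect_error(find_local_peak(ct3, c(10, 10, 10), radius = -1),
               class = "ielec_bounds_error")
})

test_that("snap_to_center recovers a Gaussian blob center and is idempotent", {
  ctr <- c(11.35, 10.62, 12.21)
  ct <- blob_volume(ctr, sigma = 1.5)
  set.seed(17)
  centers <- t(replicate(8, {
    seed <- ctr + runif_ball(1, 4)[1, ]
    snap_to_center(ct, seed)$center
  }))
  expect_lt(max(rownorms(sweep(centers, 2, ctr))), 0.2)
  # all basin seeds agree with each other to 0.1 mm
  expect_lt(max(dist(centers)), 0.1)

  s1 <- snap_to_center(ct, ctr + c(1.5, -1, 0.5))
  s2 <- snap_to_center(ct, s1$center)
  expect_lt(sqrt(sum((s1$center - s2$center)^2)), 0.05)
  expect_gte(s1$region_voxels, 1)
  expect_lte(s1$moved_mm, 5 + 5)
})

test_that("the region radius cap keeps two nearby blobs separate", {
  a <- c(8.2, 12.1, 12.3)
  b <- a + c(8, 0, 0)
  ct <- blob_volume(a, sigma = 1.5,
                    extra = list(center = b, sigma = 1.5, amplitude = 1000))
  s <- snap_to_center(ct, a + c(2, 1, -1), max_region_radius = 5)
  expect_lt(sqrt(sum((s$center - a)^2)), 0.3)
  # region must exclude blob B's peak voxel
  pkb <- find_local_peak(ct, b, radius = 2)
  expect_gt(sqrt(sum((s$center - b)^2)), 5)
})

test_that("an all-equal ball degenerates to the full admissible region", {
  v <- array(100, c(15, 15, 15))
  ct <- volume3d(v, diag(4), "ct")
  s <- snap_to_center(ct, c(7, 7, 7), radius = 3, max_region_radius = 3)
  g <- as.matrix(expand.grid(0:14, 0:14, 0:14))
  n_ball <- sum(rownorms(sweep(g, 2, c(7, 7, 7))) <= 3 + 1e-9)
  expect_equal(s$region_voxels, n_ball)
  expect_equal(s$center, c(7, 7, 7), tolerance = 1e-9)
})

test_that("BFS and fixed-point region growth agree on random phantoms", {
  set.seed(123)
  for (k in 1:20) {
    shape <- c(18L, 18L, 18L)
    nblob <- sample(1:3, 1)
    v <- array(rnorm(prod(shape), 50, 15), shape)
    g <- as.matrix(expand.grid(0:17, 0:17, 0:17))
    for (bcen in replicate(nblob, runif(3, 5, 12), simplify = FALSE))
      v <- v + array(900 * exp(-rowSums(sweep(g, 2, bcen)^2) / (2 * 1.2^2)),
                     shape)
    ct <- volume3d(v, diag(4), "ct")
    seed <- runif(3, 6, 11)
    peak <- find_local_peak(ct, seed, radius = 4)
    cand <- ielec:::region_candidates(ct, peak, 0.25, 5)
    r1 <- sort(ielec:::region_grow_fixedpoint(cand, peak))
    r2 <- sort(ielec:::region_grow_bfs(cand, peak))
    expect_identical(r1, r2)
  }
})

test_that("montage marking enforces the predetermined name list", {
  m <- montage(c(paste0("LPM", 1:9), "GR1"))
  m2 <- mark_contact(m, "LPM1", c(1, 2, 3))
  expect_identical(m2$contacts$status[1], "located")
  expect_equal(montage_positions(m2)["LPM1", ], c(x = 1, y = 2, z = 3),
               ignore_attr = TRUE)
  err <- tryCatch(mark_contact(m, "LPM99", c(0, 0, 0)), error = identity)
  expect_s3_class(err, "ielec_name_error")
  expect_match(conditionMessage(err), "LPM9")
  # re-marking keeps the located count constant
  m3 <- suppressMessages(mark_contact(m2, "LPM1", c(9, 9, 9)))
  expect_identical(sum(m3$contacts$status == "located"),
                   sum(m2$contacts$status == "located"))
  expect_equal(unname(montage_positions(m3)["LPM1", ]), c(9, 9, 9))
  # located count is monotone under marking
  m4 <- mark_contact(m3, "GR1", c(0, 1, 2))
  expect_gte(sum(m4$contacts$status == "located"),
             sum(m3$contacts$status == "located"))
  expect_error(montage(c("A", "A")), class = "ielec_name_error")
})

test_that("electrodes.tsv round-trips names, order, status and coordinates", {
  m <- montage(c("A1", "A2", "B1", "B2"),
               rbind(c(1.2345, -2.5, 3), c(NA, NA, NA),
                     c(10, 20, 30), c(NA, NA, NA)))
  f <- tempfile(fileext = ".tsv")
  write_electrodes_tsv(m, f)
  back <- read_electrodes_tsv(f)
  expect_identical(back$contacts$name, m$contacts$name)
  expect_identical(back$contacts$status, m$contacts$status)
  expect_lt(max(abs(montage_positions(back) - montage_positions(m))), 1e-3)

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty", "A\t1\t2"), f2)
  err <- tryCatch(read_electrodes_tsv(f2), error = identity)
  expect_s3_class(err, "ielec_format_error")
  expect_match(conditionMessage(err), "z")
})
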