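test_that("color LUTs parse, reserve id 0, and reject duplicates", {
  f <- tempfile()
  writeLines(c("# a comment", "",
               "10  Thalamus     0 118  14 0",
               "17  Hippocampus 220 216  20 0"), f)
  lut <- read_lut(f)
  expect_identical(lut$id, c(0L, 10L, 17L))
  expect_identical(lut$name[lut$id == 0], "Unknown")

  writeLines("# only comments here", f)
  lut2 <- read_lut(f)
  expect_identical(lut2$id, 0L)

  writeLines(c("17 A 0 0 0 0", "5 B 0 0 0 0", "17 C 1 1 1 0"), f)
  err <- tryCatch(read_lut(f), error = identity)
  expect_s3_class(err, "ielec_format_error")
  expect_match(conditionMessage(err), "1 and 3")
})

test_that("labels_at_positions: uniform block, flat boundary, outside", {
  ids <- array(17L, c(12, 12, 12))
  ids[7:12, , ] <- 2L    # flat boundary between x index 5 and 6
  seg <- volume3d(ids, diag(4), "mr_subject", kind = "label")
  lut <- read_lut({f <- tempfile()
    writeLines(c("17 Hippocampus 0 0 0 0", "2 White 0 0 0 0"), f); f})

  r <- labels_at_positions(seg, lut, c(2, 6, 6), radius = 2)[[1]]
  expect_identical(r$label, "Hippocampus")
  expect_equal(r$fraction, 1)

  # centered on the boundary plane x = 5.5: ~50/50 split, verified against
  # an exhaustive ball count
  b <- labels_at_positions(seg, lut, c(5.5, 6, 6), radius = 2)[[1]]
  g <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  inball <- rownorms(sweep(g, 2, c(5.5, 6, 6))) <= 2
  frac17 <- mean(seg$data[g[inball, ] + 1] == 17L)
  expect_equal(sum(b$fraction), 1, tolerance = 1e-9)
  expect_equal(b$fraction[b$id == 17], frac17, tolerance = 1e-12)
  expect_lt(abs(b$fraction[b$id == 17] - 0.5), 0.2)

  out <- labels_at_positions(seg, lut, c(100, 0, 0), radius = 2)[[1]]
  expect_identical(out$label, "Unknown")
  expect_equal(out$fraction, 1)

  # radius 0 is the nearest-voxel label, matching the small-radius limit
  r0 <- labels_at_positions(seg, lut, c(2.2, 6.1, 5.9), radius = 0)[[1]]
  reps <- labels_at_positions(seg, lut, c(2.2, 6.1, 5.9), radius = 0.4)[[1]]
  expect_identical(r0$label, "Hippocampus")
  expect_identical(r0$label, reps$label[1])

  expect_error(labels_at_positions(blob_volume(c(5, 5, 5)), lut, c(1, 1, 1)),
               class = "ielec_kind_error")
})

test_that("shaft label sequences run deep to superficial with ties broken by id", {
  ph <- default_phantom()
  seqr <- shaft_label_sequence(ph$seg, ph$lut, ph$montage_truth, "LPM")
  expect_identical(seqr$number, 1:10)
  truth <- ph$truth_labels$label[match(seqr$name, ph$truth_labels$name)]
  expect_identical(seqr$label, truth)

  m1 <- mark_contact(montage("X1"), "X1", c(31.5, 31.5, 31.5))
  s1 <- shaft_label_sequence(ph$seg, ph$lut, m1, "X")
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$label, "Thalamus")

  mbad <- mark_contact(mark_contact(montage(c("XA", "X1")), "XA", c(1, 1, 1)),
                       "X1", c(2, 2, 2))
  expect_error(shaft_label_sequence(ph$seg, ph$lut, mbad, "X"),
               class = "ielec_name_error")
  # gaps in numbering are allowed with a notice
  mgap <- mark_contact(mark_contact(montage(c("Y1", "Y3")), "Y1", c(31, 31, 31)),
                       "Y3", c(33, 31, 31))
  expect_message(shaft_label_sequence(ph$seg, ph$lut, mgap, "Y"), "gaps")
})

test_that("fraction lists are normalized and deterministically ordered", {
  ph <- default_phantom()
  pos <- montage_positions(ph$montage_truth)
  labs <- labels_at_positions(ph$seg, ph$lut, pos, radius = 2)
  for (d in labs) {
    expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
    expect_true(all(d$fraction > 0))
    expect_true(all(diff(d$fraction) <= 1e-12))
    ties <- which(diff(d$fraction) == 0)
    if (length(ties)) expect_true(all(d$id[ties] < d$id[ties + 1]))
  }
})
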