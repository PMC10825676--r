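test_that("internode lengths are calibrated midpoint distances", {
  # vertical pair: (500,100) -> (500,600) at 10 px/cm = 50 cm
  set <- make_annotation_set(rbind(c(500, 100), c(500, 600)), cal = 10)
  res <- internode_lengths(set)
  expect_equal(res$length_cm, 50)
  expect_identical(res$internode_index, 1L)

  # slanted stalk: 3-4-5 triangle, (100,100) -> (400,500) at 5 px/cm
  set2 <- make_annotation_set(rbind(c(100, 100), c(400, 500)), cal = 5)
  expect_equal(internode_lengths(set2)$length_cm, 100)
})

test_that("fewer than two nodes is an error", {
  set <- make_annotation_set(rbind(c(500, 100)))
  expect_error(internode_lengths(set), "fewer than 2")
})

test_that("annotation order never matters and collinear lengths telescope", {
  mids <- cbind(500, c(100, 260, 430, 620, 800))
  set <- make_annotation_set(mids)
  res <- internode_lengths(set)
  for (i in 1:5) {
    perm <- make_annotation_set(mids[sample(5), , drop = FALSE])
    expect_equal(internode_lengths(perm)$length_cm, res$length_cm)
  }
  expect_equal(sum(res$length_cm), (800 - 100) / 10)
})

test_that("lengths are invariant under uniform image rescaling", {
  mids <- rbind(c(300, 120), c(340, 400), c(360, 700))
  r1 <- internode_lengths(make_annotation_set(mids, img = c(1000, 1000),
                                              cal = 10))
  r2 <- internode_lengths(make_annotation_set(mids * 2, img = c(2000, 2000),
                                              cal = 20))
  expect_equal(r2$length_cm, r1$length_cm)
})

test_that("overlapping duplicate boxes are collapsed with a warning", {
  set <- make_annotation_set(rbind(c(500, 100), c(502, 103), c(500, 600)),
                             box_px = 80)
  expect_warning(res <- internode_lengths(set), "duplicate")
  expect_identical(nrow(res), 1L)
  expect_equal(res$length_cm, 50, tolerance = 0.01)
})

test_that("grid calibration handles isotropy, anisotropy and bad input", {
  expect_equal(calibration_from_grid(c(100, 100), c(1000, 1000)), 10)
  expect_warning(s <- calibration_from_grid(c(100, 80), c(1000, 840)),
                 "anisotropic")
  expect_equal(s, mean(c(10, 10.5)))
  expect_error(calibration_from_grid(c(0, 100), c(1000, 1000)), "positive")
  # recovers the generator's programmed scale from a synthetic image
  gt <- stalk_ground_truth()
  set <- simulate_annotation_set(gt, scale_px_per_cm = 12, seed = 2)
  expect_equal(calibration_from_grid(c(50, 40), c(50, 40) * 12), 12)
  expect_equal(set$calibration_px_per_cm, 12)
})

test_that("synthetic annotation sets recover programmed internode lengths", {
  gt <- stalk_ground_truth()
  for (s in 1:5) {
    set <- simulate_annotation_set(gt, scale_px_per_cm = 10, seed = s,
                                   jitter_px = 2)
    truth <- attr(set, "truth")
    res <- internode_lengths(set)
    expect_identical(nrow(res), length(truth$internode_lengths_cm))
    bound <- 4 * truth$jitter_px / set$calibration_px_per_cm
    expect_true(all(abs(res$length_cm - truth$internode_lengths_cm) <= bound))
  }
})

test_that("filename association parses StalkIDs and skips junk", {
  dir <- withr::local_tempdir()
  gt1 <- stalk_ground_truth(stalk_id = "ID2021_101-1")
  gt2 <- stalk_ground_truth(stalk_id = "ID2021_101-2")
  dims <- data.frame(filename = character(), width_px = integer(),
                     height_px = integer())
  for (gt in list(gt1, gt2)) {
    set <- simulate_annotation_set(gt, seed = 3)
    ann <- set$annotations
    utils::write.table(
      cbind(0L, ann[c("x_center", "y_center", "width", "height")]),
      file.path(dir, paste0(gt$stalk_id, ".txt")),
      row.names = FALSE, col.names = FALSE)
    dims <- rbind(dims, data.frame(filename = gt$stalk_id,
                                   width_px = set$image_width_px,
                                   height_px = set$image_height_px))
  }
  writeLines("0 0.5 0.5 0.1 0.1", file.path(dir, "not_an_id.txt"))
  expect_warning(sets <- associate_filenames(dir, dims, 10), "not a valid")
  expect_identical(sort(names(sets)), c("ID2021_101-1", "ID2021_101-2"))

  tab <- suppressWarnings(process_annotation_dir(dir, dims, 10))
  expect_identical(unique(tab$stalk_id), c("ID2021_101-1", "ID2021_101-2"))
  expect_identical(nrow(tab),
                   2L * (length(gt1$node_positions_cm) - 1L))
})
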