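test_that("blank tests are flagged by peak force with a strict threshold", {
  x <- seq(-35, 5, by = 0.0254)
  zero <- force_displacement_trace(
    data.frame(time_s = seq_along(x) * 1e-3, displacement_mm = x,
               force_N = rep(0, length(x))),
    metadata = list(test_kind = "puncture", zero_plane_mm = 0))
  expect_true(detect_blank_test(zero))

  gt <- stalk_ground_truth()
  expect_false(detect_blank_test(simulate_puncture_test(gt, seed = 1)))
  expect_true(detect_blank_test(simulate_puncture_test(gt, seed = 1,
                                                       blank = TRUE)))

  at_threshold <- zero
  at_threshold$samples$force_N[500] <- 1
  expect_false(detect_blank_test(at_threshold))  # strict inequality
})

test_that("keypoints sit on the exact corners of a step-walled toy trace", {
  toy <- make_toy_puncture()
  kp <- detect_keypoints(toy)
  expect_equal(kp$A, 10)
  expect_equal(kp$C, 26)
  expect_equal(kp$D, 28)
  expect_true(kp$B > 12 && kp$B < 26)
})

test_that("keypoints recover programmed wall positions on synthetic traces", {
  gt <- stalk_ground_truth(diameter_true_mm = 18, rind_thickness_true_mm = 2)
  spacing <- 25.4 / 1000
  for (s in 1:10) {
    tr <- simulate_puncture_test(gt, seed = s)
    kp <- detect_keypoints(tr)
    truth <- attr(tr, "truth")
    expect_lt(abs(kp$A - truth$A), 0.1)
    expect_lt(abs(kp$C - truth$C), 0.1)
    expect_equal(kp$D, truth$D)
  }
  # noiseless: within 2 sample spacings
  gt0 <- stalk_ground_truth(noise_frac = 0)
  kp0 <- detect_keypoints(simulate_puncture_test(gt0, seed = 3))
  expect_lt(abs(kp0$A + gt0$diameter_true_mm), 2 * spacing)
  expect_lt(abs(kp0$C + gt0$rind_thickness_true_mm), 2 * spacing)
})

test_that("a missing distal wall raises a reengagement error", {
  x <- seq(-35, 5, by = 0.0254)
  f <- numeric(length(x))
  f[x >= -20 & x < -18] <- 60  # proximal wall only, nothing after
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(x) * 1e-3, displacement_mm = x, force_N = f),
    metadata = list(test_kind = "puncture", zero_plane_mm = 0))
  expect_error(detect_keypoints(tr), "reengagement")
})

test_that("traces that never load raise a no-contact error", {
  x <- seq(-35, 5, by = 0.0254)
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(x) * 1e-3, displacement_mm = x,
               force_N = rep(0.01, length(x))),
    metadata = list(test_kind = "puncture", zero_plane_mm = 0))
  expect_error(detect_keypoints(tr), "no contact")
})

test_that("phenotypes are exact functions of the keypoints", {
  toy <- make_toy_puncture()  # A = 10, C = 26, D = 28
  res <- puncture_phenotypes(toy)
  expect_equal(res$minor_diameter_mm, 18)
  expect_equal(res$rind_thickness_mm, 2)
  expect_equal(res$rind_penetration_resistance_N, 60)
  expect_identical(res$minor_diameter_mm, res$keypoints$D - res$keypoints$A)
  expect_identical(res$rind_thickness_mm, res$keypoints$D - res$keypoints$C)
  expect_false(res$is_blank)
})

test_that("a constant-force span integrates to the rectangle area", {
  d <- seq(-2, 12, by = 0.01)
  f <- ifelse(d >= 0 & d <= 10, 5, 0)
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d) * 1e-3, displacement_mm = d, force_N = f),
    metadata = list(test_kind = "puncture"))
  kp <- structure(list(A = 0, B = 5, C = 9, D = 10,
                       A_idx = which(d == 0), B_idx = which(d == 5),
                       C_idx = which(d == 9), D_idx = which(d == 10)),
                  class = "puncture_keypoints")
  expect_equal(integrated_puncture_score(tr, kp), 50)
  # weighting hook scales the integrand pointwise
  expect_equal(integrated_puncture_score(tr, kp, weight = function(u) 2), 100)
  expect_equal(integrated_puncture_score(tr, kp, weight = function(u) u),
               25, tolerance = 1e-3)
})

test_that("IPS is stable under doubling the sampling rate", {
  gt <- stalk_ground_truth(noise_frac = 0)
  r1 <- puncture_phenotypes(simulate_puncture_test(gt, seed = 5))
  r2 <- puncture_phenotypes(simulate_puncture_test(gt, seed = 5,
                                                   sample_rate_hz = 2000))
  expect_lt(rel_err(r2$integrated_puncture_score_Nmm,
                    r1$integrated_puncture_score_Nmm), 0.005)
})

test_that("RPR is invariant under monotone time reparameterization", {
  gt <- stalk_ground_truth()
  tr <- simulate_puncture_test(gt, seed = 8)
  r1 <- puncture_phenotypes(tr)
  tr$samples$time_s <- exp(tr$samples$time_s / 2)
  r2 <- puncture_phenotypes(tr)
  expect_identical(r2$rind_penetration_resistance_N,
                   r1$rind_penetration_resistance_N)
})

test_that("blank traces yield NA phenotypes but stay in the table", {
  gt <- stalk_ground_truth()
  res <- puncture_phenotypes(simulate_puncture_test(gt, seed = 2, blank = TRUE))
  expect_true(res$is_blank)
  expect_true(is.na(res$minor_diameter_mm))

  tmp <- withr::local_tempdir()
  paths <- vapply(1:3, function(k) {
    p <- file.path(tmp, sprintf("p%d.csv", k))
    write_instron_csv(simulate_puncture_test(gt, seed = k,
                                             internode_index = k,
                                             blank = k == 2), p)
    p
  }, character(1))
  tab <- process_puncture_files(paths)
  expect_identical(tab$internode_index, c(1, 2, 3))
  expect_identical(tab$is_blank, c(FALSE, TRUE, FALSE))
  expect_true(is.na(tab$minor_diameter_mm[2]))
  expect_false(anyNA(tab$minor_diameter_mm[c(1, 3)]))
})

test_that("instron files reject missing columns and non-monotone puncture displacement", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("test_kind,puncture", "", "time_s,force_N", "0,1", "1,2"), p)
  expect_error(read_instron_csv(p), "missing column")

  writeLines(c("test_kind,puncture", "", "time_s,displacement_mm,force_N",
               "0,0,1", "1,2,2", "2,1,3"), p)
  expect_error(read_instron_csv(p), "monotone")
})
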