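test_that("deflection follows h*sin(theta) and its small-angle limit", {
  expect_equal(deflection_from_rotation(0, 1), 0)
  expect_equal(deflection_from_rotation(90, 0.8), 0.8)
  expect_equal(deflection_from_rotation(7, 0.75), 0.75 * sin(7 * pi / 180))
  # small-angle limit: delta / (h * theta_rad) -> 1, within 0.5% at <= 5 deg
  for (th in c(0.5, 1, 2, 5)) {
    ratio <- deflection_from_rotation(th, 0.6) / (0.6 * th * pi / 180)
    expect_lt(abs(ratio - 1), 0.005)
  }
  expect_error(deflection_from_rotation(10, -1), "positive")
  expect_message(deflection_from_rotation(95, 1), "outside")
})

test_that("structured DARLING files parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_darling(path)
  tr <- read_darling_csv(path)
  expect_s3_class(tr, "force_rotation_trace")
  expect_identical(nrow(tr$samples), 5L)
  expect_equal(tr$header$load_height_m, 0.6)
  expect_identical(tr$header$stalk_id, "ID2021_101-3")

  write_tiny_darling(path, drop_key = "load_height_m")
  expect_error(read_darling_csv(path), "load_height_m")

  # write -> read -> write reproduces the body byte for byte
  gt <- stalk_ground_truth()
  tr1 <- simulate_darling_test(gt, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_darling_csv(tr1, p1)
  tr2 <- read_darling_csv(p1)
  write_darling_csv(tr2, p2)
  l1 <- readLines(p1)
  l2 <- readLines(p2)
  body_at <- which(!nzchar(l1))[1]
  expect_identical(l1[body_at:length(l1)], l2[body_at:length(l2)])
  expect_equal(tr2$samples, tr1$samples, tolerance = 1e-9)
  expect_equal(tr2$header$calibration, tr1$header$calibration)
})

test_that("unknown header keys are preserved as opaque metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stalk_id,ID2021_101-3", "load_height_m,0.5",
               "field_note,lodged near gate", "",
               "time_s,force_N,rotation_deg", "0,1,180", "1,2,179"), path)
  tr <- read_darling_csv(path)
  expect_identical(tr$header$extra$field_note, "lodged near gate")
})

test_that("the four-push protocol is segmented into preloads and a failure push", {
  gt <- stalk_ground_truth(noise_frac = 0)
  tr <- simulate_darling_test(gt, seed = 2)
  seg <- segment_pushes(tr)
  expect_identical(nrow(seg), 4L)
  expect_identical(seg$kind, c(rep("preload_cycle", 3), "failure_push"))
  expect_true(all(seg$peak_rotation[1:3] >= 5 & seg$peak_rotation[1:3] <= 10))

  # boundaries sit exactly at the hysteresis onset of the clean angle signal
  theta <- attr(tr, "truth")$theta_deg
  for (k in seq_len(nrow(seg))) {
    bounds <- attr(tr, "truth")$push_bounds[k, ]
    in_push <- bounds$start:bounds$end
    expect_identical(seg$start[k], in_push[which(theta[in_push] >= 2)[1]])
  }
})

test_that("protocol violations warn and flat traces are fatal", {
  gt <- stalk_ground_truth(noise_frac = 0)
  tr2 <- simulate_darling_test(gt, seed = 5, n_preload = 1L)
  expect_warning(seg <- segment_pushes(tr2), "protocol violation")
  expect_identical(seg$kind, c("preload_cycle", "failure_push"))

  flat <- make_fr_trace(rep(0, 100), rep(0, 100))
  expect_error(segment_pushes(flat), "no push")
})

test_that("segmentation is invariant to uniform time rescaling", {
  gt <- stalk_ground_truth(noise_frac = 0)
  tr <- simulate_darling_test(gt, seed = 9)
  seg1 <- segment_pushes(tr)
  tr$samples$time_s <- tr$samples$time_s * 7.5
  expect_identical(segment_pushes(tr), seg1)
})

test_that("bending strength is the peak moment of the failure push", {
  # direct product on a hand-built ramp: F_max = 20 N at h = 0.6 m
  theta <- c(seq(0, 20, length.out = 50), seq(20, 22, length.out = 10))
  force <- c(seq(0, 20, length.out = 50), seq(20, 2, length.out = 10))
  tr <- suppressWarnings(make_fr_trace(theta, force, h = 0.6))
  seg <- suppressWarnings(segment_pushes(tr))
  expect_equal(bending_strength(tr, seg), 12)

  # appending lower-force post-failure samples never changes the result
  theta2 <- c(theta, seq(22, 25, length.out = 20))
  force2 <- c(force, rep(1.5, 20))
  tr2 <- make_fr_trace(theta2, force2, h = 0.6)
  seg2 <- suppressWarnings(segment_pushes(tr2))
  expect_equal(bending_strength(tr2, seg2), 12)

  # programmed failure: 31.4 N at h = 0.5 m -> 15.7 N m
  gt <- stalk_ground_truth(strength_true_Nm = 15.7, noise_frac = 0)
  tr3 <- simulate_darling_test(gt, h = 0.5, seed = 4)
  expect_equal(bending_strength(tr3), 15.7, tolerance = 1e-9)
})

test_that("flexural stiffness inverts the cantilever relation", {
  expect_equal(cantilever_stiffness(100, 1), 100 / 3)

  gt <- stalk_ground_truth(EI_true_Nm2 = 25, noise_frac = 0)
  tr <- simulate_darling_test(gt, h = 0.7, seed = 6)
  st <- flexural_stiffness(tr)
  expect_lt(rel_err(st$EI, 25), 1e-3)
  expect_identical(nrow(st$per_cycle), 3L)
  expect_equal(st$EI, mean(st$per_cycle$EI))
  expect_gt(st$r_squared, 0.999)
})

test_that("noiseless EI recovery holds across the stiffness and height range", {
  for (EI in c(1, 50, 500)) {
    for (h in c(0.3, 0.75, 1.2)) {
      gt <- stalk_ground_truth(EI_true_Nm2 = EI,
                               strength_true_Nm = min(0.4 * 3 * EI / h, 25),
                               noise_frac = 0)
      tr <- simulate_darling_test(gt, h = h, seed = 7)
      expect_lt(rel_err(flexural_stiffness(tr)$EI, EI), 1e-3)
    }
  }
})

test_that("degenerate preload fits are reported as errors", {
  # 3-sample cycles cannot support a slope fit
  theta <- c(0, 3, 0, 0, seq(0, 20, length.out = 30))
  force <- c(0, 5, 0, 0, seq(0, 30, length.out = 30))
  tr <- make_fr_trace(theta, force)
  seg <- suppressWarnings(segment_pushes(tr))
  expect_error(flexural_stiffness(tr, seg), "degenerate fit")
})

test_that("analyze_darling assembles the full per-stalk result", {
  gt <- stalk_ground_truth(noise_frac = 0, failure_mode = "root_lodged")
  res <- analyze_darling(simulate_darling_test(gt, seed = 3))
  expect_s3_class(res, "darling_result")
  expect_identical(res$failure_note, "root_lodged")
  expect_identical(res$n_pushes, 4L)
  expect_lt(rel_err(res$flexural_stiffness_Nm2, gt$EI_true_Nm2), 1e-3)
  expect_lt(rel_err(res$bending_strength_Nm, gt$strength_true_Nm), 1e-3)
})
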