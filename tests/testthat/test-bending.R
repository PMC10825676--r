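test_that("the moment profile matches the non-symmetric beam formulas", {
  sym <- span_geometry(a = 200, b = 200)
  expect_equal(moment_profile(100, sym, 200), 100 * 400 / 4)  # FL/4
  expect_equal(moment_profile(100, sym, 0), 0)
  expect_equal(moment_profile(100, sym, 400), 0)

  g <- span_geometry(a = 150, b = 250)
  expect_equal(moment_profile(60, g, 150), 60 * 250 * 150 / 400)
  expect_error(moment_profile(60, g, 401), "outside")

  # both branch formulas agree at the load point for randomized geometry
  set.seed(42)
  for (i in 1:50) {
    L <- runif(1, 200, 800)
    a <- runif(1, 0.2 * L, 0.8 * L)
    F <- runif(1, 10, 300)
    g <- span_geometry(a = a, L = L)
    left <- F * g$b * a / L
    right <- F * a * (L - a) / L
    expect_equal(moment_profile(F, g, a), left)
    expect_equal(left, right)
  }
})

test_that("structural bending strength is F_max a b / L with span checks", {
  d <- seq(0, 20, by = 0.1667)
  f <- c(seq(0, 200, length.out = 100), seq(200, 50, length.out = 21))
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d[1:121]) * 0.1, displacement_mm = d[1:121],
               force_N = f),
    metadata = list(test_kind = "bending3pt"))
  g <- span_geometry(a = 250, b = 250)
  expect_equal(structural_bending_strength(tr, g), 25000)
  expect_warning(structural_bending_strength(tr, g, diameter_mm = 60),
                 "short span")

  zero <- tr
  zero$samples$force_N <- rep(0, nrow(zero$samples))
  expect_warning(m <- structural_bending_strength(zero, g), "invalid test")
  expect_equal(m, 0)
})

test_that("symmetric three-point stiffness reduces to phi L^3 / 48", {
  g <- span_geometry(a = 250, b = 250)
  expect_equal(bend3pt_stiffness(50, g), 50 * 500^3 / 48)

  # linear-elastic trace with slope 50 N/mm
  d <- seq(0, 5.5, by = 0.1667)
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d) * 0.1, displacement_mm = d,
               force_N = 50 * d),
    metadata = list(test_kind = "bending3pt"))
  st <- structural_flexural_stiffness(tr, g)
  expect_equal(st$EI, 50 * 500^3 / 48, tolerance = 1e-9)
  expect_equal(st$r_squared, 1)
})

test_that("noiseless stiffness and strength recovery across random geometries", {
  set.seed(7)
  for (i in 1:10) {
    L <- runif(1, 400, 700)
    a <- runif(1, 0.2 * L, 0.8 * L)
    g <- span_geometry(a = a, L = L)
    gt <- stalk_ground_truth(EI_true_Nm2 = runif(1, 10, 40),
                             strength_true_Nm = runif(1, 8, 25),
                             noise_frac = 0)
    tr <- simulate_bending_test(gt, g, seed = i)
    res <- analyze_bending3pt(tr, g)
    truth <- attr(tr, "truth")
    expect_lt(rel_err(res$flexural_stiffness_Nmm2, truth$EI_Nmm2), 0.01)
    expect_lt(rel_err(res$bending_strength_Nmm, truth$strength_Nmm), 0.01)
  }
})

test_that("near-support loading and short fit windows are flagged", {
  expect_warning(span_geometry(a = 10, b = 490), "degenerate geometry")
  d <- seq(0, 0.3, by = 0.1667)
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d) * 0.1, displacement_mm = d,
               force_N = 50 * d),
    metadata = list(test_kind = "bending3pt"))
  expect_error(structural_flexural_stiffness(tr, span_geometry(a = 250, b = 250)),
               "degenerate fit")
})

test_that("a mid-test force drop flags the specimen as roll-suspect", {
  d <- seq(0, 15, by = 0.1667)
  n <- length(d)
  f <- 20 * d
  drop <- d > 5 & d < 7
  f[drop] <- f[drop] * 0.5  # 50% collapse well before peak
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d) * 0.1, displacement_mm = d, force_N = f),
    metadata = list(test_kind = "bending3pt"))
  res <- analyze_bending3pt(tr, span_geometry(a = 250, b = 250))
  expect_true(res$discard_recommended)
})

test_that("flexural stress and strain follow the strip formulas", {
  strip <- rind_strip_geometry()  # 2.8 x 0.7 mm, span 10 mm
  expect_equal(flexural_stress(10, strip), 3 * 10 * 10 / (2 * 2.8 * 0.7^2))
  expect_equal(flexural_stress(0, strip), 0)
  expect_equal(flexural_strain(0.1, strip), 6 * 0.1 * 0.7 / 100)
  # vectorised over the trace
  expect_equal(flexural_stress(c(0, 5, 10), strip),
               c(0, 0.5, 1) * flexural_stress(10, strip))
})

test_that("stress/strain = E pointwise on a noiseless linear-elastic strip", {
  gt <- stalk_ground_truth(E_tissue_true_MPa = 5000, noise_frac = 0)
  tr <- simulate_micro_bending_test(gt, seed = 1)
  res <- tissue_flexural_curve(tr)
  curve <- res$stress_strain_curve
  lin <- curve$strain > 1e-4 & curve$stress_MPa > 0.1 * max(curve$stress_MPa) &
    seq_len(nrow(curve)) <= which.max(curve$stress_MPa)
  expect_lt(max(abs(curve$stress_MPa[lin] / curve$strain[lin] / 5000 - 1)), 1e-6)
  expect_lt(rel_err(res$youngs_modulus_MPa, 5000), 0.01)
  expect_identical(res$n_preload_cycles, 3L)
  expect_equal(res$strain_at_failure, 0.025, tolerance = 1e-6)
})

test_that("monotone micro-bending traces warn about missing preload cycles", {
  strip <- rind_strip_geometry()
  d <- seq(0, 0.6, by = 0.002)
  tr <- force_displacement_trace(
    data.frame(time_s = seq_along(d) * 0.1, displacement_mm = d,
               force_N = 20 * d),
    metadata = list(test_kind = "micro_bending"))
  expect_warning(res <- tissue_flexural_curve(tr, strip), "preload")
  expect_lt(rel_err(res$youngs_modulus_MPa,
                    20 * strip$span_mm^3 / (48 * strip$width_mm *
                                              strip$thickness_mm^3 / 12)), 1e-6)
})
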