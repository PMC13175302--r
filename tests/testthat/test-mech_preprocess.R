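test_that("stretch and nominal stress follow the kinematic definitions", {
  expect_equal(compute_stretch(-0.45, 3), 0.85)
  expect_equal(compute_stretch(0, 3), 1)
  expect_error(compute_stretch(-3, 3), class = "nq_validation_error")
  expect_error(compute_stretch(-0.1, 0), class = "nq_validation_error")

  expect_equal(compute_nominal_stress(-0.01, pi * 4.5^2), -0.01 / (pi * 4.5^2 * 1e-6))
  expect_equal(compute_nominal_stress(-0.01, 63.617), -157.19, tolerance = 1e-4)
  expect_equal(compute_nominal_stress(0, 10), 0)
  expect_error(compute_nominal_stress(-0.01, 0), class = "nq_validation_error")
  # linearity: doubling force doubles stress exactly
  f <- c(-0.003, -0.011, 0.002)
  expect_identical(compute_nominal_stress(2 * f, 5), 2 * compute_nominal_stress(f, 5))
})

test_that("a triangular 3-cycle recording segments into 6 tagged phase curves", {
  sim <- generate_cyclic_recording(1000, 2, hysteresis = 0.1, seed = 1)
  phases <- segment_cycles(sim$recording, cycles = 3)
  expect_length(phases, 6)
  expect_equal(vapply(phases, function(p) attr(p, "phase"), ""),
               rep(c("loading", "unloading"), 3))
  expect_equal(vapply(phases, function(p) attr(p, "cycle"), 1L),
               rep(1:3, each = 2))
  # loading spans full 15% compression
  expect_equal(range(phases[[1]]$lambda), c(0.85, 1))
})

test_that("incomplete or absent cycles are rejected with a cycle-count error", {
  ramp <- compression_recording(time = 0:49, displacement = seq(0, -0.45, length.out = 50),
                                force = seq(0, -0.01, length.out = 50),
                                height_mm = 3, area_mm2 = 63.617)
  expect_error(segment_cycles(ramp, cycles = 3), class = "nq_cycle_error")
  flat <- compression_recording(time = 0:9, displacement = rep(0, 10),
                                force = rep(0, 10), height_mm = 3, area_mm2 = 63.617)
  expect_error(segment_cycles(flat, cycles = 3), class = "nq_cycle_error")
})

test_that("turning points survive 1% displacement noise within 2 samples", {
  sim <- generate_cyclic_recording(1000, 2, hysteresis = 0.1, seed = 5)
  rec <- sim$recording
  set.seed(11)
  noisy <- compression_recording(
    rec$time,
    rec$displacement + 0.01 * max(abs(rec$displacement)) * rnorm(nrow(rec)),
    rec$force, attr(rec, "height_mm"), attr(rec, "area_mm2"))
  phases <- segment_cycles(noisy, cycles = 3)
  found <- attr(phases, "turning_points")
  truth <- sort(c(sim$truth$tops, sim$truth$troughs))
  matched <- vapply(truth, function(t) min(abs(found - t)), numeric(1))
  expect_true(all(matched <= 2))
})

test_that("segmented phases reassemble into the original stress-stretch sequence", {
  sim <- generate_cyclic_recording(600, -10, hysteresis = 0.08, noise_sd = 0.02, seed = 9)
  rec <- sim$recording
  phases <- segment_cycles(rec, cycles = 3)
  # drop shared junction samples when concatenating
  seq_l <- unlist(lapply(seq_along(phases), function(i) {
    v <- phases[[i]]$lambda
    if (i > 1) v[-1] else v
  }))
  lambda_full <- compute_stretch(rec$displacement, attr(rec, "height_mm"))
  expect_equal(seq_l, lambda_full)
})

test_that("averaging is idempotent, symmetric, and cancels symmetric hysteresis", {
  base <- make_ogden_curve(1000, 2, n = 80, phase = "loading", cycle = 1)
  up <- hyperelastic_curve(base$lambda, base$stress, cycle = 1, phase = "loading")
  down <- hyperelastic_curve(rev(base$lambda), rev(base$stress), cycle = 1,
                             phase = "unloading")
  avg <- average_load_unload(up, down, grid_size = 80)
  expect_equal(avg$stress, base$stress, tolerance = 1e-12)
  expect_equal(attr(avg, "label"), "unconditioned")

  # scaled pair averages back to baseline; argument order is irrelevant
  up2 <- hyperelastic_curve(base$lambda, 1.1 * base$stress, cycle = 1, phase = "loading")
  down2 <- hyperelastic_curve(rev(base$lambda), rev(0.9 * base$stress),
                              cycle = 1, phase = "unloading")
  a1 <- average_load_unload(up2, down2, grid_size = 80)
  a2 <- average_load_unload(down2, up2, grid_size = 80)
  expect_equal(a1$stress, base$stress, tolerance = 1e-9)
  expect_identical(a1$stress, a2$stress)
})

test_that("generator hysteresis pair averages to the Ogden baseline at grid nodes", {
  sim <- generate_cyclic_recording(1000, 2, hysteresis = 0.1, noise_sd = 0, seed = 2)
  pp <- preprocess_recording(sim$recording, cycles = 3, grid_size = 100)
  baseline <- ogden_stress(pp$unconditioned$lambda, ogden_parameters(1000, 2))
  expect_lt(max(abs(pp$unconditioned$stress - baseline)), 1e-9)
})

test_that("disjoint stretch ranges are rejected when averaging", {
  a <- hyperelastic_curve(seq(0.85, 0.9, length.out = 10), rep(-1, 10),
                          cycle = 1, phase = "loading")
  b <- hyperelastic_curve(seq(0.95, 1, length.out = 10), rep(-1, 10),
                          cycle = 1, phase = "unloading")
  expect_error(average_load_unload(a, b), class = "nq_validation_error")
})

test_that("first-cycle maximum nominal stress is the loading-curve magnitude", {
  lam <- seq(0.85, 1, length.out = 60)
  curve <- hyperelastic_curve(rev(lam), ogden_stress(rev(lam), ogden_parameters(1000, 2)),
                              cycle = 1, phase = "loading")
  expect_equal(max_nominal_stress(curve), abs(1000 * (0.85 - 0.85^-2)),
               tolerance = 1e-12)
  zero <- hyperelastic_curve(rev(lam), rep(0, 60), cycle = 1, phase = "loading")
  expect_equal(max_nominal_stress(zero), 0)
  wrong <- hyperelastic_curve(lam, rep(0, 60), cycle = 1, phase = "unloading")
  expect_error(max_nominal_stress(wrong), class = "nq_validation_error")
})
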