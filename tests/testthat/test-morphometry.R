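straight_filament <- function(radius = 0.5) {
  filament_model(tibble::tibble(id = 1:2, type = 3L, x = c(0, 10), y = 0, z = 0,
                                radius = radius, parent = c(-1L, 1L)))
}

test_that("surface distance matches closed-form perpendicular and endpoint cases", {
  fil <- straight_filament()
  # perpendicular: 3.0 from the axis minus radius 0.5
  expect_equal(distance_to_filament_surface(tibble::tibble(x = 5, y = 0, z = 3), fil), 2.5)
  # point on the skeleton clamps to zero
  expect_equal(distance_to_filament_surface(tibble::tibble(x = 5, y = 0, z = 0), fil), 0)
  # beyond the endpoint: 2.0 to the cap centre minus radius
  expect_equal(distance_to_filament_surface(tibble::tibble(x = -2, y = 0, z = 0), fil), 1.5)
})

test_that("the inclusion rule is inclusive at the threshold", {
  fil <- straight_filament()
  at <- puncta_set(tibble::tibble(x = 5, y = 0, z = 3.0))     # exactly 2.5
  past <- puncta_set(tibble::tibble(x = 5, y = 0, z = 3.01))  # 2.51
  expect_equal(count_puncta_near_filament(at, fil, 2.5), 1)
  expect_equal(count_puncta_near_filament(past, fil, 2.5), 0)
})

test_that("counting equals the brute-force per-segment oracle on seeded scenes", {
  for (s in 1:20) {
    scene <- generate_scene(n_nodes = 6, n_inside = 15, n_outside = 35, seed = s)
    fast <- count_puncta_near_filament(scene$puncta, scene$filament, 2.5)
    brute <- brute_count_near(scene$puncta, scene$filament, 2.5)
    expect_identical(as.integer(fast), as.integer(brute))
    expect_identical(as.integer(fast), scene$truth$n_inside)
  }
})

test_that("distances are invariant under rigid transforms to 1e-9 um", {
  scene <- generate_scene(n_nodes = 6, n_inside = 20, n_outside = 20, seed = 3)
  d0 <- distance_to_filament_surface(scene$puncta, scene$filament)
  R <- rotation_matrix(c(1, 2, 0.5), 0.83)
  shift <- c(12, -7, 30)
  nodes <- tibble::as_tibble(scene$filament)
  rn <- apply_rigid(nodes[, c("x", "y", "z")], R, shift)
  fil2 <- filament_model(dplyr::mutate(nodes, x = rn[, 1], y = rn[, 2], z = rn[, 3]))
  rp <- apply_rigid(scene$puncta[, c("x", "y", "z")], R, shift)
  p2 <- puncta_set(tibble::tibble(x = rp[, 1], y = rp[, 2], z = rp[, 3]))
  d1 <- distance_to_filament_surface(p2, fil2)
  expect_lt(max(abs(d1 - d0)), 1e-9)
})

test_that("counts are non-decreasing in the threshold", {
  scene <- generate_scene(seed = 8)
  counts <- vapply(c(0.5, 1, 2, 2.5, 3, 5),
                   function(th) count_puncta_near_filament(scene$puncta, scene$filament, th),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("density normalizations follow the 100-unit conventions", {
  # cylinder: radius 0.5, length 10 -> volume pi * 0.25 * 10
  fil <- straight_filament()
  expect_equal(filament_volume(fil), pi * 0.25 * 10, tolerance = 1e-12)
  d <- synapse_density(12, fil)
  expect_equal(d$density_per_100um3, 12 / (pi * 2.5) * 100)
  expect_equal(d$density_per_100um, 12 / 10 * 100)
  expect_equal(synapse_density(0, fil)$density_per_100um3, 0)

  # arithmetic fixture: 12 puncta in 400 um^3 -> 3.0 per 100 um^3
  expect_equal(12 / 400 * 100, 3.0)
})

test_that("frustum volume handles tapered segments", {
  fil <- filament_model(tibble::tibble(id = 1:2, type = 3L, x = c(0, 6), y = 0, z = 0,
                                       radius = c(1, 0.5), parent = c(-1L, 1L)))
  expect_equal(filament_volume(fil), pi / 3 * 6 * (1 + 0.5 + 0.25))
})

test_that("neurite mean length averages per-filament totals", {
  two_seg <- filament_model(tibble::tibble(
    id = 1:3, type = 3L, x = c(0, 3, 3), y = c(0, 4, 4), z = c(0, 0, 12),
    radius = 0.5, parent = c(-1L, 1L, 2L)))
  expect_equal(filament_total_length(two_seg), 17)  # 5 + 12
  expect_equal(neurite_mean_length(list(two_seg)), 17)
  scaled <- function(f) {
    filament_model(dplyr::mutate(tibble::as_tibble(two_seg), x = x * f, y = y * f, z = z * f))
  }
  expect_equal(neurite_mean_length(list(scaled(100 / 17), scaled(200 / 17), scaled(300 / 17))),
               200, tolerance = 1e-9)
  expect_error(neurite_mean_length(list()), class = "nq_validation_error")
})

test_that("viability percentages follow live/(live+dead)", {
  expect_equal(viability_percent(60, 40)$percent_viable, 60)
  expect_equal(viability_percent(0, 10)$percent_viable, 0)
  expect_equal(viability_percent(67, 33)$percent_viable, 67)
  expect_error(viability_percent(0, 0), class = "nq_validation_error")
})

test_that("density recovery on shell-uniform scenes is within 10%", {
  # puncta placed uniformly inside the 2.5 um shell at known density
  scene <- generate_scene(n_nodes = 10, n_inside = 250, n_outside = 0,
                          box = c(80, 80, 40), seed = 21)
  n_in <- count_puncta_near_filament(scene$puncta, scene$filament, 2.5)
  d_est <- synapse_density(n_in, scene$filament)$density_per_100um3
  d_true <- scene$truth$n_inside / filament_volume(scene$filament) * 100
  expect_lt(abs(d_est - d_true) / d_true, 0.10)
})
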