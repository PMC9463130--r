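test_that("height field renders the spherical cap on the pixel grid", {
  scene <- test_scene(97L)  # odd size: a pixel sits at the exact centre
  flat <- render_height_field(cap_from_height(3.5, 0), scene)
  expect_true(all(flat == 0))

  cap <- cap_from_height(3.5, 2.2)
  z <- render_height_field(cap, scene)
  expect_equal(z[49, 49], 2.2, tolerance = 1e-9)  # apex at the centre pixel
  # radial symmetry under reflection through the centre
  expect_equal(z, z[97:1, 97:1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(z >= 0))

  tiny <- scene_params(image_size_px = c(32L, 32L), mm_per_px = 0.05)
  expect_error(render_height_field(cap, tiny), "field of view")
})

test_that("Lambertian shading matches closed forms on flat fields", {
  n <- 64L
  flat <- matrix(0, n, n)
  vert <- scene_params(image_size_px = c(n, n),
                       light_direction = c(0, 0, 1))
  expect_equal(lambertian_render(flat, vert), matrix(1, n, n))
  oblique <- scene_params(image_size_px = c(n, n),
                          light_direction = c(sin(pi / 4), 0, cos(pi / 4)))
  expect_equal(lambertian_render(flat, oblique),
               matrix(cos(pi / 4), n, n), tolerance = 1e-12)
})

test_that("shading of a cap varies monotonically along the light azimuth", {
  # light in the x-z plane: along the centre row, intensity increases from
  # the away-facing rising side towards the descending side that faces the
  # light, up to the singular point where the normal meets the light; the
  # whole profile matches the analytic normals of the sphere
  zen <- 0.6
  scene <- test_scene(97L, light_direction = c(sin(zen), 0, cos(zen)))
  cap <- cap_from_height(3.5, 1.5)
  z <- render_height_field(cap, scene)
  img <- lambertian_render(z, scene)
  mid <- img[49, ]
  L <- scene$light_direction
  cols <- which(ring_mask(scene)[49, ])
  cols <- cols[3:(length(cols) - 2)]       # skip one-sided rim gradients
  x <- (cols - 49) * scene$mm_per_px
  slope <- -x / sqrt(cap$R^2 - x^2)
  expected <- (L[3] - slope * L[1]) / sqrt(1 + slope^2)
  expect_equal(mid[cols], expected, tolerance = 0.02, ignore_attr = TRUE)
  # monotone up to (a margin before) the singular point where the surface
  # normal meets the light, at slope = -tan(zenith)
  before_singular <- cols[slope > -tan(zen) + 0.1]
  expect_true(all(diff(mid[before_singular]) > -1e-9))
})

test_that("simulated recordings honour the frame-count and ground-truth contracts", {
  cycle <- cycle_params(n_cycles = 4L)
  scene <- test_scene(64L, noise_sd = 0.01)
  rec <- simulate_recording(cycle, scene, seed = 7)
  n_expected <- round(cycle$n_cycles * cycle$period_s * scene$fps)
  expect_length(rec$video$frames, n_expected)
  gt <- rec$ground_truth
  expect_length(gt$apex_height_trace, n_expected)
  expect_equal(gt$true_period_s, cycle$period_s)
  expect_equal(gt$true_contraction_s + gt$true_relaxation_s, gt$true_period_s)
  # stretch trace is percent_stretch of the height trace, frame by frame
  expect_equal(gt$true_stretch_trace,
               vapply(gt$apex_height_trace, function(h)
                 percent_stretch(cap_from_height(scene$ring_radius_mm, h)),
                 numeric(1)),
               tolerance = 1e-9)
  expect_equal(max(gt$apex_height_trace),
               pressure_to_height(80, default_calibration()),
               tolerance = max(gt$apex_height_trace) * 0.01)
  expect_true(all(vapply(rec$video$frames,
                         function(f) all(f >= 0 & f <= 1), logical(1))))
})

test_that("recordings are reproducible and noise-free runs ignore the seed", {
  cycle <- cycle_params(n_cycles = 3L)
  scene <- test_scene(48L, noise_sd = 0.02)
  a <- simulate_recording(cycle, scene, seed = 3)
  b <- simulate_recording(cycle, scene, seed = 3)
  expect_identical(a$video$frames, b$video$frames)
  c1 <- simulate_recording(cycle, test_scene(48L, noise_sd = 0), seed = 1)
  c2 <- simulate_recording(cycle, test_scene(48L, noise_sd = 0), seed = 99)
  expect_identical(c1$video$frames, c2$video$frames)
})

test_that("simulated traces align with the pressure cycle and are seeded", {
  cycle <- cycle_params(n_cycles = 12L)
  clean <- simulate_trace(cycle, noise_sd = 0, duration_s = 10)
  # maxima of the clean trace coincide with waveform pressure maxima
  peaks <- detect_peaks_valleys(clean$trace)
  t_peaks <- clean$trace$t_s[peaks$peak_indices]
  Td <- cycle$period_s * (1 - cycle$systole_fraction)
  offsets <- (t_peaks - Td) %% cycle$period_s
  offsets <- pmin(offsets, cycle$period_s - offsets)
  expect_true(all(offsets <= 1 / clean$trace$fps + 1e-9))

  drifted <- simulate_trace(cycle, noise_sd = 0,
                            drift_coeffs = c(0, 1, -2, 0.5, 0, 0, 3),
                            duration_s = 10)
  expect_identical(drifted$ground_truth$apex_height_trace,
                   clean$ground_truth$apex_height_trace)
  expect_false(identical(drifted$trace$value, clean$trace$value))

  s1 <- simulate_trace(cycle, noise_sd = 0.1, duration_s = 10, seed = 5)
  s2 <- simulate_trace(cycle, noise_sd = 0.1, duration_s = 10, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(s1$trace, p1)
  write_trace_csv(s2$trace, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  expect_error(simulate_trace(cycle, duration_s = 2), "three cycles")
})

test_that("stimulated/unstimulated pairs differ only by peak deflection", {
  cycle <- cycle_params(n_cycles = 3L)
  scene <- test_scene(48L, noise_sd = 0.01)
  same <- simulate_stim_pair(cycle, scene, 20, 20, seed = 2)
  expect_identical(same$stim$video$frames, same$unstim$video$frames)

  pair <- simulate_stim_pair(cycle, scene, 25, 20.833, seed = 2)
  expect_equal(pair$stretch_ratio, 25 / 20.833)
  expect_equal(max(pair$stim$ground_truth$true_stretch_trace), 25,
               tolerance = 0.01)
  expect_equal(max(pair$unstim$ground_truth$true_stretch_trace), 20.833,
               tolerance = 0.01)

  static <- simulate_stim_pair(cycle, test_scene(48L, noise_sd = 0), 25, 0,
                               seed = 2)
  frames <- static$unstim$video$frames
  expect_true(all(vapply(frames, function(f)
    max(abs(f - frames[[1]])), numeric(1)) < 1e-6))

  expect_error(simulate_stim_pair(cycle, scene, 20, 25, seed = 1), ">=")
})
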