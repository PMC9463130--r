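test_that("movement trace is the masked mean absolute difference", {
  f1 <- matrix(0.5, 4, 4)
  f2 <- f1; f2[1, 1] <- 0.6; f2[1, 2] <- 0.4; f2[2, 1] <- 0.8; f2[2, 2] <- 0.2
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  video <- structure(list(frames = list(f1, f2), fps = 30, mm_per_px = 0.1),
                     class = "ctcm_video")
  tr <- movement_trace(video, mask)
  expect_equal(tr$value, c(0, mean(c(0.1, 0.1, 0.3, 0.3))))

  same <- structure(list(frames = list(f1, f1, f1), fps = 30,
                         mm_per_px = 0.1), class = "ctcm_video")
  expect_equal(movement_trace(same, mask)$value, rep(0, 3))

  expect_error(movement_trace(video, matrix(FALSE, 4, 4)), "foreground")
  expect_error(movement_trace(video, matrix(TRUE, 3, 3)), "shape")
})

test_that("movement trace is invariant to a constant added to all frames", {
  scene <- test_scene(48L, noise_sd = 0)
  rec <- simulate_recording(cycle_params(n_cycles = 3L), scene, seed = 1)
  mask <- ring_mask(scene)
  base <- movement_trace(rec$video, mask)
  shifted <- rec$video
  shifted$frames <- lapply(shifted$frames, function(f) f + 0.05)
  expect_equal(movement_trace(shifted, mask)$value, base$value,
               tolerance = 1e-12)
})

test_that("trace of a noiseless recording beats at the pacing frequency", {
  scene <- test_scene(48L, noise_sd = 0)
  cycle <- cycle_params(n_cycles = 12L)  # 10 s
  rec <- simulate_recording(cycle, scene, seed = 1)
  tr <- movement_trace(rec$video, ring_mask(scene))
  v <- tr$value - mean(tr$value)
  spec <- Mod(fft(v))[seq_len(length(v) / 2)]
  freqs <- (seq_along(spec) - 1) * tr$fps / length(v)
  dominant <- freqs[which.max(spec[-1]) + 1]
  expect_equal(dominant, 1.2, tolerance = 1 / (length(v) / tr$fps) / 1.2)
})

test_that("zero-phase filter halves power at the cutoff and keeps constants", {
  const <- motion_trace(rep(2.5, 300), fps = 30)
  expect_equal(zero_phase_lowpass(const, 5)$value, rep(2.5, 300),
               tolerance = 1e-9)

  fps <- 100; cutoff <- 5
  tr <- sine_trace(cutoff, fps, 60)
  filt <- zero_phase_lowpass(tr, cutoff)
  mid <- 1000:5000  # away from the ends
  amp <- (max(filt$value[mid]) - min(filt$value[mid])) / 2
  expect_equal(amp, 0.5, tolerance = 0.01)

  expect_error(zero_phase_lowpass(tr, 60), "cutoff")
})

test_that("zero-phase filtering leaves peak positions in place", {
  tr <- sine_trace(1.2, 30, 10)
  before <- detect_peaks_valleys(tr)$peak_indices
  after <- detect_peaks_valleys(zero_phase_lowpass(tr, 5))$peak_indices
  expect_length(after, length(before))
  expect_true(all(abs(after - before) <= 1))
})

test_that("polynomial detrending removes drift without touching the oscillation", {
  fps <- 30; t <- seq(0, 10 - 1 / fps, by = 1 / fps)
  poly6 <- 2 + 0.5 * t - 0.3 * t^2 + 0.02 * t^3 - 1e-3 * t^4 +
    2e-5 * t^5 - 1e-7 * t^6
  res <- detrend_polynomial(motion_trace(poly6, fps = fps))
  expect_lt(max(abs(res$value)), 1e-9 * diff(range(poly6)))

  zero <- detrend_polynomial(motion_trace(rep(0, 300), fps = fps))
  expect_equal(zero$value, rep(0, 300))

  sig <- sin(2 * pi * 1.2 * t)
  drift <- 0.8 * t - 0.05 * t^3
  det <- detrend_polynomial(motion_trace(sig + drift, fps = fps))
  # least-squares oracle: detrending is linear and annihilates the cubic,
  # so the result must equal the detrended drift-free signal
  det_clean <- detrend_polynomial(motion_trace(sig, fps = fps))
  expect_equal(det$value, det_clean$value, tolerance = 1e-9)
  expect_equal(diff(range(det$value)), diff(range(det_clean$value)),
               tolerance = 0.01)
  expect_lt(abs(mean(det$value)), 1e-10)

  expect_error(detrend_polynomial(motion_trace(1:5, fps = 30), order = 6),
               "short")
})

test_that("peak detection finds all cycles of clean and noisy sinusoids", {
  tr <- sine_trace(1, 50, 10)  # 10 full cycles, peaks and valleys interior
  pk <- detect_peaks_valleys(tr)
  expect_length(pk$peak_indices, 10)
  expect_length(pk$valley_indices, 10)
  merged <- sort(c(pk$peak_indices, pk$valley_indices))
  types <- ifelse(merged %in% pk$peak_indices, 1, -1)
  expect_true(all(diff(types) != 0))  # strict alternation

  noisy <- tr
  noisy$value <- tr$value + with_seed_test(42, rnorm(length(tr$value), 0, 0.05))
  pk2 <- detect_peaks_valleys(noisy)
  expect_length(pk2$peak_indices, 10)
  expect_length(pk2$valley_indices, 10)

  flat <- detect_peaks_valleys(motion_trace(rep(1, 100), fps = 30))
  expect_length(flat$peak_indices, 0)
  expect_length(flat$valley_indices, 0)
})

test_that("cycle metrics recover the timing of symmetric and device-driven traces", {
  tr <- sine_trace(1.2, 60, 10)
  res <- analyze_trace(tr, cutoff_hz = 10)
  m <- res$metrics
  expect_equal(m$cycle_time_s, 1 / 1.2, tolerance = 1 / 60 / (1 / 1.2))
  expect_equal(m$contraction_time_s, 1 / 2.4, tolerance = 2 / 60 / (1 / 2.4))
  expect_equal(m$relaxation_time_s, 1 / 2.4, tolerance = 2 / 60 / (1 / 2.4))
  expect_equal(m$movement_amplitude_au, 2, tolerance = 0.05)

  # peak speeds of A sin(2 pi f t) are 2 pi f A
  fps <- 100
  sin_tr <- sine_trace(1.2, fps, 10, amplitude = 3)
  pk <- detect_peaks_valleys(sin_tr)
  m2 <- compute_cycle_metrics(sin_tr, pk)
  expect_equal(m2$peak_contraction_speed_au_per_s, 2 * pi * 1.2 * 3,
               tolerance = 0.02 * 2 * pi * 1.2 * 3)
  expect_equal(m2$peak_relaxation_speed_au_per_s, 2 * pi * 1.2 * 3,
               tolerance = 0.02 * 2 * pi * 1.2 * 3)

  # device waveform: 40% systole = contraction, 60% diastole = relaxation
  st <- simulate_trace(cycle_params(n_cycles = 12L), noise_sd = 0,
                       duration_s = 10)
  m3 <- analyze_trace(st$trace)$metrics
  expect_equal(m3$contraction_time_s, 1 / 1.2 * 0.4, tolerance = (1 / 30) / (1 / 3))
  expect_equal(m3$relaxation_time_s, 1 / 1.2 * 0.6, tolerance = (1 / 30) / 0.5)
  expect_equal(m3$contraction_time_s + m3$relaxation_time_s, m3$cycle_time_s,
               tolerance = (1 / 30) / m3$cycle_time_s)

  expect_error(compute_cycle_metrics(tr, detect_peaks_valleys(
    motion_trace(rep(0, 100), fps = 30))), "insufficient")
})

test_that("end-to-end timing recovery tolerates noise and polynomial drift", {
  cycle <- cycle_params(n_cycles = 24L)
  base <- simulate_trace(cycle, noise_sd = 0, duration_s = 20)
  m0 <- analyze_trace(base$trace)$metrics
  # mean recovery error over independent noise realisations stays within
  # one frame period for each timing metric
  errs <- t(vapply(1:5, function(seed) {
    noisy <- simulate_trace(cycle, noise_sd = 0.1,
                            drift_coeffs = c(0, 1.5, -3, 2, 0.5, -1, 0.7),
                            duration_s = 20, seed = seed)
    m1 <- analyze_trace(noisy$trace)$metrics
    gt <- noisy$ground_truth
    c(m1$cycle_time_s - gt$true_period_s,
      m1$contraction_time_s - gt$true_contraction_s,
      m1$relaxation_time_s - gt$true_relaxation_s)
  }, numeric(3)))
  frame <- 1 / base$trace$fps
  expect_lt(abs(mean(errs[, 1])), frame)
  expect_lt(abs(mean(errs[, 2])), frame)
  expect_lt(abs(mean(errs[, 3])), frame)
  # drift alone changes no metric by more than 2%
  drifted <- simulate_trace(cycle, noise_sd = 0,
                            drift_coeffs = c(0, 1.5, -3, 2, 0.5, -1, 0.7),
                            duration_s = 20)
  m2 <- analyze_trace(drifted$trace)$metrics
  for (fld in c("cycle_time_s", "contraction_time_s", "relaxation_time_s",
                "movement_amplitude_au", "peak_contraction_speed_au_per_s",
                "peak_relaxation_speed_au_per_s")) {
    expect_lt(abs(m2[[fld]] - m0[[fld]]) / abs(m0[[fld]]), 0.02)
  }
})
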