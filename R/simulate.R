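#' Simulate a synthetic recording of a beating ring-mounted slice
#'
#' Renders a complete grayscale video of a membrane-mounted tissue slice
#' distending under the device pressure cycle, with full ground truth. Per
#' frame: the air-chamber pressure is evaluated at the frame time, mapped to
#' a membrane apex height through the calibration, the spherical-cap height
#' field is rendered with Lambertian shading over the textured albedo,
#' optional slow illumination drift is added, then seeded Gaussian sensor
#' noise, and intensities are clipped to [0, 1]. Identical `(parameters,
#' seed)` give bit-identical frame stacks.
#'
#' @param cycle A [cycle_params()] object; the recording spans
#'   `n_cycles * period_s` seconds.
#' @param scene A [scene_params()] object.
#' @param cal A [calibration_map()]; default [default_calibration()].
#' @param seed Integer seed for the sensor noise.
#' @param keep_height_fields If `TRUE`, store per-frame true height fields
#'   in the ground truth (memory-heavy; default `FALSE`).
#' @return A list with elements
#'   \describe{
#'     \item{video}{class `ctcm_video`: `frames` (list of matrices in
#'       [0, 1]), `fps`, `mm_per_px`.}
#'     \item{ground_truth}{class `ctcm_ground_truth`: `apex_height_trace`
#'       (mm/frame), `true_stretch_trace` (percent/frame), `true_period_s`,
#'       `true_contraction_s`, `true_relaxation_s`, `stimulus_frames`
#'       (1-based frame indices), and optionally `height_fields`.}
#'   }
#' @export
simulate_recording <- function(cycle, scene, cal = default_calibration(),
                               seed = 1L, keep_height_fields = FALSE) {
  validate_cycle_params(cycle)
  stopifnot(inherits(scene, "ctcm_scene"))
  duration_s <- cycle$n_cycles * cycle$period_s
  n_frames <- round(duration_s * scene$fps)
  t <- (seq_len(n_frames) - 1) / scene$fps
  p <- pressure_at(t, cycle)
  h <- pressure_to_height(p, cal)
  a <- scene$ring_radius_mm

  albedo <- make_albedo(scene)
  drift <- polyval_drift(scene$drift_coeffs, t / max(duration_s, 1e-12))
  npx <- prod(scene$image_size_px)

  frames <- vector("list", n_frames)
  fields <- if (keep_height_fields) vector("list", n_frames) else NULL
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      z <- render_height_field(cap_from_height(a, h[k]), scene)
      frame <- lambertian_render(z, scene, albedo) + drift[k]
      if (scene$noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(npx, sd = scene$noise_sd),
                                nrow(frame), ncol(frame))
      frame <- apply_camera_tilt(frame, scene)
      frames[[k]] <- pmin(pmax(frame, 0), 1)
      if (keep_height_fields) fields[[k]] <- z
    }
  })

  sched <- schedule_stimulation(generate_pressure_waveform(cycle), cycle)
  gt <- structure(list(
    apex_height_trace = h,
    true_stretch_trace = stretch_from_height(a, h),
    true_period_s = cycle$period_s,
    true_contraction_s = cycle$period_s * cycle$systole_fraction,
    true_relaxation_s = cycle$period_s * (1 - cycle$systole_fraction),
    stimulus_frames = unique(pmin(n_frames,
                                  round(sched$onset_times_s * scene$fps) + 1L)),
    height_fields = fields
  ), class = "ctcm_ground_truth")

  list(video = structure(list(frames = frames, fps = scene$fps,
                              mm_per_px = scene$mm_per_px),
                         class = "ctcm_video"),
       ground_truth = gt)
}

#' @export
print.ctcm_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Synthetic video: %d frames of %dx%d px at %g fps (%.2f s)\n",
              length(x$frames), d[1], d[2], x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Simulate a 1-D movement trace with ground truth
#'
#' Fast fixture that bypasses video rendering: the movement signal is taken
#' proportional to the membrane apex height (in arbitrary units), with an
#' optional polynomial baseline drift and seeded additive Gaussian noise
#' whose standard deviation is expressed as a fraction of the clean signal's
#' peak-to-peak amplitude.
#'
#' @param cycle A [cycle_params()] object.
#' @param noise_sd Noise standard deviation as a fraction of the clean
#'   peak-to-peak amplitude.
#' @param drift_coeffs Polynomial drift coefficients (intercept first, in
#'   normalised time `t / duration_s`), arbitrary units.
#' @param duration_s Trace duration in seconds; must cover at least three
#'   cycles.
#' @param seed Integer noise seed.
#' @param fps Sampling rate in Hz (default 30, the camera frame rate).
#' @param cal A [calibration_map()].
#' @return A list with `trace` (a [motion_trace()], stage `"raw"`) and
#'   `ground_truth` (as in [simulate_recording()], plus
#'   `true_amplitude_au`, the clean peak-to-peak amplitude).
#' @export
simulate_trace <- function(cycle, noise_sd = 0, drift_coeffs = numeric(0),
                           duration_s, seed = 1L, fps = 30,
                           cal = default_calibration()) {
  validate_cycle_params(cycle)
  if (duration_s < 3 * cycle$period_s)
    stop("`duration_s` must cover at least three cycles", call. = FALSE)
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  clean <- pressure_to_height(pressure_at(t, cycle), cal)
  amp <- diff(range(clean))
  value <- clean + polyval_drift(drift_coeffs, t / duration_s)
  if (noise_sd > 0)
    value <- value + with_seed(seed, stats::rnorm(n, sd = noise_sd * amp))
  gt <- structure(list(
    apex_height_trace = clean,
    true_stretch_trace = stretch_from_height(3.5, clean),
    true_period_s = cycle$period_s,
    true_contraction_s = cycle$period_s * cycle$systole_fraction,
    true_relaxation_s = cycle$period_s * (1 - cycle$systole_fraction),
    true_amplitude_au = amp
  ), class = "ctcm_ground_truth")
  list(trace = motion_trace(value, fps = fps, stage = "raw"),
       ground_truth = gt)
}

#' Simulate a stimulated / unstimulated recording pair
#'
#' Emulates filming the same slice with and without electrical stimulation:
#' two recordings share the scene, albedo texture, and noise seed and differ
#' only in peak membrane deflection, set through the target peak stretches.
#' Per-clip calibrations map the pressure cycle linearly onto apex height so
#' the peak stretch of each clip is exactly its target.
#'
#' @param cycle A [cycle_params()] object.
#' @param scene A [scene_params()] object.
#' @param stim_stretch_pct Peak percent stretch with stimulation.
#' @param unstim_stretch_pct Peak percent stretch without stimulation;
#'   must not exceed `stim_stretch_pct`.
#' @param seed Shared noise seed.
#' @return A list with `stim`, `unstim` (each as returned by
#'   [simulate_recording()]) and `stretch_ratio`
#'   (`stim_stretch_pct / unstim_stretch_pct`, `NA` when the unstimulated
#'   stretch is 0).
#' @export
simulate_stim_pair <- function(cycle, scene, stim_stretch_pct,
                               unstim_stretch_pct, seed = 1L) {
  if (unstim_stretch_pct < 0 || stim_stretch_pct < unstim_stretch_pct)
    stop("need `stim_stretch_pct` >= `unstim_stretch_pct` >= 0", call. = FALSE)
  a <- scene$ring_radius_mm
  clip_for <- function(pct) {
    if (pct == 0) {
      # static membrane: flat calibration via a vanishing peak height
      cal <- calibration_map(c(cycle$baseline_pressure_mmHg,
                               cycle$peak_pressure_mmHg), c(0, 1e-12))
    } else {
      cal <- calibration_map(c(cycle$baseline_pressure_mmHg,
                               cycle$peak_pressure_mmHg),
                             c(0, height_for_stretch(pct, a)))
    }
    simulate_recording(cycle, scene, cal, seed = seed)
  }
  list(stim = clip_for(stim_stretch_pct),
       unstim = clip_for(unstim_stretch_pct),
       stretch_ratio = if (unstim_stretch_pct > 0)
         stim_stretch_pct / unstim_stretch_pct else NA_real_)
}
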