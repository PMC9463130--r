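#' Cardiac-cycle parameters for the tissue culture device
#'
#' Bundles every parameter of the pneumatic cardiac cycle the culture device
#' imposes on ring-mounted heart slices: cycle period, the systolic
#' (pressure-release) fraction, peak and baseline air-chamber pressures, and
#' the electrical stimulation settings. Defaults reproduce the physiological
#' operating point: 1.2 Hz (72 beats per minute), 40% systole / 60% diastole,
#' 80 mmHg peak pressure, and a 2 ms, 4 V biphasic pulse fired 100 ms before
#' systole onset. The overstretch regime is obtained by raising
#' `peak_pressure_mmHg` to 140.
#'
#' @param period_s Cycle period in seconds (default `1/1.2`, i.e. 72 bpm).
#' @param systole_fraction Fraction of the cycle spent in systole (pressure
#'   falling), strictly between 0 and 1. Default 0.40.
#' @param peak_pressure_mmHg Peak air-chamber pressure in mmHg (80 normal,
#'   140 overstretch).
#' @param baseline_pressure_mmHg Baseline (end-systolic) pressure in mmHg.
#' @param stim_lead_ms Lead of the electrical stimulus before systole onset,
#'   in milliseconds. Must be shorter than the diastolic duration.
#' @param stim_duration_ms Stimulus pulse duration in milliseconds.
#' @param stim_amplitude_V Stimulus amplitude in volts.
#' @param n_cycles Number of cycles to generate (positive integer).
#' @param sample_rate_hz Sampling rate of the generated waveform in Hz.
#'
#' @return An object of class `ctcm_cycle_params` (a validated list).
#' @examples
#' cycle_params()                         # physiological defaults
#' cycle_params(peak_pressure_mmHg = 140) # overstretch regime
#' @export
cycle_params <- function(period_s = 1 / 1.2,
                         systole_fraction = 0.40,
                         peak_pressure_mmHg = 80,
                         baseline_pressure_mmHg = 0,
                         stim_lead_ms = 100,
                         stim_duration_ms = 2,
                         stim_amplitude_V = 4,
                         n_cycles = 3L,
                         sample_rate_hz = 1000) {
  p <- list(
    period_s = as.numeric(period_s),
    systole_fraction = as.numeric(systole_fraction),
    peak_pressure_mmHg = as.numeric(peak_pressure_mmHg),
    baseline_pressure_mmHg = as.numeric(baseline_pressure_mmHg),
    stim_lead_ms = as.numeric(stim_lead_ms),
    stim_duration_ms = as.numeric(stim_duration_ms),
    stim_amplitude_V = as.numeric(stim_amplitude_V),
    n_cycles = as.integer(n_cycles),
    sample_rate_hz = as.numeric(sample_rate_hz)
  )
  validate_cycle_params(p)
  structure(p, class = "ctcm_cycle_params")
}

validate_cycle_params <- function(p) {
  stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
  stop_if(!is.finite(p$period_s) || p$period_s <= 0,
          "`period_s` must be a positive number")
  stop_if(!is.finite(p$systole_fraction) ||
            p$systole_fraction <= 0 || p$systole_fraction >= 1,
          "`systole_fraction` must lie strictly between 0 and 1")
  stop_if(p$peak_pressure_mmHg <= p$baseline_pressure_mmHg,
          "`peak_pressure_mmHg` must exceed `baseline_pressure_mmHg`")
  diastole_ms <- 1000 * p$period_s * (1 - p$systole_fraction)
  stop_if(p$stim_lead_ms < 0 || p$stim_lead_ms >= diastole_ms,
          "`stim_lead_ms` must be non-negative and shorter than the diastolic duration")
  stop_if(is.na(p$n_cycles) || p$n_cycles < 1L,
          "`n_cycles` must be a positive integer")
  stop_if(!is.finite(p$sample_rate_hz) || p$sample_rate_hz <= 0,
          "`sample_rate_hz` must be positive")
  invisible(p)
}

#' @export
print.ctcm_cycle_params <- function(x, ...) {
  cat(sprintf(
    "Cardiac-cycle parameters: %.3f s period (%.1f bpm), %d%% systole,\n",
    x$period_s, 60 / x$period_s, round(100 * x$systole_fraction)))
  cat(sprintf("  pressure %g -> %g mmHg, stimulus %g V / %g ms, lead %g ms,\n",
              x$baseline_pressure_mmHg, x$peak_pressure_mmHg,
              x$stim_amplitude_V, x$stim_duration_ms, x$stim_lead_ms))
  cat(sprintf("  %d cycle(s) sampled at %g Hz\n", x$n_cycles, x$sample_rate_hz))
  invisible(x)
}

# Closed-form air-chamber pressure at arbitrary times for one parameter set.
# Diastole: raised-cosine rise over the first (1 - systole_fraction) of the
# cycle; systole: raised-cosine fall over the remainder. C1 at the joins.
pressure_at <- function(t, params) {
  Td <- params$period_s * (1 - params$systole_fraction)
  Ts <- params$period_s * params$systole_fraction
  amp <- params$peak_pressure_mmHg - params$baseline_pressure_mmHg
  tau <- t %% params$period_s
  p <- ifelse(tau < Td,
              (1 - cos(pi * tau / Td)) / 2,
              (1 + cos(pi * (tau - Td) / Ts)) / 2)
  params$baseline_pressure_mmHg + amp * p
}
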