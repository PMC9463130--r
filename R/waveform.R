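#' Generate the device pressure waveform
#'
#' Samples the air-chamber pressure of the culture device over
#' `params$n_cycles` cardiac cycles. Each cycle is a raised-cosine rise from
#' baseline to peak over the diastolic fraction of the period followed by a
#' raised-cosine fall back to baseline over the systolic fraction, so the
#' trace is C1-continuous with exactly one pressure maximum per cycle.
#' Samples are labelled `"diastole"` while the pressure is on the rising limb
#' and `"systole"` on the falling limb.
#'
#' @param params A [cycle_params()] object.
#' @return A data frame of class `ctcm_waveform` with columns `t_s` (seconds,
#'   uniform grid starting at 0), `p_mmHg`, and `phase`
#'   (`"diastole"`/`"systole"`). The generating parameters are attached as
#'   attribute `"params"`.
#' @examples
#' wf <- generate_pressure_waveform(cycle_params())
#' max(wf$p_mmHg)  # 80 mmHg peak
#' @seealso [schedule_stimulation()]
#' @export
generate_pressure_waveform <- function(params) {
  validate_cycle_params(params)
  dt <- 1 / params$sample_rate_hz
  n <- round(params$n_cycles * params$period_s * params$sample_rate_hz)
  t <- (seq_len(n) - 1) * dt
  Td <- params$period_s * (1 - params$systole_fraction)
  tau <- t %% params$period_s
  wf <- data.frame(
    t_s = t,
    p_mmHg = pressure_at(t, params),
    phase = ifelse(tau < Td, "diastole", "systole"),
    stringsAsFactors = FALSE
  )
  attr(wf, "params") <- params
  class(wf) <- c("ctcm_waveform", "data.frame")
  wf
}

#' Schedule electrical stimulation from the pressure waveform
#'
#' Reproduces the device's synchronization logic: the data-acquisition system
#' watches the air-chamber pressure and fires the pacing stimulus when the
#' rising (diastolic) limb crosses a threshold. The threshold is the waveform
#' value at `stim_lead_ms` milliseconds before systole onset, so each stimulus
#' leads the pressure peak by the configured lead time (100 ms by default),
#' to within one sample period.
#'
#' @param waveform A `ctcm_waveform` from [generate_pressure_waveform()]
#'   containing at least one complete cycle.
#' @param params The [cycle_params()] used to generate the waveform. Defaults
#'   to the parameters attached to `waveform`.
#' @return A list of class `ctcm_stim_schedule` with elements
#'   `onset_times_s` (one strictly increasing onset per cycle),
#'   `duration_ms`, `amplitude_V`, and `threshold_mmHg`.
#' @examples
#' wf <- generate_pressure_waveform(cycle_params(n_cycles = 2))
#' schedule_stimulation(wf)
#' @export
schedule_stimulation <- function(waveform, params = attr(waveform, "params")) {
  validate_cycle_params(params)
  if (nrow(waveform) < params$period_s * params$sample_rate_hz)
    stop("waveform must contain at least one complete cycle", call. = FALSE)
  Td <- params$period_s * (1 - params$systole_fraction)
  lead_s <- params$stim_lead_ms / 1000
  threshold <- pressure_at(Td - lead_s, params)

  p <- waveform$p_mmHg
  n <- length(p)
  rising <- c(FALSE, diff(p) > 0)
  # upward threshold crossings on the rising limb
  crossed <- c(FALSE, p[-1] >= threshold & p[-n] < threshold) & rising
  if (params$stim_lead_ms == 0) {
    # threshold equals the peak: take the per-cycle maximum sample instead,
    # which the strict-crossing test misses by construction
    cycle_id <- floor(waveform$t_s / params$period_s)
    idx <- vapply(split(seq_len(n), cycle_id),
                  function(i) i[which.max(p[i])], integer(1))
    crossed <- rep(FALSE, n)
    crossed[idx] <- TRUE
  }
  onsets <- waveform$t_s[crossed]
  if (length(onsets) == 0)
    stop("stimulation threshold was never crossed on a rising limb",
         call. = FALSE)
  structure(list(
    onset_times_s = onsets,
    duration_ms = params$stim_duration_ms,
    amplitude_V = params$stim_amplitude_V,
    threshold_mmHg = threshold
  ), class = "ctcm_stim_schedule")
}

#' @export
print.ctcm_stim_schedule <- function(x, ...) {
  cat(sprintf(
    "Stimulation schedule: %d onset(s), threshold %.2f mmHg, %g V / %g ms\n",
    length(x$onset_times_s), x$threshold_mmHg, x$amplitude_V, x$duration_ms))
  invisible(x)
}

#' Write a waveform (and optional stimulus schedule) to CSV
#'
#' Columns are `time_s`, `pressure_mmHg`, `phase`, and `stimulus` (0/1; 1 for
#' samples within a stimulus pulse, all 0 when no schedule is supplied).
#'
#' @param waveform A `ctcm_waveform`.
#' @param path Output CSV path.
#' @param schedule Optional `ctcm_stim_schedule`.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path, schedule = NULL) {
  stim <- integer(nrow(waveform))
  if (!is.null(schedule)) {
    for (on in schedule$onset_times_s) {
      stim[waveform$t_s >= on &
             waveform$t_s < on + schedule$duration_ms / 1000] <- 1L
    }
  }
  out <- data.frame(time_s = waveform$t_s, pressure_mmHg = waveform$p_mmHg,
                    phase = waveform$phase, stimulus = stim)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
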