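#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its default: the `cycle`
#' section mirrors [cycle_params()], `scene` mirrors [scene_params()],
#' `trace` holds the filter/detrend/peak parameters, `strain` the
#' shape-from-shading and region parameters, `io` the file paths, and
#' `seed` the noise seed.
#'
#' @return A nested list of class `ctcm_config`.
#' @export
default_config <- function() {
  structure(list(
    cycle = list(period_s = 1 / 1.2, systole_fraction = 0.40,
                 peak_pressure_mmHg = 80, baseline_pressure_mmHg = 0,
                 stim_lead_ms = 100, stim_duration_ms = 2,
                 stim_amplitude_V = 4, n_cycles = 12L, sample_rate_hz = 1000),
    scene = list(image_size_px = c(128L, 128L), mm_per_px = NULL,
                 light_direction = c(sin(51 * pi / 180) * cos(pi / 4),
                                     sin(51 * pi / 180) * sin(pi / 4),
                                     cos(51 * pi / 180)),
                 albedo_texture_seed = 1L, texture_contrast = 0.10,
                 tissue_albedo = 0.90, background_albedo = 0.08,
                 noise_sd = 0.01, fps = 30, drift_coeffs = numeric(0),
                 camera_tilt_deg = 0, ring_radius_mm = 3.5),
    trace = list(cutoff_hz = 5, detrend_order = 6,
                 min_prominence_frac = 0.3, min_separation_s = 0.4,
                 ref_index = 1L),
    strain = list(n_regions = 10L, n_iter = 200L),
    io = list(out_dir = ".", video = NULL, video_nostim = NULL,
              mask = NULL, trace_csv = NULL),
    seed = 1L
  ), class = "ctcm_config")
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    path <- if (prefix == "") key else paste0(prefix, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: `", path, "`", call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]),
                                      path)
    } else {
      value <- if (is.list(user[[key]])) unlist(user[[key]]) else user[[key]]
      if (is.null(value) && !is.null(defaults[[key]]) &&
          is.atomic(defaults[[key]])) {
        # empty sequence in the file for an atomic field (e.g. drift_coeffs)
        value <- vector(mode(defaults[[key]]), 0)
      }
      defaults[key] <- list(value)  # keeps explicit NULLs
    }
  }
  defaults
}

config_cycle <- function(config) {
  tryCatch(do.call(cycle_params, config$cycle),
           error = function(e) stop("invalid `cycle` configuration: ",
                                    conditionMessage(e), call. = FALSE))
}

config_scene <- function(config) {
  tryCatch(do.call(scene_params, config$scene),
           error = function(e) stop("invalid `scene` configuration: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Load (and validate) a pipeline configuration file
#'
#' Reads a YAML configuration, fills unset fields with the documented
#' defaults, rejects unknown keys by name, and validates values against the
#' parameter invariants. An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return A validated `ctcm_config`.
#' @seealso [default_config()], [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  config <- merge_config(default_config(), user)
  config_cycle(config)
  config_scene(config)
  class(config) <- "ctcm_config"
  config
}

#' @rdname load_config
#' @param config A `ctcm_config` to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

log_line <- function(lines, ...) c(lines, sprintf(...))

#' Run a pipeline command
#'
#' Orchestrates the analysis stages under one configuration:
#' \describe{
#'   \item{`"simulate"`}{render a synthetic recording; writes `video.tif`
#'     (+ metadata side-car), `mask.png` (ring aperture),
#'     `ground_truth.json`, `ground_truth.csv`.}
#'   \item{`"analyze-trace"`}{movement trace from `io$video`/`io$mask` (or
#'     `io$trace_csv`), filter, detrend, peaks, metrics; writes per-stage
#'     CSVs and `metrics.json`.}
#'   \item{`"analyze-strain"`}{full strain chain on `io$video`, optionally
#'     compared against `io$video_nostim` (the unstimulated clip, analysed
#'     on the stimulated clip's mask so regions pair up); writes
#'     `strain.csv` and, for pairs, `comparison.csv`.}
#'   \item{`"report"`}{collects outputs of earlier commands in `io$out_dir`
#'     into `report.json` with a parameter echo, package version, and input
#'     checksums.}
#' }
#' Every stage parameter is echoed in `run_log.txt`; identical
#' configuration, seed and inputs reproduce identical metric values.
#'
#' @param config A `ctcm_config` (see [load_config()]).
#' @param command One of `"simulate"`, `"analyze-trace"`,
#'   `"analyze-strain"`, `"report"`.
#' @return The written results, invisibly (stage-dependent list).
#' @export
run_pipeline <- function(config, command = c("simulate", "analyze-trace",
                                             "analyze-strain", "report")) {
  command <- match.arg(command)
  out_dir <- config$io$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- sprintf("ctcm %s | version %s", command,
                   as.character(utils::packageVersion("ctcm")))
  lines <- log_line(lines, "parameters: %s",
                    jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     null = "null"))
  result <- switch(command,
    "simulate" = {
      cycle <- config_cycle(config)
      scene <- config_scene(config)
      rec <- simulate_recording(cycle, scene, seed = config$seed)
      write_video_tiff(rec$video, file.path(out_dir, "video.tif"))
      write_mask_png(ring_mask(scene), file.path(out_dir, "mask.png"))
      gt <- rec$ground_truth
      write_metrics_json(gt[c("true_period_s", "true_contraction_s",
                              "true_relaxation_s", "stimulus_frames")],
                         file.path(out_dir, "ground_truth.json"))
      utils::write.csv(
        data.frame(frame = seq_along(gt$apex_height_trace),
                   apex_height_mm = gt$apex_height_trace,
                   stretch_pct = gt$true_stretch_trace),
        file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
      lines <- log_line(lines, "wrote %d frames", length(rec$video$frames))
      rec
    },
    "analyze-trace" = {
      tp <- config$trace
      if (!is.null(config$io$trace_csv)) {
        tr <- read_trace_csv(config$io$trace_csv)
      } else {
        if (is.null(config$io$video))
          stop("`io$video` (or `io$trace_csv`) is required", call. = FALSE)
        video <- read_video_tiff(config$io$video)
        mask <- if (!is.null(config$io$mask)) read_mask_png(config$io$mask)
                else matrix(TRUE, nrow(video$frames[[1]]),
                            ncol(video$frames[[1]]))
        tr <- movement_trace(video, mask, tp$ref_index)
      }
      stages <- analyze_trace(tr, tp$cutoff_hz, tp$detrend_order,
                              tp$min_prominence_frac, tp$min_separation_s)
      write_trace_csv(tr, file.path(out_dir, "trace_raw.csv"))
      write_trace_csv(stages$filtered, file.path(out_dir, "trace_filtered.csv"))
      write_trace_csv(stages$detrended,
                      file.path(out_dir, "trace_detrended.csv"))
      write_metrics_json(stages$metrics, file.path(out_dir, "metrics.json"))
      lines <- log_line(lines, "cycle metrics over %d cycles",
                        stages$metrics$n_cycles)
      stages
    },
    "analyze-strain" = {
      if (is.null(config$io$video))
        stop("`io$video` is required", call. = FALSE)
      video <- read_video_tiff(config$io$video)
      scene <- config_scene(config)
      sp <- config$strain; tp <- config$trace
      mask <- if (!is.null(config$io$mask)) read_mask_png(config$io$mask)
              else NULL
      res <- analyze_strain(video, scene$light_direction, mask = mask,
                            n_regions = sp$n_regions, n_iter = sp$n_iter,
                            cutoff_hz = tp$cutoff_hz,
                            detrend_order = tp$detrend_order,
                            min_prominence_frac = tp$min_prominence_frac,
                            min_separation_s = tp$min_separation_s)
      utils::write.csv(res$strain, file.path(out_dir, "strain.csv"),
                       row.names = FALSE)
      out <- list(stim = res)
      if (!is.null(config$io$video_nostim)) {
        video2 <- read_video_tiff(config$io$video_nostim)
        res2 <- analyze_strain(video2, scene$light_direction,
                               mask = res$mask, n_regions = sp$n_regions,
                               n_iter = sp$n_iter, cutoff_hz = tp$cutoff_hz,
                               detrend_order = tp$detrend_order,
                               min_prominence_frac = tp$min_prominence_frac,
                               min_separation_s = tp$min_separation_s)
        cmp <- compare_stim(matrix(res$strain$strain, ncol = 1),
                            matrix(res2$strain$strain, ncol = 1))
        utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                         row.names = FALSE)
        out$unstim <- res2
        out$comparison <- cmp
      }
      lines <- log_line(lines, "strain over %d regions (up frame %d, down %d)",
                        nrow(res$strain), res$up_frame, res$down_frame)
      out
    },
    "report" = {
      collect <- function(f) {
        p <- file.path(out_dir, f)
        if (file.exists(p)) {
          if (grepl("json$", f)) jsonlite::read_json(p, simplifyVector = TRUE)
          else utils::read.csv(p)
        } else NULL
      }
      inputs <- Filter(function(p) !is.null(p) && file.exists(p),
                       config$io[c("video", "video_nostim", "mask",
                                   "trace_csv")])
      report <- list(
        version = as.character(utils::packageVersion("ctcm")),
        timestamp = format(Sys.time(), tz = "UTC"),
        parameters = unclass(config),
        input_checksums = as.list(vapply(inputs, function(p)
          unname(tools::md5sum(p)), character(1))),
        metrics = collect("metrics.json"),
        strain = collect("strain.csv"),
        comparison = collect("comparison.csv")
      )
      write_metrics_json(report, file.path(out_dir, "report.json"))
      report
    })
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}
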