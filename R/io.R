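#' Read and write videos as multi-page TIFF
#'
#' Videos are stored as 16-bit grayscale multi-page TIFFs; frame rate and
#' pixel pitch travel in a JSON side-car (`<path>.json`) written next to the
#' TIFF.
#'
#' @param video A `ctcm_video`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  tiff::writeTIFF(video$frames, path, bits.per.sample = 16)
  jsonlite::write_json(list(fps = video$fps, mm_per_px = video$mm_per_px),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_video_tiff
#' @param fps,mm_per_px Overrides used when no side-car JSON is present.
#' @return For `read_video_tiff`, a `ctcm_video`.
#' @export
read_video_tiff <- function(path, fps = 30, mm_per_px = NA_real_) {
  if (!file.exists(path)) stop("video file not found: ", path, call. = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fps <- meta$fps; mm_per_px <- meta$mm_per_px
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  structure(list(frames = frames, fps = fps, mm_per_px = mm_per_px),
            class = "ctcm_video")
}

#' Read and write binary masks as PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` (writer) or a logical matrix (reader).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a movement trace to CSV (columns `time_s`, `value`)
#'
#' @param trace A [motion_trace()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$t_s, value = trace$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fps Sampling rate of the stored trace.
#' @param stage Stage tag for the loaded trace.
#' @export
read_trace_csv <- function(path, fps = NULL, stage = "raw") {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (is.null(fps)) fps <- 1 / stats::median(diff(df$time_s))
  motion_trace(df$value, fps = fps, stage = stage, t_s = df$time_s)
}

#' Write cycle metrics (or any result list) as JSON
#'
#' @param x A list or metrics object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
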