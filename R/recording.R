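#' Raw sensor channel
#'
#' One named sensor stream: a sample matrix (rows = time, columns = axes),
#' strictly increasing timestamps in seconds, and the nominal sampling rate.
#' Units are sensor-native: m/s^2 for accelerometer, rad/s for gyroscope,
#' microtesla for magnetometer, normalized amplitude for audio, degrees for
#' GPS latitude/longitude.
#'
#' @param name channel identifier, one of `"acc"`, `"gyr"`, `"mag"`,
#'   `"audio"`, `"gps"`.
#' @param data numeric matrix of samples, one column per axis (a plain vector
#'   is accepted for single-axis channels such as audio).
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing, same length as `nrow(data)`.
#' @param rate_hz nominal sampling rate in Hz.
#' @return An object of class `"raw_channel"`.
#' @export
raw_channel <- function(name, data, timestamps, rate_hz) {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  timestamps <- as.numeric(timestamps)
  if (nrow(data) != length(timestamps))
    stopf("channel '%s': %d samples but %d timestamps", name, nrow(data),
          length(timestamps))
  if (length(timestamps) > 1) {
    bad <- which(diff(timestamps) <= 0)
    if (length(bad))
      stopf("channel '%s': timestamps not strictly increasing at row %d",
            name, bad[1] + 1L)
  }
  structure(list(name = name, data = data, timestamps = timestamps,
                 rate_hz = as.numeric(rate_hz)),
            class = "raw_channel")
}

#' Multi-sensor recording
#'
#' The pipeline's raw input: a set of [raw_channel] streams from one labeled
#' interval, with optional activity and location labels. After
#' [align_and_resample()] all inertial channels share a common uniform grid;
#' audio and GPS may keep their native rates but cover the same time span.
#'
#' @param channels named list of [raw_channel] objects; names must match the
#'   channels' own `name` fields.
#' @param fs common inertial sampling rate in Hz once aligned, else `NA`.
#' @param activity_label,location_label optional class labels (character).
#' @param subject_id optional subject identifier.
#' @return An object of class `"sensor_recording"`.
#' @export
sensor_recording <- function(channels, fs = NA_real_, activity_label = NA_character_,
                             location_label = NA_character_, subject_id = "s1") {
  stopifnot(is.list(channels), length(channels) >= 1)
  nms <- vapply(channels, function(ch) ch$name, "")
  names(channels) <- nms
  dur <- max(vapply(channels, function(ch) ch$timestamps[length(ch$timestamps)], 0)) -
    min(vapply(channels, function(ch) ch$timestamps[1], 0))
  structure(list(channels = channels, fs = as.numeric(fs), duration_s = dur,
                 activity_label = activity_label, location_label = location_label,
                 subject_id = subject_id),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording>", sprintf("%.1f s", x$duration_s),
      if (!is.na(x$fs)) sprintf("@ %g Hz", x$fs) else "(unaligned)", "\n")
  for (ch in x$channels)
    cat(sprintf("  %-6s %d x %d @ %g Hz\n", ch$name, nrow(ch$data),
                ncol(ch$data), ch$rate_hz))
  cat(sprintf("  activity: %s  location: %s  subject: %s\n",
              x$activity_label, x$location_label, x$subject_id))
  invisible(x)
}

#' @export
print.raw_channel <- function(x, ...) {
  cat(sprintf("<raw_channel %s> %d samples x %d axes @ %g Hz, [%.3f, %.3f] s\n",
              x$name, nrow(x$data), ncol(x$data), x$rate_hz,
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}
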