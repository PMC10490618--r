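# --- step detection ------------------------------------------------------

#' Per-sample acceleration magnitude
#'
#' @param acc numeric matrix with three equal-length axis columns.
#' @return `sqrt(ax^2 + ay^2 + az^2)` per sample.
#' @export
acceleration_magnitude <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stopf("shape error: expected 3 axis columns, got %d", ncol(acc))
  sqrt(rowSums(acc^2))
}

#' Detect steps from the acceleration magnitude
#'
#' The gravity offset is removed by subtracting the mean of the magnitude
#' ("net magnitude"); peaks of the net magnitude above the detection
#' threshold are steps. The literal "mean of the net magnitude" is
#' identically zero after mean subtraction, so the default threshold is the
#' mean *absolute* net magnitude (`mode = "abs_mean"`), with `"zero"` and
#' `"quantile"` available. Peaks closer than `min_separation_s` are resolved
#' by keeping the larger one (a physiological cadence cap of 4 steps/s).
#'
#' @param magnitude numeric sequence from [acceleration_magnitude()].
#' @param fs sampling rate in Hz.
#' @param min_separation_s minimum peak separation in seconds (default 0.25).
#' @param threshold_mode `"abs_mean"`, `"zero"` or `"quantile"`.
#' @param quantile quantile level when `threshold_mode = "quantile"`.
#' @return An object of class `"step_events"`: `peak_indices` (1-based sample
#'   indices, strictly increasing), `threshold`, `net`; `valley_pairs` and
#'   `step_intervals_s` are filled by [estimate_step_intervals()].
#' @export
detect_steps <- function(magnitude, fs, min_separation_s = 0.25,
                         threshold_mode = c("abs_mean", "zero", "quantile"),
                         quantile = 0.75) {
  threshold_mode <- match.arg(threshold_mode)
  n <- length(magnitude)
  if (n < fs) stopf("length error: need at least one second of samples")
  net <- magnitude - mean(magnitude)
  thr <- switch(threshold_mode,
                abs_mean = mean(abs(net)),
                zero = 0,
                quantile = stats::quantile(net, quantile, names = FALSE))
  i <- 2:(n - 1)
  cand <- i[net[i] > net[i - 1] & net[i] >= net[i + 1] & net[i] > thr]
  # amplitude-priority refractory rule: keep the larger peak on conflict
  min_gap <- round(min_separation_s * fs)
  keep <- logical(0)
  if (length(cand)) {
    ord <- cand[order(net[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) if (!length(kept) || min(abs(kept - p)) >= min_gap)
      kept <- c(kept, p)
    keep <- sort(kept)
  }
  structure(list(peak_indices = as.integer(keep), valley_pairs = NULL,
                 step_intervals_s = NULL, threshold = thr, net = net, fs = fs),
            class = "step_events")
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps (threshold %.3f)\n",
              length(x$peak_indices), x$threshold))
  invisible(x)
}

#' Dynamic step-interval estimation
#'
#' For each detected peak, locates the nearest local minimum of the net
#' magnitude on either side (the flanking valleys); the step interval is the
#' timestamp difference of the two valleys in seconds. A peak at a sequence
#' boundary lacking a valley on one side gets an `NA` interval. This is the
#' dynamic per-step "step length" of the heading pipeline — a duration, not
#' a distance.
#'
#' @param magnitude the same magnitude sequence the events came from.
#' @param events a `"step_events"` object from [detect_steps()].
#' @param fs sampling rate in Hz.
#' @return The events with `valley_pairs` (two-column matrix of sample
#'   indices) and `step_intervals_s` filled.
#' @export
estimate_step_intervals <- function(magnitude, events, fs = events$fs) {
  net <- magnitude - mean(magnitude)
  n <- length(net)
  i <- 2:(n - 1)
  mins <- i[net[i] < net[i - 1] & net[i] <= net[i + 1]]
  vp <- matrix(NA_integer_, length(events$peak_indices), 2,
               dimnames = list(NULL, c("left", "right")))
  for (k in seq_along(events$peak_indices)) {
    p <- events$peak_indices[k]
    left <- mins[mins < p]
    right <- mins[mins > p]
    if (length(left)) vp[k, 1] <- max(left)
    if (length(right)) vp[k, 2] <- min(right)
  }
  events$valley_pairs <- vp
  events$step_intervals_s <- (vp[, 2] - vp[, 1]) / fs
  events
}

# --- attitude and heading ------------------------------------------------

#' Euler angles from accelerometer and magnetometer
#'
#' Tilt from gravity, yaw from the tilt-compensated field:
#' `roll = atan2(ay, az)`, `pitch = atan2(-ax, sqrt(ay^2 + az^2))`,
#' `yaw = atan2(My, Mx)` with
#' `My = mx sin(roll) sin(pitch) + my cos(roll) - mz sin(roll) cos(pitch)` and
#' `Mx = mx cos(pitch) + mz sin(pitch)`. `atan2` preserves the quadrant
#' everywhere an arctangent appears.
#'
#' @param acc length-3 accelerometer sample (device frame, m/s^2 or g).
#' @param mag length-3 magnetometer sample (microtesla).
#' @return List of class `"euler_angles"` with `roll`, `pitch`, `yaw`
#'   (radians, wrapped to (-pi, pi]).
#' @export
euler_angles <- function(acc, mag) {
  if (sqrt(sum(acc^2)) == 0)
    stopf("undefined-attitude error: zero acceleration vector")
  roll <- atan2(acc[2], acc[3])
  pitch <- atan2(-acc[1], sqrt(acc[2]^2 + acc[3]^2))
  My <- mag[1] * sin(roll) * sin(pitch) + mag[2] * cos(roll) -
    mag[3] * sin(roll) * cos(pitch)
  Mx <- mag[1] * cos(pitch) + mag[3] * sin(pitch)
  yaw <- atan2(My, Mx)
  structure(list(roll = wrap_angle(roll), pitch = wrap_angle(pitch),
                 yaw = wrap_angle(yaw)), class = "euler_angles")
}

#' Magnetometer heading
#'
#' Rotates the raw field into the earth-horizontal frame with the
#' roll/pitch rotation matrix and takes the heading as the `atan2` of the
#' two horizontal components of the rotated vector (the printed matrix
#' product alone yields a 3-vector; the scalarization is the standard
#' tilt-compensated compass reading).
#'
#' @param e an `"euler_angles"` object.
#' @param mag length-3 magnetometer sample.
#' @return Heading in radians, wrapped to (-pi, pi]; `NA` with attribute
#'   `flagged = TRUE` when the rotated horizontal field vanishes.
#' @export
magnetometer_heading <- function(e, mag) {
  cf <- cos(e$roll); sf <- sin(e$roll)
  ct <- cos(e$pitch); st <- sin(e$pitch)
  R <- matrix(c(cf, sf * st, -sf * ct,
                0,  ct,       st,
                sf, -st * cf, cf * ct), 3, 3, byrow = TRUE)
  v <- as.numeric(R %*% as.numeric(mag))
  if (sqrt(v[1]^2 + v[2]^2) < 1e-12)
    return(structure(NA_real_, flagged = TRUE))
  wrap_angle(atan2(v[2], v[1]))
}

# Unit quaternion from intrinsic roll/pitch/yaw.
euler_to_quaternion <- function(roll, pitch, yaw) {
  cr <- cos(roll / 2); sr <- sin(roll / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cy <- cos(yaw / 2); sy <- sin(yaw / 2)
  c(cr * cp * cy + sr * sp * sy,
    sr * cp * cy - cr * sp * sy,
    cr * sp * cy + sr * cp * sy,
    cr * cp * sy - sr * sp * cy)
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Create a heading state
#'
#' @param q unit quaternion `(q0, q1, q2, q3)`, scalar first.
#' @param t time in seconds.
#' @return An object of class `"heading_state"` with the quaternion and the
#'   magnetometer (`H_M`), gyroscope (`H_G`) and fused (`H_fused`) headings.
#' @export
heading_state <- function(q = c(1, 0, 0, 0), t = 0) {
  nq <- sqrt(sum(q^2))
  if (abs(nq - 1) > 1e-6) stopf("state error: quaternion norm %.8f != 1", nq)
  structure(list(q = q / nq, H_M = NA_real_, H_G = quat_yaw(q / nq),
                 H_fused = NA_real_, t = t), class = "heading_state")
}

# yaw extracted from the orientation quaternion:
# G_x = 2 (q0 q3 + q1 q2), G_y = 1 - 2 (q2^2 + q3^2), H_G = atan2(G_x, G_y)
quat_yaw <- function(q) {
  gx <- 2 * (q[1] * q[4] + q[2] * q[3])
  gy <- 1 - 2 * (q[3]^2 + q[4]^2)
  wrap_angle(atan2(gx, gy))
}

#' Propagate the gyroscope heading by one sample
#'
#' Converts the body rates to Euler-angle rates through the current
#' roll/pitch (`roll* = gx + gy sin(roll) tan(pitch) + gz cos(roll) tan(pitch)`,
#' `pitch* = gy cos(roll) - gz sin(roll)`,
#' `yaw* = gy sin(roll)/cos(pitch) + gz cos(roll)/cos(pitch)`), forms the
#' incremental gyro-quaternion GQ of the rate-times-`dt` angles, composes it
#' with the running orientation quaternion and re-normalizes. Composing the
#' half-Omega rate update *and* GQ would double-count the rotation, so the
#' increment is applied once; the gyroscope heading is the yaw read off the
#' updated quaternion via `atan2(G_x, G_y)` (a bare ratio diverges at
#' `G_y = 0`).
#'
#' @param state a `"heading_state"`.
#' @param gyr length-3 body angular rates (rad/s).
#' @param e current `"euler_angles"` (roll/pitch source for the rate
#'   transformation).
#' @param dt time step in seconds (> 0).
#' @return The updated `"heading_state"` (unit quaternion, `H_G` filled).
#' @export
gyroscope_heading_step <- function(state, gyr, e, dt) {
  if (dt <= 0) stopf("parameter error: dt must be positive")
  nq <- sqrt(sum(state$q^2))
  if (abs(nq - 1) > 1e-6) stopf("state error: non-unit quaternion")
  sf <- sin(e$roll); cf <- cos(e$roll)
  tt <- tan(e$pitch); ct <- cos(e$pitch)
  roll_rate <- gyr[1] + gyr[2] * sf * tt + gyr[3] * cf * tt
  pitch_rate <- gyr[2] * cf - gyr[3] * sf
  yaw_rate <- gyr[2] * sf / ct + gyr[3] * cf / ct
  GQ <- euler_to_quaternion(roll_rate * dt, pitch_rate * dt, yaw_rate * dt)
  q <- quat_multiply(state$q, GQ)
  q <- q / sqrt(sum(q^2))
  state$q <- q
  state$H_G <- quat_yaw(q)
  state$t <- state$t + dt
  state
}

#' Fuse magnetometer and gyroscope headings
#'
#' Circular mean of the two headings, `atan2(sin H_M + sin H_G,
#' cos H_M + cos H_G)`, which survives the +/-pi wrap (the arithmetic mean of
#' 350 and 10 degrees would point south). Antipodal inputs have no mean; the
#' gyroscope heading is returned with attribute `flagged = TRUE`.
#'
#' @param H_M,H_G headings in radians.
#' @return Fused heading in (-pi, pi].
#' @export
fuse_heading <- function(H_M, H_G) {
  s <- sin(H_M) + sin(H_G); c <- cos(H_M) + cos(H_G)
  if (sqrt(s^2 + c^2) < 1e-9) return(structure(wrap_angle(H_G), flagged = TRUE))
  wrap_angle(atan2(s, c))
}

#' Run the full heading pipeline over aligned samples
#'
#' Per sample: Euler angles from accelerometer/magnetometer, magnetometer
#' heading from the rotated field, gyroscope heading from quaternion
#' propagation (initialized from the first sample's Euler angles so both
#' estimates share an origin), and the circular-mean fusion.
#'
#' @param acc,gyr,mag n-by-3 matrices of aligned samples.
#' @param fs sampling rate in Hz.
#' @return Data frame with `t`, `roll`, `pitch`, `H_M`, `H_G`, `H_fused`.
#' @export
heading_track <- function(acc, gyr, mag, fs) {
  n <- nrow(acc)
  e1 <- euler_angles(acc[1, ], mag[1, ])
  st <- heading_state(euler_to_quaternion(e1$roll, e1$pitch, e1$yaw))
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("roll", "pitch", "H_M", "H_G", "H_fused")))
  dt <- 1 / fs
  for (i in seq_len(n)) {
    e <- euler_angles(acc[i, ], mag[i, ])
    hm <- magnetometer_heading(e, mag[i, ])
    if (i > 1) st <- gyroscope_heading_step(st, gyr[i, ], e, dt)
    hf <- if (is.na(hm)) st$H_G else fuse_heading(hm, st$H_G)
    out[i, ] <- c(e$roll, e$pitch, hm, st$H_G, hf)
  }
  data.frame(t = (seq_len(n) - 1) * dt, out)
}

# --- localization feature bank -------------------------------------------

#' Default configuration of the localization feature bank
#'
#' @return Named list: step-detector settings and audio MFCC framing
#'   (25 ms / 10 ms, 26 filters, 13 coefficients).
#' @export
loc_feature_config <- function() {
  list(min_separation_s = 0.25, threshold_mode = "abs_mean",
       mfcc = list(n_coeffs = 13, n_filters = 26, frame_s = 0.025, hop_s = 0.010))
}

#' Extract the localization feature bank from a window stack
#'
#' Concatenates the stack's raw (unweighted) inertial samples into one 15-s
#' signal and computes: step count and step-interval mean/SD; circular mean,
#' circular SD and net change of the fused heading; 13 audio MFCC
#' frame-means plus an audio-presence flag (zeros when no audio channel);
#' GPS availability plus speed mean/SD (zeros when absent). Missing inertial
#' channels raise a precondition error rather than being imputed.
#'
#' @param stack a `"window_stack"`.
#' @param cfg configuration, see [loc_feature_config()].
#' @return A `"feature_vector"` with a 23-slot layout manifest.
#' @export
extract_loc_features <- function(stack, cfg = loc_feature_config()) {
  need <- c("acc", "gyr", "mag")
  have <- names(stack$windows[[1]]$samples)
  if (!all(need %in% have))
    stopf("precondition error: inertial channel(s) missing: %s",
          paste(setdiff(need, have), collapse = ", "))
  cat3 <- function(nm) do.call(rbind, lapply(stack$windows, function(w) w$samples[[nm]]))
  acc <- cat3("acc"); gyr <- cat3("gyr"); mag <- cat3("mag")
  fs <- stack$windows[[1]]$fs

  magn <- acceleration_magnitude(acc)
  ev <- detect_steps(magn, fs, min_separation_s = cfg$min_separation_s,
                     threshold_mode = cfg$threshold_mode)
  ev <- estimate_step_intervals(magn, ev, fs)
  iv <- ev$step_intervals_s[!is.na(ev$step_intervals_s)]
  step_feats <- c(length(ev$peak_indices),
                  if (length(iv)) mean(iv) else 0,
                  if (length(iv) > 1) stats::sd(iv) else 0)

  ht <- heading_track(acc, gyr, mag, fs)
  hf <- ht$H_fused[is.finite(ht$H_fused)]
  uw <- unwrap_angle(hf)
  head_feats <- c(circ_mean(hf),
                  circ_sd(hf),
                  uw[length(uw)] - uw[1])
  head_feats[!is.finite(head_feats)] <- 0

  audio <- stack$windows[[1]]$samples$audio
  if (!is.null(audio)) {
    audio <- do.call(rbind, lapply(stack$windows, function(w) w$samples$audio))
    afs <- stack$windows[[1]]$rates$audio
    audio_feats <- c(mfcc(audio[, 1], afs, n_coeffs = cfg$mfcc$n_coeffs,
                          n_filters = cfg$mfcc$n_filters,
                          frame_s = cfg$mfcc$frame_s, hop_s = cfg$mfcc$hop_s)$mean, 1)
  } else {
    audio_feats <- c(rep(0, cfg$mfcc$n_coeffs), 0)
  }

  gps <- stack$windows[[1]]$samples$gps
  if (!is.null(gps) && nrow(gps) >= 2) {
    gps <- do.call(rbind, lapply(stack$windows, function(w) w$samples$gps))
    gfs <- stack$windows[[1]]$rates$gps
    # coarse speed from consecutive lat/lon fixes (equirectangular, m/s)
    dlat <- diff(gps[, 1]) * 111320
    dlon <- diff(gps[, 2]) * 111320 * cos(mean(gps[, 1]) * pi / 180)
    speed <- sqrt(dlat^2 + dlon^2) * gfs
    gps_feats <- c(1, mean(speed), if (length(speed) > 1) stats::sd(speed) else 0)
  } else {
    gps_feats <- c(0, 0, 0)
  }

  values <- c(step_feats, head_feats, audio_feats, gps_feats)
  layout <- data.frame(
    feature = c("step_count", "step_interval_mean", "step_interval_sd",
                "heading_mean", "heading_sd", "heading_net_change",
                paste0("audio_mfcc", 0:(cfg$mfcc$n_coeffs - 1)), "audio_present",
                "gps_present", "gps_speed_mean", "gps_speed_sd"),
    channel = c(rep("acc", 3), rep("fused", 3),
                rep("audio", cfg$mfcc$n_coeffs + 1), rep("gps", 3)),
    axis = "all", window = NA_integer_)
  stopifnot(all(is.finite(values)), nrow(layout) == length(values))
  structure(list(values = values, layout = layout, bank = "loc"),
            class = "feature_vector")
}
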