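# Seeded generator of labeled multi-sensor recordings: activity-specific gait
# periodicity and device attitude, location-specific audio spectra, heading
# profiles that rotate gravity and the earth magnetic field consistently so
# the heading pipeline sees physically coherent inputs.

# built-in activity presets: cadence (Hz), vertical gait amplitude (m/s^2),
# constant device roll (rad), tremor/sway parameters, channel noise SDs
activity_presets <- function() {
  list(
    sitting  = list(step_rate_hz = 0, acc_amplitude = 0, roll = 1.2,
                    sway_hz = 0, sway_amp = 0, acc_noise = 0.03,
                    gyr_noise = 0.01),
    standing = list(step_rate_hz = 0, acc_amplitude = 0, roll = 0,
                    sway_hz = 0.7, sway_amp = 0.35, acc_noise = 0.12,
                    gyr_noise = 0.02),
    walking  = list(step_rate_hz = 2.0, acc_amplitude = 2.0, roll = 0,
                    sway_hz = 0, sway_amp = 0, acc_noise = 0.15,
                    gyr_noise = 0.05),
    running  = list(step_rate_hz = 2.8, acc_amplitude = 5.0, roll = 0,
                    sway_hz = 0, sway_amp = 0, acc_noise = 0.25,
                    gyr_noise = 0.08)
  )
}

# built-in location presets: audio band (Hz, below the 400 Hz audio Nyquist),
# audio level, GPS availability and nominal speed (m/s), yaw-rate schedule
location_presets <- function() {
  list(
    home    = list(audio_profile = "band", band = c(50, 120), audio_level = 0.05,
                   gps = FALSE, speed = 0, turns = 1),
    office  = list(audio_profile = "band", band = c(150, 250), audio_level = 0.08,
                   gps = FALSE, speed = 0, turns = 2),
    street  = list(audio_profile = "white", band = NULL, audio_level = 0.20,
                   gps = TRUE, speed = 1.4, turns = 1),
    vehicle = list(audio_profile = "band", band = c(15, 60), audio_level = 0.35,
                   gps = TRUE, speed = 10, turns = 0)
  )
}

#' Scenario specification for the synthetic generator
#'
#' Describes one labeled recording: activity signature (cadence, amplitude,
#' attitude, tremor), location signature (audio spectrum, GPS), a
#' piecewise-constant yaw-rate heading profile, noise levels and a seed. All
#' defaults come from the built-in presets; see the package vignette for the
#' rationale behind each value.
#'
#' @param activity one of `names(activity_presets())` —
#'   sitting, standing, walking, running.
#' @param location one of `names(location_presets())` —
#'   home, office, street, vehicle.
#' @param duration_s recording length in seconds, >= 15 (one stack).
#' @param fs inertial sampling rate (default 40 Hz).
#' @param audio_fs audio sampling rate (default 800 Hz).
#' @param heading_profile data frame `(t_start, rate)` of yaw-rate segments
#'   (rad/s); `NULL` derives one from the location's `turns` preset.
#' @param seed integer seed; the recording is a pure function of the spec.
#' @param ... overrides for individual preset fields (e.g. `step_rate_hz`,
#'   `acc_amplitude`, `acc_noise`).
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(activity, location, duration_s = 30, fs = 40,
                          audio_fs = 800, heading_profile = NULL, seed = 1, ...) {
  ap <- activity_presets(); lp <- location_presets()
  if (!activity %in% names(ap))
    stopf("spec error: unknown activity '%s'", activity)
  if (!location %in% names(lp))
    stopf("spec error: unknown location '%s'", location)
  if (duration_s < 15) stopf("spec error: duration_s must be >= 15 (one stack)")
  spec <- c(list(activity = activity, location = location,
                 duration_s = duration_s, fs = fs, audio_fs = audio_fs,
                 heading_profile = heading_profile, seed = seed,
                 mag_noise = 0.4),
            ap[[activity]], lp[[location]])
  dots <- list(...)
  spec[names(dots)] <- dots
  if (spec$step_rate_hz < 0 || spec$step_rate_hz > 4)
    stopf("spec error: step_rate_hz must lie in [0, 4]")
  structure(spec, class = "scenario_spec")
}

# yaw-rate schedule: `turns` 90-degree turns spread over the recording,
# each executed in 2 s
default_heading_profile <- function(duration_s, turns) {
  if (turns == 0) return(data.frame(t_start = 0, rate = 0))
  starts <- duration_s * seq_len(turns) / (turns + 1)
  segs <- data.frame(t_start = 0, rate = 0)
  for (s in starts) {
    segs <- rbind(segs, data.frame(t_start = s, rate = (pi / 2) / 2),
                  data.frame(t_start = s + 2, rate = 0))
  }
  segs
}

# integrate a piecewise-constant yaw-rate schedule onto the sample grid
integrate_heading <- function(profile, t, psi0 = 0) {
  rate <- numeric(length(t))
  for (i in seq_len(nrow(profile)))
    rate[t >= profile$t_start[i]] <- profile$rate[i]
  psi0 + c(0, cumsum(rate[-length(rate)] * diff(t)))
}

# FFT-shaped noise: white, pink (1/sqrt(f)), or band-passed white
shaped_noise <- function(n, fs, profile, band = NULL) {
  x <- stats::rnorm(n)
  if (profile == "white") return(x)
  X <- stats::fft(x)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)
  shape <- switch(profile,
                  pink = 1 / sqrt(pmax(f, fs / n)),
                  band = as.numeric(f >= band[1] & f <= band[2]),
                  stopf("spec error: unknown audio profile '%s'", profile))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate one labeled multi-sensor recording
#'
#' Device frame is x-right, y-forward, z-up. The accelerometer reads gravity
#' rotated into the (possibly tilted) device frame plus a vertical gait
#' sinusoid at the activity cadence (with a weaker forward second harmonic)
#' plus Gaussian noise; the gyroscope carries the heading profile's yaw rate;
#' the magnetometer is the earth field (22 uT horizontal, -42 uT vertical)
#' rotated by the integrated heading and the device tilt; audio is
#' FFT-shaped noise with the location's spectral profile; GPS (when the
#' location has it) is a 1 Hz track at the nominal speed along the heading.
#' Bitwise-reproducible for a given spec.
#'
#' @param spec a [scenario_spec()].
#' @return A labeled, aligned [sensor_recording] at `spec$fs`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs
    n <- round(spec$duration_s * fs)
    t <- (0:(n - 1)) / fs
    profile <- spec$heading_profile %||%
      default_heading_profile(spec$duration_s, spec$turns)
    psi0 <- stats::runif(1, -pi, pi)
    psi <- integrate_heading(profile, t, psi0)
    g <- 9.81
    cr <- cos(spec$roll); sr <- sin(spec$roll)
    # gait: vertical bounce at cadence + weaker forward second harmonic
    f0 <- spec$step_rate_hz
    bounce <- if (f0 > 0) spec$acc_amplitude * sin(2 * pi * f0 * t) else 0
    fwd <- if (f0 > 0) 0.3 * spec$acc_amplitude * sin(4 * pi * f0 * t + 0.8) else 0
    sway <- if (spec$sway_hz > 0) spec$sway_amp * sin(2 * pi * spec$sway_hz * t) else 0
    # world-frame specific force (0, fwd, g + bounce + sway), tilted by roll
    az_w <- g + bounce + sway
    ay_w <- fwd
    acc <- cbind(x = stats::rnorm(n, 0, spec$acc_noise),
                 y = cr * ay_w - sr * az_w + stats::rnorm(n, 0, spec$acc_noise),
                 z = sr * ay_w + cr * az_w + stats::rnorm(n, 0, spec$acc_noise))
    # yaw rate about the world vertical, expressed in the tilted device frame
    rate <- c(0, diff(psi)) * fs
    gyr <- cbind(x = stats::rnorm(n, 0, spec$gyr_noise),
                 y = -sr * rate + stats::rnorm(n, 0, spec$gyr_noise),
                 z = cr * rate + stats::rnorm(n, 0, spec$gyr_noise))
    # earth field rotated by heading (compass convention), then tilted
    Mh <- 22; Mz <- -42
    mx_l <- Mh * cos(psi); my_l <- Mh * sin(psi)
    mag <- cbind(x = mx_l + stats::rnorm(n, 0, spec$mag_noise),
                 y = cr * my_l - sr * Mz + stats::rnorm(n, 0, spec$mag_noise),
                 z = sr * my_l + cr * Mz + stats::rnorm(n, 0, spec$mag_noise))
    chans <- list(acc = raw_channel("acc", acc, t, fs),
                  gyr = raw_channel("gyr", gyr, t, fs),
                  mag = raw_channel("mag", mag, t, fs))
    na <- round(spec$duration_s * spec$audio_fs)
    audio <- spec$audio_level *
      shaped_noise(na, spec$audio_fs, spec$audio_profile, spec$band)
    chans$audio <- raw_channel("audio", audio, (0:(na - 1)) / spec$audio_fs,
                               spec$audio_fs)
    if (isTRUE(spec$gps)) {
      tg <- seq(0, spec$duration_s - 1, by = 1)
      psi_g <- psi[pmin(round(tg * fs) + 1, n)]
      step_m <- spec$speed * c(0, diff(tg))
      lat <- 45 + cumsum(step_m * cos(psi_g)) / 111320
      lon <- 7 + cumsum(step_m * sin(psi_g)) / (111320 * cos(45 * pi / 180))
      chans$gps <- raw_channel("gps", cbind(lat = lat, lon = lon), tg, 1)
    }
    rec <- sensor_recording(chans, fs = fs, activity_label = spec$activity,
                            location_label = spec$location)
    rec$true_heading <- psi
    rec
  })
}

#' Generate a balanced labeled corpus
#'
#' Draws `n_per_class` recordings per template, jittering the gait rate,
#' amplitude and noise levels by +/-10% per recording; every recording gets
#' its own seed derived from `seed`, so the corpus is reproducible as a
#' whole.
#'
#' @param n_per_class recordings per template (>= 1).
#' @param templates list of [scenario_spec()] objects used as class
#'   templates.
#' @param seed master seed.
#' @return List of [sensor_recording] objects, length
#'   `n_per_class * length(templates)`.
#' @export
generate_dataset <- function(n_per_class, templates, seed = 1) {
  if (!length(templates)) stopf("spec error: empty template list")
  if (n_per_class < 1) stopf("spec error: n_per_class must be >= 1")
  n_tot <- n_per_class * length(templates)
  plan <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n_tot)
    jit <- matrix(stats::runif(n_tot * 3, 0.9, 1.1), n_tot, 3)
    list(seeds = seeds, jit = jit)
  })
  recs <- vector("list", n_tot)
  k <- 0L
  for (tmpl in templates) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sp <- tmpl
      sp$seed <- plan$seeds[k]
      sp$step_rate_hz <- min(sp$step_rate_hz * plan$jit[k, 1], 4)
      sp$acc_amplitude <- sp$acc_amplitude * plan$jit[k, 2]
      sp$acc_noise <- sp$acc_noise * plan$jit[k, 3]
      recs[[k]] <- generate_recording(sp)
    }
  }
  recs
}

#' Write a recording to disk in the generic CSV (+ audio/GPS CSV) layout
#'
#' The inertial channels go to `<stem>.csv` in the layout [read_generic_csv()]
#' understands; audio and GPS, being on their own grids, go to
#' `<stem>_audio.csv` / `<stem>_gps.csv`.
#'
#' @param rec a [sensor_recording].
#' @param stem output path stem (no extension).
#' @return The main CSV path, invisibly.
#' @export
write_recording_csv <- function(rec, stem) {
  imu <- rec
  imu$channels <- rec$channels[intersect(names(rec$channels), c("acc", "gyr", "mag"))]
  write_generic_csv(imu, paste0(stem, ".csv"))
  if (!is.null(rec$channels$audio)) {
    a <- rec$channels$audio
    utils::write.csv(data.frame(t = a$timestamps, audio = a$data[, 1]),
                     paste0(stem, "_audio.csv"), row.names = FALSE)
  }
  if (!is.null(rec$channels$gps)) {
    gp <- rec$channels$gps
    utils::write.csv(data.frame(t = gp$timestamps, lat = gp$data[, 1],
                                lon = gp$data[, 2]),
                     paste0(stem, "_gps.csv"), row.names = FALSE)
  }
  invisible(paste0(stem, ".csv"))
}

#' Generate a corpus crossing activities with locations
#'
#' Assigns activity-location combinations round-robin over
#' `length(activities) * length(locations)` cells, so the two label sets are
#' (near-)balanced and mutually unconfounded — the location classifier cannot
#' lean on gait signatures and vice versa. Per-recording seeds and +/-10%
#' parameter jitter are drawn from the master seed.
#'
#' @param n_total total number of recordings.
#' @param activities,locations class sets (defaults: all presets).
#' @param duration_s per-recording duration in seconds.
#' @param fs inertial sampling rate.
#' @param seed master seed.
#' @return List of labeled [sensor_recording] objects.
#' @export
generate_crossed_corpus <- function(n_total = 100,
                                    activities = names(activity_presets()),
                                    locations = names(location_presets()),
                                    duration_s = 20, fs = 40, seed = 1) {
  grid <- expand.grid(activity = activities, location = locations,
                      stringsAsFactors = FALSE)
  plan <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max, n_total),
         jit = matrix(stats::runif(n_total * 3, 0.9, 1.1), n_total, 3))
  })
  lapply(seq_len(n_total), function(i) {
    g <- grid[(i - 1) %% nrow(grid) + 1, ]
    sp <- scenario_spec(g$activity, g$location, duration_s = duration_s,
                        fs = fs, seed = plan$seeds[i])
    sp$step_rate_hz <- min(sp$step_rate_hz * plan$jit[i, 1], 4)
    sp$acc_amplitude <- sp$acc_amplitude * plan$jit[i, 2]
    sp$acc_noise <- sp$acc_noise * plan$jit[i, 3]
    generate_recording(sp)
  })
}
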