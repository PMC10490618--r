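# programmatic fixtures shared across test files

# a minimal aligned recording with sinusoidal gait on acc z, constant yaw rate
make_walk_recording <- function(duration_s = 20, fs = 40, step_rate = 2,
                                amp = 2, yaw_rate = 0, seed = 1) {
  generate_recording(scenario_spec(
    "walking", "home", duration_s = duration_s, fs = fs, seed = seed,
    step_rate_hz = step_rate, acc_amplitude = amp,
    heading_profile = data.frame(t_start = 0, rate = yaw_rate)))
}

# write a 3-axis accelerometer CSV and return its path
write_acc_csv <- function(t, ax, ay, az, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(t = t, acc_x = ax, acc_y = ay, acc_z = az),
                   path, row.names = FALSE)
  path
}

# measured amplitude of the component at normalized frequency w (fraction of
# Nyquist) by projection onto the quadrature pair, over a central span
measure_amplitude <- function(y, w, drop = 500) {
  n <- length(y)
  core <- (drop + 1):(n - drop)
  t <- core - 1
  2 * sqrt(mean(y[core] * sin(pi * w * t))^2 + mean(y[core] * cos(pi * w * t))^2)
}

# fixture directory in the ExtraSensory text layout; returns its path
make_extrasensory_fixture <- function(root = tempfile("es_"), drop_mag = FALSE) {
  ud <- file.path(root, "uuid-0001")
  dir.create(ud, recursive = TRUE)
  t <- seq(0, 16, by = 0.025)
  for (iv in c("100", "200")) {
    for (sens in c("m_raw_acc", "m_raw_gyro", "m_raw_magnet")) {
      if (drop_mag && sens == "m_raw_magnet" && iv == "200") next
      utils::write.table(
        data.frame(t = t, x = sin(t), y = cos(t), z = 9.8 + 0 * t),
        file.path(ud, paste0(iv, ".", sens, ".dat")),
        row.names = FALSE, col.names = FALSE)
    }
  }
  utils::write.csv(
    data.frame(interval = c("100", "200"),
               activity = c("SITTING", "FIX_walking"),
               location = c("LOC_home", "OR_outside")),
    file.path(ud, "labels.csv"), row.names = FALSE)
  root
}

# fixture directory in the SHL text layout
make_shl_fixture <- function(root = tempfile("shl_"), codes = c(1, 2)) {
  dd <- file.path(root, "day1")
  dir.create(dd, recursive = TRUE)
  t_ms <- seq(0, 20000, by = 10)
  for (f in c("Acc.txt", "Gyr.txt", "Mag.txt"))
    utils::write.table(
      data.frame(t = t_ms, x = sin(t_ms / 1000), y = cos(t_ms / 1000), z = 1),
      file.path(dd, f), row.names = FALSE, col.names = FALSE)
  lab_t <- seq(0, 20000, by = 1000)
  lab <- rep(codes, each = ceiling(length(lab_t) / length(codes)))[seq_along(lab_t)]
  utils::write.table(data.frame(t = lab_t, code = lab),
                     file.path(dd, "Label.txt"),
                     row.names = FALSE, col.names = FALSE)
  root
}
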