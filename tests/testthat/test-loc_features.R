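test_that("acceleration magnitude is the per-sample Euclidean norm", {
  expect_equal(acceleration_magnitude(cbind(3, 4, 0)), 5)
  expect_equal(acceleration_magnitude(cbind(0, 0, 0)), 0)
  expect_equal(acceleration_magnitude(cbind(1, 1, 1)), sqrt(3))
  expect_error(acceleration_magnitude(cbind(1, 2)), "shape error")
})

test_that("step detector finds one step per gait cycle", {
  fs <- 100; t <- (0:(10 * fs - 1)) / fs
  m <- 10 + 2 * sin(2 * pi * 2 * t)
  ev <- detect_steps(m, fs)
  expect_length(ev$peak_indices, 20)
  expect_true(all(diff(ev$peak_indices) > 0))
  expect_length(detect_steps(rep(5, 1000), fs)$peak_indices, 0)
  # single Gaussian bump on a flat baseline: exactly one step
  bump <- 1 + 3 * exp(-((t - 5)^2) / 0.1)
  expect_length(detect_steps(bump, fs)$peak_indices, 1)
})

test_that("step detection is amplitude-scale-invariant", {
  set.seed(9)
  fs <- 40
  m <- 9.8 + 2 * sin(2 * pi * 2 * (0:399) / fs) + rnorm(400, 0, 0.3)
  for (c in c(0.1, 3, 250))
    expect_identical(detect_steps(c * m, fs)$peak_indices,
                     detect_steps(m, fs)$peak_indices)
})

test_that("step intervals are valley-to-valley durations", {
  fs <- 100; t <- (0:(10 * fs - 1)) / fs
  m <- 10 + 2 * sin(2 * pi * 2 * t)
  ev <- estimate_step_intervals(m, detect_steps(m, fs), fs)
  iv <- ev$step_intervals_s
  # first peak precedes the first valley: its interval is absent
  expect_true(is.na(iv[1]))
  expect_true(all(!is.na(iv[-1])))
  expect_true(all(abs(iv[-1] - 0.5) <= 1 / fs + 1e-12))
  # peaks lie strictly between their valleys
  ok <- stats::complete.cases(ev$valley_pairs)
  expect_true(all(ev$valley_pairs[ok, 1] < ev$peak_indices[ok] &
                    ev$peak_indices[ok] < ev$valley_pairs[ok, 2]))

  # hand-built single bump: interval equals the bump base width (a shallow
  # parabola gives the flanks genuine local minima, symmetric about t = 5)
  t2 <- (0:999) / 100
  bump <- exp(-((t2 - 5)^2) / 0.05) + 0.001 * (t2 - 5)^2
  ev2 <- estimate_step_intervals(bump, detect_steps(bump, 100), 100)
  expect_length(ev2$peak_indices, 1)
  # valleys straddle the bump symmetrically around t = 5
  w <- ev2$valley_pairs[1, ]
  expect_equal(mean(t2[w]), 5, tolerance = 0.05)
})

test_that("Euler angles match the closed-form attitude cases", {
  e <- euler_angles(c(0, 0, 1), c(1, 0, 0))
  expect_equal(c(e$roll, e$pitch, e$yaw), c(0, 0, 0))
  e2 <- euler_angles(c(0, 1, 0), c(1, 0, 0))
  expect_equal(e2$roll, pi / 2)
  expect_equal(e2$pitch, 0)
  e3 <- euler_angles(c(0, 0, 1), c(0, 1, 0))
  expect_equal(e3$yaw, pi / 2)
  expect_error(euler_angles(c(0, 0, 0), c(1, 0, 0)), "undefined-attitude")
})

test_that("magnetometer heading is the tilt-compensated compass", {
  level <- euler_angles(c(0, 0, 1), c(1, 0, 0))
  expect_equal(magnetometer_heading(level, c(1, 0, 0)), 0)
  expect_equal(magnetometer_heading(level, c(0, 1, 0)), pi / 2)
  for (alpha in c(30, 120, -45) * pi / 180)
    expect_equal(magnetometer_heading(level, c(cos(alpha), sin(alpha), 0)),
                 alpha, tolerance = 1e-12)
  flagged <- magnetometer_heading(level, c(0, 0, 1))
  expect_true(is.na(flagged) && isTRUE(attr(flagged, "flagged")))
})

test_that("gyroscope heading integrates yaw and preserves the quaternion norm", {
  level <- euler_angles(c(0, 0, 1), c(1, 0, 0))
  st <- heading_state()
  st0 <- gyroscope_heading_step(st, c(0, 0, 0), level, 0.01)
  expect_equal(st0$H_G, 0)
  expect_equal(st0$q, c(1, 0, 0, 0))

  for (i in 1:1000) st <- gyroscope_heading_step(st, c(0, 0, 0.1), level, 0.01)
  expect_equal(st$H_G, 1.0, tolerance = 0.02)

  st2 <- heading_state()
  for (i in 1:10000)
    st2 <- gyroscope_heading_step(st2, c(0.05, 0.02, 0.1), level, 0.005)
  expect_lt(abs(sqrt(sum(st2$q^2)) - 1), 1e-9)

  for (alpha in c(pi / 6, pi / 2))
    expect_equal(imupipe:::quat_yaw(c(cos(alpha / 2), 0, 0, sin(alpha / 2))),
                 alpha)
  expect_error(gyroscope_heading_step(
    structure(list(q = c(2, 0, 0, 0)), class = "heading_state"),
    c(0, 0, 0), level, 0.01), "state error")
})

test_that("heading fusion is the circular mean with antipodal fallback", {
  expect_equal(fuse_heading(0.7, 0.7), 0.7)
  expect_equal(fuse_heading(10 * pi / 180, 20 * pi / 180), 15 * pi / 180)
  expect_equal(fuse_heading(350 * pi / 180, 10 * pi / 180), 0, tolerance = 1e-9)
  anti <- fuse_heading(0, pi)
  expect_true(isTRUE(attr(anti, "flagged")))
  expect_equal(as.numeric(anti), wrap_angle(pi))
})

test_that("heading pipeline is world-rotation-equivariant", {
  # exact attitude (level device, z-only forces) so tilt compensation is exact;
  # gait/noise-induced attitude error would blur equivariance (see vignette)
  base <- generate_recording(scenario_spec(
    "standing", "home", duration_s = 15, seed = 21, acc_noise = 0,
    mag_noise = 0, gyr_noise = 0,
    heading_profile = data.frame(t_start = 0, rate = 0.05)))
  h0 <- heading_track(base$channels$acc$data, base$channels$gyr$data,
                      base$channels$mag$data, base$fs)
  for (alpha in c(30, -120) * pi / 180) {
    rot <- base
    # rotate the magnetometer's horizontal field by alpha (compass convention)
    mx <- base$channels$mag$data[, 1]; my <- base$channels$mag$data[, 2]
    rot$channels$mag$data[, 1] <- cos(alpha) * mx - sin(alpha) * my
    rot$channels$mag$data[, 2] <- sin(alpha) * mx + cos(alpha) * my
    h1 <- heading_track(rot$channels$acc$data, rot$channels$gyr$data,
                        rot$channels$mag$data, base$fs)
    for (col in c("H_M", "H_G", "H_fused")) {
      dh <- imupipe:::wrap_angle(h1[[col]] - h0[[col]] - alpha)
      expect_lt(max(abs(dh), na.rm = TRUE), 1e-3)
    }
  }
})

test_that("LOC bank counts synthetic gait steps and flags absent channels", {
  rec <- make_walk_recording(duration_s = 15, step_rate = 2, seed = 13)
  st <- stack_windows(segment_windows(rec),
                      activity_label = "walking", location_label = "home")[[1]]
  fv <- extract_loc_features(st)
  expect_equal(fv$values[fv$layout$feature == "step_count"], 30, tolerance = 2 / 30)
  expect_length(fv$values, 23)
  expect_identical(extract_loc_features(st)$values, fv$values)

  # stationary, noise-free: zero steps and near-zero heading spread
  calm <- generate_recording(scenario_spec("sitting", "home", duration_s = 15,
                                           seed = 3, acc_noise = 0,
                                           turns = 0, mag_noise = 0))
  stc <- stack_windows(segment_windows(calm))[[1]]
  fvc <- extract_loc_features(stc)
  expect_equal(fvc$values[fvc$layout$feature == "step_count"], 0)
  expect_lt(fvc$values[fvc$layout$feature == "heading_sd"], 0.05)

  rec$channels$gyr <- NULL
  st2 <- stack_windows(segment_windows(rec))
  expect_error(extract_loc_features(st2[[1]]), "precondition.*gyr")
})
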