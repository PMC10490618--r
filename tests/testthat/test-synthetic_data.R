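test_that("generated recordings are seeded, labeled and well-formed", {
  sp <- scenario_spec("walking", "street", duration_s = 15, seed = 42)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1$channels$acc$data, r2$channels$acc$data)
  expect_identical(r1$channels$audio$data, r2$channels$audio$data)
  expect_equal(r1$activity_label, "walking")
  expect_equal(r1$location_label, "street")
  expect_true(all(c("acc", "gyr", "mag", "audio", "gps") %in% names(r1$channels)))
  expect_error(scenario_spec("flying", "home"), "unknown activity")
  expect_error(scenario_spec("walking", "moon"), "unknown location")
  expect_error(scenario_spec("walking", "home", duration_s = 5), ">= 15")
})

test_that("gait cadence is recovered by the step detector", {
  sp <- scenario_spec("walking", "home", duration_s = 30, seed = 1,
                      step_rate_hz = 2)
  rec <- generate_recording(sp)
  m <- acceleration_magnitude(rec$channels$acc$data)
  ev <- detect_steps(m, rec$fs)
  expect_equal(length(ev$peak_indices), 60, tolerance = 3 / 60)
})

test_that("sitting recordings are near-still compared to walking", {
  sit <- generate_recording(scenario_spec("sitting", "home", seed = 2))
  walk <- generate_recording(scenario_spec("walking", "home", seed = 2))
  vs <- stats::var(acceleration_magnitude(sit$channels$acc$data))
  vw <- stats::var(acceleration_magnitude(walk$channels$acc$data))
  expect_lt(vs, 0.05 * vw)
  # noise-free stationary magnitude yields zero steps
  calm <- generate_recording(scenario_spec("sitting", "home", seed = 2,
                                           acc_noise = 0))
  expect_length(detect_steps(acceleration_magnitude(calm$channels$acc$data),
                             calm$fs)$peak_indices, 0)
})

test_that("a programmed turn is recovered by the heading pipeline", {
  sp <- scenario_spec("walking", "home", duration_s = 20, seed = 5,
                      heading_profile = data.frame(t_start = c(0, 9, 11),
                                                   rate = c(0, pi / 4, 0)))
  rec <- generate_recording(sp)
  ht <- heading_track(rec$channels$acc$data, rec$channels$gyr$data,
                      rec$channels$mag$data, rec$fs)
  uw <- imupipe:::unwrap_angle(ht$H_fused)
  expect_equal(uw[length(uw)] - uw[1], pi / 2, tolerance = 0.05)
})

test_that("generator ground truth is recovered across seeded scenarios", {
  ok_steps <- 0; ok_head <- 0; n_trial <- 20
  for (s in seq_len(n_trial)) {
    sp <- scenario_spec("walking", "home", duration_s = 20, seed = 300 + s,
                        heading_profile = data.frame(t_start = c(0, 8, 10),
                                                     rate = c(0, pi / 4, 0)))
    rec <- generate_recording(sp)
    m <- acceleration_magnitude(rec$channels$acc$data)
    n_steps <- length(detect_steps(m, rec$fs)$peak_indices)
    if (abs(n_steps - 40) <= 3) ok_steps <- ok_steps + 1
    ht <- heading_track(rec$channels$acc$data, rec$channels$gyr$data,
                        rec$channels$mag$data, rec$fs)
    uw <- imupipe:::unwrap_angle(ht$H_fused)
    if (abs((uw[length(uw)] - uw[1]) - pi / 2) < 0.1) ok_head <- ok_head + 1
  }
  expect_gte(ok_steps / n_trial, 0.95)
  expect_gte(ok_head / n_trial, 0.95)
})

test_that("datasets are balanced, jittered and reproducible", {
  templates <- list(scenario_spec("sitting", "home", duration_s = 15),
                    scenario_spec("walking", "street", duration_s = 15))
  recs <- generate_dataset(3, templates, seed = 9)
  expect_length(recs, 6)
  expect_equal(as.numeric(table(vapply(recs, `[[`, "", "activity_label"))),
               c(3, 3))
  recs2 <- generate_dataset(3, templates, seed = 9)
  expect_identical(recs[[4]]$channels$acc$data, recs2[[4]]$channels$acc$data)
  # jitter differentiates recordings of one class
  expect_false(identical(recs[[4]]$channels$acc$data,
                         recs[[5]]$channels$acc$data))
  expect_error(generate_dataset(0, templates), "n_per_class")
  expect_error(generate_dataset(2, list()), "empty template")
})

test_that("activity classes are separable by at least one feature mean", {
  # 3-pooled-sigma separation, checked on a cheap feature (acc magnitude SD)
  feats <- lapply(names(imupipe:::activity_presets()), function(a) {
    vapply(1:8, function(s) {
      rec <- generate_recording(scenario_spec(a, "home", duration_s = 15,
                                              seed = 400 + s))
      stats::sd(acceleration_magnitude(rec$channels$acc$data))
    }, 0)
  })
  names(feats) <- names(imupipe:::activity_presets())
  combs <- utils::combn(names(feats), 2)
  for (k in seq_len(ncol(combs))) {
    a <- feats[[combs[1, k]]]; b <- feats[[combs[2, k]]]
    pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
    expect_gte(abs(mean(a) - mean(b)) / pooled, 3)
  }
})

test_that("recordings survive the CSV round trip through the generic reader", {
  rec <- generate_recording(scenario_spec("walking", "street", duration_s = 15,
                                          seed = 77))
  stem <- tempfile("rec_")
  write_recording_csv(rec, stem)
  lab <- data.frame(stem = basename(stem), activity = "walking",
                    location = "street")
  utils::write.csv(lab, file.path(dirname(stem), "labels.csv"),
                   row.names = FALSE)
  back <- imupipe:::read_recording_dir(dirname(stem))
  expect_length(back, 1)
  expect_lt(max(abs(back[[1]]$channels$acc$data - rec$channels$acc$data)), 1e-9)
  expect_lt(max(abs(back[[1]]$channels$audio$data - rec$channels$audio$data)),
            1e-9)
  expect_equal(back[[1]]$activity_label, "walking")
})
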