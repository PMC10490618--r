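test_that("generic CSV reader parses channels and normalizes timestamps", {
  p <- write_acc_csv(t = c(10, 10.5, 11), ax = 1:3, ay = 4:6, az = 7:9)
  rec <- read_generic_csv(p)
  expect_s3_class(rec, "sensor_recording")
  expect_named(rec$channels, "acc")
  expect_equal(nrow(rec$channels$acc$data), 3)
  expect_equal(rec$channels$acc$timestamps, c(0, 0.5, 1))
  expect_equal(rec$channels$acc$data[, 2], c(4, 5, 6))
})

test_that("reader rejects bad schemas and non-monotone timestamps", {
  p <- write_acc_csv(t = c(0, 1, 1), ax = 1:3, ay = 1:3, az = 1:3)
  expect_error(read_generic_csv(p), "row 3")
  p2 <- write_acc_csv(t = 0:2, ax = 1:3, ay = 1:3, az = 1:3)
  expect_error(
    read_generic_csv(p2, generic_schema("t", list(gyr = c("gyr_x")))),
    "schema error")
})

test_that("write -> read round-trip is value-stable to 1e-9", {
  set.seed(4)
  t <- seq(0, 2, by = 0.05)
  rec <- sensor_recording(list(
    acc = raw_channel("acc", matrix(rnorm(3 * length(t)), ncol = 3), t, 20),
    gyr = raw_channel("gyr", matrix(rnorm(3 * length(t)), ncol = 3), t, 20)))
  p <- tempfile(fileext = ".csv")
  write_generic_csv(rec, p)
  back <- read_generic_csv(p)
  for (nm in c("acc", "gyr")) {
    expect_lt(max(abs(back$channels[[nm]]$data - rec$channels[[nm]]$data)), 1e-9)
    expect_lt(max(abs(back$channels[[nm]]$timestamps - t)), 1e-9)
  }
})

test_that("align_and_resample interpolates onto the overlap and is idempotent", {
  # 1 Hz ramp resampled to 2 Hz: midpoints are means of neighbours
  ramp <- raw_channel("acc", cbind(0:10, 0:10, 0:10), 0:10, 1)
  rec <- sensor_recording(list(acc = ramp))
  out <- align_and_resample(rec, fs = 2)
  v <- out$channels$acc$data[, 1]
  expect_equal(v[2], 0.5)
  expect_equal(v[seq(1, 21, by = 2)], as.numeric(0:10))

  # channel already uniform at fs stays unchanged at grid points
  t <- seq(0, 5, by = 1 / 40)
  ch <- raw_channel("acc", matrix(sin(t), ncol = 1), t, 40)
  rec2 <- sensor_recording(list(acc = ch))
  out2 <- align_and_resample(rec2, fs = 40)
  expect_equal(out2$channels$acc$data[, 1], sin(t), tolerance = 1e-12)

  # two channels offset by 1 s: output spans only the intersection
  a <- raw_channel("acc", matrix(0:40 / 10, ncol = 1), seq(0, 4, by = 0.1), 10)
  g <- raw_channel("gyr", matrix(0:40 / 10, ncol = 1), seq(1, 5, by = 0.1), 10)
  out3 <- align_and_resample(sensor_recording(list(acc = a, gyr = g)), fs = 10)
  expect_equal(out3$duration_s, 3)
  expect_equal(nrow(out3$channels$acc$data), 31)

  # idempotence
  out4 <- align_and_resample(out3, fs = 10)
  expect_equal(out4$channels$acc$data, out3$channels$acc$data, tolerance = 1e-12)
  expect_error(align_and_resample(sensor_recording(list(
    acc = raw_channel("acc", matrix(1:3, ncol = 1), 0:2, 1),
    gyr = raw_channel("gyr", matrix(1:3, ncol = 1), 10:12, 1))), fs = 1),
    "overlap")
})

test_that("raw_channel enforces its invariants", {
  expect_error(raw_channel("acc", matrix(1:9, ncol = 3), c(0, 0.1, 0.1), 10),
               "strictly increasing")
  expect_error(raw_channel("acc", matrix(1:9, ncol = 3), c(0, 0.1), 10),
               "timestamps")
})

test_that("ExtraSensory adapter reads intervals and maps labels", {
  root <- make_extrasensory_fixture()
  recs <- read_extrasensory(root)
  expect_length(recs, 2)
  expect_setequal(vapply(recs, `[[`, "", "activity_label"),
                  c("sitting", "strolling"))
  expect_setequal(vapply(recs, `[[`, "", "location_label"),
                  c("at_home", "outdoor"))
  expect_true(all(vapply(recs, function(r)
    all(c("acc", "gyr", "mag") %in% names(r$channels)), TRUE)))

  # interval without magnetometer is flagged and later fails HAR precondition
  root2 <- make_extrasensory_fixture(drop_mag = TRUE)
  recs2 <- read_extrasensory(root2)
  flagged <- recs2[[which(!vapply(recs2, `[[`, TRUE, "complete_imu"))]]
  al <- align_and_resample(flagged, fs = 40)
  w <- segment_windows(al)
  st <- stack_windows(w)
  expect_error(extract_har_features(st[[1]]), "precondition")
})

test_that("SHL adapter segments label runs and maps Still to standing", {
  root <- make_shl_fixture(codes = c(1, 2))
  recs <- read_shl(root)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$activity_label, "standing")
  expect_equal(recs[[2]]$activity_label, "walking")
  expect_equal(recs[[1]]$location_label, "indoor")
  # unknown codes are skipped with a warning
  root2 <- make_shl_fixture(codes = c(1, 99))
  expect_warning(recs2 <- read_shl(root2), "unknown label")
  expect_length(recs2, 1)
})
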