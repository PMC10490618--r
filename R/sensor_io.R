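# --- generic CSV reader/writer -------------------------------------------

#' Column schema for the generic CSV layout
#'
#' @param time name of the timestamp column (seconds or any monotone unit).
#' @param channels named list mapping channel name to the character vector of
#'   its value columns, e.g. `list(acc = c("acc_x","acc_y","acc_z"))`.
#' @param rate_hz optional named numeric vector of nominal rates; estimated
#'   from the median timestamp spacing when absent.
#' @return A list of class `"generic_schema"`.
#' @export
generic_schema <- function(time = "t", channels, rate_hz = NULL) {
  stopifnot(is.character(time), is.list(channels), length(channels) >= 1)
  structure(list(time = time, channels = channels, rate_hz = rate_hz),
            class = "generic_schema")
}

# Infer a schema from a header: first column is time, remaining columns are
# grouped by the prefix before the last underscore ("acc_x" -> channel "acc").
infer_schema <- function(cols) {
  value_cols <- cols[-1]
  pref <- sub("_[^_]*$", "", value_cols)
  pref[pref == value_cols] <- value_cols[pref == value_cols]
  generic_schema(time = cols[1],
                 channels = split(value_cols, factor(pref, unique(pref))))
}

#' Read a multi-channel recording from a single CSV file
#'
#' Expects a header row, one timestamp column and one column per sensor axis.
#' Timestamps are converted to seconds relative to the recording start.
#'
#' @param path CSV file path.
#' @param schema a [generic_schema()]; when `NULL` the schema is inferred from
#'   the header (first column = time, remaining columns grouped by the prefix
#'   before the last underscore).
#' @param activity_label,location_label,subject_id optional labels.
#' @return A [sensor_recording].
#' @export
read_generic_csv <- function(path, schema = NULL, activity_label = NA_character_,
                             location_label = NA_character_, subject_id = "s1") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(schema)) schema <- infer_schema(names(df))
  need <- c(schema$time, unlist(schema$channels, use.names = FALSE))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("schema error: column(s) %s not present in %s",
          paste(missing_cols, collapse = ", "), path)
  t_raw <- as.numeric(df[[schema$time]])
  if (length(t_raw) > 1) {
    bad <- which(diff(t_raw) <= 0)
    if (length(bad))
      stopf("format error: non-monotone timestamp at row %d of %s",
            bad[1] + 1L, path)
  }
  t_rel <- t_raw - t_raw[1]
  chans <- lapply(names(schema$channels), function(nm) {
    cols <- schema$channels[[nm]]
    dat <- as.matrix(df[cols])
    rate <- schema$rate_hz[[nm]] %||%
      (if (length(t_rel) > 1) 1 / stats::median(diff(t_rel)) else NA_real_)
    raw_channel(nm, dat, t_rel, rate)
  })
  names(chans) <- names(schema$channels)
  sensor_recording(chans, activity_label = activity_label,
                   location_label = location_label, subject_id = subject_id)
}

#' Write a recording to the generic single-file CSV layout
#'
#' Only channels sharing the timestamp grid of the first channel are written
#' (audio/GPS on their own grids are skipped with a warning); this is the
#' inverse of [read_generic_csv()] for aligned recordings.
#'
#' @param rec a [sensor_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generic_csv <- function(rec, path) {
  ref <- rec$channels[[1]]$timestamps
  out <- data.frame(t = ref)
  for (ch in rec$channels) {
    if (length(ch$timestamps) != length(ref) ||
        max(abs(ch$timestamps - ref)) > 1e-9) {
      warnf("channel '%s' is not on the reference grid; skipped", ch$name)
      next
    }
    m <- ch$data
    ax <- colnames(m) %||% letters[24:(23 + ncol(m))]
    if (is.null(colnames(m))) ax <- c("x", "y", "z", "w")[seq_len(ncol(m))]
    for (j in seq_len(ncol(m))) out[[paste(ch$name, ax[j], sep = "_")]] <- m[, j]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# --- alignment -----------------------------------------------------------

#' Align and resample the inertial channels of a recording
#'
#' Linearly interpolates every inertial channel (acc, gyr, mag) onto a common
#' uniform grid at `fs` Hz over the overlapping time span, re-zeroed so the
#' grid starts at t = 0. Audio keeps its native (usually higher) rate and GPS
#' its own, both cropped to the same span. Idempotent.
#'
#' @param rec a [sensor_recording].
#' @param fs target inertial sampling rate in Hz (default 40).
#' @return The aligned [sensor_recording] with `fs` set.
#' @export
align_and_resample <- function(rec, fs = 40) {
  imu <- intersect(names(rec$channels), c("acc", "gyr", "mag"))
  if (!length(imu)) stopf("alignment error: no inertial channels present")
  spans <- vapply(rec$channels, function(ch)
    c(ch$timestamps[1], ch$timestamps[length(ch$timestamps)]), c(0, 0))
  t0 <- max(spans[1, ]); t1 <- min(spans[2, ])
  if (t1 - t0 < 1 / fs)
    stopf("alignment error: channels have empty (or sub-sample) overlap")
  grid <- seq(t0, t1, by = 1 / fs)
  out <- rec$channels
  for (nm in imu) {
    ch <- out[[nm]]
    dat <- vapply(seq_len(ncol(ch$data)), function(j)
      stats::approx(ch$timestamps, ch$data[, j], xout = grid)$y,
      numeric(length(grid)))
    colnames(dat) <- colnames(ch$data)
    out[[nm]] <- raw_channel(nm, dat, grid - t0, fs)
  }
  for (nm in setdiff(names(out), imu)) {
    ch <- out[[nm]]
    keep <- ch$timestamps >= t0 - 1e-12 & ch$timestamps <= t1 + 1e-12
    out[[nm]] <- raw_channel(nm, ch$data[keep, , drop = FALSE],
                             ch$timestamps[keep] - t0, ch$rate_hz)
  }
  res <- sensor_recording(out, fs = fs, activity_label = rec$activity_label,
                          location_label = rec$location_label,
                          subject_id = rec$subject_id)
  res$duration_s <- t1 - t0
  res
}

# --- dataset adapters ----------------------------------------------------

#' Default label maps for the public dataset adapters
#'
#' Maps dataset-native label strings/codes to this package's canonical class
#' names (8 activities / 8 locations for the ExtraSensory layout, 4 / 6 for
#' the SHL layout). Users may supply edited copies to the adapters.
#'
#' @return A nested list with `extrasensory` and `shl` entries.
#' @export
default_label_maps <- function() {
  list(
    extrasensory = list(
      activity = c(SITTING = "sitting", LYING_DOWN = "lying_down",
                   OR_standing = "standing", BICYCLING = "bicycling",
                   FIX_running = "running", FIX_walking = "strolling",
                   STAIRS_UP = "stairs_up", STAIRS_DOWN = "stairs_down"),
      location = c(LOC_home = "at_home", IN_CLASS = "in_class",
                   LOC_main_workplace = "at_workplace", AT_SCHOOL = "at_school",
                   OR_indoors = "indoor", OR_outside = "outdoor",
                   AT_THE_GYM = "at_gym", AT_THE_BEACH = "at_beach")),
    shl = list(
      # coarse SHL codes 1..8; "Still" maps to standing per the configured map
      activity = c(`1` = "standing", `2` = "walking", `3` = "running",
                   `4` = NA, `5` = "sitting", `6` = "sitting",
                   `7` = "sitting", `8` = "sitting"),
      location = c(`1` = "indoor", `2` = "outdoor", `3` = "outdoor",
                   `4` = "outdoor", `5` = "car", `6` = "bus",
                   `7` = "train", `8` = "subway"),
      names = c(Still = 1, Walking = 2, Run = 3, Bike = 4, Car = 5,
                Bus = 6, Train = 7, Subway = 8))
  )
}

#' Read an ExtraSensory-style directory of labeled intervals
#'
#' Expects the unzipped per-UUID text layout: `dir/<uuid>/<interval>.m_raw_acc.dat`
#' (whitespace-separated `t x y z`), likewise `.m_raw_gyro.dat` and
#' `.m_raw_magnet.dat`, plus `dir/<uuid>/labels.csv` with columns
#' `interval,activity,location`. One [sensor_recording] per labeled interval;
#' intervals with unknown labels are skipped with a warning, and intervals
#' missing the magnetometer are kept but flagged (downstream activity features
#' will raise a precondition error).
#'
#' @param dir dataset root directory.
#' @param label_map list with `activity` and `location` named vectors; see
#'   [default_label_maps()].
#' @return A list of [sensor_recording] objects.
#' @export
read_extrasensory <- function(dir, label_map = default_label_maps()$extrasensory) {
  uuids <- list.dirs(dir, recursive = FALSE)
  recs <- list()
  read_dat <- function(f) utils::read.table(f, col.names = c("t", "x", "y", "z"))
  for (ud in uuids) {
    lab_file <- file.path(ud, "labels.csv")
    if (!file.exists(lab_file)) next
    labs <- utils::read.csv(lab_file, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(labs))) {
      iv <- as.character(labs$interval[i])
      act <- unname(label_map$activity[labs$activity[i]])
      loc <- unname(label_map$location[labs$location[i]])
      if (is.na(act) && is.na(loc)) {
        warnf("extrasensory: unknown labels '%s'/'%s' in %s; interval skipped",
              labs$activity[i], labs$location[i], basename(ud))
        next
      }
      files <- c(acc = file.path(ud, paste0(iv, ".m_raw_acc.dat")),
                 gyr = file.path(ud, paste0(iv, ".m_raw_gyro.dat")),
                 mag = file.path(ud, paste0(iv, ".m_raw_magnet.dat")))
      chans <- list()
      for (nm in names(files)) {
        if (!file.exists(files[[nm]])) next
        d <- read_dat(files[[nm]])
        rate <- if (nrow(d) > 1) 1 / stats::median(diff(d$t)) else NA_real_
        chans[[nm]] <- raw_channel(nm, as.matrix(d[c("x", "y", "z")]),
                                   d$t - d$t[1], rate)
      }
      if (!length(chans)) next
      rec <- sensor_recording(chans, activity_label = act, location_label = loc,
                              subject_id = basename(ud))
      rec$complete_imu <- all(c("acc", "gyr", "mag") %in% names(chans))
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}

#' Read a Sussex-Huawei-Locomotion-style directory
#'
#' Expects per-recording subdirectories each holding whitespace-separated
#' `Acc.txt`, `Gyr.txt`, `Mag.txt` (`t_ms x y z`) and `Label.txt`
#' (`t_ms code`, coarse codes 1-8). Each maximal run of a single label code
#' becomes one [sensor_recording]; unknown codes are skipped with a warning.
#'
#' @param dir dataset root directory.
#' @param label_map list with `activity` and `location` vectors indexed by
#'   code; see [default_label_maps()].
#' @return A list of [sensor_recording] objects.
#' @export
read_shl <- function(dir, label_map = default_label_maps()$shl) {
  days <- list.dirs(dir, recursive = FALSE)
  recs <- list()
  for (dd in days) {
    need <- file.path(dd, c("Acc.txt", "Gyr.txt", "Mag.txt", "Label.txt"))
    if (!all(file.exists(need))) next
    imu <- lapply(need[1:3], utils::read.table,
                  col.names = c("t", "x", "y", "z"))
    names(imu) <- c("acc", "gyr", "mag")
    lab <- utils::read.table(need[4], col.names = c("t", "code"))
    runs <- rle(lab$code)
    ends <- cumsum(runs$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    for (k in seq_along(runs$values)) {
      code <- as.character(runs$values[k])
      if (!code %in% names(label_map$activity)) {
        warnf("shl: unknown label code '%s' in %s; segment skipped", code,
              basename(dd))
        next
      }
      t0 <- lab$t[starts[k]] / 1000; t1 <- lab$t[ends[k]] / 1000
      chans <- list()
      for (nm in names(imu)) {
        d <- imu[[nm]]
        ts <- d$t / 1000
        keep <- ts >= t0 & ts <= t1
        if (sum(keep) < 2) next
        rate <- 1 / stats::median(diff(ts[keep]))
        chans[[nm]] <- raw_channel(nm, as.matrix(d[keep, c("x", "y", "z")]),
                                   ts[keep] - ts[keep][1], rate)
      }
      if (length(chans) < 3) next
      recs[[length(recs) + 1L]] <- sensor_recording(
        chans, activity_label = unname(label_map$activity[code]),
        location_label = unname(label_map$location[code]),
        subject_id = basename(dd))
    }
  }
  recs
}
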