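# End-to-end orchestration: denoise -> window/stack -> dual feature banks ->
# RFE -> GA augmentation -> two parallel DNDF classifiers, evaluated by
# stratified k-fold cross-validation with augmentation applied to training
# splits only.

#' Pipeline configuration
#'
#' Nested configuration covering every stage's tunables. Unknown keys are
#' rejected, so typos fail loudly before any stage runs. Note the filter
#' default: the denoiser runs as a 10 Hz low-pass (`cutoff_units = "hz"`),
#' which strips sensor noise while keeping the 0-4 Hz gait band; the literal
#' normalized 0.001 cutoff of [butterworth_denoise()] is available via
#' `filter$cutoff`/`filter$cutoff_units` but removes the entire motion band
#' at inertial rates (see the vignette).
#'
#' @param ... overrides as nested lists, e.g.
#'   `pipeline_config(dndf = list(epochs = 10), eval = list(folds = 5))`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    filter = list(order = 2, cutoff = 10, cutoff_units = "hz"),
    window = list(seconds = 5),
    stack = list(size = 3, stride = 1),
    features = list(har = har_feature_config(), loc = loc_feature_config()),
    select = list(keep_frac = 0.5, step_frac = 0.05, lambda = 1e-2),
    ga = list(n_generations = 10, same_class = TRUE, chained = FALSE),
    dndf = list(embed_dim = 128, hidden_layers = c(512, 256), n_trees = 10,
                tree_depth = 6, epochs = 15, batch_size = 128,
                learning_rate = 2e-3, class_weights = "none"),
    eval = list(folds = 10),
    seed = 1
  )
  cfg <- utils::modifyList(defaults, list(...))
  check_keys <- function(given, ref, path = "") {
    extra <- setdiff(names(given), names(ref))
    if (length(extra))
      stopf("config error: unknown key(s) %s%s", path,
            paste(extra, collapse = ", "))
    for (nm in names(given))
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
        check_keys(given[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  check_keys(list(...), defaults)
  structure(cfg, class = "pipeline_config")
}

# feature banks for a list of labeled recordings; returns matrices + labels
pipeline_features <- function(recordings, cfg, progress = FALSE) {
  har <- list(); loc <- list(); act <- character(0); locl <- character(0)
  layout_har <- NULL; layout_loc <- NULL
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    rec <- denoise_recording(rec, order = cfg$filter$order,
                             cutoff = cfg$filter$cutoff,
                             cutoff_units = cfg$filter$cutoff_units)
    wins <- suppressWarnings(segment_windows(rec, cfg$window$seconds))
    stacks <- suppressWarnings(
      stack_windows(wins, cfg$stack$size, cfg$stack$stride,
                    activity_label = rec$activity_label,
                    location_label = rec$location_label))
    for (st in stacks) {
      hv <- extract_har_features(st, cfg$features$har)
      lv <- extract_loc_features(st, cfg$features$loc)
      har[[length(har) + 1L]] <- hv$values
      loc[[length(loc) + 1L]] <- lv$values
      act <- c(act, st$activity_label)
      locl <- c(locl, st$location_label)
      layout_har <- layout_har %||% hv$layout
      layout_loc <- layout_loc %||% lv$layout
    }
    if (progress && ri %% 10 == 0)
      message(sprintf("  features: %d/%d recordings", ri, length(recordings)))
  }
  list(har = do.call(rbind, har), loc = do.call(rbind, loc),
       activity = act, location = locl,
       layout_har = layout_har, layout_loc = layout_loc)
}

# one task (activity or location): CV with per-fold RFE + GA + DNDF
pipeline_task_cv <- function(X, y, cfg, task_seed) {
  n_keep <- max(2L, ceiling(cfg$select$keep_frac * ncol(X)))
  selections <- list()
  train_fn <- function(Xtr, ytr) {
    sel <- rfe_select(Xtr[, , drop = FALSE], ytr, n_keep,
                      step_frac = cfg$select$step_frac,
                      lambda = cfg$select$lambda)
    selections[[length(selections) + 1L]] <<- sel$kept_indices
    aug <- ga_augment(Xtr[, sel$kept_indices, drop = FALSE], ytr,
                      n_generations = cfg$ga$n_generations,
                      seed = task_seed + length(selections),
                      same_class = cfg$ga$same_class,
                      chained = cfg$ga$chained)
    model <- dndf(aug$X, aug$y, embed_dim = cfg$dndf$embed_dim,
                  hidden_layers = cfg$dndf$hidden_layers,
                  n_trees = cfg$dndf$n_trees, tree_depth = cfg$dndf$tree_depth,
                  epochs = cfg$dndf$epochs, batch_size = cfg$dndf$batch_size,
                  learning_rate = cfg$dndf$learning_rate,
                  seed = task_seed, class_weights = cfg$dndf$class_weights)
    model$kept_indices <- sel$kept_indices
    class(model) <- c("dndf_selected", class(model))
    model
  }
  cv <- cross_validate(X, y, folds = cfg$eval$folds, seed = task_seed,
                       train_fn = train_fn)
  cv$selections <- selections
  cv
}

#' @export
predict.dndf_selected <- function(object, newdata, ...) {
  base <- object
  class(base) <- setdiff(class(object), "dndf_selected")
  predict(base, as.matrix(newdata)[, object$kept_indices, drop = FALSE], ...)
}

#' Run the full pipeline on a set of labeled recordings
#'
#' Denoises, windows, stacks, extracts both feature banks, and evaluates the
#' two parallel classifiers by stratified cross-validation (RFE and GA
#' augmentation are refit inside each training fold; the evaluation split
#' never sees offspring vectors). Stage artifacts — feature CSVs with layout
#' headers, per-fold selections (JSON), per-task metrics (JSON) and a run
#' manifest recording the configuration and seed — are written to `out_dir`.
#'
#' @param recordings list of labeled [sensor_recording] objects, or a
#'   directory of generic CSV recordings written by [write_recording_csv()]
#'   with a `labels.csv` (columns `stem,activity,location`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   artifact writing.
#' @param progress emit per-stage progress messages.
#' @return List with `metrics` (per task: fold metrics and aggregate
#'   accuracies), `features`, and the `manifest`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  if (is.character(recordings)) recordings <- read_recording_dir(recordings)
  stopifnot(length(recordings) >= 2)
  if (progress) message("extracting features ...")
  fx <- pipeline_features(recordings, config, progress = progress)
  metrics <- list()
  for (task in c("activity", "location")) {
    y <- fx[[task]]
    X <- if (task == "activity") fx$har else fx$loc
    keep_rows <- !is.na(y)
    if (progress) message(sprintf("cross-validating %s (%d stacks) ...",
                                  task, sum(keep_rows)))
    metrics[[task]] <- pipeline_task_cv(X[keep_rows, , drop = FALSE],
                                        y[keep_rows], config,
                                        task_seed = config$seed +
                                          ifelse(task == "activity", 0L, 1000L))
  }
  manifest <- list(
    seed = config$seed, folds = config$eval$folds,
    n_recordings = length(recordings), n_stacks = nrow(fx$har),
    config = unclass(config),
    accuracy = lapply(metrics, function(m)
      list(accuracy = m$accuracy, macro_accuracy = m$macro_accuracy)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (bank in c("har", "loc")) {
      m <- fx[[bank]]
      colnames(m) <- make.unique(apply(
        fx[[paste0("layout_", bank)]][c("feature", "channel", "axis", "window")],
        1, paste, collapse = "."))
      utils::write.csv(
        cbind(data.frame(activity = fx$activity, location = fx$location), m),
        file.path(out_dir, paste0("features_", bank, ".csv")), row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(metrics, function(m) list(
        accuracy = m$accuracy, macro_accuracy = m$macro_accuracy,
        folds = lapply(m$fold_metrics, function(f)
          f[c("accuracy", "macro_accuracy", "precision", "recall", "f1")]))),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(lapply(metrics, `[[`, "selections"),
                         file.path(out_dir, "selections.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(metrics = metrics, features = fx, manifest = manifest)
}

# read a directory of write_recording_csv() outputs plus labels.csv
read_recording_dir <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lab)), function(i) {
    stem <- file.path(dir, lab$stem[i])
    rec <- read_generic_csv(paste0(stem, ".csv"),
                            activity_label = lab$activity[i],
                            location_label = lab$location[i])
    af <- paste0(stem, "_audio.csv")
    if (file.exists(af)) {
      a <- utils::read.csv(af)
      rec$channels$audio <- raw_channel("audio", a$audio, a$t,
                                        1 / stats::median(diff(a$t)))
    }
    gf <- paste0(stem, "_gps.csv")
    if (file.exists(gf)) {
      g <- utils::read.csv(gf)
      rec$channels$gps <- raw_channel("gps", cbind(lat = g$lat, lon = g$lon),
                                      g$t, 1)
    }
    rec$fs <- rec$channels$acc$rate_hz
    rec
  })
}
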