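#' Default pipeline configuration
#'
#' Nested configuration for the full measurement flow: segmentation ->
#' detection -> features -> statistics, mirroring each stage's config type.
#' [read_config()] merges a YAML file over these defaults; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @return nested list with sections `segmentation`, `detector`, `features`,
#'   `stats`, and `output_dir`.
#' @export
default_config <- function() {
  list(
    segmentation = list(backend = "threshold", intensity_thr = 80, morph_radius = 2),
    detector     = list(ca_thr = 300, as_thr = 0.4, ca_max = NULL),
    features     = list(delta_thr = "auto", smoothing_window = 1),
    stats        = list(test = "welch_t"),
    output_dir   = "."
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(user)) {
    if (!sec %in% names(base)) stop("unknown config section: ", sec)
    if (is.list(base[[sec]])) {
      for (k in names(user[[sec]])) {
        if (!k %in% names(base[[sec]]))
          stop("unknown config key: ", sec, ".", k)
        base[[sec]][[k]] <- user[[sec]][[k]]
      }
    } else base[[sec]] <- user[[sec]]
  }
  base
}

#' Run the full visual-fatigue measurement pipeline on one recording
#'
#' Stages run in the order appropriate to the recording's source kind: image
#' recordings are segmented and detected; mask recordings skip segmentation;
#' trace recordings go straight to feature extraction. Intermediate artifacts
#' (the pupil-size trace, per-frame detections, the feature row) are always
#' written to `output_dir` so any stage can be audited.
#'
#' @param recording an `eye_recording` (see [recording_from_frames()] /
#'   [read_image_sequence()] and friends).
#' @param config a configuration list as from [default_config()] /
#'   [read_config()].
#' @param segment_id,condition labels written to the feature table.
#' @return list with `series` (a [pupil_ts()]), `features` (a
#'   `fatigue_features`), and `paths` of the written artifacts.
#' @export
run_pipeline <- function(recording, config = default_config(),
                         segment_id = "seg1", condition = "reference") {
  stopifnot(inherits(recording, "eye_recording"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (recording$kind == "images") {
    sc <- config$segmentation
    recording <- tryCatch(
      segment_recording(recording, segmenter_config(sc$backend, sc$intensity_thr,
                                                    sc$morph_radius)),
      error = function(e) stop("segmentation stage failed: ", conditionMessage(e)))
  }
  if (recording$kind == "masks") {
    dc <- config$detector
    series <- tryCatch(
      detect_sequence(recording, detector_config(dc$ca_thr, dc$as_thr, dc$ca_max),
                      details = TRUE),
      error = function(e) stop("detection stage failed: ", conditionMessage(e)))
    paths$detections <- file.path(out_dir, "detections.csv")
    utils::write.csv(attr(series, "measurements"), paths$detections,
                     row.names = FALSE, quote = FALSE)
  } else {
    series <- recording$payload
  }
  paths$trace <- file.path(out_dir, "trace.csv")
  write_trace_csv(series, paths$trace)

  fc <- config$features
  feats <- tryCatch(
    extract_features(series, inflection_config(fc$delta_thr, fc$smoothing_window)),
    error = function(e) stop("feature stage failed: ", conditionMessage(e)))
  paths$features <- file.path(out_dir, "features.csv")
  write_features_csv(features_row(feats, segment_id, condition), paths$features)

  list(series = series, features = feats, paths = paths)
}

#' End-to-end demonstration on synthetic data
#'
#' Generates seeded synthetic recordings for a reference viewing condition and
#' a visually harsher "modified" condition (higher blink rate, slower pupil
#' oscillation, i.e. lower accommodation speed), extracts the three fatigue
#' features for several segments per condition, and writes `features.csv` and
#' `comparison.csv` (one row per feature, with significance stars) to
#' `output_dir`.
#'
#' @param seed integer master seed; segment seeds derive from it.
#' @param output_dir where to write the artifacts.
#' @param n_segments segments (independent recordings) per condition.
#' @param segment_s length of each segment in seconds.
#' @param modified optional named list overriding [signal_spec()] arguments
#'   for the modified condition (defaults: `blink_rate = 1.2`,
#'   `osc_amplitude = 120`).
#' @param test significance test passed to [compare_to_reference()].
#' @return invisibly, list with `features` (data frame), `comparisons`
#'   (data frame), `table` (formatted [feature_table()]), and `paths`.
#' @export
fatigue_demo <- function(seed = 42L, output_dir = tempfile("fatigue_demo_"),
                         n_segments = 8L, segment_s = 60,
                         modified = list(blink_rate = 1.2, osc_amplitude = 120),
                         test = "welch_t") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  base_args <- list(duration_s = segment_s, noise_sigma = 15)
  conditions <- list(reference = base_args,
                     modified = utils::modifyList(base_args, modified))
  fc <- inflection_config(smoothing_window = 9L)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cn <- names(conditions)[ci]
    for (s in seq_len(n_segments)) {
      args <- conditions[[ci]]
      args$seed <- as.integer(seed) + 1000L * ci + s
      sig <- generate_signal(do.call(signal_spec, args))
      feats <- extract_features(sig$series, fc)
      rows[[length(rows) + 1L]] <- features_row(feats, sprintf("%s_%02d", cn, s), cn)
    }
  }
  features <- do.call(rbind, rows)
  f_path <- file.path(output_dir, "features.csv")
  write_features_csv(features, f_path)

  ref <- features[features$condition == "reference", ]
  mod <- features[features$condition == "modified", ]
  comps <- lapply(c(accommodation_speed = "accommodation_speed",
                    blink_freq = "blink_freq",
                    eye_closed_duration = "eye_closed_duration"),
                  function(col) compare_to_reference(ref[[col]], mod[[col]],
                                                     test = test,
                                                     feature_name = col,
                                                     condition = "modified"))
  comparisons <- do.call(rbind, comps)
  c_path <- file.path(output_dir, "comparison.csv")
  utils::write.csv(comparisons, c_path, row.names = FALSE, quote = FALSE)
  invisible(list(features = features, comparisons = comparisons,
                 table = feature_table(comps),
                 paths = list(features = f_path, comparison = c_path)))
}
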