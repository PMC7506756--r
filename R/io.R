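#' Construct a pupil-size time series
#'
#' Per-frame pupil areas in pixels, 0 meaning the eye is closed / no pupil was
#' detected. Frames are 0-based; time of frame `i` is `i / fps` seconds.
#'
#' @param areas numeric vector of per-frame areas (pixels), all `>= 0`.
#' @param fps frames per second, `> 0` (default 30, the usual IR eye-camera
#'   rate).
#' @return an object of class `pupil_ts`: a list with `areas` and `fps`.
#' @export
#' @examples
#' ts <- pupil_ts(c(1200, 1180, 0, 0, 1210), fps = 30)
#' blink_frequency(ts)
pupil_ts <- function(areas, fps = 30) {
  areas <- as.numeric(areas)
  if (length(areas) < 1L) stop("series must contain at least one frame")
  if (anyNA(areas) || any(areas < 0)) stop("invalid area: areas must be finite and >= 0")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) stop("fps must be a single value > 0")
  structure(list(areas = areas, fps = as.numeric(fps)), class = "pupil_ts")
}

#' @export
print.pupil_ts <- function(x, ...) {
  cat(sprintf("<pupil_ts> %d frames @ %g fps (%.2f s), %d closed frames\n",
              length(x$areas), x$fps, length(x$areas) / x$fps, sum(x$areas == 0)))
  invisible(x)
}

#' @export
length.pupil_ts <- function(x) length(x$areas)

## ---- recordings -------------------------------------------------------------

new_recording <- function(kind, payload, fps) {
  stopifnot(kind %in% c("images", "masks", "trace"), fps > 0)
  structure(list(kind = kind, payload = payload, fps = as.numeric(fps)),
            class = "eye_recording")
}

#' Wrap eye frames, masks, or a trace as a recording
#'
#' A recording carries exactly one source kind: grayscale frames (`images`),
#' binary masks (`masks`), or a precomputed pupil-size trace (`trace`), plus
#' the frame rate. [run_pipeline()] dispatches on the kind.
#'
#' @param frames list of integer matrices (0-255), identical dimensions.
#' @param masks list of 0/1 integer matrices, identical dimensions.
#' @param trace a [pupil_ts()].
#' @param fps frames per second.
#' @return an `eye_recording`.
#' @export
recording_from_frames <- function(frames, fps = 30) {
  check_frame_list(frames, "frame")
  new_recording("images", frames, fps)
}

#' @rdname recording_from_frames
#' @export
recording_from_masks <- function(masks, fps = 30) {
  check_frame_list(masks, "mask")
  bad <- which(!vapply(masks, function(m) all(m %in% c(0, 1)), logical(1)))
  if (length(bad)) stop("mask values must be 0/1 (frame ", bad[1] - 1L, ")")
  new_recording("masks", masks, fps)
}

#' @rdname recording_from_frames
#' @export
recording_from_trace <- function(trace, fps = trace$fps) {
  stopifnot(inherits(trace, "pupil_ts"))
  new_recording("trace", trace, fps)
}

#' @export
print.eye_recording <- function(x, ...) {
  n <- if (x$kind == "trace") length(x$payload$areas) else length(x$payload)
  cat(sprintf("<eye_recording> kind=%s, %d frames @ %g fps\n", x$kind, n, x$fps))
  invisible(x)
}

check_frame_list <- function(frames, what) {
  if (!is.list(frames) || length(frames) < 1L) stop("no frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch among ", what, "s: frame ",
         which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1] - 1L)
  invisible(TRUE)
}

## ---- image sequence I/O -----------------------------------------------------

# Extract the last run of digits in each filename as the frame number.
frame_number <- function(paths) {
  base <- basename(paths)
  m <- regmatches(base, gregexpr("[0-9]+", base))
  num <- vapply(m, function(g) {
    if (!length(g) || identical(g, character(0)) || is.na(g[1]) || !nzchar(g[length(g)]))
      return(NA_real_)
    as.numeric(g[length(g)])
  }, numeric(1))
  if (anyNA(num)) stop("cannot extract a frame number from: ",
                       base[which(is.na(num))[1]])
  num
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = stop("BMP input is not supported; convert to PNG or TIFF first"),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) {           # RGB(A) -> luma grayscale
    px <- LUMA_WEIGHTS["r"] * px[, , 1] +
          LUMA_WEIGHTS["g"] * px[, , 2] +
          LUMA_WEIGHTS["b"] * px[, , 3]
  }
  round(px * 255)
}

#' Read a numbered image sequence as a recording
#'
#' Files are ordered by the last run of digits in their filename (zero-padded
#' frame numbers), not by directory listing order. Color images are converted
#' to grayscale with fixed luma weights (0.299, 0.587, 0.114).
#'
#' @param directory directory containing the frames.
#' @param pattern filename glob (default `"*.png"`).
#' @param fps frames per second of the recording.
#' @return an `eye_recording` of kind `images`; pixel values are 0-255.
#' @export
read_image_sequence <- function(directory, pattern = "*.png", fps = 30) {
  if (!dir.exists(directory)) stop("no frames: directory does not exist: ", directory)
  files <- list.files(directory, pattern = utils::glob2rx(pattern), full.names = TRUE)
  if (!length(files)) stop("no frames match '", pattern, "' in ", directory)
  files <- files[order(frame_number(files))]
  frames <- lapply(files, read_gray_image)
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad)) stop("shape mismatch: ", basename(files[bad[1]]), " is ",
                        dims[1, bad[1]], "x", dims[2, bad[1]], ", expected ",
                        dims[1, 1], "x", dims[2, 1])
  new_recording("images", frames, fps)
}

#' Read a numbered binary mask sequence
#'
#' Masks are stored on disk as 0/255 grayscale PNG/TIFF and normalized to 0/1
#' on read (threshold at 127).
#'
#' @inheritParams read_image_sequence
#' @return an `eye_recording` of kind `masks`; values are 0/1 integer.
#' @export
read_mask_sequence <- function(directory, pattern = "*.png", fps = 30) {
  rec <- read_image_sequence(directory, pattern, fps)
  rec$payload <- lapply(rec$payload, function(m) {
    storage.mode(m) <- "integer"
    m[] <- as.integer(m > 127)
    m
  })
  rec$kind <- "masks"
  rec
}

#' Write frames or masks as numbered PNG files
#'
#' @param frames list of matrices: 0-255 grayscale frames, or 0/1 masks when
#'   `binary = TRUE` (written as 0/255).
#' @param directory output directory (created if needed).
#' @param prefix filename prefix; files are `<prefix><000i>.png`.
#' @param binary write 0/1 masks as 0/255.
#' @return invisibly, the written paths.
#' @export
write_image_sequence <- function(frames, directory, prefix = "frame_", binary = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, sprintf("%s%04d.png", prefix, seq_along(frames) - 1L))
  for (i in seq_along(frames)) {
    px <- frames[[i]]
    if (binary) px <- px * 255
    png::writePNG(px / 255, paths[i])
  }
  invisible(paths)
}

## ---- trace and feature tables ----------------------------------------------

#' Read a pupil-size trace from CSV
#'
#' Expects header `frame,area`. Frame numbers must be 0-based, strictly
#' increasing and gap-free; gaps are an error rather than silently filled.
#'
#' @param path CSV file path.
#' @param fps frames per second to attach to the series.
#' @return a [pupil_ts()].
#' @export
read_trace_csv <- function(path, fps = 30) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "area") %in% names(df)))
    stop("trace CSV must have header columns 'frame' and 'area'")
  if (anyNA(df$area) || any(df$area < 0)) stop("invalid area: negative or missing values")
  if (nrow(df) > 1 && any(diff(df$frame) <= 0)) stop("unsorted trace: frame column must be strictly increasing")
  if (!identical(as.numeric(df$frame), as.numeric(seq_len(nrow(df)) - 1L)))
    stop("unsorted trace: frame numbers must be contiguous from 0 (missing frames are an error)")
  pupil_ts(df$area, fps = fps)
}

#' Write a pupil-size trace to CSV
#'
#' @param series a [pupil_ts()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(series, path) {
  stopifnot(inherits(series, "pupil_ts"))
  # %.17g so doubles survive the round-trip bit-exactly
  writeLines(c("frame,area",
               sprintf("%d,%.17g", seq_along(series$areas) - 1L, series$areas)),
             path)
  invisible(path)
}

#' Write per-segment fatigue features to CSV
#'
#' One row per recording segment with the three fatigue features. Column order
#' is fixed: `segment_id, condition, accommodation_speed, blink_freq,
#' eye_closed_duration`. Values are written at full double precision so the
#' table round-trips exactly.
#'
#' @param features a data frame (or list of [fatigue_features()] rows built by
#'   [features_row()]) with the five columns above.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  if (!is.data.frame(features) || nrow(features) < 1L)
    stop("need at least one feature record")
  cols <- c("segment_id", "condition", "accommodation_speed", "blink_freq",
            "eye_closed_duration")
  if (!all(cols %in% names(features)))
    stop("feature table must contain columns: ", paste(cols, collapse = ", "))
  writeLines(c(paste(cols, collapse = ","),
               sprintf("%s,%s,%.17g,%.17g,%.17g", features$segment_id,
                       features$condition, features$accommodation_speed,
                       features$blink_freq, features$eye_closed_duration)),
             path)
  invisible(path)
}

#' Read a fatigue-feature table written by [write_features_csv()]
#' @param path CSV path.
#' @return data frame with the five feature columns.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("segment_id", "condition", "accommodation_speed", "blink_freq",
            "eye_closed_duration")
  if (!all(cols %in% names(df))) stop("not a feature table: ", path)
  df
}

#' Flatten one [fatigue_features()] result to a feature-table row
#'
#' @param feats a `fatigue_features` object.
#' @param segment_id segment identifier.
#' @param condition condition label.
#' @return one-row data frame matching the [write_features_csv()] schema.
#' @export
features_row <- function(feats, segment_id, condition) {
  stopifnot(inherits(feats, "fatigue_features"))
  data.frame(segment_id = segment_id, condition = condition,
             accommodation_speed = feats$P, blink_freq = feats$blink_freq,
             eye_closed_duration = feats$eye_closed)
}
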