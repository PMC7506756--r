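#' Inflection-point selection configuration
#'
#' Pupil size changes constantly but not every wiggle is physiologically
#' meaningful. Candidates (all sample-level extrema) are accepted as
#' inflection points only when the size change from the previously accepted
#' point alternates in sign and exceeds `delta_thr` pixels.
#'
#' @param delta_thr minimum absolute size change (pixels) from the previously
#'   accepted inflection point, or `"auto"` (default): 5% of the interquartile
#'   range of the non-zero areas, a scale-adaptive gate that works for both
#'   synthetic and real traces.
#' @param smoothing_window odd window (frames) for moving-median pre-smoothing
#'   of the signal before extrema detection; 1 (default) disables smoothing.
#'   At 30 fps a window of 9 frames (0.3 s) suppresses frame-level sensor
#'   noise while leaving multi-second accommodation swings intact.
#' @return an `inflection_config` list.
#' @export
inflection_config <- function(delta_thr = "auto", smoothing_window = 1L) {
  if (!identical(delta_thr, "auto")) {
    if (!is.numeric(delta_thr) || delta_thr < 0) stop("delta_thr must be >= 0 or 'auto'")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be an odd integer >= 1")
  structure(list(delta_thr = delta_thr, smoothing_window = smoothing_window),
            class = "inflection_config")
}

resolve_delta_thr <- function(config, areas) {
  if (!identical(config$delta_thr, "auto")) return(config$delta_thr)
  nz <- areas[areas > 0]
  if (length(nz) < 2L) return(0)
  0.05 * stats::IQR(nz)
}

# Maximal runs of a logical vector: data frame with start/end/length of TRUE runs.
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Find inflection-point candidates of a pupil-size series
#'
#' Candidates are the sample-level local extrema of the (optionally
#' moving-median-smoothed) signal, computed independently within each maximal
#' non-zero segment; the first and last frame of each segment are included.
#' Zero-runs (blinks) are excluded entirely — a zero sample is sensor dropout,
#' not a pupil size, so no inflection interval spans a blink boundary.
#'
#' Frames are 0-based. On plateaus the first frame of the plateau is the
#' candidate. Segments shorter than 3 frames (a momentary opening between two
#' blinks) are a single size observation, not a swing: they contribute one
#' median-valued candidate at their middle frame.
#'
#' @param series a [pupil_ts()].
#' @param config an [inflection_config()] (only `smoothing_window` is used
#'   here).
#' @return data frame with columns `F` (frame) and `S` (size, from the
#'   analysis signal), ordered by `F`; zero rows when the series has no
#'   non-zero segment.
#' @export
find_inflection_candidates <- function(series, config = inflection_config()) {
  stopifnot(inherits(series, "pupil_ts"))
  areas <- series$areas
  segs <- runs_of(areas > 0)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    v <- areas[idx]
    if (length(v) < 3L) {
      # a 1-2 frame opening between blinks is a single size observation, not
      # a swing: one median-valued candidate at its middle frame
      out[[i]] <- data.frame(F = idx[ceiling(length(v) / 2)] - 1L,
                             S = stats::median(v))
      next
    }
    w <- config$smoothing_window
    if (w > 1L && length(v) >= 3L) {
      # clamp the window to the segment (odd, <= n) so short inter-blink
      # segments are smoothed too; constant endrule keeps segment ends from
      # contributing raw-noise extrema
      w_eff <- min(w, length(v) - (1L - length(v) %% 2L))
      if (w_eff > 1L) v <- stats::runmed(v, w_eff, endrule = "constant")
    }
    n <- length(v)
    cand <- c(1L, n)
    if (n >= 3L) {
      d <- sign(diff(v))
      # first nonzero difference sign at or after each position
      nz_right <- d
      for (j in (n - 2L):1L) if (nz_right[j] == 0) nz_right[j] <- nz_right[j + 1L]
      interior <- which(d[-(n - 1L)] != 0 & nz_right[-1L] != 0 &
                        d[-(n - 1L)] != nz_right[-1L]) + 1L
      cand <- sort(unique(c(cand, interior)))
    } else cand <- unique(cand)
    out[[i]] <- data.frame(F = idx[cand] - 1L, S = v[cand])
  }
  if (!length(out)) return(data.frame(F = integer(0), S = numeric(0)))
  do.call(rbind, out)
}

#' Select inflection points from candidates
#'
#' Greedy left-to-right scan over the candidates. The first candidate is
#' accepted as the anchor. A later candidate is accepted when (1) the sign of
#' its size difference from the previously accepted point alternates relative
#' to the previously accepted difference (the first accepted difference sets
#' the reference), and (2) the absolute difference exceeds `delta_thr`.
#' Among consecutive candidates continuing in the same direction as the last
#' accepted swing, the most extreme one is retained (the accepted point is
#' replaced, so each swing ends at its true extremum rather than the first
#' sufficiently large wiggle).
#'
#' The accepted list therefore has strictly alternating difference signs and
#' every consecutive difference exceeds the threshold.
#'
#' @param cands candidate data frame from [find_inflection_candidates()].
#' @param delta_thr numeric threshold in pixels.
#' @return data frame `F`, `S` of accepted inflection points.
#' @export
select_inflections <- function(cands, delta_thr = 0) {
  n <- nrow(cands)
  if (n <= 1L) return(cands)
  acc_F <- cands$F[1]; acc_S <- cands$S[1]
  last_sign <- 0
  for (i in 2:n) {
    d <- cands$S[i] - acc_S[length(acc_S)]
    if (d == 0) next
    if (last_sign == 0) {                      # no reference direction yet
      if (abs(d) > delta_thr) {
        acc_F <- c(acc_F, cands$F[i]); acc_S <- c(acc_S, cands$S[i])
        last_sign <- sign(d)
      }
    } else if (sign(d) == last_sign) {         # swing continues: keep extreme
      acc_F[length(acc_F)] <- cands$F[i]
      acc_S[length(acc_S)] <- cands$S[i]
    } else if (abs(d) > delta_thr) {           # alternation + threshold
      acc_F <- c(acc_F, cands$F[i]); acc_S <- c(acc_S, cands$S[i])
      last_sign <- sign(d)
    }
  }
  data.frame(F = acc_F, S = acc_S)
}

#' Average pupil accommodation speed between inflection points
#'
#' With inflection points `(F_n, S_n)`, `n = 1..N+1`, the speed is
#' `P = (1/N) * sum_n |S_{n+1} - S_n| / |F_{n+1} - F_n|` in pixels per frame,
#' where `N` is the number of inflection points minus one. The speed slows as
#' the iris muscles fatigue. Fewer than two inflection points give `P = 0` by
#' convention (no completed accommodation swing was observed).
#'
#' @param infl data frame with columns `F` and `S`, ordered by `F`.
#' @return `P` in pixels per frame.
#' @export
#' @examples
#' accommodation_speed(data.frame(F = c(0, 30, 60), S = c(100, 200, 100)))  # 10/3
accommodation_speed <- function(infl) {
  n <- nrow(infl)
  if (n < 2L) return(0)
  dF <- diff(infl$F)
  if (any(dF == 0)) stop("zero frame gap between inflection points")
  mean(abs(diff(infl$S)) / abs(dF))
}

#' Blink frequency of a pupil-size series
#'
#' A blink is one maximal run of consecutive zero-area frames (the pupil is
#' invisible while the eye is closed). Leading and trailing zero-runs count as
#' blinks — a truncated blink cannot be distinguished from a complete one.
#'
#' @param series a [pupil_ts()].
#' @return blinks per second: run count divided by recording duration.
#' @export
blink_frequency <- function(series) {
  stopifnot(inherits(series, "pupil_ts"))
  n_blinks <- nrow(runs_of(series$areas == 0))
  n_blinks / (length(series$areas) / series$fps)
}

#' Eye-closed duration of a pupil-size series
#'
#' @param series a [pupil_ts()].
#' @return list with `closed_frames` (total zero frames), `closed_seconds`
#'   (`closed_frames / fps`) and `avg_closed_per_second` (closed seconds per
#'   second of recording, in `[0, 1]`).
#' @export
eye_closed_duration <- function(series) {
  stopifnot(inherits(series, "pupil_ts"))
  closed <- sum(series$areas == 0)
  dur <- length(series$areas) / series$fps
  list(closed_frames = closed,
       closed_seconds = closed / series$fps,
       avg_closed_per_second = (closed / series$fps) / dur)
}

#' Extract the three fatigue features from a pupil-size series
#'
#' Composes inflection-point detection and selection, the accommodation-speed
#' summation, blink counting and eye-closure accounting. Deterministic for a
#' fixed series and configuration.
#'
#' @param series a [pupil_ts()] with at least 3 frames.
#' @param config an [inflection_config()].
#' @return a `fatigue_features` object: list with `P` (pixels/frame),
#'   `P_per_s` (pixels/second, `P * fps`), `blink_freq` (blinks/s),
#'   `eye_closed` (average closed seconds per second), and diagnostics
#'   `n_inflections`, `n_blinks`, `closed_frames`, `delta_thr` (resolved
#'   value), `duration_s`.
#' @export
extract_features <- function(series, config = inflection_config()) {
  stopifnot(inherits(series, "pupil_ts"))
  if (length(series$areas) < 3L) stop("series must have at least 3 frames")
  thr <- resolve_delta_thr(config, series$areas)
  infl <- select_inflections(find_inflection_candidates(series, config), thr)
  closure <- eye_closed_duration(series)
  dur <- length(series$areas) / series$fps
  P <- accommodation_speed(infl)
  structure(list(
    P = P, P_per_s = P * series$fps,
    blink_freq = blink_frequency(series),
    eye_closed = closure$avg_closed_per_second,
    n_inflections = nrow(infl),
    n_blinks = nrow(runs_of(series$areas == 0)),
    closed_frames = closure$closed_frames,
    closed_seconds = closure$closed_seconds,
    delta_thr = thr, duration_s = dur,
    inflections = infl), class = "fatigue_features")
}

#' @export
print.fatigue_features <- function(x, ...) {
  cat(sprintf(paste0(
    "<fatigue_features> %.1f s\n",
    "  accommodation speed P : %.4f px/frame (%.2f px/s, %d inflection points)\n",
    "  blink frequency       : %.4f blinks/s (%d blinks)\n",
    "  eye-closed duration   : %.4f s per s (%d frames, %.2f s)\n"),
    x$duration_s, x$P, x$P_per_s, x$n_inflections,
    x$blink_freq, x$n_blinks, x$eye_closed, x$closed_frames, x$closed_seconds))
  invisible(x)
}
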