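#' Specification of a synthetic pupil-size signal
#'
#' The generator emulates the statistical structure an infrared pupillometry
#' recording presents to the pipeline: a slow accommodation oscillation of the
#' pupil area around a baseline, frame-level measurement noise, and
#' intermittent blinks during which the pupil area is exactly 0.
#'
#' Defaults describe a plausible adult recording at 30 fps on a 640x480 IR
#' eye camera: a baseline pupil of ~1200 px (radius ~20 px), a 300 px
#' oscillation with a 4 s period, and 0.5 blinks/s lasting 1-8 frames.
#'
#' @param duration_s recording length in seconds.
#' @param fps frames per second (default 30).
#' @param base_area baseline pupil area in pixels.
#' @param osc_amplitude oscillation amplitude in pixels (`< base_area`).
#' @param osc_period_s oscillation period in seconds.
#' @param blink_rate expected blinks per second (Poisson process).
#' @param blink_duration_frames integer range `c(min, max)`; each blink zeroes
#'   a uniform-length run of frames.
#' @param noise_sigma standard deviation of Gaussian per-frame noise (pixels).
#' @param seed integer RNG seed; the whole signal is deterministic given the
#'   spec.
#' @return a `signal_spec` list.
#' @export
signal_spec <- function(duration_s = 10, fps = 30, base_area = 1200,
                        osc_amplitude = 300, osc_period_s = 4,
                        blink_rate = 0.5, blink_duration_frames = c(1L, 8L),
                        noise_sigma = 0, seed = 1L) {
  if (fps <= 0 || duration_s <= 0) stop("fps and duration_s must be > 0")
  if (osc_amplitude < 0 || base_area <= osc_amplitude)
    stop("need base_area > osc_amplitude >= 0")
  if (blink_rate < 0) stop("blink_rate must be >= 0")
  bd <- as.integer(blink_duration_frames)
  if (length(bd) != 2L || bd[1] < 1L || bd[2] < bd[1])
    stop("blink_duration_frames must be c(min, max) with 1 <= min <= max")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(duration_s = duration_s, fps = fps, base_area = base_area,
                 osc_amplitude = osc_amplitude, osc_period_s = osc_period_s,
                 blink_rate = blink_rate, blink_duration_frames = bd,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a synthetic pupil-size signal with ground truth
#'
#' The clean signal is
#' `area(t) = base_area + osc_amplitude * sin(2 * pi * t / osc_period_s)`;
#' Gaussian noise is added per frame and the result clipped at 0. The blink
#' count over the recording is Poisson at `blink_rate`; each blink zeroes a
#' uniform-length run of frames. Runs are placed without overlap (real blinks
#' do not overlap, and merging would bias the realized run count below the
#' requested rate), so the number of zero-runs is Poisson-distributed with
#' mean `blink_rate * duration_s`.
#'
#' The ground truth records the noise-free signal, the blink (zero) flags, the
#' interior extrema of the noise-free *blink-free* signal
#' (`true_inflections`), and `true_P`: the accommodation speed obtained by
#' applying the inflection-speed summation to those extrema — the mean
#' inter-extremum slope of the underlying accommodation oscillation, the
#' target an estimator on the noisy, blink-interrupted series should recover.
#' (Blinks are measurement dropouts; the oscillation continues beneath them,
#' so the speed oracle is defined on the uninterrupted signal.)
#'
#' @param spec a [signal_spec()].
#' @return list with `series` (a [pupil_ts()]) and `truth` (list:
#'   `clean_area`, `blink`, `n_blink_runs`, `true_inflections`, `true_P`).
#' @export
generate_signal <- function(spec = signal_spec()) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1L) / spec$fps
  clean <- spec$base_area + spec$osc_amplitude * sin(2 * pi * t / spec$osc_period_s)
  with_seed(spec$seed, {
    areas <- pmax(0, clean + stats::rnorm(n, 0, spec$noise_sigma))
    blink <- rep(FALSE, n)
    k <- stats::rpois(1, spec$blink_rate * spec$duration_s)
    placed <- 0L; tries <- 0L
    while (placed < k && tries < 200L * k) {
      tries <- tries + 1L
      onset <- sample.int(n, 1)
      len <- sample(seq(spec$blink_duration_frames[1],
                        spec$blink_duration_frames[2]), 1)
      lo <- max(1L, onset - 1L); hi <- min(n, onset + len)  # 1-frame guard gap
      if (!any(blink[lo:hi])) {
        blink[onset:min(n, onset + len - 1L)] <- TRUE
        placed <- placed + 1L
      }
    }
    if (placed < k)
      warning("placed only ", placed, " of ", k, " blinks (recording too dense)")
  })
  areas[blink] <- 0
  clean_blinked <- clean
  clean_blinked[blink] <- 0
  series <- pupil_ts(areas, fps = spec$fps)
  cands <- find_inflection_candidates(pupil_ts(clean, fps = spec$fps),
                                      inflection_config(smoothing_window = 1L))
  interior <- cands[!(cands$F %in% c(0L, n - 1L)), , drop = FALSE]
  true_P <- if (nrow(interior) >= 2L) accommodation_speed(interior) else 0
  list(series = series,
       truth = list(clean_area = clean_blinked, blink = blink,
                    n_blink_runs = nrow(runs_of(blink)),
                    true_inflections = interior, true_P = true_P))
}

#' Specification of rendered infrared-style eye frames
#'
#' Frames emulate a near-infrared eye image: a dark pupil ellipse inside a
#' darker-than-skin iris disc on a bright skin background, with optional
#' bright corneal-glint speckles. Blink frames render a uniform eyelid at skin
#' intensity and an empty truth mask.
#'
#' @param width,height frame size in pixels (default 640x480; `>= 64`).
#' @param pupil_center_jitter max per-axis uniform displacement of the pupil
#'   center from frame to frame, pixels.
#' @param pupil_intensity,iris_intensity,skin_intensity gray levels 0-255 with
#'   `pupil < iris < skin` (dark-pupil imaging).
#' @param glint_count number of bright glint speckles per open-eye frame.
#' @param glint_radius glint radius in pixels.
#' @param eccentricity axis ratio a/b of the rendered pupil ellipse (1 =
#'   circle); area is preserved.
#' @param seed integer RNG seed for jitter and glint placement.
#' @return an `image_spec` list.
#' @export
image_spec <- function(width = 640, height = 480, pupil_center_jitter = 2,
                       pupil_intensity = 30, iris_intensity = 120,
                       skin_intensity = 200, glint_count = 1L,
                       glint_radius = 2L, eccentricity = 1, seed = 1L) {
  if (width < 64 || height < 64) stop("dimensions must be >= 64")
  if (!(pupil_intensity < iris_intensity && iris_intensity < skin_intensity))
    stop("need pupil_intensity < iris_intensity < skin_intensity")
  if (any(c(pupil_intensity, iris_intensity, skin_intensity) < 0) ||
      any(c(pupil_intensity, iris_intensity, skin_intensity) > 255))
    stop("intensities must be in [0, 255]")
  if (eccentricity < 1) stop("eccentricity is the major/minor axis ratio, >= 1")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pupil_center_jitter = pupil_center_jitter,
                 pupil_intensity = pupil_intensity,
                 iris_intensity = iris_intensity,
                 skin_intensity = skin_intensity,
                 glint_count = as.integer(glint_count),
                 glint_radius = as.integer(glint_radius),
                 eccentricity = eccentricity, seed = as.integer(seed)),
            class = "image_spec")
}

# Rasterize a filled axis-aligned ellipse on an H x W grid of pixel centers.
ellipse_mask <- function(h, w, cx, cy, a, b) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  matrix(as.integer(((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1), h, w)
}

#' Render a pupil-size series as infrared-style frames with truth masks
#'
#' Each open-eye frame draws a filled pupil ellipse whose rasterized area
#' matches the series value (semi-axes `a = r * sqrt(ecc)`, `b = r / sqrt(ecc)`
#' with `r = sqrt(area / pi)`), centered near the image center with uniform
#' jitter, inside an iris disc on a skin background, plus bright glints near
#' the pupil. Blink frames (area 0) are uniform skin intensity with an empty
#' truth mask.
#'
#' @param series a [pupil_ts()].
#' @param spec an [image_spec()].
#' @return list with `frames` (0-255 integer matrices) and `masks` (0/1
#'   ground-truth pupil masks).
#' @export
render_frames <- function(series, spec = image_spec()) {
  stopifnot(inherits(series, "pupil_ts"), inherits(spec, "image_spec"))
  h <- spec$height; w <- spec$width
  r_max <- sqrt(max(series$areas) / pi) * sqrt(spec$eccentricity)
  iris_r <- min(h, w) / 3
  if (r_max > iris_r - spec$pupil_center_jitter)
    stop("pupil radius ", round(r_max, 1), " px exceeds the iris disc (",
         round(iris_r, 1), " px); enlarge the frame or shrink the signal")
  cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
  iris <- ellipse_mask(h, w, cx0, cy0, iris_r, iris_r)
  n <- length(series$areas)
  frames <- vector("list", n); masks <- vector("list", n)
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      area <- series$areas[i]
      if (area == 0) {                      # eyelid closed
        frames[[i]] <- matrix(as.integer(spec$skin_intensity), h, w)
        masks[[i]] <- matrix(0L, h, w)
        next
      }
      cx <- cx0 + stats::runif(1, -1, 1) * spec$pupil_center_jitter
      cy <- cy0 + stats::runif(1, -1, 1) * spec$pupil_center_jitter
      r <- sqrt(area / pi)
      pupil <- ellipse_mask(h, w, cx, cy, r * sqrt(spec$eccentricity),
                            r / sqrt(spec$eccentricity))
      img <- matrix(as.integer(spec$skin_intensity), h, w)
      img[iris == 1L] <- as.integer(spec$iris_intensity)
      img[pupil == 1L] <- as.integer(spec$pupil_intensity)
      if (spec$glint_count > 0) {
        for (g in seq_len(spec$glint_count)) {
          gx <- cx + stats::runif(1, -1, 1) * r
          gy <- cy + stats::runif(1, -1, 1) * r
          img[ellipse_mask(h, w, gx, gy, spec$glint_radius,
                           spec$glint_radius) == 1L] <- 255L
        }
      }
      frames[[i]] <- img
      masks[[i]] <- pupil
    }
  })
  list(frames = frames, masks = masks)
}
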