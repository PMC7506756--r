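#' Pupil detector configuration
#'
#' Thresholds of the candidate-filtering stage. A connected component survives
#' iff its filled contour area `CA` is strictly greater than `ca_thr` pixels,
#' its bounding-box aspect ratio `min(W, H) / max(W, H)` is strictly greater
#' than `as_thr` (pupils are near-circular, elongated blobs are eyelash or
#' eyelid artifacts), and, when `ca_max` is set, `CA < ca_max`.
#'
#' Note on the aspect test direction: the ratio is symmetrized as
#' `min(W, H) / max(W, H)` in `(0, 1]` and candidates are *kept* above the
#' threshold — a near-circular pupil has ratio close to 1 and must survive the
#' default 0.4 cutoff; tall and wide elongations are treated alike.
#'
#' @param ca_thr minimum candidate area in pixels (default 300).
#' @param as_thr minimum aspect ratio in `(0, 1]` (default 0.4).
#' @param ca_max optional maximum area in pixels; `NULL` (default) disables
#'   the upper bound.
#' @return a `detector_config` list.
#' @export
detector_config <- function(ca_thr = 300, as_thr = 0.4, ca_max = NULL) {
  if (ca_thr < 0) stop("ca_thr must be >= 0")
  if (as_thr <= 0 || as_thr > 1) stop("as_thr must be in (0, 1]")
  if (!is.null(ca_max) && ca_max <= ca_thr) stop("ca_max must exceed ca_thr")
  structure(list(ca_thr = ca_thr, as_thr = as_thr, ca_max = ca_max),
            class = "detector_config")
}

#' Find pupil candidates in a binary mask
#'
#' Connected components (8-connectivity) of the mask become candidates. For
#' each component the interior holes are filled (a corneal glint punches a
#' bright hole into the dark pupil; only the outer boundary matters), and the
#' candidate records its filled area `CA` (pixel count of the filled
#' component, the discrete equivalent of the filled outer-contour polygon
#' area), axis-aligned bounding-box width `W` and height `H`, the aspect
#' ratio `min(W, H)/max(W, H)`, and the ordered outer-boundary contour.
#'
#' @param mask 0/1 matrix (rows = y, columns = x).
#' @return list of `pupil_candidate` objects, in label (frame-scan) order;
#'   empty list for an empty mask.
#' @export
find_candidates <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  if (!any(mask == 1)) return(list())
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    comp <- matrix(as.integer(lab == k), nrow(mask), ncol(mask))
    filled <- EBImage::fillHull(comp)
    px <- which(filled == 1L, arr.ind = TRUE)   # col1 = row (y), col2 = col (x)
    w <- diff(range(px[, 2])) + 1L
    h <- diff(range(px[, 1])) + 1L
    oc <- EBImage::ocontour(filled)[[1]]        # 0-based (dim1, dim2) = (y, x)
    contour <- cbind(x = oc[, 2], y = oc[, 1])
    out[[k]] <- structure(
      list(contour = contour, CA = nrow(px), W = w, H = h,
           aspect = min(w, h) / max(w, h)),
      class = "pupil_candidate")
  }
  out
}

#' @export
print.pupil_candidate <- function(x, ...) {
  cat(sprintf("<pupil_candidate> CA=%d px, W=%d, H=%d, aspect=%.3f\n",
              x$CA, x$W, x$H, x$aspect))
  invisible(x)
}

#' Filter candidates by area and aspect ratio
#'
#' Keeps a candidate iff `CA > ca_thr` and `aspect > as_thr` (strict
#' inequalities) and, when configured, `CA < ca_max`. Order is preserved and
#' the operation is idempotent.
#'
#' @param cands list of candidates from [find_candidates()].
#' @param config a [detector_config()].
#' @return the surviving candidates.
#' @export
filter_candidates <- function(cands, config = detector_config()) {
  keep <- vapply(cands, function(cc) {
    cc$CA > config$ca_thr && cc$aspect > config$as_thr &&
      (is.null(config$ca_max) || cc$CA < config$ca_max)
  }, logical(1))
  cands[keep]
}

#' Select the pupil among surviving candidates
#'
#' The largest surviving component (maximal `CA`) is taken as the pupil; ties
#' go to the earliest candidate in frame-scan order. `NULL` when no candidate
#' survives (the frame is treated as eye-closed).
#'
#' @param cands filtered candidates.
#' @return a `pupil_candidate` or `NULL`.
#' @export
select_pupil <- function(cands) {
  if (!length(cands)) return(NULL)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "CA"))]]
}

# Direct least-squares ellipse fit (eigen-solved conic fit constrained to
# ellipses), on centered/scaled coordinates for numerical stability.
# Returns conic coefficients (a,b,c,d,e,f) for ax^2+bxy+cy^2+dx+ey+f=0 in the
# original coordinates, or NULL when the fit degenerates.
fit_ellipse_conic <- function(xy) {
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  s <- mean(c(stats::sd(xy[, 1]), stats::sd(xy[, 2])))
  if (!is.finite(s) || s == 0) return(NULL)
  x <- (xy[, 1] - mx) / s; y <- (xy[, 2] - my) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.numeric(Tm %*% a1))       # (a, b, c, d, e, f) scaled frame
  # un-scale: x' = (x-mx)/s, y' = (y-my)/s
  a <- coef[1]; b <- coef[2]; cc <- coef[3]; d <- coef[4]; e <- coef[5]; f <- coef[6]
  c(a = a,
    b = b,
    c = cc,
    d = (-2 * a * mx - b * my + d * s),
    e = (-2 * cc * my - b * mx + e * s),
    f = a * mx^2 + b * mx * my + cc * my^2 - d * s * mx - e * s * my + f * s^2)
}

conic_to_geometry <- function(k) {
  A <- matrix(c(k["a"], k["b"] / 2, k["b"] / 2, k["c"]), 2, 2)
  ctr <- tryCatch(solve(2 * A, -c(k["d"], k["e"])), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  f0 <- as.numeric(k["a"] * ctr[1]^2 + k["b"] * ctr[1] * ctr[2] + k["c"] * ctr[2]^2 +
                   k["d"] * ctr[1] + k["e"] * ctr[2] + k["f"])
  ev <- eigen(A, symmetric = TRUE)
  ax2 <- -f0 / ev$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(NULL)
  semi <- sqrt(ax2)
  list(cx = ctr[1], cy = ctr[2],
       a = max(semi), b = min(semi),
       angle = atan2(ev$vectors[2, which.max(semi)], ev$vectors[1, which.max(semi)]))
}

#' Fit an ellipse to a candidate and measure its area
#'
#' A direct least-squares conic fit constrained to ellipses is applied to the
#' candidate's outer-boundary points; the reported pupil size is the fitted
#' ellipse area `pi * a * b` (semi-axes), not the raw pixel count. Because the
#' contour consists of boundary *pixel centers*, which lie on average half a
#' pixel inside the continuous region boundary, the fitted semi-axes are
#' inflated by 0.5 px before the area is computed. A contour with fewer than
#' 5 points cannot determine a conic; such frames are treated as no-pupil
#' (area 0) with a warning.
#'
#' @param cand a `pupil_candidate`, or `NULL`.
#' @param index frame number to stamp on the measurement.
#' @return a `pupil_measurement`: list with `index`, `area`, and `ellipse`
#'   (`cx, cy, a, b, angle`; `NULL` when `area == 0`).
#' @export
fit_ellipse_area <- function(cand, index = 0L) {
  empty <- structure(list(index = index, area = 0, ellipse = NULL),
                     class = "pupil_measurement")
  if (is.null(cand)) return(empty)
  pts <- unique(cand$contour)
  if (nrow(pts) < 5L) {
    warning("degenerate contour (", nrow(pts), " points) at frame ", index,
            "; treated as no pupil")
    return(empty)
  }
  k <- fit_ellipse_conic(pts)
  g <- if (is.null(k)) NULL else conic_to_geometry(k)
  if (is.null(g)) {
    warning("ellipse fit degenerate at frame ", index, "; treated as no pupil")
    return(empty)
  }
  g$a <- g$a + 0.5; g$b <- g$b + 0.5   # half-pixel boundary correction
  structure(list(index = index, area = pi * g$a * g$b, ellipse = g),
            class = "pupil_measurement")
}

#' Detect the pupil in every mask and build the size time series
#'
#' Runs the full per-frame chain — contour detection, area and aspect-ratio
#' filtering, largest-candidate selection, ellipse fitting — and emits one
#' area per frame; frames with no surviving candidate get area 0.
#'
#' @param masks list of 0/1 matrices ordered by frame, or an `eye_recording`
#'   of kind `masks`.
#' @param config a [detector_config()].
#' @param fps frames per second for the resulting series (taken from the
#'   recording when one is passed).
#' @param details if `TRUE`, attach a per-frame data frame
#'   (`frame, area, cx, cy, axis_a, axis_b, angle`) as attribute
#'   `"measurements"`.
#' @return a [pupil_ts()].
#' @export
detect_sequence <- function(masks, config = detector_config(), fps = 30,
                            details = FALSE) {
  if (inherits(masks, "eye_recording")) {
    if (masks$kind != "masks") stop("recording must be of kind 'masks'")
    fps <- masks$fps
    masks <- masks$payload
  }
  n <- length(masks)
  if (!n) stop("no masks")
  areas <- numeric(n)
  rows <- if (details) vector("list", n)
  for (i in seq_len(n)) {
    cand <- select_pupil(filter_candidates(find_candidates(masks[[i]]), config))
    m <- fit_ellipse_area(cand, index = i - 1L)
    areas[i] <- m$area
    if (details) {
      e <- m$ellipse
      rows[[i]] <- data.frame(
        frame = i - 1L, area = m$area,
        cx = if (is.null(e)) NA_real_ else e$cx,
        cy = if (is.null(e)) NA_real_ else e$cy,
        axis_a = if (is.null(e)) NA_real_ else e$a,
        axis_b = if (is.null(e)) NA_real_ else e$b,
        angle = if (is.null(e)) NA_real_ else e$angle)
    }
  }
  out <- pupil_ts(areas, fps = fps)
  if (details) attr(out, "measurements") <- do.call(rbind, rows)
  out
}
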