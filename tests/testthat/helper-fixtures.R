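# Fixtures and independent oracles shared across test files.

# Rasterized filled ellipse / disk on an h x w grid (pixel centers).
raster_ellipse <- function(h, w, cx, cy, a, b = a) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  matrix(as.integer(((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1), h, w)
}

# Axis-aligned filled rectangle mask.
raster_rect <- function(h, w, y0, x0, rh, rw) {
  m <- matrix(0L, h, w)
  m[y0:(y0 + rh - 1L), x0:(x0 + rw - 1L)] <- 1L
  m
}

# The worked 10-s, 30-fps trace: five zero-runs of 6, 1, 5, 8, 6 frames
# separated by non-zero frames.
worked_example_series <- function(level = 1000) {
  areas <- rep(level, 300)
  areas[c(10:15, 40, 70:74, 100:107, 200:205)] <- 0
  pupil_ts(areas, fps = 30)
}

# Brute-force 4-connected component labelling by BFS, independent of EBImage.
bfs_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1L && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
              mask[q[1], q[2]] == 1L && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nxt
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# Independent Eq.-1 style summation over an inflection list, written as a
# plain loop (oracle for accommodation_speed).
speed_oracle <- function(F, S) {
  n <- length(F)
  if (n < 2) return(0)
  acc <- 0
  for (k in seq_len(n - 1)) acc <- acc + abs(S[k + 1] - S[k]) / abs(F[k + 1] - F[k])
  acc / (n - 1)
}

# Independent zero-run counter (oracle for blink counting).
count_zero_runs <- function(x) {
  inzero <- FALSE; runs <- 0L
  for (v in x) {
    if (v == 0 && !inzero) { runs <- runs + 1L; inzero <- TRUE }
    if (v != 0) inzero <- FALSE
  }
  runs
}
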