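test_that("inflection candidates are segment extrema plus endpoints, skipping blinks", {
  cfg <- inflection_config(smoothing_window = 1)
  # constant non-zero series: endpoints only
  cc <- find_inflection_candidates(pupil_ts(rep(500, 20), 30), cfg)
  expect_equal(cc$F, c(0, 19))

  # forced local max
  cc <- find_inflection_candidates(pupil_ts(c(100, 150, 200, 150, 100), 30), cfg)
  expect_equal(cc$F, c(0, 2, 4))
  expect_equal(cc$S[2], 200)

  # zero-runs are excised; no candidate falls on a blink frame
  areas <- c(100, 200, 100, 0, 0, 300, 150, 300)
  cc <- find_inflection_candidates(pupil_ts(areas, 30), cfg)
  expect_true(all(areas[cc$F + 1] > 0))
  expect_equal(cc$F, c(0, 1, 2, 5, 6, 7))
})

test_that("candidate count on a sampled sinusoid matches the discrete-derivative oracle", {
  t <- 0:599
  v <- 1000 + 300 * sin(2 * pi * t / 120)   # period 120 frames, no blinks
  cc <- find_inflection_candidates(pupil_ts(v, 30), inflection_config(smoothing_window = 1))
  # independent oracle: sign changes of the first difference
  d <- diff(v)
  oracle <- sum(sign(d[-1]) * sign(d[-length(d)]) < 0)
  interior <- nrow(cc) - 2L     # endpoints excluded
  expect_lte(abs(interior - oracle), 1)
  expect_gte(interior, 9); expect_lte(interior, 11)  # ~10 extrema in 5 periods
})

test_that("inflection selection enforces sign alternation and the delta threshold", {
  cands <- data.frame(F = c(0, 10, 20), S = c(100, 200, 100))
  sel <- select_inflections(cands, delta_thr = 50)
  expect_equal(sel$S, c(100, 200, 100))

  sel <- select_inflections(data.frame(F = c(0, 10, 20), S = c(100, 130, 100)), 50)
  expect_equal(nrow(sel), 1)    # |30| <= 50: only the anchor survives

  # noisy triangle wave: vertices recovered exactly, count exact
  period <- 60; amp <- 300; n <- 600
  tri <- amp * (2 / pi) * asin(sin(2 * pi * (0:(n - 1)) / period)) + 1000
  set.seed(77)
  noisy <- tri + rnorm(n, 0, 10)
  cc <- find_inflection_candidates(pupil_ts(noisy, 30), inflection_config(smoothing_window = 1))
  sel <- select_inflections(cc, delta_thr = 50)
  vert <- seq(period / 4, n - 1, by = period / 2)   # true vertex frames
  interior <- sel[sel$F > 0 & sel$F < n - 1, ]
  expect_equal(nrow(interior), length(vert))
  expect_true(all(abs(interior$F - vert) <= 2))

  # assertable post-conditions: alternating signs, every step over threshold
  dS <- diff(sel$S)
  expect_true(all(abs(dS) > 50))
  expect_true(all(sign(dS[-1]) == -sign(dS[-length(dS)])))
})

test_that("accommodation speed equals the inflection-slope average (worked case + oracle)", {
  expect_equal(accommodation_speed(data.frame(F = c(0, 30, 60), S = c(100, 200, 100))),
               10 / 3)
  expect_equal(accommodation_speed(data.frame(F = 5, S = 100)), 0)
  expect_error(accommodation_speed(data.frame(F = c(3, 3), S = c(1, 2))),
               "zero frame gap")
  set.seed(12)
  for (rep in 1:5) {
    F <- sort(sample.int(2000, 20))
    S <- runif(20, 100, 2000)
    expect_equal(accommodation_speed(data.frame(F = F, S = S)),
                 speed_oracle(F, S), tolerance = 1e-12)
  }
})

test_that("blink frequency and closure reproduce the 10-s worked example", {
  ts <- worked_example_series()
  expect_identical(blink_frequency(ts), 0.5)
  cl <- eye_closed_duration(ts)
  expect_identical(cl$closed_frames, 26L)
  expect_equal(cl$closed_seconds, 26 / 30)
  expect_equal(cl$avg_closed_per_second, 26 / 300)
  expect_equal(blink_frequency(pupil_ts(rep(100, 50), 30)), 0)
})

test_that("blink counting matches a run-length oracle under random placement", {
  set.seed(55)
  for (rep in 1:10) {
    x <- runif(1000, 500, 1500)
    k <- sample(3:12, 1)
    starts <- sort(sample(seq(1, 950, by = 40), k))
    for (s in starts) x[s:(s + sample(1:10, 1))] <- 0
    ts <- pupil_ts(x, 30)
    runs <- count_zero_runs(x)
    expect_equal(blink_frequency(ts), runs / (1000 / 30))
    expect_equal(sum(ts$areas == 0) + sum(ts$areas > 0), 1000)  # conservation
  }
})

test_that("features depend on scale and direction the way the definitions demand", {
  sig <- generate_signal(signal_spec(duration_s = 20, noise_sigma = 0,
                                     blink_rate = 0.4, seed = 21))
  cfg <- inflection_config()   # auto threshold: scale-adaptive
  f1 <- extract_features(sig$series, cfg)
  # scaling all non-zero areas by c scales P by c, leaves blink/closure alone
  for (c_scale in c(0.25, 3)) {
    f2 <- extract_features(pupil_ts(sig$series$areas * c_scale, 30), cfg)
    expect_equal(f2$P, f1$P * c_scale, tolerance = 1e-10)
    expect_identical(f2$blink_freq, f1$blink_freq)
    expect_identical(f2$closed_frames, f1$closed_frames)
  }
  # time reversal preserves blink count, closure and P (absolute values)
  f3 <- extract_features(pupil_ts(rev(sig$series$areas), 30), cfg)
  expect_equal(f3$blink_freq, f1$blink_freq)
  expect_identical(f3$closed_frames, f1$closed_frames)
  expect_equal(f3$P, f1$P, tolerance = 1e-8)
})

test_that("an all-zero series degenerates to one long blink", {
  f <- extract_features(pupil_ts(rep(0, 90), 30))
  expect_equal(f$P, 0)
  expect_equal(f$blink_freq, 1 / 3)   # one run over 3 s
  expect_equal(f$eye_closed, 1)
})

test_that("estimated blink frequency recovers the generating rate", {
  for (lambda in c(0.1, 0.3, 0.5)) {
    est <- vapply(1:20, function(s) {
      sig <- generate_signal(signal_spec(duration_s = 100, blink_rate = lambda,
                                         seed = 7000 + s))
      blink_frequency(sig$series)
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lte(abs(mean(est) - lambda), 2 * se + 1e-9)
  }
})
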