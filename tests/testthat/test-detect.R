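test_that("candidates carry the geometry of their connected component", {
  expect_equal(find_candidates(matrix(0L, 20, 20)), list())

  sq <- raster_rect(40, 40, 10, 10, 20, 20)
  cands <- find_candidates(sq)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$W, 20)
  expect_equal(cands[[1]]$H, 20)
  expect_equal(cands[[1]]$aspect, 1.0)
  expect_equal(cands[[1]]$CA, 400)

  # disk of radius 30 plus a separate 5x40 bar
  m <- raster_ellipse(120, 200, 60, 60, 30)
  m[20:24, 130:169] <- 1L
  cands <- find_candidates(m)
  expect_length(cands, 2)
  aspects <- sort(vapply(cands, `[[`, numeric(1), "aspect"))
  expect_equal(aspects[1], 5 / 40)
  # agreement with an independent BFS component labelling
  lab <- bfs_components(m)
  expect_equal(sort(vapply(cands, `[[`, numeric(1), "CA")),
               sort(as.numeric(table(lab[lab > 0]))))
})

test_that("holes are filled before measuring a candidate (outer boundary only)", {
  disk <- raster_ellipse(80, 80, 40, 40, 20)
  holed <- disk
  holed[38:42, 38:42] <- 0L    # interior glint hole
  cands <- find_candidates(holed)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$CA, sum(disk))
})

test_that("area and aspect filters use strict thresholds and match a brute-force scan", {
  mk <- function(CA, aspect) structure(list(CA = CA, W = 1, H = 1, aspect = aspect,
                                            contour = NULL), class = "pupil_candidate")
  cands <- list(mk(250, 0.9), mk(500, 0.125), mk(301, 0.95), mk(299, 0.95),
                mk(300, 0.75), mk(3900, 0.39), mk(4100, 0.41), mk(9000, 0.4))
  cfg <- detector_config()
  kept <- filter_candidates(cands, cfg)
  brute <- cands[vapply(cands, function(cc) cc$CA > 300 && cc$aspect > 0.4, logical(1))]
  expect_identical(kept, brute)
  expect_equal(vapply(kept, `[[`, numeric(1), "CA"), c(301, 4100))
  # idempotence
  expect_identical(filter_candidates(kept, cfg), kept)
  # optional upper bound
  kept2 <- filter_candidates(cands, detector_config(ca_max = 5000))
  expect_equal(vapply(kept2, `[[`, numeric(1), "CA"), c(301, 4100))
  kept3 <- filter_candidates(cands, detector_config(ca_max = 4100))
  expect_equal(vapply(kept3, `[[`, numeric(1), "CA"), 301)
})

test_that("the largest surviving candidate is the pupil; ties go to scan order", {
  mk <- function(CA, tag) structure(list(CA = CA, W = 1, H = 1, aspect = 1,
                                         contour = NULL, tag = tag),
                                    class = "pupil_candidate")
  expect_null(select_pupil(list()))
  expect_equal(select_pupil(list(mk(400, "a"), mk(900, "b"), mk(500, "c")))$tag, "b")
  expect_equal(select_pupil(list(mk(400, "first"), mk(400, "second")))$tag, "first")
})

test_that("least-squares ellipse fit recovers analytic areas of rasterized shapes", {
  circ <- find_candidates(raster_ellipse(100, 100, 50.3, 50.7, 20))[[1]]
  expect_lt(abs(fit_ellipse_area(circ)$area - pi * 20^2) / (pi * 20^2), 0.05)

  ell <- find_candidates(raster_ellipse(120, 120, 60, 60, 25, 15))[[1]]
  m <- fit_ellipse_area(ell)
  expect_lt(abs(m$area - pi * 25 * 15) / (pi * 25 * 15), 0.05)
  expect_equal(sort(c(round(m$ellipse$a), round(m$ellipse$b))), c(15, 25))

  degen <- structure(list(contour = cbind(x = c(0, 1, 2, 3), y = c(0, 0, 1, 1)),
                          CA = 4, W = 4, H = 2, aspect = 0.5),
                     class = "pupil_candidate")
  expect_warning(md <- fit_ellipse_area(degen), "degenerate")
  expect_equal(md$area, 0)
  expect_null(md$ellipse)
})

test_that("detect_sequence runs the full per-frame chain with 0 for no-pupil frames", {
  empty <- replicate(10, matrix(0L, 30, 30), simplify = FALSE)
  ts <- detect_sequence(empty, fps = 30)
  expect_equal(ts$areas, rep(0, 10))

  # sub-threshold blobs (< 300 px) never register
  small <- replicate(5, raster_rect(40, 40, 10, 10, 15, 15), simplify = FALSE)  # 225 px
  expect_equal(detect_sequence(small, fps = 30)$areas, rep(0, 5))

  # known disk radii recovered within 5%, blink frames exactly zero
  radii <- c(14, 16, 18, 0, 0, 20, 22, 0, 19, 17)
  masks <- lapply(radii, function(r) {
    if (r == 0) matrix(0L, 120, 120) else raster_ellipse(120, 120, 60, 60, r)
  })
  ts <- detect_sequence(masks, fps = 30, details = TRUE)
  open <- radii > 0
  expect_equal(ts$areas == 0, !open)
  expect_true(all(abs(ts$areas[open] - pi * radii[open]^2) / (pi * radii[open]^2) < 0.05))
  det <- attr(ts, "measurements")
  expect_equal(names(det), c("frame", "area", "cx", "cy", "axis_a", "axis_b", "angle"))
  expect_true(all(is.na(det$cx[!open])) && all(!is.na(det$cx[open])))
})

test_that("detection is invariant under mask translation", {
  base <- raster_ellipse(100, 140, 40, 45, 18, 12)
  shifted <- matrix(0L, 100, 140)
  shifted[31:100, 21:140] <- base[1:70, 1:120]  # shift by (+30, +20)
  a1 <- detect_sequence(list(base), fps = 30)$areas
  a2 <- detect_sequence(list(shifted), fps = 30)$areas
  expect_equal(a1, a2, tolerance = 1e-8)
})
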