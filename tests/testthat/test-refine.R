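test_that("edge snap pulls the radius onto the ring and reports support", {
  em <- ring_edge_map(160, 160, list(circle(80, 80, 50)))
  snap <- edge_snap(em, circle(80, 80, 45), edge_snap_config())
  expect_lt(abs(snap$circle$r - 50), 1)
  expect_equal(snap$circle$cx, 80) # center untouched
  expect_gt(snap$support, 0.9)

  # No signal: radius unchanged, support zero.
  blank <- blank_edge_map(120, 120)
  s0 <- edge_snap(blank, circle(60, 60, 30), edge_snap_config())
  expect_equal(s0$circle$r, 30)
  expect_equal(s0$support, 0)

  # Annulus band that excludes the true ring: radius unchanged.
  s1 <- edge_snap(em, circle(80, 80, 30), edge_snap_config(annulus_frac = 0.2))
  expect_equal(s1$circle$r, 30)
  expect_lt(s1$support, 0.1)

  expect_error(edge_snap(em, circle(5000, 5000, 10), edge_snap_config()),
               class = "hipwear_out_of_bounds")
})

test_that("ring-point harvesting respects the band and response threshold", {
  blank <- blank_edge_map(64, 64)
  expect_equal(nrow(harvest_ring_points(blank, circle(32, 32, 10))), 0)

  em <- ring_edge_map(160, 160, list(circle(80, 80, 50)))
  pts <- harvest_ring_points(em, circle(80, 80, 50), ring_frac = 0.1)
  expect_gt(nrow(pts), 100)
  d <- sqrt((pts[, 1] - 80)^2 + (pts[, 2] - 80)^2)
  expect_true(all(abs(d - 50) <= 0.1 * 50))

  # Count is monotone non-decreasing in the ring width.
  counts <- vapply(c(0.05, 0.10, 0.20), function(f) {
    nrow(harvest_ring_points(em, circle(80, 80, 47), ring_frac = f))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("RANSAC recovers circles exactly and under contamination", {
  truth <- circle(80, 80, 40)
  clean <- circle_points(truth, 100)
  fit <- ransac_circle(clean, ransac_config(seed = 1))
  expect_equal(c(fit$circle$cx, fit$circle$cy, fit$circle$r), c(80, 80, 40),
               tolerance = 1e-6)
  expect_equal(fit$inlier_fraction, 1)

  set.seed(42)
  inl <- circle_points(truth, 80, radial_sd = 1)
  out <- cbind(runif(20, 0, 160), runif(20, 0, 160))
  fit2 <- ransac_circle(rbind(inl, out), ransac_config(n_iter = 500, seed = 42))
  expect_lt(abs(fit2$circle$cx - 80), 1)
  expect_lt(abs(fit2$circle$cy - 80), 1)
  expect_lt(abs(fit2$circle$r - 40), 1)

  expect_error(ransac_circle(clean[1:2, ]), class = "hipwear_insufficient_data")
  degen <- cbind(1:5, 1:5)
  expect_error(ransac_circle(degen), class = "hipwear_degenerate_geometry")
})

test_that("RANSAC is deterministic for a fixed seed", {
  set.seed(5)
  pts <- rbind(circle_points(circle(50, 50, 20), 40, radial_sd = 1),
               cbind(runif(60, 0, 100), runif(60, 0, 100)))
  a <- ransac_circle(pts, ransac_config(n_iter = 200, seed = 9))
  b <- ransac_circle(pts, ransac_config(n_iter = 200, seed = 9))
  expect_identical(a, b)
})

test_that("Hough voting finds single and multiple rings", {
  em <- ring_edge_map(128, 128, list(circle(64, 64, 40)))
  peaks <- hough_circles(em, 30, 50, r_step = 1, n_peaks = 3)
  expect_gt(length(peaks), 0)
  top <- peaks[[1]]$circle
  expect_lte(abs(top$cx - 64), 2)
  expect_lte(abs(top$cy - 64), 2)
  expect_lte(abs(top$r - 40), 1)

  expect_equal(hough_circles(blank_edge_map(64, 64), 10, 20), list())

  em2 <- ring_edge_map(200, 100, list(circle(50, 50, 30), circle(150, 50, 30)))
  pk2 <- hough_circles(em2, 20, 40, n_peaks = 2)
  expect_length(pk2, 2)
  centers <- sort(vapply(pk2, function(p) p$circle$cx, 0))
  expect_lte(abs(centers[1] - 50), 2)
  expect_lte(abs(centers[2] - 150), 2)
})

test_that("the cup candidate grid is deterministic and bounded", {
  c0 <- circle(100, 100, 60)
  expect_length(generate_cup_candidates(c0, n_shifts = 1, n_scales = 1), 1)
  g <- generate_cup_candidates(c0, n_shifts = 1, n_scales = 1)[[1]]
  expect_equal(c(g$cx, g$cy, g$r), c(100, 100, 60))

  cands <- generate_cup_candidates(c0, n_shifts = 3, shift_frac = 0.1,
                                   scale_range = c(0.9, 1.1), n_scales = 5)
  expect_length(cands, 3^2 * 5)
  dc <- vapply(cands, function(cc) {
    sqrt((cc$cx - 100)^2 + (cc$cy - 100)^2)
  }, 0)
  expect_true(all(dc <= sqrt(2) * 0.1 * 60 + 1e-9))
  # The proposal itself is in the grid (odd shifts, scale grid contains 1).
  expect_true(any(vapply(cands, function(cc) {
    cc$cx == 100 && cc$cy == 100 && cc$r == 60
  }, TRUE)))
})

test_that("composite cup scoring rewards supported, enclosing candidates", {
  fem <- circle(80, 80, 30)
  em <- ring_edge_map(160, 160, list(fem, circle(80, 80, 55)))
  sc <- score_cup_candidate(circle(80, 80, 55), em, fem, c(80, 80))
  expect_gt(sc$edge_support, 0.9)
  expect_gt(sc$angular_coverage, 0.9)
  expect_gt(sc$longest_arc, 0.9 * 2 * pi)
  expect_gt(sc$gradient_alignment, 0.95)
  expect_equal(sc$outside_fraction, 1)

  # Candidate over a blank corner region scores near zero.
  far <- score_cup_candidate(circle(20, 150, 12), em, fem, c(80, 80))
  expect_lt(far$total, 0.1)

  # Enclosing vs head-cutting candidate: the enclosing one has the higher
  # outside fraction.
  emx <- ring_edge_map(200, 200, list(circle(100, 100, 35), circle(100, 100, 60)))
  enclosing <- score_cup_candidate(circle(100, 100, 60), emx,
                                   circle(100, 100, 35), c(100, 100))
  cutting <- score_cup_candidate(circle(130, 100, 45), emx,
                                 circle(100, 100, 35), c(100, 100))
  expect_gt(enclosing$outside_fraction, cutting$outside_fraction)

  expect_error(
    score_cup_candidate(fem, em, fem, c(80, 80), weights = rep(0, 6)),
    class = "hipwear_parameter"
  )
})

test_that("deleting supporting edge pixels never increases support or coverage", {
  fem <- circle(80, 80, 30)
  cup <- circle(80, 80, 55)
  em <- ring_edge_map(160, 160, list(fem, cup))
  before <- score_cup_candidate(cup, em, fem, c(80, 80))
  set.seed(44)
  idx <- which(em$edges)
  d <- sqrt((((idx - 1) %/% em$H) - 80)^2 + (((idx - 1) %% em$H) - 80)^2)
  supp_idx <- idx[abs(d - 55) <= 2]
  for (frac in c(0.2, 0.5, 0.8)) {
    em2 <- em
    drop <- sample(supp_idx, round(frac * length(supp_idx)))
    em2$edges[drop] <- FALSE
    em2$combined[drop] <- 0
    after <- score_cup_candidate(cup, em2, fem, c(80, 80))
    expect_lte(after$edge_support, before$edge_support + 1e-12)
    expect_lte(after$angular_coverage, before$angular_coverage + 1e-12)
  }
})

test_that("the anatomical filter enforces ordering, gap, ROI and edge density", {
  em <- ring_edge_map(200, 200, list(circle(100, 100, 40), circle(100, 100, 60)))
  roi <- roi_box(20, 20, 180, 180)

  ok <- anatomical_filter(circle(100, 100, 40), circle(100, 100, 60), em, roi = roi)
  expect_true(ok$pass)
  expect_length(ok$reasons, 0)

  eq <- anatomical_filter(circle(100, 100, 60), circle(100, 100, 60), em, roi = roi)
  expect_false(eq$pass)
  expect_true(any(grepl("radius ordering", eq$reasons)))

  cross <- anatomical_filter(circle(100, 100, 40), circle(135, 100, 60), em, roi = roi)
  expect_false(cross$pass)
  expect_true(any(grepl("joint-space gap", cross$reasons)))

  outside <- anatomical_filter(circle(100, 100, 40), circle(100, 100, 60), em,
                               roi = roi_box(150, 150, 190, 190))
  expect_false(outside$pass)
  expect_true(any(grepl("outside ROI", outside$reasons)))

  faint <- anatomical_filter(circle(100, 100, 40), circle(100, 100, 80), em, roi = roi)
  expect_false(faint$pass) # no edges anywhere near r = 80
  expect_true(any(grepl("edge density", faint$reasons)))
})

test_that("prosthesis fitting is deterministic and rejects blank ROIs", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 5, seed = 77))
  dims <- image_dims(320, 320)
  rois <- oracle_roi_provider(ph$truth, dims, jitter = 0.02, seed = 3)
  f1 <- fit_prosthesis(ph$image, rois)
  f2 <- fit_prosthesis(ph$image, rois)
  expect_identical(f1[c("femoral", "cup", "method")], f2[c("femoral", "cup", "method")])
  expect_true(f1$cup$r > f1$femoral$r)

  blank <- matrix(90, 320, 320)
  expect_error(fit_prosthesis(blank, rois), class = "hipwear_no_valid_fit")
  expect_error(fit_prosthesis(ph$image, list()), class = "hipwear_input")
})
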