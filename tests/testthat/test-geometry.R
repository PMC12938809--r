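test_that("circle normalization follows the mean-dimension convention", {
  dims <- image_dims(640, 480)
  nc <- normalize_circle(circle(320, 240, 56), dims, cls = 0)
  expect_equal(nc$x, 0.5)
  expect_equal(nc$y, 0.5)
  expect_equal(nc$r, 0.1) # 56 / ((640 + 480) / 2)

  z <- normalize_circle(circle(0, 0, 0), dims, cls = 1)
  expect_equal(c(z$x, z$y, z$r), c(0, 0, 0))

  sq <- normalize_circle(circle(50, 50, 50), image_dims(100, 100), cls = 0)
  expect_equal(sq$r, 0.5)

  expect_error(image_dims(0, 100), class = "hipwear_invalid_dimension")
})

test_that("denormalization inverts normalization", {
  dims <- image_dims(640, 480)
  c1 <- denormalize_circle(norm_circle(0, 0.5, 0.5, 0.1), dims)
  expect_equal(c(c1$cx, c1$cy, c1$r), c(320, 240, 56))

  z <- denormalize_circle(norm_circle(0, 0, 0, 0), dims)
  expect_equal(c(z$cx, z$cy, z$r), c(0, 0, 0))

  set.seed(11)
  for (i in 1:200) {
    dims <- image_dims(sample(16:2048, 1), sample(16:2048, 1))
    c0 <- random_circle(dims)
    back <- denormalize_circle(normalize_circle(c0, dims, cls = i %% 2), dims)
    expect_equal(c(back$cx, back$cy, back$r), c(c0$cx, c0$cy, c0$r),
                 tolerance = 1e-12)
  }
})

test_that("the normalized box circumscribes the pixel circle exactly", {
  sq <- circle_to_normbox(norm_circle(1, 0.5, 0.5, 0.2), image_dims(100, 100))
  expect_equal(sq$w, 0.4)
  expect_equal(sq$h, 0.4)

  dims <- image_dims(640, 480)
  b <- circle_to_normbox(norm_circle(0, 0.5, 0.5, 0.1), dims)
  expect_equal(b$w, 0.175)
  expect_equal(b$h, 7 / 30, tolerance = 1e-12) # 0.2333...
  expect_equal(b$w * dims$W, 112) # = 2 * 56 px

  z <- circle_to_normbox(norm_circle(0, 0.5, 0.5, 0), dims)
  expect_equal(c(z$w, z$h), c(0, 0))

  # Property: box side equals the circle diameter in both axes.
  set.seed(12)
  for (i in 1:100) {
    dims <- image_dims(sample(32:1500, 1), sample(32:1500, 1))
    r_px <- runif(1, 0, min(dims$W, dims$H) / 2)
    nc <- normalize_circle(circle(dims$W / 2, dims$H / 2, r_px), dims, cls = 0)
    b <- circle_to_normbox(nc, dims)
    expect_equal(b$w * dims$W, 2 * r_px, tolerance = 1e-9)
    expect_equal(b$h * dims$H, 2 * r_px, tolerance = 1e-9)
  }
})

test_that("three-point circle construction is exact and permutation-invariant", {
  u <- circle_from_three_points(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(c(u$cx, u$cy, u$r), c(0, 0, 1), tolerance = 1e-12)

  v <- circle_from_three_points(c(0, 0), c(2, 0), c(1, 1))
  expect_equal(c(v$cx, v$cy, v$r), c(1, 0, 1), tolerance = 1e-12)

  expect_error(circle_from_three_points(c(0, 0), c(1, 1), c(2, 2)),
               class = "hipwear_degenerate_geometry")
  expect_error(circle_from_three_points(c(1, 1), c(1, 1), c(2, 2)),
               class = "hipwear_degenerate_geometry")

  set.seed(13)
  pts <- matrix(runif(6, 0, 100), 3, 2)
  ref <- circle_from_three_points(pts[1, ], pts[2, ], pts[3, ])
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    alt <- circle_from_three_points(pts[perm[1], ], pts[perm[2], ], pts[perm[3], ])
    expect_equal(c(alt$cx, alt$cy, alt$r), c(ref$cx, ref$cy, ref$r),
                 tolerance = 1e-9)
  }
})

test_that("least-squares circle fit recovers exact and noisy circles", {
  truth <- circle(50, 50, 30)
  fit <- fit_circle_lsq(circle_points(truth, 20))
  expect_equal(c(fit$cx, fit$cy, fit$r), c(50, 50, 30), tolerance = 1e-6)

  # Duplicating a point changes nothing beyond solver tolerance.
  pts <- circle_points(truth, 20)
  fit2 <- fit_circle_lsq(rbind(pts, pts[1, ]))
  expect_equal(c(fit2$cx, fit2$cy, fit2$r), c(fit$cx, fit$cy, fit$r),
               tolerance = 1e-6)

  # Radially noisy points: compare against an independent geometric
  # minimizer of the sum of squared radial residuals.
  set.seed(17)
  noisy <- circle_points(truth, 60, radial_sd = 0.5)
  fitn <- fit_circle_lsq(noisy)
  obj <- function(p) sum((sqrt((noisy[, 1] - p[1])^2 + (noisy[, 2] - p[2])^2) - p[3])^2)
  oracle <- stats::optim(c(49, 51, 29), obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 5000))$par
  expect_lt(abs(fitn$cx - 50), 0.3)
  expect_lt(abs(fitn$cy - 50), 0.3)
  expect_lt(abs(fitn$r - 30), 0.3)
  expect_equal(c(fitn$cx, fitn$cy, fitn$r), oracle, tolerance = 0.05)

  expect_error(fit_circle_lsq(matrix(c(0, 0, 1, 1), 2, 2)),
               class = "hipwear_degenerate_geometry")
  expect_error(fit_circle_lsq(cbind(0:5, 0:5)),
               class = "hipwear_degenerate_geometry")
})
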