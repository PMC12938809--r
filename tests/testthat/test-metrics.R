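test_that("IoU is exact, symmetric, and bounded", {
  a <- roi_box(0, 0, 1, 1)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, roi_box(5, 5, 6, 6)), 0)
  expect_equal(iou(a, roi_box(0.5, 0, 1.5, 1)), 1 / 3)

  set.seed(61)
  for (i in 1:50) {
    b1 <- roi_box(runif(1, 0, 5), runif(1, 0, 5),
                  runif(1, 5.1, 10), runif(1, 5.1, 10))
    b2 <- roi_box(runif(1, 0, 5), runif(1, 0, 5),
                  runif(1, 5.1, 10), runif(1, 5.1, 10))
    v <- iou(b1, b2)
    expect_equal(v, iou(b2, b1))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("detection matching is greedy, one-to-one, and per class", {
  truths <- list(roi_box(0, 0, 10, 10, cls = 0),
                 roi_box(20, 0, 30, 10, cls = 0),
                 roi_box(40, 0, 50, 10, cls = 1))
  m <- match_detections(truths, truths, conf_t = 0.5, iou_tau = 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))

  m0 <- match_detections(list(), truths, conf_t = 0.5, iou_tau = 0.5)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 3L))

  # A duplicate prediction of a matched truth is a false positive.
  preds <- c(truths, list(roi_box(1, 0, 11, 10, confidence = 0.8, cls = 0)))
  m1 <- match_detections(preds, truths, conf_t = 0.5, iou_tau = 0.5)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(3L, 1L, 0L))

  # tp + fn always equals the number of truths.
  set.seed(62)
  for (i in 1:20) {
    tr <- lapply(1:4, function(k) {
      x <- runif(1, 0, 80)
      roi_box(x, 0, x + 10, 10, cls = k %% 2)
    })
    pr <- lapply(1:6, function(k) {
      x <- runif(1, 0, 80)
      roi_box(x, 0, x + 10, 10, confidence = runif(1), cls = k %% 2)
    })
    mm <- match_detections(pr, tr, conf_t = 0.3, iou_tau = 0.5)
    expect_equal(mm$tp + mm$fn, 4L)
  }
})

test_that("precision, recall and F1 handle all regimes", {
  pr <- precision_recall_f1(list(tp = 9, fp = 1, fn = 2))
  expect_equal(pr[["precision"]], 0.9)
  expect_equal(pr[["recall"]], 9 / 11)
  expect_equal(pr[["f1"]], 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))

  expect_equal(unname(precision_recall_f1(list(tp = 5, fp = 0, fn = 0))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 0, fn = 0))),
               c(0, 0, 0))
})

test_that("average precision integrates the all-points PR curve", {
  perfect <- data.frame(confidence = c(0.9, 0.8, 0.7), is_tp = TRUE)
  expect_equal(average_precision(perfect, 3)$ap, 1)

  none <- data.frame(confidence = c(0.9, 0.8), is_tp = FALSE)
  expect_equal(average_precision(none, 2)$ap, 0)

  # Hand enumeration for a 5-item ranked list (2 truths):
  # ranks: TP, FP, TP, FP, FP -> points at conf levels:
  #   after 1: P=1, R=1/2 ; after 3: P=2/3, R=1 ; (others add no recall)
  # AP = 1 * 1/2 + 2/3 * 1/2 = 5/6
  five <- data.frame(confidence = c(0.9, 0.8, 0.7, 0.6, 0.5),
                     is_tp = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(average_precision(five, 2)$ap, 5 / 6, tolerance = 1e-12)

  pc <- average_precision(five, 2)
  expect_true(!is.unsorted(pc$points$recall))
})

test_that("mAP averages per-class AP", {
  expect_equal(mean_ap(c(1.0, 0.5)), 0.75)
  expect_equal(mean_ap(0.42), 0.42)
  expect_equal(mean_ap(c(0.2, 0.9, 0.4)), mean_ap(c(0.9, 0.4, 0.2)))
  expect_error(mean_ap(numeric(0)), class = "hipwear_empty_input")
})

test_that("tolerance-accuracy curves count fractions and stay monotone", {
  tc <- tolerance_accuracy_curve(c(0.005, 0.015, 0.025), c(0.01, 0.02, 0.03))
  expect_equal(tc$accuracy, c(1 / 3, 2 / 3, 1))

  z <- tolerance_accuracy_curve(rep(0, 5), c(0.001, 0.01))
  expect_equal(z$accuracy, c(1, 1))

  set.seed(63)
  e <- runif(40, 0, 0.1)
  tc2 <- tolerance_accuracy_curve(e, seq(0.005, 0.1, by = 0.005))
  expect_true(all(diff(tc2$accuracy) >= 0))
  expect_true(all(tc2$accuracy >= 0 & tc2$accuracy <= 1))

  expect_error(tolerance_accuracy_curve(numeric(0), c(0.1)),
               class = "hipwear_empty_input")
})

test_that("error summaries report the stated statistics", {
  s <- error_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$max, 5)
  expect_equal(s$std, sd(1:5))
  expect_lte(s$median, s$p95)
  expect_lte(s$p95, s$max)

  one <- error_summary(0.7)
  expect_equal(unlist(one[c("mean", "median", "p95", "max")]),
               c(mean = 0.7, median = 0.7, p95 = 0.7, max = 0.7))
  expect_equal(one$std, 0)

  set.seed(64)
  e <- runif(30)
  expect_equal(unclass(error_summary(e)), unclass(error_summary(sample(e))))
  expect_error(error_summary(numeric(0)), class = "hipwear_empty_input")
})
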