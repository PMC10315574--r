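fake_gt <- function(x, y, pickable = TRUE, ax = numeric(0), ay = numeric(0)) {
  n <- length(x)
  structure(list(
    colonies = data.frame(id = seq_len(n), x_px = x, y_px = y,
                          pickable = rep_len(pickable, n)),
    artifacts = data.frame(id = seq_along(ax), x_px = ax, y_px = ay,
                           radius_px = rep(2, length(ax))),
    dish = list(scale_mm_per_px = 0.1)), class = "gt_plate")
}

fake_det <- function(x, y, labels = NULL) {
  structure(list(
    labels = labels,
    footprints = data.frame(id = seq_along(x), x = x, y = y),
    segmap = list(crop_origin = c(1, 1))), class = "colony_footprints")
}

test_that("perfect detection gives TP only and unit metrics", {
  gt <- fake_gt(x = seq(100, 1000, by = 100), y = rep(200, 10))
  det <- fake_det(gt$colonies$x_px + 2, gt$colonies$y_px - 2)
  m <- match_detections(det, gt, crop_origin = c(1, 1))
  expect_equal(m$TP, 10); expect_equal(m$FP, 0); expect_equal(m$FN, 0)
  r <- compute_metrics(m)
  expect_equal(r$sensitivity, 1); expect_equal(r$precision, 1)
  expect_equal(r$accuracy, 1); expect_equal(r$misclassification_rate, 0)
  expect_equal(r$raw_performance_pickable, 1)
})

test_that("missed colonies count as false negatives", {
  gt <- fake_gt(x = seq(100, 1000, by = 100), y = rep(200, 10))
  m <- match_detections(fake_det(numeric(0), numeric(0)), gt,
                        crop_origin = c(1, 1))
  expect_equal(m$FN, 10); expect_equal(m$TP, 0)
  r <- compute_metrics(m)
  expect_equal(r$sensitivity, 0)
  expect_true(is.na(r$precision))  # zero denominator reported as absent
})

test_that("metric arithmetic matches the count definitions", {
  gt <- fake_gt(x = seq(100, 1000, by = 100), y = rep(200, 10))
  det_x <- c(gt$colonies$x_px[1:9], 300, 500, 700)
  det_y <- c(gt$colonies$y_px[1:9], 600, 600, 600)
  m <- match_detections(fake_det(det_x, det_y), gt, crop_origin = c(1, 1))
  expect_equal(m$TP, 9); expect_equal(m$FP, 3); expect_equal(m$FN, 1)
  r <- compute_metrics(m)
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$precision, 0.75)
  expect_equal(r$accuracy, 9 / 13)
  expect_equal(r$misclassification_rate, 1 - 9 / 13)
})

test_that("surplus detections of one colony are flagged as multi-pick", {
  gt <- fake_gt(x = c(100, 300), y = c(100, 100))
  det <- fake_det(c(100, 104, 300), c(100, 100, 100))
  m <- match_detections(det, gt, crop_origin = c(1, 1))
  expect_equal(m$TP, 2)
  expect_equal(m$FP, 1)
  expect_equal(m$multi_pick, 1)
})

test_that("non-pickable truths are excluded from the pickable metrics", {
  gt <- fake_gt(x = c(100, 200, 300, 400), y = rep(100, 4),
                pickable = c(TRUE, TRUE, FALSE, FALSE))
  det <- fake_det(c(100, 200, 300), rep(100, 3))
  m <- match_detections(det, gt, crop_origin = c(1, 1))
  expect_equal(m$TP, 2)                 # only pickable matches are TP
  expect_equal(m$matched_not_pickable, 1)
  expect_equal(m$FP, 0)                 # a matched border colony is not noise
  expect_equal(m$not_pickable, 2)
  expect_equal(compute_metrics(m)$raw_performance_pickable, 1)
})

test_that("artifact hits are separated from plain false positives", {
  gt <- fake_gt(x = 100, y = 100, ax = 400, ay = 400)
  det <- fake_det(c(100, 400, 700), c(100, 400, 700))
  m <- match_detections(det, gt, crop_origin = c(1, 1))
  expect_equal(m$TP, 1); expect_equal(m$FP, 2)
  expect_equal(m$detected_artifacts, 1)
})

test_that("one mask covering two truth centres counts as group-as-single", {
  labels <- matrix(0L, 60, 60)
  labels[10:40, 10:20] <- 1L
  gt <- fake_gt(x = c(15, 35), y = c(15, 15))
  det <- fake_det(25, 15, labels = labels)
  m <- match_detections(det, gt, crop_origin = c(1, 1))
  expect_equal(m$group_as_single, 1)
})

test_that("accuracy never exceeds sensitivity or precision", {
  set.seed(55)
  for (i in 1:50) {
    m <- structure(list(TP = sample(0:50, 1), FP = sample(0:20, 1),
                        FN = sample(0:20, 1), total_truth = 60,
                        pickable_truth = 50), class = "match_result")
    if (m$TP + m$FP + m$FN == 0) next
    r <- compute_metrics(m)
    if (!is.na(r$accuracy)) {
      if (!is.na(r$sensitivity)) expect_lte(r$accuracy, r$sensitivity + 1e-12)
      if (!is.na(r$precision)) expect_lte(r$accuracy, r$precision + 1e-12)
    }
  }
})

test_that("pooling plates equals metrics on summed counts, order-free", {
  gt1 <- fake_gt(x = seq(100, 500, 100), y = rep(100, 5))
  gt2 <- fake_gt(x = seq(100, 300, 100), y = rep(300, 3))
  m1 <- match_detections(fake_det(gt1$colonies$x_px[1:4], rep(100, 4)), gt1,
                         crop_origin = c(1, 1))
  m2 <- match_detections(fake_det(c(gt2$colonies$x_px, 800), rep(300, 4)), gt2,
                         crop_origin = c(1, 1))
  pooled <- pool_matches(list(m1, m2))
  pooled_rev <- pool_matches(list(m2, m1))
  expect_equal(unclass(pooled), unclass(pooled_rev))
  expect_equal(pooled$TP, m1$TP + m2$TP)
  r <- compute_metrics(pooled)
  expect_equal(r$sensitivity, pooled$TP / (pooled$TP + pooled$FN))
  expect_equal(r$precision, pooled$TP / (pooled$TP + pooled$FP))
})

test_that("matching rejects a non-positive tolerance", {
  gt <- fake_gt(100, 100)
  expect_error(match_detections(fake_det(100, 100), gt, crop_origin = c(1, 1),
                                tol_mm = 0), "tol_mm")
})
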