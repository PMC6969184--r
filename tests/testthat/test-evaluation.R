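det_tbl <- function(peak, score) {
  out <- tibble::tibble(peak_time_s = peak, score = score,
                        begin_time_s = peak - 1, end_time_s = peak + 1)
  class(out) <- c("detections", class(out))
  out
}

test_that("matching is one-to-one with count identities", {
  ann <- annotations(10, 11, 50, 200)
  m <- match_detections(det_tbl(10.5, 0.9), ann)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  # two detections inside one annotation: higher score wins, other is FP
  m2 <- match_detections(det_tbl(c(10.2, 10.8), c(0.4, 0.9)), ann)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))
  expect_equal(m2$tp_pairs$detection, 2L)

  # identities on random inputs
  set.seed(12)
  for (k in 1:20) {
    nd <- sample(0:60, 1); na <- sample(1:30, 1)
    b <- sort(stats::runif(na, 0, 500))
    ann_r <- annotations(b, b + stats::runif(na, 0.5, 2), 50, 200)
    det_r <- det_tbl(stats::runif(nd, 0, 500), stats::runif(nd))
    m <- match_detections(det_r, ann_r)
    expect_equal(m$TP + m$FN, na)
    expect_equal(m$TP + m$FP, nd)
  }
})

test_that("matching counts equal an independent greedy reference", {
  set.seed(77)
  for (k in 1:10) {
    nd <- 200; na <- 50
    b <- sort(stats::runif(na, 0, 2000))
    ann <- annotations(b, b + stats::runif(na, 0.5, 2), 50, 200)
    det <- det_tbl(stats::runif(nd, 0, 2000), stats::runif(nd))
    m <- match_detections(det, ann, tolerance_s = 0.5)
    ref <- reference_match_counts(det$peak_time_s, det$score,
                                  ann$begin_time_s, ann$end_time_s, 0.5)
    expect_equal(c(m$TP, m$FP, m$FN), unname(ref))
  }
})

test_that("precision and recall are exact ratios with undefined flags", {
  m <- list(TP = 8, FP = 2, FN = 2)
  class(m) <- "match_result"
  pr <- precision_recall(m)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)

  m0 <- list(TP = 0, FP = 0, FN = 3)
  class(m0) <- "match_result"
  pr0 <- precision_recall(m0)
  expect_false(pr0$precision_defined)
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)

  # spreadsheet oracle over a seeded sweep
  set.seed(4)
  for (k in 1:10) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    mk <- list(TP = tp, FP = fp, FN = fn)
    class(mk) <- "match_result"
    prk <- precision_recall(mk)
    expect_equal(prk$precision, tp / (tp + fp))
    expect_equal(prk$recall, tp / (tp + fn))
  }
})

test_that("pr_curve hits its degenerate anchors", {
  ann <- annotations(c(10, 20, 30), c(11, 21, 31), 50, 200)
  # perfect detector
  perfect <- det_tbl(c(10.5, 20.5, 30.5), c(0.9, 0.8, 0.7))
  expect_equal(average_precision(pr_curve(perfect, ann)), 1.0)
  # detector that never matches truth
  misses <- det_tbl(c(100, 200), c(0.9, 0.8))
  expect_equal(average_precision(pr_curve(misses, ann)), 0)
  expect_error(pr_curve(perfect, annotations()),
               class = "upcallr_error_no_annotations")
})

test_that("average precision equals a brute-force recomputation and is
           invariant to monotone score transforms", {
  set.seed(21)
  b <- sort(stats::runif(40, 0, 1000))
  ann <- annotations(b, b + 1, 50, 200)
  peaks <- c(b[1:30] + 0.5, stats::runif(70, 0, 1000))
  scores <- stats::runif(100)
  det <- det_tbl(peaks, scores)

  curve <- pr_curve(det, ann)
  # brute force: recompute precision/recall at every threshold directly
  ths <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    keep <- det[det$score >= ths[i], ]
    cts <- reference_match_counts(keep$peak_time_s, keep$score,
                                  ann$begin_time_s, ann$end_time_s, 0.5)
    prec[i] <- cts["TP"] / (cts["TP"] + cts["FP"])
    rec[i] <- cts["TP"] / nrow(ann)
  }
  ap_ref <- sum(diff(c(0, rec)) * prec)
  expect_equal(average_precision(curve), ap_ref)

  det2 <- det
  det2$score <- plogis(5 * det$score - 2)  # strictly monotone transform
  expect_equal(average_precision(pr_curve(det2, ann)),
               average_precision(curve))
})

test_that("fp/hour and the recall-vs-fph sweep behave", {
  ann <- annotations(c(10, 20), c(11, 21), 50, 200)
  det <- det_tbl(c(10.5, 100, 200, 300, 400, 500, 600, 700, 800, 900,
                   1000, 1100, 1200, 1300, 1400, 1500, 1600, 1700, 1800,
                   1900, 2000, 10.2),
                 c(0.9, stats::runif(20, 0.1, 0.8), 0.05))
  m <- match_detections(det, ann)
  expect_equal(fp_per_hour(m, 2), m$FP / 2)
  expect_error(fp_per_hour(m, 0), class = "upcallr_error_bad_hours")

  curve <- recall_vs_fph(det, ann, recording_hours = 2)
  # recall is non-decreasing as fph grows (threshold decreasing)
  expect_true(all(diff(curve$recall) >= 0))
  expect_true(all(diff(curve$fp_per_hour) >= 0))
  # recall values agree with pr_curve at identical thresholds
  pc <- pr_curve(det, ann)
  expect_equal(curve$recall, pc$recall)
})

test_that("workload arithmetic follows the review-rate model", {
  w <- workload(0, 10, 0)
  expect_equal(w$total_hours, 0)
  w2 <- workload(5, 100, 250, review_rate_per_hour = 1000)
  expect_equal(w2$fp_count, 500)
  expect_equal(w2$verification_hours_fp, 0.5)
  expect_equal(w2$verification_hours_tp, 0.25)
  expect_equal(w2$total_hours, 0.75)
  expect_error(workload(-1, 1, 1), class = "upcallr_error_negative_input")
})

test_that("relative improvement is a rounded percent", {
  expect_equal(relative_improvement(0.6, 0.6), 0)
  expect_equal(relative_improvement(0.75, 0.5), 50)
  expect_error(relative_improvement(0.5, 0),
               class = "upcallr_error_bad_baseline")
})
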