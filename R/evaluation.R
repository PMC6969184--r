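#' Match detections against ground-truth annotations
#'
#' A detection may match an annotation iff its peak time falls in
#' `[begin - tolerance_s, end + tolerance_s]`. Assignment is greedy by
#' descending detection score and one-to-one: each annotation is used at
#' most once. Unmatched detections are false positives; unmatched
#' annotations are false negatives. So `TP + FN = n_annotations` and
#' `TP + FP = n_detections` always hold.
#'
#' @param detections A `detections` tibble ([non_max_suppress()]).
#' @param ann An [annotations()] tibble (ground truth, same stream).
#' @param tolerance_s Temporal tolerance in seconds (default 0.5).
#' @return A list of class `match_result`: `tp_pairs` (tibble of matched
#'   detection/annotation indices and times), `fp_idx`, `fn_idx`, and
#'   counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(detections, ann, tolerance_s = 0.5) {
  n_det <- nrow(detections)
  n_ann <- nrow(ann)
  matched_ann <- logical(n_ann)
  det_match <- rep(NA_integer_, n_det)
  ord <- order(-detections$score, detections$peak_time_s)
  for (i in ord) {
    t <- detections$peak_time_s[i]
    cand <- which(!matched_ann &
                    t >= ann$begin_time_s - tolerance_s &
                    t <= ann$end_time_s + tolerance_s)
    if (length(cand)) {
      # nearest annotation midpoint wins among the eligible
      mid <- (ann$begin_time_s[cand] + ann$end_time_s[cand]) / 2
      j <- cand[which.min(abs(mid - t))]
      matched_ann[j] <- TRUE
      det_match[i] <- j
    }
  }
  tp_idx <- which(!is.na(det_match))
  structure(
    list(
      tp_pairs = tibble::tibble(
        detection = tp_idx,
        annotation = det_match[tp_idx],
        peak_time_s = detections$peak_time_s[tp_idx],
        score = detections$score[tp_idx]),
      fp_idx = which(is.na(det_match)),
      fn_idx = which(!matched_ann),
      TP = length(tp_idx),
      FP = sum(is.na(det_match)),
      FN = sum(!matched_ann)),
    class = "match_result")
}

#' Precision and recall from a match result
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. Degenerate
#' cases (no detections, no annotations) are flagged as undefined rather
#' than silently reported as 0.
#'
#' @param match A `match_result` from [match_detections()].
#' @return List with `precision`, `recall` (NA when undefined) and flags
#'   `precision_defined`, `recall_defined`.
#' @export
precision_recall <- function(match) {
  pd <- (match$TP + match$FP) > 0
  rd <- (match$TP + match$FN) > 0
  list(
    precision = if (pd) match$TP / (match$TP + match$FP) else NA_real_,
    recall = if (rd) match$TP / (match$TP + match$FN) else NA_real_,
    precision_defined = pd,
    recall_defined = rd)
}

#' Precision-recall curve and average precision
#'
#' Sweeps the detection score threshold over the sorted unique scores
#' (descending), re-matching the surviving detections at each threshold.
#' Average precision is the step-wise area under the curve,
#' `sum((R_i - R_{i-1}) * P_i)`, which is invariant to strictly monotone
#' transformations of the scores.
#'
#' @param detections A `detections` tibble with scores.
#' @param ann Ground-truth [annotations()]; must be non-empty.
#' @param tolerance_s Matching tolerance in seconds (default 0.5).
#' @return A tibble of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`, and attribute `average_precision`.
#' @export
pr_curve <- function(detections, ann, tolerance_s = 0.5) {
  if (nrow(ann) == 0) {
    abort_upcallr("pr_curve requires at least one ground-truth annotation",
                  "upcallr_error_no_annotations")
  }
  thresholds <- sort(unique(detections$score), decreasing = TRUE)
  prec <- rec <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    keep <- detections[detections$score >= thresholds[k], ]
    m <- match_detections(keep, ann, tolerance_s)
    pr <- precision_recall(m)
    prec[k] <- pr$precision
    rec[k] <- pr$recall
  }
  ap <- if (length(thresholds)) {
    sum(diff(c(0, rec)) * prec)
  } else 0
  out <- tibble::tibble(threshold = thresholds, precision = prec, recall = rec)
  attr(out, "average_precision") <- ap
  class(out) <- c("pr_curve", class(out))
  out
}

#' Average precision of a PR curve
#' @param curve A `pr_curve` (or detections + truth via [pr_curve()]).
#' @return The step-wise area under the precision-recall curve.
#' @export
average_precision <- function(curve) {
  attr(curve, "average_precision")
}

#' False positives per recording hour
#'
#' The operational cost metric of continuous passive acoustic monitoring:
#' detector errors normalized by recording duration.
#'
#' @param match A `match_result`.
#' @param recording_hours Hours of audio the detections came from, `> 0`.
#' @return `FP / recording_hours`.
#' @export
fp_per_hour <- function(match, recording_hours) {
  if (recording_hours <= 0) {
    abort_upcallr("recording_hours must be positive",
                  "upcallr_error_bad_hours")
  }
  match$FP / recording_hours
}

#' Recall as a function of hourly false positives
#'
#' Sweeps the score threshold as in [pr_curve()] and reports
#' `(fp_per_hour, recall)` pairs, the operating curve used to pick a
#' detector threshold under a false-positive budget.
#'
#' @inheritParams pr_curve
#' @param recording_hours Hours of audio, `> 0`.
#' @return A tibble with columns `threshold`, `fp_per_hour`, `recall`.
#' @export
recall_vs_fph <- function(detections, ann, recording_hours, tolerance_s = 0.5) {
  if (recording_hours <= 0) {
    abort_upcallr("recording_hours must be positive",
                  "upcallr_error_bad_hours")
  }
  thresholds <- sort(unique(detections$score), decreasing = TRUE)
  fph <- rec <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    keep <- detections[detections$score >= thresholds[k], ]
    m <- match_detections(keep, ann, tolerance_s)
    fph[k] <- m$FP / recording_hours
    rec[k] <- if ((m$TP + m$FN) > 0) m$TP / (m$TP + m$FN) else 0
  }
  tibble::tibble(threshold = thresholds, fp_per_hour = fph, recall = rec)
}

#' Analyst-workload estimate for a detector operating point
#'
#' Converts a false-positive rate into analyst review time. An experienced
#' analyst can verify about 2,000 detections per working hour, so a
#' detector producing `fp_per_hour` false positives over
#' `recording_hours` hours of audio yields
#' `fp_count = fp_per_hour * recording_hours` detections to dismiss and
#' `fp_count / review_rate_per_hour` hours of review; verifying the true
#' calls adds `n_true_calls / review_rate_per_hour` hours.
#'
#' @param fp_per_hour False positives per recording hour.
#' @param recording_hours Hours of recording reviewed.
#' @param n_true_calls Number of true calls in the data.
#' @param review_rate_per_hour Detections an analyst can verify per working
#'   hour (default 2000).
#' @return A list of class `workload_estimate` with `fp_count`,
#'   `verification_hours_fp`, `verification_hours_tp` and `total_hours`.
#' @export
workload <- function(fp_per_hour, recording_hours, n_true_calls,
                     review_rate_per_hour = 2000) {
  if (any(c(fp_per_hour, recording_hours, n_true_calls,
            review_rate_per_hour) < 0)) {
    abort_upcallr("workload inputs must be non-negative",
                  "upcallr_error_negative_input")
  }
  fp_count <- fp_per_hour * recording_hours
  structure(
    list(fp_count = fp_count,
         verification_hours_fp = fp_count / review_rate_per_hour,
         verification_hours_tp = n_true_calls / review_rate_per_hour,
         total_hours = (fp_count + n_true_calls) / review_rate_per_hour,
         inputs = list(fp_per_hour = fp_per_hour,
                       recording_hours = recording_hours,
                       n_true_calls = n_true_calls,
                       review_rate_per_hour = review_rate_per_hour)),
    class = "workload_estimate")
}

#' Relative recall improvement over a baseline detector, in percent
#'
#' @param recall Recall of the detector under study.
#' @param baseline_recall Recall of the baseline, `> 0`.
#' @return `100 * (recall - baseline_recall) / baseline_recall`, rounded to
#'   the nearest integer percent.
#' @export
relative_improvement <- function(recall, baseline_recall) {
  if (baseline_recall <= 0) {
    abort_upcallr("baseline_recall must be positive",
                  "upcallr_error_bad_baseline")
  }
  round(100 * (recall - baseline_recall) / baseline_recall)
}
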