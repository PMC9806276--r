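# Detection evaluation: greedy confidence-ordered matching at a fixed
# IoU threshold, and the standard summary metrics
#   P  = TP / (TP + FP) * 100%          R = TP / (TP + FN) * 100%
#   F1 = 2 P R / (P + R)                AP = integral of P over R in [0,1]
# AP uses the exact all-points area under the precision envelope (not
# the legacy 11-point approximation). TN is recorded for completeness
# but enters none of the formulas.

# greedy one-to-one matching: detections in descending confidence (ties
# by input order), each ground truth matched at most once, IoU >= thr
match_detections <- function(detections, truths, iou_thr = 0.5) {
  nd <- nrow(detections); ng <- nrow(truths)
  tp_flag <- logical(nd)
  matched_gt <- integer(0)
  if (nd) {
    ord <- order(-detections$confidence)
    gt_used <- logical(ng)
    gt_m <- if (ng) as.matrix(truths[, c("x1", "y1", "x2", "y2")]) else NULL
    for (i in ord) {
      if (!ng) break
      iou <- box_iou(as.matrix(detections[i, c("x1", "y1", "x2", "y2")]),
                     gt_m)
      iou[gt_used] <- -1
      j <- which.max(iou)
      if (length(j) && iou[j] >= iou_thr) {
        gt_used[j] <- TRUE
        tp_flag[i] <- TRUE
      }
    }
    matched_gt <- which(gt_used)
  }
  list(tp_flag = tp_flag, order = if (nd) order(-detections$confidence)
       else integer(0), n_gt = ng, matched_gt = matched_gt)
}

#' Evaluate detections against ground truth
#'
#' @param detections a [pred_boxes()] data.frame with confidences
#'   (single class).
#' @param ground_truths a [pred_boxes()]-style data.frame of true boxes.
#' @param iou_thr IoU threshold for a match (default 0.5).
#' @return list of class `detection_eval`: `P_pct` and `R_pct`
#'   (percent), `F1` (fraction), `AP` (fraction), `counts` (TP, FP, FN,
#'   TN), and `zero_denominator` (TRUE when a rate's denominator was 0
#'   and the rate was defined as 0).
#' @examples
#' eval_from_counts(8, 2, 2)  # P = R = 80%, F1 = 0.80
#' @export
evaluate_detections <- function(detections, ground_truths, iou_thr = 0.5) {
  m <- match_detections(detections, ground_truths, iou_thr)
  tp <- sum(m$tp_flag)
  fp <- nrow(detections) - tp
  fn <- m$n_gt - tp
  res <- eval_from_counts(tp, fp, fn)
  res$AP <- average_precision(detections, ground_truths, iou_thr)
  res
}

#' Metrics from match counts
#'
#' @param tp,fp,fn true positives, false positives, false negatives.
#' @param tn true negatives (recorded, unused by any formula).
#' @return same structure as [evaluate_detections()] without `AP`.
#' @export
eval_from_counts <- function(tp, fp, fn, tn = 0L) {
  zero <- FALSE
  P <- if (tp + fp > 0) tp / (tp + fp) else { zero <- TRUE; 0 }
  R <- if (tp + fn > 0) tp / (tp + fn) else { zero <- TRUE; 0 }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else { zero <- TRUE; 0 }
  structure(list(P_pct = 100 * P, R_pct = 100 * R, F1 = F1, AP = NA_real_,
                 counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 zero_denominator = zero),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "<detection_eval> P %.2f%%  R %.2f%%  F1 %.3f  AP %s  (TP %d FP %d FN %d)\n",
    x$P_pct, x$R_pct, x$F1,
    if (is.na(x$AP)) "-" else sprintf("%.3f", x$AP),
    x$counts["TP"], x$counts["FP"], x$counts["FN"]))
  invisible(x)
}

#' Average precision (all-points area under the PR curve)
#'
#' Detections are swept in descending confidence; at every *distinct*
#' confidence level the running precision and recall are computed from
#' the greedy matching (detections sharing a confidence enter the curve
#' together, which makes AP invariant to how their tie is ordered), the
#' precision is replaced by its right-to-left running maximum (the
#' precision envelope), and AP is the area of the resulting step
#' function over recall.
#'
#' @inheritParams evaluate_detections
#' @return AP in `[0, 1]` (0 when there are no ground truths or no
#'   detections).
#' @export
average_precision <- function(detections, ground_truths, iou_thr = 0.5) {
  m <- match_detections(detections, ground_truths, iou_thr)
  if (m$n_gt == 0 || !length(m$order)) return(0)
  tp_sorted <- m$tp_flag[m$order]
  conf_sorted <- detections$confidence[m$order]
  cum_tp <- cumsum(tp_sorted)
  cum_fp <- cumsum(!tp_sorted)
  # one PR point per distinct confidence level (last index of each tie)
  at <- which(!duplicated(conf_sorted, fromLast = TRUE))
  recall <- cum_tp[at] / m$n_gt
  precision <- cum_tp[at] / (cum_tp[at] + cum_fp[at])
  envelope <- rev(cummax(rev(precision)))
  sum((recall - c(0, utils::head(recall, -1))) * envelope)
}
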