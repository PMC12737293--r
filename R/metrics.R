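# Detection evaluation: IoU / complete-IoU, greedy NMS, confidence-ranked
# matching, precision/recall, all-points average precision and mAP.
# Detections are data.frames with columns image, class_id, confidence,
# x1, y1, x2, y2; ground truth the same minus confidence. Boxes are
# half-open pixel rectangles with x1 < x2, y1 < y2.

#' Intersection-over-union of two boxes
#'
#' @param a,b numeric length-4 vectors (x1, y1, x2, y2).
#' @return IoU in \[0, 1\]; degenerate (zero-area) boxes give 0.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- max(0, a[3] - a[1]) * max(0, a[4] - a[2]) +
    max(0, b[3] - b[1]) * max(0, b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

# vectorized IoU of one box against a matrix of boxes (rows)
iou_many <- function(a, m) {
  iw <- pmax(0, pmin(a[3], m[, 3]) - pmax(a[1], m[, 1]))
  ih <- pmax(0, pmin(a[4], m[, 4]) - pmax(a[2], m[, 2]))
  inter <- iw * ih
  ua <- max(0, a[3] - a[1]) * max(0, a[4] - a[2]) +
    pmax(0, m[, 3] - m[, 1]) * pmax(0, m[, 4] - m[, 2]) - inter
  ifelse(ua <= 0, 0, inter / ua)
}

#' Complete-IoU loss between two boxes
#'
#' loss = 1 - IoU + rho^2/c^2 + alpha * v, where rho is the center distance,
#' c the diagonal of the smallest enclosing box, and v the aspect-ratio
#' consistency term 4/pi^2 (atan(w_g/h_g) - atan(w/h))^2 with
#' alpha = v / (1 - IoU + v). Zero-size boxes contribute no aspect term.
#'
#' @param pred,gt numeric length-4 boxes (x1, y1, x2, y2).
#' @return non-negative loss; 0 iff the boxes coincide.
#' @export
ciou_loss <- function(pred, gt) {
  i <- iou(pred, gt)
  cxp <- (pred[1] + pred[3]) / 2; cyp <- (pred[2] + pred[4]) / 2
  cxg <- (gt[1] + gt[3]) / 2; cyg <- (gt[2] + gt[4]) / 2
  rho2 <- (cxp - cxg)^2 + (cyp - cyg)^2
  cw <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  ch <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  c2 <- cw^2 + ch^2
  wp <- pred[3] - pred[1]; hp <- pred[4] - pred[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  v <- if (wp <= 0 || hp <= 0 || wg <= 0 || hg <= 0) 0 else {
    (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
  }
  alpha <- if (v == 0) 0 else v / (1 - i + v)
  dist <- if (c2 > 0) rho2 / c2 else 0
  1 - i + dist + alpha * v
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are processed per image and class in order of descending
#' confidence (ties broken by input order); a detection is suppressed if its
#' IoU with an already kept detection of the same image/class reaches the
#' threshold. The operation is idempotent.
#'
#' @param dets detection data.frame.
#' @param iou_threshold suppression threshold in \[0, 1\].
#' @return the surviving subset, original row order preserved within groups.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1)
  if (!nrow(dets)) return(dets)
  keep_rows <- integer()
  for (img in unique(dets$image)) {
    for (cl in unique(dets$class_id[dets$image == img])) {
      rows <- which(dets$image == img & dets$class_id == cl)
      ord <- rows[order(-dets$confidence[rows])]
      kept <- integer()
      for (r in ord) {
        if (length(kept)) {
          km <- as.matrix(dets[kept, c("x1", "y1", "x2", "y2")])
          if (any(iou_many(as.numeric(dets[r, c("x1", "y1", "x2", "y2")]), km) >=
                  iou_threshold)) next
        }
        kept <- c(kept, r)
      }
      keep_rows <- c(keep_rows, kept)
    }
  }
  dets[sort(keep_rows), , drop = FALSE]
}

#' Greedy one-to-one matching of detections against ground truth
#'
#' Detections are ranked by descending confidence (ties by input order) and
#' matched within class and image to the unmatched ground-truth box of
#' highest IoU, provided IoU >= threshold. Each ground truth matches at most
#' once, so TP + FN equals the number of ground truths.
#'
#' @param dets detection data.frame.
#' @param gts ground-truth data.frame (image, class_id, x1, y1, x2, y2).
#' @param iou_threshold matching threshold, default 0.5.
#' @return list with `tp`, `fp`, `fn` counts and `tp_flags` (logical, one per
#'   detection, in the input row order).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  n <- nrow(dets)
  flags <- logical(n)
  matched <- logical(nrow(gts))
  if (n) {
    ord <- order(-dets$confidence)
    for (r in ord) {
      cand <- which(!matched & gts$image == dets$image[r] &
                      gts$class_id == dets$class_id[r])
      if (!length(cand)) next
      gm <- as.matrix(gts[cand, c("x1", "y1", "x2", "y2")])
      ious <- iou_many(as.numeric(dets[r, c("x1", "y1", "x2", "y2")]), gm)
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        flags[r] <- TRUE
        matched[cand[j]] <- TRUE
      }
    }
  }
  list(tp = sum(flags), fp = n - sum(flags), fn = nrow(gts) - sum(matched),
       tp_flags = flags)
}

#' Precision and recall from match counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN); a 0/0 ratio is defined as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  list(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Average precision for one class (all-points PR-curve area)
#'
#' Sweeps the confidence ranking, accumulates TP/FP against greedy one-to-one
#' matching, applies the monotone precision envelope and integrates the area
#' under the precision-recall curve over all recall change points.
#'
#' @param dets detections of a single class (any images).
#' @param gts ground truths of the same class; must be non-empty.
#' @param iou_threshold matching threshold, default 0.5.
#' @return list with `recall`, `precision` (curve points, envelope applied)
#'   and `ap` in \[0, 1\].
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  if (!nrow(gts)) stop("average_precision: no ground truths for this class")
  npos <- nrow(gts)
  if (!nrow(dets)) return(list(recall = numeric(), precision = numeric(), ap = 0))
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  flags <- match_detections(dets, gts, iou_threshold)$tp_flags
  tp_cum <- cumsum(flags)
  fp_cum <- cumsum(!flags)
  recall <- tp_cum / npos
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotone envelope from the right
  penv <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  ap <- sum((r[-1] - r[-length(r)]) * penv)
  list(recall = recall, precision = penv, ap = ap)
}

#' Mean average precision over classes
#'
#' @param per_class_ap numeric vector of per-class AP values (must be
#'   non-empty).
#' @return their arithmetic mean.
#' @examples
#' mean_average_precision(c(0.883, 0.782, 0.686, 0.599))  # 0.7375
#' @export
mean_average_precision <- function(per_class_ap) {
  if (!length(per_class_ap)) stop("mean_average_precision: empty AP list")
  mean(per_class_ap)
}

#' Evaluate detections against ground truth, per class
#'
#' @param dets detection data.frame over a whole split.
#' @param gts ground-truth data.frame.
#' @param iou_threshold matching threshold (default 0.5).
#' @param class_names optional names for the report.
#' @return list with `per_class` data.frame (class, n_gt, tp, fp, fn,
#'   precision, recall, ap) and `map`. Classes without ground truth are
#'   excluded from mAP with a warning.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                class_names = NULL) {
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  rows <- list()
  aps <- numeric()
  for (cl in classes) {
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    if (!nrow(gc)) {
      warning(sprintf("class %d has no ground truth; excluded from mAP", cl))
      next
    }
    mm <- match_detections(dc, gc, iou_threshold)
    pr <- precision_recall(mm$tp, mm$fp, mm$fn)
    ap <- average_precision(dc, gc, iou_threshold)$ap
    nm <- if (!is.null(class_names) && cl + 1 <= length(class_names)) {
      class_names[cl + 1]
    } else as.character(cl)
    rows[[length(rows) + 1L]] <- data.frame(
      class = nm, n_gt = nrow(gc), tp = mm$tp, fp = mm$fp, fn = mm$fn,
      precision = pr$precision, recall = pr$recall, ap = ap,
      stringsAsFactors = FALSE)
    aps <- c(aps, ap)
  }
  per_class <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), n_gt = integer(), tp = integer(),
               fp = integer(), fn = integer(), precision = numeric(),
               recall = numeric(), ap = numeric())
  list(per_class = per_class,
       map = if (length(aps)) mean_average_precision(aps) else NA_real_)
}
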