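#' Intersection over union of two boxes
#'
#' Boxes are corner-format numeric vectors \code{(x_min, y_min, x_max,
#' y_max)} in pixel coordinates, origin top-left. IoU is the ratio of the
#' intersection area to the union area; it is symmetric and equals 1 only
#' for identical boxes.
#'
#' @param a,b Numeric length-4 boxes.
#' @return IoU in [0, 1].
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))   # 1/3
#' @export
iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 4L, length(b) == 4L, a[1] < a[3], a[2] < a[4],
            b[1] < b[3], b[2] < b[4])
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  inter / union
}

box_mat <- function(d) as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])

# IoU of every row of box matrix A against every row of B (vectorized)
iou_matrix <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(0, nrow(A), nrow(B)))
  iw <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j)
    pmin(A[i, 3], B[j, 3]) - pmax(A[i, 1], B[j, 1]))
  ih <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j)
    pmin(A[i, 4], B[j, 4]) - pmax(A[i, 2], B[j, 2]))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, "+") - inter)
}

#' Match predicted boxes to ground truth
#'
#' Greedy class-aware matching: predictions are visited in descending
#' confidence (ties broken by input order, stable); each prediction is a
#' true positive iff it matches a not-yet-matched ground-truth box of the
#' same class on the same image with IoU at or above \code{iou_thr}, taking
#' the highest-IoU candidate. Each ground truth matches at most once.
#'
#' @param preds Prediction \code{data.frame}: columns
#'   \code{image_id,class,x_min,y_min,x_max,y_max,confidence}.
#' @param gts Ground-truth \code{data.frame}: same columns without
#'   \code{confidence}.
#' @param iou_thr IoU threshold for a positive match (default 0.5).
#' @return List: \code{tp}, logical per prediction in input order;
#'   \code{matched_gt}, matching GT row index per prediction (\code{NA} for
#'   false positives); \code{n_unmatched_gt}, the false-negative count.
#' @export
match_predictions <- function(preds, gts, iou_thr = 0.5) {
  np <- nrow(preds); ng <- nrow(gts)
  tp <- logical(np); matched_gt <- rep(NA_integer_, np)
  gt_used <- logical(ng)
  if (np && ng) {
    M <- iou_matrix(box_mat(preds), box_mat(gts))
    ord <- order(-preds$confidence)   # stable: ties keep input order
    for (i in ord) {
      cand <- which(!gt_used & gts$image_id == preds$image_id[i] &
                      gts$class == preds$class[i] & M[i, ] >= iou_thr)
      if (length(cand)) {
        j <- cand[which.max(M[i, cand])]
        tp[i] <- TRUE; matched_gt[i] <- j; gt_used[j] <- TRUE
      }
    }
  }
  list(tp = tp, matched_gt = matched_gt, n_unmatched_gt = sum(!gt_used))
}

#' Precision, recall and F1 from match counts
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)},
#' \code{F1 = 2 P R / (P + R)}. A zero denominator makes the statistic
#' undefined (\code{NA}), and F1 is \code{NA} whenever either component is.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named list \code{precision, recall, f1}.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in [0, 1].
#' @return F1 score; \code{NA} if either input is \code{NA}, 0 if both are
#'   zero.
#' @examples
#' f1_score(0.990, 0.897)   # 0.941
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0))
}

#' Average precision for one class at a fixed IoU threshold
#'
#' Builds the precision-recall curve by sweeping the confidence-ranked
#' predictions of the class and integrates it with all-point (continuous)
#' interpolation: at each recall increment the precision is the maximum
#' precision attained at that recall or higher.
#'
#' @inheritParams match_predictions
#' @param class_label Class to evaluate.
#' @return AP in [0, 1]; 0 when there are no predictions; \code{NA} (with a
#'   warning) when the class has no ground truth.
#' @export
average_precision <- function(preds, gts, class_label, iou_thr = 0.5) {
  assert_class_label(class_label)
  gts_c <- gts[gts$class == class_label, , drop = FALSE]
  preds_c <- preds[preds$class == class_label, , drop = FALSE]
  n_gt <- nrow(gts_c)
  if (!n_gt) {
    warning("no ground truth for class ", class_label, "; AP undefined")
    return(NA_real_)
  }
  if (!nrow(preds_c)) return(0)
  m <- match_predictions(preds_c, gts_c, iou_thr)
  ord <- order(-preds_c$confidence)
  tp_cum <- cumsum(m$tp[ord])
  fp_cum <- cumsum(!m$tp[ord])
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope: max precision at this recall or beyond
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Per-class evaluation report with mAP50
#'
#' Counts TP/FP/FN per class with predictions filtered at
#' \code{conf_thr} (the operating threshold of the deployed detector),
#' derives precision/recall/F1, computes per-class AP over the full
#' confidence sweep, and averages AP over the classes with ground truth
#' into mAP.
#'
#' @inheritParams match_predictions
#' @param conf_thr Confidence filter applied before counting TP/FP/FN
#'   (default 0.45); AP uses all predictions.
#' @return List with \code{per_class} \code{data.frame}
#'   (\code{class,n_gt,tp,fp,fn,precision,recall,f1,ap}) and scalar
#'   \code{map}.
#' @export
eval_report <- function(preds, gts, iou_thr = 0.5, conf_thr = 0.45) {
  rows <- lapply(behavior_classes(), function(cl) {
    gts_c <- gts[gts$class == cl, , drop = FALSE]
    preds_c <- preds[preds$class == cl & preds$confidence >= conf_thr, ,
                     drop = FALSE]
    m <- match_predictions(preds_c, gts_c, iou_thr)
    tp <- sum(m$tp); fp <- sum(!m$tp); fn <- nrow(gts_c) - tp
    prf <- precision_recall_f1(tp, fp, fn)
    ap <- if (nrow(gts_c)) average_precision(preds, gts, cl, iou_thr)
          else NA_real_
    data.frame(class = cl, n_gt = nrow(gts_c), tp = tp, fp = fp, fn = fn,
               precision = prf$precision, recall = prf$recall, f1 = prf$f1,
               ap = ap, stringsAsFactors = FALSE)
  })
  per_class <- reset_rownames(do.call(rbind, rows))
  list(per_class = per_class, map = mean(per_class$ap, na.rm = TRUE))
}

#' Detection confusion matrix with background row and column
#'
#' Predictions are first filtered at the operating confidence threshold,
#' then assigned to ground-truth boxes per image by greedy best-IoU
#' matching regardless of class (so cross-class confusions are counted).
#' Entry (i, j) counts ground truths of class j assigned to predicted class
#' i; an unmatched ground truth counts in the \code{background} row of its
#' column, an unmatched prediction in the \code{background} column of its
#' row.
#'
#' @inheritParams eval_report
#' @param normalize If \code{TRUE}, divide each column by its sum.
#' @return 4 x 4 matrix (rows = predicted, columns = true), classes plus
#'   \code{background}.
#' @export
confusion_matrix <- function(preds, gts, iou_thr = 0.5, conf_thr = 0.45,
                             normalize = FALSE) {
  classes <- c(behavior_classes(), "background")
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(predicted = classes,
                                         true = classes))
  preds <- preds[preds$confidence >= conf_thr, , drop = FALSE]
  p_used <- logical(nrow(preds)); g_used <- logical(nrow(gts))
  if (nrow(preds) && nrow(gts)) {
    M <- iou_matrix(box_mat(preds), box_mat(gts))
    same_img <- outer(preds$image_id, gts$image_id, "==")
    M[!same_img] <- 0
    repeat {
      M[p_used, ] <- 0; M[, g_used] <- 0
      if (all(M < iou_thr)) break
      idx <- arrayInd(which.max(M), dim(M))
      i <- idx[1]; j <- idx[2]
      cm[preds$class[i], gts$class[j]] <- cm[preds$class[i], gts$class[j]] + 1L
      p_used[i] <- TRUE; g_used[j] <- TRUE
    }
  }
  for (j in which(!g_used)) cm["background", gts$class[j]] <-
    cm["background", gts$class[j]] + 1L
  for (i in which(!p_used)) cm[preds$class[i], "background"] <-
    cm[preds$class[i], "background"] + 1L
  if (normalize) {
    cs <- colSums(cm)
    cm <- sweep(cm, 2, ifelse(cs > 0, cs, 1), "/")
  }
  cm
}

#' Read and write box CSV files
#'
#' Dialect: header \code{image_id,class,x_min,y_min,x_max,y_max} with an
#' optional trailing \code{confidence} column (predictions).
#'
#' @param path CSV path.
#' @return \code{data.frame} of boxes.
#' @export
read_box_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "class", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(d)))
    stop("bad header in ", path, "; expected columns: ",
         paste(need, collapse = ","))
  if (nrow(d) && !all(d$class %in% behavior_classes()))
    stop("unknown class label in ", path)
  d
}

#' @rdname read_box_csv
#' @param boxes Box \code{data.frame}.
#' @export
write_box_csv <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
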