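gt_df <- function(image_id, class, x0, y0, x1, y1) {
  data.frame(image_id = image_id, class = class, x_min = x0, y_min = y0,
             x_max = x1, y_max = y1, stringsAsFactors = FALSE)
}
pred_df <- function(image_id, class, x0, y0, x1, y1, conf) {
  cbind(gt_df(image_id, class, x0, y0, x1, y1), confidence = conf)
}

test_that("IoU matches area arithmetic and is symmetric", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(iou(a, c(5, 0, 15, 10)), 1 / 3)
  set.seed(15)
  for (rep in 1:50) {
    p <- sort(runif(4, 0, 100)); q <- sort(runif(4, 0, 100))
    b1 <- c(p[1], q[1], p[3], q[3]); b2 <- c(p[2], q[2], p[4], q[4])
    v <- iou(b1, b2)
    expect_equal(v, iou(b2, b1))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(iou(b1, b1), 1)
  }
})

test_that("greedy class-aware matching labels TP/FP/FN correctly", {
  g <- gt_df(1L, "aggressive", 0, 0, 10, 10)
  # exact hit
  m <- match_predictions(pred_df(1L, "aggressive", 0, 0, 10, 10, 0.9), g)
  expect_equal(sum(m$tp), 1L)
  expect_equal(m$n_unmatched_gt, 0L)
  # duplicate detections: higher confidence wins, second becomes FP
  p2 <- rbind(pred_df(1L, "aggressive", 0, 0, 10, 10, 0.9),
              pred_df(1L, "aggressive", 1, 0, 11, 10, 0.8))
  m <- match_predictions(p2, g)
  expect_equal(m$tp, c(TRUE, FALSE))
  # wrong class on a GT: FP and FN
  m <- match_predictions(pred_df(1L, "ear_biting", 0, 0, 10, 10, 0.9), g)
  expect_equal(sum(m$tp), 0L)
  expect_equal(m$n_unmatched_gt, 1L)
  # other image never matches
  m <- match_predictions(pred_df(2L, "aggressive", 0, 0, 10, 10, 0.9), g)
  expect_equal(sum(m$tp), 0L)
  # count identities on a random instance
  cfg <- sim_config(box_drop_prob = 0.2, box_class_flip_prob = 0.2,
                    box_spurious_rate = 0.5)
  fx <- make_box_fixture(40, cfg, seed = 9)
  m <- match_predictions(fx$pred, fx$gt)
  expect_equal(sum(m$tp) + m$n_unmatched_gt, nrow(fx$gt))
  expect_equal(length(m$tp), nrow(fx$pred))
  matched <- m$matched_gt[!is.na(m$matched_gt)]
  expect_equal(anyDuplicated(matched), 0L)
})

test_that("precision/recall/F1 formulas, including undefined cases", {
  prf <- precision_recall_f1(90, 10, 10)
  expect_equal(unlist(prf), c(precision = 0.9, recall = 0.9, f1 = 0.9))
  expect_equal(round(f1_score(0.990, 0.897), 3), 0.941)
  expect_equal(round(f1_score(0.943, 0.896), 3), 0.919)
  und <- precision_recall_f1(0, 0, 5)
  expect_true(is.na(und$precision))
  expect_true(is.na(und$f1))
  expect_equal(precision_recall_f1(0, 3, 0)$precision, 0)
  expect_equal(f1_score(0, 0), 0)
})

test_that("average precision matches the hand-built PR-curve value", {
  # 2 GT; three predictions ranked TP (0.9), FP (0.8), TP (0.7):
  # envelope integrates to 1 * 0.5 + (2/3) * 0.5
  g <- rbind(gt_df(1L, "aggressive", 0, 0, 10, 10),
             gt_df(2L, "aggressive", 0, 0, 10, 10))
  p <- rbind(pred_df(1L, "aggressive", 0, 0, 10, 10, 0.9),
             pred_df(3L, "aggressive", 0, 0, 10, 10, 0.8),
             pred_df(2L, "aggressive", 0, 0, 10, 10, 0.7))
  expect_equal(average_precision(p, g, "aggressive"), 0.5 + 0.5 * 2 / 3)
  # perfect detector and no-prediction extremes
  expect_equal(average_precision(p[c(1, 3), ], g, "aggressive"), 1)
  expect_equal(average_precision(p[0, ], g, "aggressive"), 0)
  expect_warning(ap <- average_precision(p, g[0, ], "aggressive"),
                 "no ground truth")
  expect_true(is.na(ap))
  # an extra top-ranked FP can only lower AP
  p_fp <- rbind(pred_df(4L, "aggressive", 0, 0, 10, 10, 0.99), p)
  expect_lt(average_precision(p_fp, g, "aggressive"),
            average_precision(p, g, "aggressive"))
})

test_that("evaluation report is perfect on a noise-free fixture", {
  fx <- make_box_fixture(30, noise_free_config(), seed = 5)
  er <- eval_report(fx$pred, fx$gt)
  expect_equal(er$per_class$precision, rep(1, 3))
  expect_equal(er$per_class$recall, rep(1, 3))
  expect_equal(er$per_class$f1, rep(1, 3))
  expect_equal(er$per_class$ap, rep(1, 3))
  expect_equal(er$map, 1)
  cm <- confusion_matrix(fx$pred, fx$gt)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(unname(diag(cm)[1:3]),
               unname(table(factor(fx$gt$class,
                                   levels = behavior_classes()))[1:3]),
               ignore_attr = TRUE)
  # empty predictions: recall 0 everywhere
  er0 <- eval_report(fx$pred[0, ], fx$gt)
  expect_equal(er0$per_class$recall, rep(0, 3))
})

test_that("confusion matrix routes unmatched boxes to background", {
  g <- gt_df(1L, "aggressive", 0, 0, 10, 10)
  p <- pred_df(2L, "tail_biting", 50, 50, 60, 60, 0.9)
  cm <- confusion_matrix(p, g)
  expect_equal(cm["tail_biting", "background"], 1L)
  expect_equal(cm["background", "aggressive"], 1L)
  # cross-class assignment is recorded off-diagonal, not as background
  p2 <- pred_df(1L, "ear_biting", 0, 0, 10, 10, 0.9)
  cm2 <- confusion_matrix(p2, g)
  expect_equal(cm2["ear_biting", "aggressive"], 1L)
  # sub-threshold predictions are dropped before assignment
  p3 <- pred_df(1L, "aggressive", 0, 0, 10, 10, 0.30)
  cm3 <- confusion_matrix(p3, g)
  expect_equal(cm3["background", "aggressive"], 1L)
  # normalized columns sum to one where occupied
  cfg <- sim_config(box_class_flip_prob = 0.3)
  fx <- make_box_fixture(25, cfg, seed = 2)
  cmn <- confusion_matrix(fx$pred, fx$gt, normalize = TRUE)
  occupied <- colSums(cmn) > 0
  expect_equal(unname(colSums(cmn)[occupied]),
               rep(1, sum(occupied)))
})

test_that("confusion matrix equals a brute-force greedy assignment", {
  # independent oracle: sort all same-image pairs by IoU and assign greedily
  oracle_cm <- function(preds, gts, iou_thr = 0.5, conf_thr = 0.45) {
    classes <- c(behavior_classes(), "background")
    cm <- matrix(0L, 4, 4, dimnames = list(classes, classes))
    preds <- preds[preds$confidence >= conf_thr, , drop = FALSE]
    pairs <- expand.grid(i = seq_len(nrow(preds)), j = seq_len(nrow(gts)))
    pairs$iou <- mapply(function(i, j)
      iou(as.numeric(preds[i, c("x_min", "y_min", "x_max", "y_max")]),
          as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")])),
      pairs$i, pairs$j)
    pairs <- pairs[preds$image_id[pairs$i] == gts$image_id[pairs$j] &
                     pairs$iou >= iou_thr, ]
    pairs <- pairs[order(-pairs$iou), ]
    pu <- logical(nrow(preds)); gu <- logical(nrow(gts))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!pu[i] && !gu[j]) {
        cm[preds$class[i], gts$class[j]] <- cm[preds$class[i],
                                               gts$class[j]] + 1L
        pu[i] <- TRUE; gu[j] <- TRUE
      }
    }
    for (j in which(!gu)) cm["background", gts$class[j]] <-
      cm["background", gts$class[j]] + 1L
    for (i in which(!pu)) cm[preds$class[i], "background"] <-
      cm[preds$class[i], "background"] + 1L
    cm
  }
  cfg <- sim_config(box_jitter_sd_px = 10, box_drop_prob = 0.15,
                    box_class_flip_prob = 0.25, box_spurious_rate = 0.6)
  for (s in 1:5) {
    fx <- make_box_fixture(15, cfg, seed = s)
    expect_equal(confusion_matrix(fx$pred, fx$gt),
                 oracle_cm(fx$pred, fx$gt), ignore_attr = TRUE)
  }
})
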