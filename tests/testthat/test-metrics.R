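# Evaluation stack: IoU closed forms, NMS vs a quadratic oracle, greedy
# matching vs exhaustive assignment, precision/recall/AP/mAP closed forms,
# PR-curve invariances, and the confusion matrix.

test_that("iou closed forms", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0.0)
})

test_that("nms suppresses duplicates, keeps disjoint, matches the oracle", {
  two <- make_dets(c(0, 0), c(0, 0), c(2, 2), c(2, 2), c(0.9, 0.8), c(0, 0))
  out <- nms(two, 0.5, 0.1)
  expect_equal(nrow(out), 1)
  expect_equal(out$conf, 0.9)
  disj <- make_dets(c(0, 5), c(0, 5), c(2, 7), c(2, 7), c(0.9, 0.8), c(0, 0))
  expect_equal(nrow(nms(disj, 0.5, 0.1)), 2)
  set.seed(17)
  n <- 50
  x1 <- runif(n, 0, 80)
  y1 <- runif(n, 0, 80)
  rd <- make_dets(x1, y1, x1 + runif(n, 5, 25), y1 + runif(n, 5, 25),
                  runif(n), sample(0:2, n, replace = TRUE))
  got <- nms(rd, 0.45, 0.2)
  want <- oracle_nms(rd, 0.45, 0.2)
  expect_equal(got[order(-got$conf), ], want[order(-want$conf), ],
               ignore_attr = TRUE)
})

test_that("match tallies: trivial cases and TP+FN conservation", {
  t <- make_truths(c(0, 10), c(0, 10), c(5, 15), c(5, 15), c(0, 1))
  perfect <- make_dets(c(0, 10), c(0, 10), c(5, 15), c(5, 15), c(0.9, 0.8),
                       c(0, 1))
  tal <- match_detections(perfect, t, 0.5, num_classes = 2)
  expect_equal(sum(tal$tp), 2)
  expect_equal(sum(tal$fp), 0)
  expect_equal(sum(tal$fn), 0)
  lone <- make_dets(0, 0, 5, 5, 0.9, 0)
  none <- make_truths(numeric(0), numeric(0), numeric(0), numeric(0),
                      integer(0))
  tal2 <- match_detections(lone, none, 0.5, num_classes = 1)
  expect_equal(tal2$fp, 1L)
  # conservation per class against truth counts
  expect_equal(tal$tp + tal$fn, c(1L, 1L))
})

test_that("crafted 5-det/3-truth fixture matches hand enumeration at IoU 0.5", {
  # truths: three unit-spaced 10x10 boxes, class 0
  t <- make_truths(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                   c(0, 0, 0))
  # dets: d1 exact on t1; d2 shifted 2px on t1 (IoU .67, t1 taken by d1);
  # d3 exact on t2; d4 off in empty space; d5 class-1 exact on t3
  d <- make_dets(x1 = c(0, 2, 20, 70, 40), y1 = c(0, 0, 0, 0, 0),
                 x2 = c(10, 12, 30, 80, 50), y2 = c(10, 10, 10, 10, 10),
                 conf = c(0.95, 0.9, 0.85, 0.8, 0.75),
                 class_id = c(0, 0, 0, 0, 1))
  tal <- match_detections(d, t, 0.5, num_classes = 2)
  # hand enumeration: TP = {d1, d3}; FP = {d2, d4, d5}; FN = {t3}
  expect_equal(tal$tp, c(2L, 0L))
  expect_equal(tal$fp, c(2L, 1L))
  expect_equal(tal$fn, c(1L, 0L))
})

test_that("greedy matching agrees with the exhaustive oracle on small sets", {
  set.seed(23)
  for (rep in 1:8) {
    nt <- sample(0:3, 1)
    nd <- sample(0:3, 1)
    mk <- function(n) {
      x1 <- runif(n, 0, 30)
      y1 <- runif(n, 0, 30)
      cbind(x1, y1, x1 + runif(n, 8, 15), y1 + runif(n, 8, 15))
    }
    tb <- mk(nt)
    db <- mk(nd)
    t <- if (nt > 0) {
      make_truths(tb[, 1], tb[, 2], tb[, 3], tb[, 4], rep(0L, nt))
    } else {
      make_truths(numeric(0), numeric(0), numeric(0), numeric(0), integer(0))
    }
    d <- if (nd > 0) {
      make_dets(db[, 1], db[, 2], db[, 3], db[, 4], runif(nd), rep(0L, nd))
    } else {
      make_dets(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
                integer(0))
    }
    tal <- match_detections(d, t, 0.3, num_classes = 1)
    oc <- oracle_exhaustive_tally(d, t, 0.3)
    # greedy-by-confidence can differ from optimal in contrived overlaps,
    # but at these low densities the TP counts coincide
    expect_equal(sum(tal$tp), oc$tp)
    expect_equal(sum(tal$fp), oc$fp)
    expect_equal(sum(tal$fn), oc$fn)
  }
})

test_that("precision and recall closed forms with the 0/0 convention", {
  expect_equal(precision(list(tp = 10, fp = 0)), 1.0)
  expect_equal(precision(list(tp = 0, fp = 5)), 0.0)
  expect_equal(precision(list(tp = 3, fp = 1)), 0.75)
  expect_equal(precision(list(tp = 0, fp = 0)), 0)
  expect_equal(recall(list(tp = 10, fn = 0)), 1.0)
  expect_equal(recall(list(tp = 0, fn = 4)), 0.0)
  expect_equal(recall(list(tp = 2, fn = 2)), 0.5)
  expect_equal(recall(list(tp = 0, fn = 0)), 0)
})

test_that("average precision: extremes and the dense-integration oracle", {
  t <- make_truths(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                   c(0, 0, 0))
  perfect <- make_dets(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                       c(0.9, 0.8, 0.7), c(0, 0, 0))
  expect_equal(average_precision(perfect, t, 0.5), 1.0)
  wrong <- make_dets(70, 70, 80, 80, 0.9, 0)
  expect_equal(average_precision(wrong, t, 0.5), 0.0)
  # 6-detection ranked toy: hits at ranks 1, 3, 4; misses at 2, 5, 6
  toy <- make_dets(x1 = c(0, 70, 20, 40, 70, 90), y1 = rep(0, 6),
                   x2 = c(10, 80, 30, 50, 80, 100), y2 = rep(10, 6),
                   conf = c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7),
                   class_id = rep(0L, 6))
  got <- average_precision(toy, t, 0.5)
  expect_lt(abs(got - oracle_ap_dense(toy, t, 0.5)), 1e-3)
  # continuous (trapezoid) mode exists and stays in [0, 1]
  cont <- average_precision(toy, t, 0.5, method = "continuous")
  expect_gte(cont, 0)
  expect_lte(cont, 1)
})

test_that("AP is invariant under strictly monotone confidence rescaling", {
  t <- make_truths(c(0, 20), c(0, 0), c(10, 30), c(10, 10), c(0, 0))
  d <- make_dets(c(0, 50, 20), c(0, 0, 0), c(10, 60, 30), c(10, 10, 10),
                 c(0.9, 0.6, 0.3), c(0, 0, 0))
  base <- average_precision(d, t, 0.5)
  for (f in list(function(p) p^3, function(p) 0.5 * p + 0.1,
                 function(p) stats::plogis(5 * p))) {
    d2 <- d
    d2$conf <- f(d$conf)
    expect_equal(average_precision(d2, t, 0.5), base)
  }
})

test_that("mean_ap closed forms and threshold grid", {
  expect_equal(mean_ap(c(1, 1, 1))$map50, 1)
  expect_equal(mean_ap(c(1.0, 0.5))$map50, 0.75)
  expect_length(iou_threshold_grid(), 10)
  expect_equal(iou_threshold_grid(), seq(0.5, 0.95, by = 0.05))
  m <- matrix(runif(20), 2, 10)
  res <- mean_ap(m)
  expect_equal(res$map50, mean(m[, 1]))
  expect_equal(res$map50_95, mean(m))
})

test_that("mAP@0.5:0.95 never exceeds mAP@0.5 on random evaluations", {
  set.seed(31)
  for (rep in 1:4) {
    nt <- 6
    x1 <- runif(nt, 0, 80)
    y1 <- runif(nt, 0, 80)
    t <- make_truths(x1, y1, x1 + 12, y1 + 12, sample(0:1, nt, TRUE),
                     image = sample(c("a", "b"), nt, TRUE))
    jit <- function(v) v + runif(nt, -3, 3)
    d <- make_dets(jit(x1), jit(y1), jit(x1 + 12), jit(y1 + 12), runif(nt),
                   sample(0:1, nt, TRUE), image = t$image)
    rep_ <- evaluate_detections(d, t, num_classes = 2)
    expect_lte(rep_$map50_95, rep_$map50 + 1e-12)
    expect_true(all(rep_$ap >= 0 & rep_$ap <= 1))
  }
})

test_that("confusion matrix: diagonal, misclassification, hand enumeration", {
  t <- make_truths(c(0, 20), c(0, 0), c(10, 30), c(10, 10), c(0, 1))
  good <- make_dets(c(0, 20), c(0, 0), c(10, 30), c(10, 10), c(0.9, 0.9),
                    c(0, 1))
  cm <- confusion_matrix(good, t, num_classes = 2)
  expect_equal(unname(diag(cm)), c(1, 1, 0))
  expect_equal(sum(cm), 2)
  wrong <- make_dets(0, 0, 10, 10, 0.9, 1)
  t1 <- make_truths(0, 0, 10, 10, 0)
  cm2 <- confusion_matrix(wrong, t1, num_classes = 2)
  expect_equal(cm2["class0", "class1"], 1)
  expect_equal(sum(cm2), 1)
  # 3-image fixture: exact match / class swap / missed truth + ghost det
  t3 <- make_truths(c(0, 0, 0), c(0, 0, 0), c(10, 10, 10), c(10, 10, 10),
                    c(0, 1, 0), image = c("i1", "i2", "i3"))
  d3 <- make_dets(c(0, 0, 50), c(0, 0, 50), c(10, 10, 60), c(10, 10, 60),
                  c(0.9, 0.9, 0.9), c(0, 0, 1),
                  image = c("i1", "i2", "i3"))
  cm3 <- confusion_matrix(d3, t3, num_classes = 2)
  expect_equal(cm3["class0", "class0"], 1)       # i1 correct
  expect_equal(cm3["class1", "class0"], 1)       # i2 swap
  expect_equal(cm3["class0", "background"], 1)   # i3 missed truth
  expect_equal(cm3["background", "class1"], 1)   # i3 ghost detection
  expect_equal(sum(cm3), 4)
})
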