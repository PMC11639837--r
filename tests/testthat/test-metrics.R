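test_that("iou matches pixel-set counting on hand and random cases", {
  a <- bounding_box(0, 0, 10, 10)
  expect_identical(iou(a, a), 1)
  expect_identical(iou(a, bounding_box(20, 20, 25, 25)), 0)
  expect_equal(iou(a, bounding_box(5, 0, 15, 10)), 1 / 3)  # 50 / 150
  expect_error(bounding_box(3, 0, 3, 5), class = "hsd_argument_error")
  set.seed(21)
  for (i in 1:100) {
    b1 <- random_box(); b2 <- random_box()
    expect_equal(iou(b1, b2), pixel_iou_oracle(b1, b2), label = sprintf("case %d", i))
  }
})

test_that("match_detections implements the greedy protocol", {
  truths <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC"),
                 list(box = bounding_box(20, 0, 30, 10), label = "CBC"))
  perfect <- lapply(truths, function(t) c(t, confidence = 0.9))
  m <- match_detections(perfect, truths)
  expect_identical(m$counts[c("TP", "FP", "FN")], list(TP = 2L, FP = 0L, FN = 0L))
  m0 <- match_detections(list(), truths)
  expect_identical(m0$counts$FN, 2L)
  # 3 preds / 2 truths hand case: highest confidence claims the best truth
  preds <- list(
    list(box = bounding_box(0, 0, 10, 10), label = "CBC", confidence = 0.6),
    list(box = bounding_box(1, 0, 11, 10), label = "CBC", confidence = 0.9),
    list(box = bounding_box(19, 0, 29, 10), label = "CBC", confidence = 0.8))
  m3 <- match_detections(preds, truths)
  o3 <- match_oracle(preds, truths, 0.5)
  expect_identical(m3$counts$TP, o3$TP)
  expect_identical(m3$assignment, o3$assignment)
  set.seed(31)
  for (i in 1:100) {
    np <- sample(0:6, 1); nt <- sample(0:5, 1)
    preds <- replicate(np, random_detection(), simplify = FALSE)
    truths <- replicate(nt, list(box = random_box(),
                                 label = sample(c("CBC", "CBB"), 1)),
                        simplify = FALSE)
    m <- match_detections(preds, truths, 0.4)
    o <- match_oracle(preds, truths, 0.4)
    expect_identical(m$counts[c("TP", "FP", "FN")],
                     list(TP = o$TP, FP = o$FP, FN = o$FN))
  }
})

test_that("precision/recall/F1 reproduce printed report-table arithmetic", {
  # harmonic-mean identities on published-style 3-decimal inputs
  expect_equal(round_half_up(f1_score(0.977, 0.984), 3), 0.980)
  expect_equal(round_half_up(f1_score(0.600, 0.643), 3), 0.621)
  expect_identical(f1_score(1, 1), 1)
  prf <- precision_recall_f1(list(TP = 8L, FP = 2L, FN = 4L))
  expect_equal(prf$precision, 0.8)
  expect_equal(prf$recall, 8 / 12)
  expect_equal(prf$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  expect_warning(precision_recall_f1(list(TP = 0L, FP = 0L, FN = 3L)), "precision")
  # F1 never exceeds the arithmetic mean; equals P when P = R
  set.seed(5)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    expect_lte(f1_score(p, r), (p + r) / 2 + 1e-12)
  }
  expect_equal(f1_score(0.7, 0.7), 0.7)
})

test_that("accuracy follows (TP+TN)/(P+N)", {
  expect_identical(accuracy(list(TP = 10, TN = 10, P = 10, N = 10)), 1)
  expect_identical(accuracy(list(TP = 0, TN = 0, P = 5, N = 5)), 0)
  expect_identical(accuracy(list(TP = 8, TN = 5, P = 10, N = 10)), 0.65)
  expect_error(accuracy(list(TP = 0, TN = 0, P = 0, N = 0)), class = "hsd_argument_error")
})

test_that("AP equals the brute-force sweep oracle and respects the degenerate cases", {
  t1 <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC"))
  hit <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC", confidence = 0.4))
  expect_identical(pr_curve_and_ap(hit, t1)$ap, 1)
  miss <- list(list(box = bounding_box(50, 50, 60, 60), label = "CBC", confidence = 0.9))
  expect_identical(pr_curve_and_ap(miss, t1)$ap, 0)
  expect_warning(r <- pr_curve_and_ap(hit, list()), "no ground truths")
  expect_true(is.na(r$ap))
  # interleaved TP/FP hand case against the threshold-sweep oracle
  truths <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC"),
                 list(box = bounding_box(20, 0, 30, 10), label = "CBC"))
  preds <- list(
    list(box = bounding_box(0, 0, 10, 10), label = "CBC", confidence = 0.9),
    list(box = bounding_box(40, 40, 50, 50), label = "CBC", confidence = 0.8),
    list(box = bounding_box(20, 0, 30, 10), label = "CBC", confidence = 0.7),
    list(box = bounding_box(60, 60, 70, 70), label = "CBC", confidence = 0.6))
  expect_equal(pr_curve_and_ap(preds, truths)$ap,
               ap_sweep_oracle(preds, truths, 0.5), tolerance = 1e-3)
  set.seed(41)
  for (i in 1:100) {
    nt <- sample(1:5, 1); np <- sample(1:8, 1)
    truths <- replicate(nt, list(box = random_box(), label = "CBC"), simplify = FALSE)
    preds <- replicate(np, {
      d <- random_detection(classes = "CBC"); d
    }, simplify = FALSE)
    expect_equal(pr_curve_and_ap(preds, truths)$ap,
                 ap_sweep_oracle(preds, truths, 0.5),
                 tolerance = 2e-3, label = sprintf("case %d", i))
  }
})

test_that("PR curves have non-decreasing recall and AP is confidence-scale invariant", {
  set.seed(51)
  truths <- replicate(4, list(box = random_box(), label = "CBC"), simplify = FALSE)
  preds <- replicate(7, random_detection(classes = "CBC"), simplify = FALSE)
  r <- pr_curve_and_ap(preds, truths)
  expect_true(all(diff(r$curve$recall) >= 0))
  expect_true(all(r$curve$precision >= 0 & r$curve$precision <= 1))
  scaled <- lapply(preds, function(p) { p$confidence <- p$confidence * 0.37; p })
  expect_identical(pr_curve_and_ap(scaled, truths)$ap, r$ap)
})

test_that("mAP is the arithmetic mean of per-class APs, matching published tables", {
  expect_equal(round_half_up(mean_ap(c(0.996, 0.963, 0.952)), 3), 0.970)
  expect_equal(round_half_up(mean_ap(c(0.522, 0.537, 0.888)), 3), 0.649)
  expect_identical(mean_ap(0.73), 0.73)
  expect_warning(m <- mean_ap(c(0.5, NA)), "dropping")
  expect_identical(m, 0.5)
  expect_error(mean_ap(numeric(0)), class = "hsd_argument_error")
  set.seed(6)
  aps <- runif(5)
  expect_equal(mean_ap(aps), sum(aps) / 5)
})

test_that("confusion matrices tally rows as truth, columns as prediction", {
  classes <- c("CBC", "CBB", "CBBR")
  cm <- confusion_matrix(classes, classes, classes)
  expect_identical(unname(diag(cm)), c(1L, 1L, 1L))
  cm2 <- confusion_matrix(c("CBC", "CBB", "CBBR"), rep("CBB", 3), classes)
  expect_equal(unname(colSums(cm2)), c(0, 3, 0))
  truth <- c("CBC", "CBC", "CBB", "CBBR", "CBB", "CBC")
  pred <- c("CBC", "CBB", "CBB", "CBBR", "CBBR", "CBC")
  cm3 <- confusion_matrix(truth, pred, classes)
  expect_identical(cm3["CBC", "CBC"], 2L)
  expect_identical(cm3["CBC", "CBB"], 1L)
  expect_identical(cm3["CBB", "CBBR"], 1L)
  expect_identical(sum(cm3), 6L)
  expect_error(confusion_matrix("x", "CBC", classes), class = "hsd_argument_error")
})

test_that("mIoU averages per image then across images, with a global-mean flag", {
  expect_identical(mean_iou(list(c(1, 1), 1)), 1)
  expect_identical(mean_iou(list(c(0.8, 0.6))), 0.7)
  by_img <- list(c(0.9, 0.5), 0.6)
  expect_equal(mean_iou(by_img), (0.7 + 0.6) / 2)
  expect_equal(mean_iou(by_img, per_image = FALSE), (0.9 + 0.5 + 0.6) / 3)
  expect_warning(m <- mean_iou(list(numeric(0))), "undefined")
  expect_true(is.na(m))
})

test_that("evaluation_report assembles a coherent table over multiple images", {
  t1 <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC"),
             list(box = bounding_box(20, 20, 30, 30), label = "CBB"))
  t2 <- list(list(box = bounding_box(5, 5, 15, 15), label = "CBC"))
  d1 <- list(list(box = bounding_box(0, 0, 10, 10), label = "CBC", confidence = 0.9),
             list(box = bounding_box(20, 20, 30, 30), label = "CBB", confidence = 0.8))
  d2 <- list(list(box = bounding_box(5, 5, 15, 14), label = "CBC", confidence = 0.7))
  rep <- evaluation_report(list(d1, d2), list(t1, t2), c("CBC", "CBB"))
  expect_equal(rep$per_class$CBC$recall, 1)
  expect_equal(rep$per_class$CBB$ap, 1)
  expect_equal(rep$map, mean(c(rep$per_class$CBC$ap, rep$per_class$CBB$ap)))
  expect_identical(sum(rep$confusion), 3L)
  expect_identical(unname(diag(rep$confusion)), c(2L, 1L))
  lines <- format_report_table(rep)
  expect_length(lines, 3)
  expect_match(lines[1], "Precision")
})
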