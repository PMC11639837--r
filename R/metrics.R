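# Detection / classification metrics: IoU, greedy detection matching,
# precision/recall/F1, AP via the all-point interpolated PR curve, mAP,
# confusion matrices and mIoU — the arithmetic behind standard object
# detection report tables.

#' Intersection over union of two boxes
#'
#' `|A : B| / |A u B|` with half-open pixel areas; 0 for disjoint boxes.
#'
#' @param a,b [bounding_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "bounding_box"), inherits(b, "bounding_box"))
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  if (inter == 0) return(0)
  area_a <- (a$x1 - a$x0) * (a$y1 - a$y0)
  area_b <- (b$x1 - b$x0) * (b$y1 - b$y0)
  inter / (area_a + area_b - inter)
}

#' Match detections to ground truth
#'
#' Greedy protocol: predictions are visited in order of decreasing
#' confidence; each matches the highest-IoU not-yet-matched truth of the
#' same class provided IoU >= `iou_threshold` (a TP), otherwise it is a
#' FP. Truths left unmatched are FN.
#'
#' @param preds list of detections (`box`, `label`, `confidence`).
#' @param truths list of `list(box, label)`.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return list with `counts` (`TP`, `FP`, `FN`, `P`), `assignment`
#'   (per-prediction matched truth index or `NA`), and `ious`
#'   (per-prediction matched IoU or `NA`).
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  np <- length(preds); nt <- length(truths)
  assignment <- rep(NA_integer_, np)
  match_iou <- rep(NA_real_, np)
  used <- rep(FALSE, nt)
  ord <- if (np > 0) order(vapply(preds, `[[`, 0, "confidence"), decreasing = TRUE) else integer(0)
  for (i in ord) {
    p <- preds[[i]]
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nt)) {
      if (used[j] || !identical(truths[[j]]$label, p$label)) next
      v <- iou(p$box, truths[[j]]$box)
      if (v >= iou_threshold && v > best) { best <- v; best_j <- j }
    }
    if (!is.na(best_j)) {
      assignment[i] <- best_j
      match_iou[i] <- best
      used[best_j] <- TRUE
    }
  }
  tp <- sum(!is.na(assignment))
  list(counts = list(TP = tp, FP = np - tp, FN = nt - tp, P = nt),
       assignment = assignment, ious = match_iou)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 their
#' harmonic mean `2PR/(P+R)`. Degenerate denominators yield 0 with a
#' warning for precision/recall, silently for F1.
#'
#' @param counts list with nonnegative integers `TP`, `FP`, `FN`.
#' @return named list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  stopifnot(is_count(tp), is_count(fp), is_count(fn))
  precision <- if (tp + fp > 0) tp / (tp + fp) else { warning("TP+FP = 0; precision defined as 0"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { warning("TP+FN = 0; recall defined as 0"); 0 }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' F1 from precision and recall
#'
#' Convenience for recomputing reported table cells from printed
#' precision/recall values.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return harmonic-mean F1.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Classification accuracy
#'
#' `(TP + TN) / (P + N)`.
#'
#' @param counts list with `TP`, `TN`, `P`, `N`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  p <- counts$P; n <- counts$N
  if (p + n <= 0) abort_hsd("P + N must be positive", "hsd_argument_error")
  (counts$TP + counts$TN) / (p + n)
}

#' Precision-recall curve and average precision for one class
#'
#' Predictions of a single class are swept over all distinct confidence
#' values (equivalently, visited in decreasing-confidence order); each
#' is a TP or FP by the greedy matching protocol of
#' [match_detections()]. AP is the area under the monotone
#' (all-point-interpolated) precision envelope integrated over recall;
#' an 11-point variant is available.
#'
#' @param preds detections of one class across images: list of
#'   `list(box, label, confidence, image)` (`image` identifies the
#'   scene; defaults to a single image when absent).
#' @param truths ground truths of the same class: `list(box, label,
#'   image)`.
#' @param iou_threshold TP matching threshold (default 0.5).
#' @param interpolation `"all_point"` (default) or `"11_point"`.
#' @return list with `curve` (data.frame `recall`, `precision`,
#'   `confidence`) and `ap`.
#' @export
pr_curve_and_ap <- function(preds, truths, iou_threshold = 0.5,
                            interpolation = c("all_point", "11_point")) {
  interpolation <- match.arg(interpolation)
  nt <- length(truths)
  if (nt == 0) {
    warning("no ground truths for this class; AP undefined")
    return(list(curve = data.frame(recall = numeric(0), precision = numeric(0),
                                   confidence = numeric(0)), ap = NA_real_))
  }
  if (length(preds) == 0)
    return(list(curve = data.frame(recall = 0, precision = 0, confidence = NA_real_), ap = 0))
  img_of <- function(x) as.character(x$image %||% "1")
  conf <- vapply(preds, `[[`, 0, "confidence")
  ord <- order(conf, decreasing = TRUE)
  used <- list()  # per image: logical vector over its truths
  t_img <- vapply(truths, img_of, "")
  tp_flag <- logical(length(preds))
  for (i in ord) {
    p <- preds[[i]]
    im <- img_of(p)
    idx <- which(t_img == im)
    if (length(idx) == 0) next
    if (is.null(used[[im]])) used[[im]] <- rep(FALSE, length(idx))
    best <- 0; best_k <- NA_integer_
    for (k in seq_along(idx)) {
      if (used[[im]][k]) next
      v <- iou(p$box, truths[[idx[k]]]$box)
      if (v >= iou_threshold && v > best) { best <- v; best_k <- k }
    }
    if (!is.na(best_k)) { tp_flag[i] <- TRUE; used[[im]][best_k] <- TRUE }
  }
  tp_cum <- cumsum(tp_flag[ord])
  fp_cum <- cumsum(!tp_flag[ord])
  recall <- tp_cum / nt
  precision <- tp_cum / (tp_cum + fp_cum)
  curve <- data.frame(recall = recall, precision = precision,
                      confidence = conf[ord])
  ap <- if (interpolation == "all_point") {
    # monotone envelope: p_interp(r) = max precision at recall >= r
    penv <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    sum((recall - r_prev) * penv)
  } else {
    sum(vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- recall >= r
      if (any(sel)) max(precision[sel]) else 0
    }, 0)) / 11
  }
  list(curve = curve, ap = ap)
}

#' Mean average precision
#'
#' Arithmetic mean of per-class AP values; `NA` entries (classes with
#' no ground truth) are dropped with a warning.
#'
#' @param aps numeric vector of per-class APs.
#' @return mAP.
#' @export
mean_ap <- function(aps) {
  if (length(aps) == 0) abort_hsd("at least one class AP required", "hsd_argument_error")
  if (anyNA(aps)) {
    warning("dropping undefined per-class AP values from mAP")
    aps <- aps[!is.na(aps)]
    if (length(aps) == 0) abort_hsd("all APs undefined", "hsd_argument_error")
  }
  mean(aps)
}

#' Confusion matrix
#'
#' @param true_labels,pred_labels equal-length character vectors.
#' @param classes class ordering for rows/columns; every label must
#'   appear here.
#' @return integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true_labels, pred_labels, classes) {
  if (length(true_labels) != length(pred_labels))
    abort_hsd("label vectors must have equal length", "hsd_argument_error")
  bad <- setdiff(unique(c(true_labels, pred_labels)), classes)
  if (length(bad) > 0)
    abort_hsd(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
              "hsd_argument_error")
  m <- table(factor(true_labels, levels = classes),
             factor(pred_labels, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  out
}

#' Mean IoU over matched detections
#'
#' Default: IoUs are averaged within each image, then across images.
#' `per_image = FALSE` instead pools all matched IoUs into one global
#' mean.
#'
#' @param ious_by_image list of numeric vectors, one per image, of
#'   matched-pair IoUs (empty vectors allowed).
#' @param per_image average per image first (default `TRUE`).
#' @return mIoU, or `NA` with a warning when nothing matched.
#' @export
mean_iou <- function(ious_by_image, per_image = TRUE) {
  keep <- vapply(ious_by_image, length, 0L) > 0
  if (!any(keep)) { warning("no matched detections; mIoU undefined"); return(NA_real_) }
  if (per_image) mean(vapply(ious_by_image[keep], mean, 0))
  else mean(unlist(ious_by_image[keep]))
}

#' Full evaluation report over a set of scenes
#'
#' Computes the standard table: per-class precision, recall, F1, AP and
#' IoU at a fixed confidence threshold, plus mIoU, mAP and the
#' confusion matrix of matched detections.
#'
#' @param detections_by_image list (one entry per image) of detection
#'   lists.
#' @param truths_by_image list (one entry per image) of truth lists.
#' @param classes class labels in report order.
#' @param iou_threshold TP matching threshold (default 0.5).
#' @param confidence_threshold detections below this are ignored for
#'   precision/recall/F1/confusion (default 0.5); AP always sweeps all
#'   confidences.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(detections_by_image, truths_by_image, classes,
                              iou_threshold = 0.5, confidence_threshold = 0.5) {
  stopifnot(length(detections_by_image) == length(truths_by_image))
  n_img <- length(detections_by_image)
  flat_preds <- list(); flat_truths <- list()
  for (i in seq_len(n_img)) {
    for (d in detections_by_image[[i]]) { d$image <- i; flat_preds[[length(flat_preds) + 1]] <- d }
    for (t in truths_by_image[[i]]) { t$image <- i; flat_truths[[length(flat_truths) + 1]] <- t }
  }
  per_class <- list()
  ious_by_image <- rep(list(numeric(0)), n_img)
  cm_true <- character(0); cm_pred <- character(0)
  for (i in seq_len(n_img)) {
    dets <- Filter(function(d) d$confidence >= confidence_threshold,
                   detections_by_image[[i]])
    # class-agnostic localization match feeds the confusion matrix
    loc <- match_detections_any_class(dets, truths_by_image[[i]], iou_threshold)
    for (k in seq_along(loc$assignment)) {
      j <- loc$assignment[k]
      if (!is.na(j)) {
        cm_true <- c(cm_true, truths_by_image[[i]][[j]]$label)
        cm_pred <- c(cm_pred, dets[[k]]$label)
      }
    }
  }
  for (cl in classes) {
    cl_preds <- Filter(function(d) identical(d$label, cl), flat_preds)
    cl_truths <- Filter(function(t) identical(t$label, cl), flat_truths)
    thr_preds <- Filter(function(d) d$confidence >= confidence_threshold, cl_preds)
    # per-image matching for counts and IoUs
    tp <- 0; fp <- 0; fn <- 0; cl_ious <- numeric(0)
    for (i in seq_len(n_img)) {
      p_i <- Filter(function(d) identical(d$label, cl) && d$confidence >= confidence_threshold,
                    detections_by_image[[i]])
      t_i <- Filter(function(t) identical(t$label, cl), truths_by_image[[i]])
      m <- match_detections(p_i, t_i, iou_threshold)
      tp <- tp + m$counts$TP; fp <- fp + m$counts$FP; fn <- fn + m$counts$FN
      got <- m$ious[!is.na(m$ious)]
      ious_by_image[[i]] <- c(ious_by_image[[i]], got)
    }
    prf <- suppressWarnings(precision_recall_f1(list(TP = tp, FP = fp, FN = fn)))
    ap <- suppressWarnings(pr_curve_and_ap(cl_preds, cl_truths, iou_threshold)$ap)
    miou_cl <- if (tp > 0) {
      v <- numeric(0)
      for (i in seq_len(n_img)) {
        p_i <- Filter(function(d) identical(d$label, cl) && d$confidence >= confidence_threshold,
                      detections_by_image[[i]])
        t_i <- Filter(function(t) identical(t$label, cl), truths_by_image[[i]])
        m <- match_detections(p_i, t_i, iou_threshold)
        v <- c(v, m$ious[!is.na(m$ious)])
      }
      mean(v)
    } else NA_real_
    per_class[[cl]] <- list(precision = prf$precision, recall = prf$recall,
                            f1 = prf$f1, ap = ap, iou = miou_cl)
  }
  aps <- vapply(per_class, function(x) x$ap, 0)
  structure(list(
    per_class = per_class,
    map = suppressWarnings(mean_ap(aps)),
    miou = suppressWarnings(mean_iou(ious_by_image)),
    confusion = confusion_matrix(cm_true, cm_pred, classes),
    classes = classes,
    iou_threshold = iou_threshold,
    confidence_threshold = confidence_threshold
  ), class = "evaluation_report")
}

# Greedy matching ignoring class labels; used to pair predicted and
# true boxes for the confusion matrix.
match_detections_any_class <- function(preds, truths, iou_threshold = 0.5) {
  np <- length(preds); nt <- length(truths)
  assignment <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)
  ord <- if (np > 0) order(vapply(preds, `[[`, 0, "confidence"), decreasing = TRUE) else integer(0)
  for (i in ord) {
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nt)) {
      if (used[j]) next
      v <- iou(preds[[i]]$box, truths[[j]]$box)
      if (v >= iou_threshold && v > best) { best <- v; best_j <- j }
    }
    if (!is.na(best_j)) { assignment[i] <- best_j; used[best_j] <- TRUE }
  }
  list(assignment = assignment)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report_table(x), sep = "\n")
  invisible(x)
}

#' Format an evaluation report as a fixed-width table
#'
#' Column order mirrors standard detection report tables: Precision,
#' Recall, F1, AP, IoU, mIoU, mAP. Values display with half-up rounding
#' to 3 decimals.
#'
#' @param report an [evaluation_report()].
#' @return character vector of table lines.
#' @export
format_report_table <- function(report) {
  f <- function(v) ifelse(is.na(v), "   NA", sprintf("%.3f", round_half_up(v, 3)))
  lines <- sprintf("%-8s %-9s %-7s %-7s %-7s %-7s %-7s %-7s",
                   "Label", "Precision", "Recall", "F1", "AP", "IoU", "mIoU", "mAP")
  for (cl in report$classes) {
    pc <- report$per_class[[cl]]
    lines <- c(lines, sprintf("%-8s %-9s %-7s %-7s %-7s %-7s %-7s %-7s",
                              cl, f(pc$precision), f(pc$recall), f(pc$f1),
                              f(pc$ap), f(pc$iou), f(report$miou), f(report$map)))
  }
  lines
}
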