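# Independent brute-force oracles used to validate the fast
# implementations. These deliberately share no code with R/: boxes are
# enumerated as pixel sets, matching and suppression are re-derived
# from first principles.

# IoU by explicit pixel-set counting (integer boxes only).
pixel_iou_oracle <- function(a, b) {
  cells <- function(bx) {
    if (bx$x1 <= bx$x0 || bx$y1 <= bx$y0) return(character(0))
    g <- expand.grid(x = bx$x0:(bx$x1 - 1), y = bx$y0:(bx$y1 - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Greedy NMS re-derivation: repeatedly take the highest-confidence
# remaining detection (ties by x0 then y0) and delete same-class
# detections overlapping it above the threshold.
nms_oracle <- function(dets, thr) {
  remaining <- dets
  kept <- list()
  while (length(remaining) > 0) {
    conf <- vapply(remaining, `[[`, 0, "confidence")
    x0 <- vapply(remaining, function(d) d$box$x0, 0)
    y0 <- vapply(remaining, function(d) d$box$y0, 0)
    pick <- order(-conf, x0, y0)[1]
    top <- remaining[[pick]]
    kept[[length(kept) + 1]] <- top
    remaining <- remaining[-pick]
    if (length(remaining) > 0) {
      drop <- vapply(remaining, function(d) {
        identical(d$label, top$label) && pixel_rect_iou(d$box, top$box) > thr
      }, TRUE)
      remaining <- remaining[!drop]
    }
  }
  kept
}

# Rectangle IoU by interval arithmetic, written independently of iou().
pixel_rect_iou <- function(a, b) {
  w <- min(a$x1, b$x1) - max(a$x0, b$x0)
  h <- min(a$y1, b$y1) - max(a$y0, b$y0)
  if (w <= 0 || h <= 0) return(0)
  ia <- w * h
  ia / ((a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - ia)
}

# Matching oracle: replays the stated protocol (decreasing confidence;
# best unmatched same-class truth at IoU >= thr) with a fresh
# implementation over explicit candidate tables.
match_oracle <- function(preds, truths, thr) {
  nt <- length(truths)
  taken <- rep(FALSE, nt)
  conf <- vapply(preds, `[[`, 0, "confidence")
  tp <- 0L
  assignment <- rep(NA_integer_, length(preds))
  for (i in order(conf, decreasing = TRUE)) {
    cand <- data.frame(j = integer(0), v = numeric(0))
    for (j in seq_len(nt)) {
      if (taken[j]) next
      if (!identical(truths[[j]]$label, preds[[i]]$label)) next
      v <- pixel_rect_iou(preds[[i]]$box, truths[[j]]$box)
      if (v >= thr) cand <- rbind(cand, data.frame(j = j, v = v))
    }
    if (nrow(cand) > 0) {
      best <- cand$j[which.max(cand$v)]
      taken[best] <- TRUE
      tp <- tp + 1L
      assignment[i] <- best
    }
  }
  list(TP = tp, FP = length(preds) - tp, FN = as.integer(nt) - tp,
       assignment = assignment)
}

# AP oracle: enumerate PR points by sweeping every confidence cutoff,
# then integrate the interpolated envelope on a fine recall lattice.
ap_sweep_oracle <- function(preds, truths, thr) {
  nt <- length(truths)
  cuts <- sort(unique(vapply(preds, `[[`, 0, "confidence")), decreasing = TRUE)
  pts <- data.frame(recall = 0, precision = 1)
  for (ct in cuts) {
    sub <- Filter(function(p) p$confidence >= ct, preds)
    m <- match_oracle(sub, truths, thr)
    pts <- rbind(pts, data.frame(recall = m$TP / nt,
                                 precision = m$TP / max(1, m$TP + m$FP)))
  }
  rs <- seq(0, 1, by = 1e-4)
  env <- vapply(rs, function(r) {
    sel <- pts$recall >= r & seq_len(nrow(pts)) > 1
    if (any(sel)) max(pts$precision[sel]) else 0
  }, 0)
  mean(env[-1]) * 1  # Riemann mean over (0, 1]
}

random_box <- function(max_xy = 20, max_wh = 8) {
  x0 <- sample(0:(max_xy - 2), 1); y0 <- sample(0:(max_xy - 2), 1)
  bounding_box(x0, y0, x0 + sample(1:max_wh, 1), y0 + sample(1:max_wh, 1))
}

random_detection <- function(classes = c("CBC", "CBB"), max_xy = 20) {
  list(box = random_box(max_xy), label = sample(classes, 1),
       confidence = round(runif(1), 3))
}

tiny_cube <- function(h = 6, w = 6, nb = 5, calibrated = TRUE, seed = 1) {
  set.seed(seed)
  hypercube(array(runif(h * w * nb), dim = c(h, w, nb)),
            desk_grid(nb), calibrated = calibrated)
}
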