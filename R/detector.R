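# Compact object detectors over pseudo-color scenes with an optional
# spectral-fusion classification stage.
#
# Both architectures share a small convolutional backbone (3 blocks of
# conv3x3/ReLU/pool2, stride 8 overall). The one-stage variant attaches
# a single-scale anchor head (objectness, box deltas, class scores) to
# the final feature map — a deliberately single-branch head. The
# two-stage variant attaches a region-proposal head (objectness +
# coordinate adjustments, class-agnostic) and classifies ROI-pooled
# region features with a small fully-connected head that includes a
# background class. With fusion enabled, region 2-D features are
# concatenated with the spectral branch's penultimate features and a
# fusion head produces the final class decision, replacing the 2-D-only
# class scores.

#' Detector configuration
#'
#' @param architecture `"one_stage"` (single-scale anchor head) or
#'   `"two_stage"` (region proposals + ROI classification head).
#' @param backbone_channels channel widths of the three backbone blocks.
#' @param anchor_sizes anchor box side lengths in pixels.
#' @param anchor_ratios anchor aspect ratios (height/width).
#' @param nms_iou NMS IoU threshold, in (0, 1).
#' @param confidence_threshold detection confidence cutoff (default 0.5).
#' @param fusion attach the spectral-fusion classification stage?
#' @param bands band indices used for pseudo-color synthesis and (zero
#'   -masked) spectral extraction; `NULL` means use the full cube for
#'   spectra (pseudo-color then requires `pseudo_bands`).
#' @param pseudo_bands bands for pseudo-color synthesis when different
#'   from `bands`.
#' @param lr Adam learning rate.
#' @param epochs detector training epochs.
#' @param head_epochs epochs for the two-stage classification head and
#'   the fusion head.
#' @param spectral_epochs epochs for the internally trained spectral
#'   branch.
#' @param roi_pool ROI pooling output size (`roi_pool x roi_pool`).
#' @param n_pools number of backbone blocks followed by max pooling;
#'   the detection stride is `2^n_pools`.
#' @param seed integer seed.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(architecture = c("one_stage", "two_stage"),
                            backbone_channels = c(8, 16, 32),
                            anchor_sizes = c(10, 14, 18),
                            anchor_ratios = c(0.7, 1, 1.4),
                            nms_iou = 0.5, confidence_threshold = 0.5,
                            fusion = TRUE, bands = NULL, pseudo_bands = NULL,
                            lr = 2e-3, epochs = 30, head_epochs = 40,
                            spectral_epochs = 25, roi_pool = 2, n_pools = 2,
                            seed = 1) {
  architecture <- match.arg(architecture)
  if (any(anchor_sizes <= 0) || any(anchor_ratios <= 0))
    abort_hsd("anchor sizes and ratios must be positive", "hsd_config_error")
  if (nms_iou <= 0 || nms_iou >= 1 || confidence_threshold <= 0 || confidence_threshold >= 1)
    abort_hsd("thresholds must lie in (0, 1)", "hsd_config_error")
  structure(list(architecture = architecture,
                 backbone_channels = backbone_channels,
                 anchor_sizes = anchor_sizes, anchor_ratios = anchor_ratios,
                 nms_iou = nms_iou, confidence_threshold = confidence_threshold,
                 fusion = fusion, bands = bands, pseudo_bands = pseudo_bands,
                 lr = lr, epochs = epochs, head_epochs = head_epochs,
                 spectral_epochs = spectral_epochs, roi_pool = roi_pool,
                 n_pools = n_pools, seed = seed),
            class = "detector_config")
}

backbone_plan <- function(channels, n_pools = 2) {
  plan <- list()
  for (i in seq_along(channels)) {
    plan[[length(plan) + 1]] <- nn_layer("conv2d", channels = channels[i], k = 3)
    plan[[length(plan) + 1]] <- nn_layer("relu")
    if (i <= n_pools) plan[[length(plan) + 1]] <- nn_layer("pool2d")
  }
  plan
}

#' Build an untrained detector
#'
#' @param cfg a [detector_config()].
#' @param classes character vector of defect class labels.
#' @return object of class `detector_model` (untrained).
#' @export
build_detector <- function(cfg, classes) {
  stopifnot(inherits(cfg, "detector_config"))
  K <- length(classes)
  A <- length(cfg$anchor_sizes) * length(cfg$anchor_ratios)
  stride <- 2^cfg$n_pools
  c_out <- cfg$backbone_channels[length(cfg$backbone_channels)]
  with_seed(cfg$seed, {
    backbone <- nn_build(backbone_plan(cfg$backbone_channels, cfg$n_pools),
                         c(64, 64, 3))
    head <- if (cfg$architecture == "one_stage") {
      nn_build(list(nn_layer("conv2d", channels = A * (5 + K), k = 1)),
               c(64 / stride, 64 / stride, c_out))
    } else {
      nn_build(list(nn_layer("conv2d", channels = A * 5, k = 3)),
               c(64 / stride, 64 / stride, c_out))
    }
    roi_dim <- cfg$roi_pool^2 * c_out
    cls_head <- if (cfg$architecture == "two_stage") {
      nn_build(list(nn_layer("dense", units = 32), nn_layer("relu"),
                    nn_layer("dense", units = K + 1)), roi_dim)
    } else NULL
    structure(list(cfg = cfg, classes = classes, A = A, stride = stride,
                   backbone = backbone, head = head, cls_head = cls_head,
                   fusion_head = NULL, spectral_model = NULL,
                   loss_history = numeric(0)),
              class = "detector_model")
  })
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> %s, stride %d, %d anchors/cell, fusion %s, classes: %s\n",
              x$cfg$architecture, x$stride, x$A,
              if (x$cfg$fusion) "on" else "off", paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Mean box spectrum restricted to configured bands
#'
#' Composition of [extract_roi_spectrum()] and [apply_band_mask()]:
#' the per-band mean over the box's pixels, zero-masked to `bands`
#' (`NULL` keeps the full spectrum).
#'
#' @param cube calibrated [hypercube()].
#' @param box a [bounding_box()].
#' @param bands band indices or `NULL` for all.
#' @return a `spectrum`.
#' @export
extract_box_spectra <- function(cube, box, bands = NULL) {
  s <- extract_roi_spectrum(cube, box)
  if (is.null(bands)) s else apply_band_mask(s, bands)
}

# --- anchors and box coding -------------------------------------------------

# Anchor centers follow feature-map cell order (row index fastest),
# matching the reshaping of the head output.
make_anchors <- function(h8, w8, stride, sizes, ratios) {
  cy <- (rep(seq_len(h8), times = w8) - 0.5) * stride
  cx <- (rep(seq_len(w8), each = h8) - 0.5) * stride
  out <- list()
  for (r in ratios) for (s in sizes) {
    ah <- s * sqrt(r); aw <- s / sqrt(r)
    out[[length(out) + 1]] <- cbind(cx - aw / 2, cy - ah / 2, cx + aw / 2, cy + ah / 2)
  }
  do.call(rbind, out)  # (cells * A) x 4, anchor-major blocks of cells
}

box_to_delta <- function(anchors, boxes) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  acx <- (anchors[, 1] + anchors[, 3]) / 2; acy <- (anchors[, 2] + anchors[, 4]) / 2
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  bcx <- (boxes[, 1] + boxes[, 3]) / 2; bcy <- (boxes[, 2] + boxes[, 4]) / 2
  cbind((bcx - acx) / aw, (bcy - acy) / ah, log(bw / aw), log(bh / ah))
}

delta_to_box <- function(anchors, deltas) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  acx <- (anchors[, 1] + anchors[, 3]) / 2; acy <- (anchors[, 2] + anchors[, 4]) / 2
  bcx <- acx + deltas[, 1] * aw; bcy <- acy + deltas[, 2] * ah
  bw <- aw * exp(pmin(deltas[, 3], 4)); bh <- ah * exp(pmin(deltas[, 4], 4))
  cbind(bcx - bw / 2, bcy - bh / 2, bcx + bw / 2, bcy + bh / 2)
}

rect_iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, `+`) - inter)
}

# anchors between neg_iou and pos_iou are ignored by the objectness
# loss; the band is kept narrow so nearly-overlapping anchors are
# trained as negatives and cannot emit untrained garbage boxes
assign_anchors <- function(anchors, truth_boxes, pos_iou = 0.5, neg_iou = 0.45) {
  n <- nrow(anchors)
  if (nrow(truth_boxes) == 0)
    return(list(pos = integer(0), neg = seq_len(n), truth_of = integer(0)))
  m <- rect_iou_matrix(anchors, truth_boxes)
  best_iou <- apply(m, 1, max)
  best_truth <- max.col(m, ties.method = "first")
  pos <- which(best_iou >= pos_iou)
  # forced best-match: each truth claims its highest-IoU anchor
  forced <- vapply(seq_len(ncol(m)), function(j) which.max(m[, j]), 0L)
  pos <- sort(union(pos, forced))
  neg <- setdiff(which(best_iou < neg_iou), pos)
  list(pos = pos, neg = neg, truth_of = best_truth[pos])
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

# --- scene preparation ------------------------------------------------------

scene_pseudo_input <- function(scene, cfg) {
  bands <- cfg$pseudo_bands %||% cfg$bands
  if (is.null(bands) || length(bands) != 3)
    abort_hsd("detector needs three pseudo-color bands (cfg$bands or cfg$pseudo_bands)",
              "hsd_config_error")
  img <- synthesize_pseudocolor(scene$cube, bands) / 255
  array(img, dim = c(1, dim(img)))
}

truth_box_matrix <- function(truths) {
  if (length(truths) == 0) return(matrix(0, 0, 4))
  t(vapply(truths, function(t) c(t$box$x0, t$box$y0, t$box$x1, t$box$y1), numeric(4)))
}

# Head output array (1, h8, w8, A*(5+K)) -> per-anchor matrices aligned
# with make_anchors ordering (anchor-major blocks of cells).
split_head_output <- function(out, A, K) {
  d <- dim(out)
  cells <- d[2] * d[3]
  P <- matrix(out, cells, d[4])  # rows: row-index fastest, then col
  per <- 5 + K
  obj <- numeric(cells * A); deltas <- matrix(0, cells * A, 4)
  cls <- if (K > 0) matrix(0, cells * A, K) else NULL
  for (a in seq_len(A)) {
    rows <- (a - 1) * cells + seq_len(cells)
    base <- (a - 1) * per
    obj[rows] <- P[, base + 1]
    deltas[rows, ] <- P[, base + 2:5]
    if (K > 0) cls[rows, ] <- P[, base + 5 + seq_len(K)]
  }
  list(obj = obj, deltas = deltas, cls = cls, cells = cells, d = d, per = per)
}

merge_head_grad <- function(sp, d_obj, d_deltas, d_cls, A, K) {
  per <- sp$per; cells <- sp$cells
  G <- matrix(0, cells, sp$d[4])
  for (a in seq_len(A)) {
    rows <- (a - 1) * cells + seq_len(cells)
    base <- (a - 1) * per
    G[, base + 1] <- d_obj[rows]
    G[, base + 2:5] <- d_deltas[rows, ]
    if (K > 0) G[, base + 5 + seq_len(K)] <- d_cls[rows, ]
  }
  array(G, dim = sp$d)
}

# Single-scene loss and gradient wrt head output for anchor heads.
anchor_head_loss <- function(sp, anchors, truth_boxes, truth_cls, K) {
  asn <- assign_anchors(anchors, truth_boxes)
  n_pos <- length(asn$pos); n_neg <- length(asn$neg)
  d_obj <- numeric(length(sp$obj))
  d_deltas <- matrix(0, nrow(sp$deltas), 4)
  d_cls <- if (K > 0) matrix(0, nrow(sp$cls), K) else NULL
  loss <- 0
  p_obj <- nn_sigmoid(sp$obj)
  if (n_pos > 0) {
    loss <- loss - mean(log(pmax(p_obj[asn$pos], 1e-12)))
    d_obj[asn$pos] <- d_obj[asn$pos] + (p_obj[asn$pos] - 1) / n_pos
  }
  if (n_neg > 0) {
    # hard-negative mining: averaging over all negatives lets a few
    # confidently-wrong anchors persist, so only the hardest 3:1
    # negatives (highest objectness) carry the loss
    k <- min(n_neg, max(8, 3 * n_pos))
    hard <- asn$neg[order(p_obj[asn$neg], decreasing = TRUE)[seq_len(k)]]
    loss <- loss - mean(log(pmax(1 - p_obj[hard], 1e-12)))
    d_obj[hard] <- d_obj[hard] + p_obj[hard] / k
  }
  if (n_pos > 0) {
    tgt <- box_to_delta(anchors[asn$pos, , drop = FALSE],
                        truth_boxes[asn$truth_of, , drop = FALSE])
    diff <- sp$deltas[asn$pos, , drop = FALSE] - tgt
    loss <- loss + 2 * mean(smooth_l1(diff))
    d_deltas[asn$pos, ] <- 2 * smooth_l1_grad(diff) / (n_pos * 4)
    if (K > 0) {
      ls <- nn_softmax_xent(sp$cls[asn$pos, , drop = FALSE], truth_cls[asn$truth_of])
      loss <- loss + ls$loss
      d_cls[asn$pos, ] <- ls$dlogits
    }
  }
  list(loss = loss, d_obj = d_obj, d_deltas = d_deltas, d_cls = d_cls)
}

# ROI pooling: adaptive average pooling of the feature map over the box
# mapped to feature-map coordinates; returns a flat feature vector.
roi_pool_features <- function(fmap, box, stride, pool) {
  h8 <- dim(fmap)[1]; w8 <- dim(fmap)[2]; C <- dim(fmap)[3]
  x0 <- max(1, floor(box[1] / stride) + 1); x1 <- min(w8, ceiling(box[3] / stride))
  y0 <- max(1, floor(box[2] / stride) + 1); y1 <- min(h8, ceiling(box[4] / stride))
  if (x1 < x0) { x0 <- x1 <- min(w8, max(1, round((box[1] + box[3]) / 2 / stride))) }
  if (y1 < y0) { y0 <- y1 <- min(h8, max(1, round((box[2] + box[4]) / 2 / stride))) }
  ys <- y0:y1; xs <- x0:x1
  feat <- numeric(pool * pool * C)
  yb <- split(ys, cut(seq_along(ys), pool, labels = FALSE))
  xb <- split(xs, cut(seq_along(xs), pool, labels = FALSE))
  k <- 0
  for (qx in seq_len(pool)) for (qy in seq_len(pool)) {
    yy <- yb[[min(qy, length(yb))]]; xx <- xb[[min(qx, length(xb))]]
    block <- fmap[yy, xx, , drop = FALSE]
    feat[k + seq_len(C)] <- apply(block, 3, mean)
    k <- k + C
  }
  feat
}

clip_box <- function(b, w, h) {
  x0 <- min(max(b[1], 0), w - 1)
  y0 <- min(max(b[2], 0), h - 1)
  x1 <- min(max(b[3], x0 + 1), w)
  y1 <- min(max(b[4], y0 + 1), h)
  c(x0, y0, x1, y1)
}

# Train a small dense net on a feature matrix (used for the two-stage
# classification head and the fusion head).
train_dense_head <- function(x, y, n_out, epochs, lr, seed, hidden = 32) {
  with_seed(seed, {
    net <- nn_build(list(nn_layer("dense", units = hidden), nn_layer("relu"),
                         nn_layer("dense", units = n_out)), ncol(x))
    state <- nn_adam_init(net)
    t_step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      for (start in seq(1, length(ord), by = 32)) {
        idx <- ord[start:min(start + 31, length(ord))]
        fw <- nn_forward(net, x[idx, , drop = FALSE])
        ls <- nn_softmax_xent(fw$out, y[idx])
        bk <- nn_backward(net, fw$caches, ls$dlogits)
        t_step <- t_step + 1
        up <- nn_adam_step(net, bk$grads, state, lr, t_step)
        net <- up$net; state <- up$state
      }
    }
    net
  })
}

jittered_boxes <- function(box, w, h, n, max_shift = 2) {
  out <- list(box)
  for (i in seq_len(n)) {
    dx <- sample(-max_shift:max_shift, 1); dy <- sample(-max_shift:max_shift, 1)
    b <- clip_box(c(box$x0 + dx, box$y0 + dy, box$x1 + dx, box$y1 + dy), w, h)
    out[[length(out) + 1]] <- bounding_box(b[1], b[2], b[3], b[4])
  }
  out
}

#' Train a detector on annotated scenes
#'
#' Staged protocol: (1) with fusion on, the spectral branch is trained
#' first on (jittered) ground-truth box spectra; (2) the backbone and
#' anchor head (one-stage) or region-proposal head (two-stage) are
#' trained with Adam, one scene per step; (3) the two-stage
#' classification head and the fusion head are trained on ROI features
#' from the frozen backbone. Deterministic given `cfg$seed`.
#'
#' @param scenes list of `annotated_scene` objects (from
#'   [generate_scene()] or built manually with fields `cube`, `truths`).
#' @param cfg a [detector_config()] with `bands` set.
#' @param spectral_model optional pre-trained `trained_spectral_net`
#'   for the fusion branch (skips stage 1).
#' @return a trained `detector_model` with `loss_history` (per-epoch
#'   mean loss).
#' @export
train_detector <- function(scenes, cfg, spectral_model = NULL) {
  all_truths <- unlist(lapply(scenes, function(s) lapply(s$truths, `[[`, "label")))
  if (length(all_truths) == 0)
    abort_hsd("no ground-truth boxes in any scene", "hsd_training_error")
  classes <- sort(unique(unlist(all_truths)))
  model <- build_detector(cfg, classes)
  K <- length(classes)
  d1 <- dim(scenes[[1]]$cube$values)
  h <- d1[1]; w <- d1[2]

  # stage 1: spectral branch
  if (cfg$fusion) {
    if (is.null(spectral_model)) {
      sp_x <- list(); sp_y <- character(0)
      with_seed(cfg$seed + 101L, {
        for (s in scenes) for (t in s$truths) {
          for (b in jittered_boxes(t$box, w, h, 3)) {
            sp_x[[length(sp_x) + 1]] <-
              spectrum_values(extract_box_spectra(s$cube, b, cfg$bands))
            sp_y <- c(sp_y, t$label)
          }
        }
      })
      sp_data <- list(spectra = do.call(rbind, sp_x), labels = sp_y)
      sp_cfg <- spectral_net_preset_scaled(input_length = ncol(sp_data$spectra),
                                           n_classes = K,
                                           epochs = cfg$spectral_epochs,
                                           seed = cfg$seed + 5L)
      spectral_model <- train_classifier(sp_data, sp_cfg)
    }
    model$spectral_model <- spectral_model
  }

  # stage 2: backbone + anchor/RPN head
  stride <- model$stride
  h8 <- h %/% stride; w8 <- w %/% stride
  anchors <- make_anchors(h8, w8, stride, cfg$anchor_sizes, cfg$anchor_ratios)
  head_K <- if (cfg$architecture == "one_stage") K else 0
  inputs <- lapply(scenes, scene_pseudo_input, cfg = cfg)
  truth_boxes <- lapply(scenes, function(s) truth_box_matrix(s$truths))
  truth_cls <- lapply(scenes, function(s)
    match(vapply(s$truths, `[[`, "", "label"), classes))
  backbone <- model$backbone; head <- model$head
  st_b <- nn_adam_init(backbone); st_h <- nn_adam_init(head)
  t_step <- 0
  history <- numeric(0)
  with_seed(cfg$seed + 11L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(scenes))
      ep_loss <- 0
      for (si in ord) {
        fb <- nn_forward(backbone, inputs[[si]])
        fh <- nn_forward(head, fb$out)
        sp <- split_head_output(fh$out, model$A, head_K)
        al <- anchor_head_loss(sp, anchors, truth_boxes[[si]], truth_cls[[si]], head_K)
        gout <- merge_head_grad(sp, al$d_obj, al$d_deltas, al$d_cls, model$A, head_K)
        bh <- nn_backward(head, fh$caches, gout)
        bb <- nn_backward(backbone, fb$caches, bh$dX)
        t_step <- t_step + 1
        uh <- nn_adam_step(head, bh$grads, st_h, cfg$lr, t_step)
        head <- uh$net; st_h <- uh$state
        ub <- nn_adam_step(backbone, bb$grads, st_b, cfg$lr, t_step)
        backbone <- ub$net; st_b <- ub$state
        ep_loss <- ep_loss + al$loss
      }
      history <- c(history, ep_loss / length(scenes))
    }
  })
  model$backbone <- backbone; model$head <- head
  model$loss_history <- history

  # stage 3: ROI-feature heads on the frozen backbone
  fmap_of <- function(i) {
    fm <- nn_forward(model$backbone, inputs[[i]], keep_cache = FALSE)$out
    array(fm, dim = dim(fm)[-1])
  }
  fmaps <- lapply(seq_along(scenes), fmap_of)
  roi_feat <- function(i, box)
    roi_pool_features(fmaps[[i]], c(box$x0, box$y0, box$x1, box$y1),
                      stride, cfg$roi_pool)
  if (cfg$architecture == "two_stage") {
    # classification head: truths (+jitters) as class examples,
    # off-truth proposals as background
    cx <- list(); cy <- integer(0)
    with_seed(cfg$seed + 21L, {
      for (i in seq_along(scenes)) {
        for (t in scenes[[i]]$truths) {
          for (b in jittered_boxes(t$box, w, h, 2)) {
            cx[[length(cx) + 1]] <- roi_feat(i, b)
            cy <- c(cy, match(t$label, classes))
          }
        }
        # background samples: random boxes with low IoU to all truths
        tb <- truth_boxes[[i]]
        n_bg <- 0
        for (try in 1:20) {
          if (n_bg >= 3) break
          bw <- sample(8:16, 1); bh2 <- sample(8:16, 1)
          x0 <- sample(0:(w - bw), 1); y0 <- sample(0:(h - bh2), 1)
          cand <- matrix(c(x0, y0, x0 + bw, y0 + bh2), 1)
          if (nrow(tb) == 0 || all(rect_iou_matrix(cand, tb) < 0.1)) {
            cx[[length(cx) + 1]] <- roi_feat(i, bounding_box(x0, y0, x0 + bw, y0 + bh2))
            cy <- c(cy, K + 1L)
            n_bg <- n_bg + 1
          }
        }
      }
    })
    model$cls_head <- train_dense_head(do.call(rbind, cx), cy, K + 1,
                                       cfg$head_epochs, cfg$lr, cfg$seed + 31L)
  }
  if (cfg$fusion) {
    fx <- list(); fy <- integer(0)
    with_seed(cfg$seed + 41L, {
      for (i in seq_along(scenes)) for (t in scenes[[i]]$truths) {
        for (b in jittered_boxes(t$box, w, h, 2)) {
          f2d <- roi_feat(i, b)
          f1d <- extract_features(model$spectral_model,
                                  extract_box_spectra(scenes[[i]]$cube, b, cfg$bands))
          fx[[length(fx) + 1]] <- c(f2d, f1d)
          fy <- c(fy, match(t$label, classes))
        }
      }
    })
    model$fusion_head <- train_dense_head(do.call(rbind, fx), fy, K,
                                          cfg$head_epochs, cfg$lr, cfg$seed + 51L)
  }
  model
}

#' Non-maximum suppression
#'
#' Greedy: detections sorted by decreasing confidence; a kept box
#' suppresses later boxes of the same class with IoU strictly greater
#' than the threshold. Ties in confidence break by lower box
#' coordinates (x0, then y0), so the result is stable.
#'
#' @param detections list of detections (`box`, `label`, `confidence`).
#' @param iou_threshold suppression threshold.
#' @return the surviving detections, in decreasing-confidence order.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  if (length(detections) == 0) return(detections)
  conf <- vapply(detections, `[[`, 0, "confidence")
  x0 <- vapply(detections, function(d) d$box$x0, 0)
  y0 <- vapply(detections, function(d) d$box$y0, 0)
  ord <- order(-conf, x0, y0)
  keep <- logical(length(detections))
  alive <- rep(TRUE, length(detections))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    for (j in ord) {
      if (j == i || !alive[j]) next
      if (identical(detections[[j]]$label, detections[[i]]$label) &&
          iou(detections[[i]]$box, detections[[j]]$box) > iou_threshold)
        alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  detections[ord[keep[ord]]]
}

# Class-agnostic greedy suppression used inside detect(): duplicate
# boxes on one object frequently carry different 2-D class labels (the
# misclassification mode the fusion stage exists to fix), so
# localization duplicates are suppressed regardless of label. The
# exported nms() keeps the per-class contract.
nms_keep_indices <- function(boxes, conf, thr) {
  ord <- order(-conf, boxes[, 1], boxes[, 2])
  alive <- rep(TRUE, length(conf))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    if (any(alive)) {
      ious <- rect_iou_matrix(boxes[i, , drop = FALSE],
                              boxes[alive, , drop = FALSE])[1, ]
      alive[alive] <- ious <= thr
    }
  }
  keep
}

fused_probs <- function(model, f2d, f1d) {
  logits <- nn_forward(model$fusion_head, matrix(c(f2d, f1d), 1), keep_cache = FALSE)$out
  p <- nn_softmax(logits)[1, ]
  names(p) <- model$classes
  p
}

#' Run detection on a scene
#'
#' Decodes the anchor head (one-stage) or proposes and classifies
#' regions (two-stage), applies per-class NMS at the configured IoU
#' threshold and the configured confidence cutoff. With fusion on, the
#' class decision of each surviving box is replaced by the fusion
#' head's output over concatenated 2-D region and 1-D spectral
#' features.
#'
#' @param model a trained `detector_model`.
#' @param scene an `annotated_scene` (its `truths` are ignored) or a
#'   list with a calibrated `cube`.
#' @return list of detections (`box`, `label`, `confidence`,
#'   `probabilities`).
#' @export
detect <- function(model, scene) {
  cfg <- model$cfg
  K <- length(model$classes)
  input <- scene_pseudo_input(scene, cfg)
  h <- dim(input)[2]; w <- dim(input)[3]
  stride <- model$stride
  h8 <- h %/% stride; w8 <- w %/% stride
  anchors <- make_anchors(h8, w8, stride, cfg$anchor_sizes, cfg$anchor_ratios)
  fmap4 <- nn_forward(model$backbone, input, keep_cache = FALSE)$out
  fmap <- array(fmap4, dim = dim(fmap4)[-1])
  out <- nn_forward(model$head, fmap4, keep_cache = FALSE)$out
  head_K <- if (cfg$architecture == "one_stage") K else 0
  sp <- split_head_output(out, model$A, head_K)
  obj <- nn_sigmoid(sp$obj)
  boxes <- delta_to_box(anchors, sp$deltas)
  cand <- list()
  if (cfg$architecture == "one_stage") {
    cls_p <- nn_softmax(sp$cls)
    idx <- which(obj >= 0.25)
    for (i in idx) {
      b <- clip_box(boxes[i, ], w, h)
      if (b[3] - b[1] < 2 || b[4] - b[2] < 2) next
      conf2d <- obj[i] * max(cls_p[i, ])
      cand[[length(cand) + 1]] <- list(
        box = bounding_box(b[1], b[2], b[3], b[4]),
        label = model$classes[which.max(cls_p[i, ])],
        confidence = conf2d,
        probabilities = stats::setNames(cls_p[i, ], model$classes),
        obj = obj[i])
    }
  } else {
    # proposals: top-scoring decoded anchors, class-agnostic NMS
    ord <- order(obj, decreasing = TRUE)[seq_len(min(50, length(obj)))]
    props <- list()
    for (i in ord) {
      b <- clip_box(boxes[i, ], w, h)
      if (b[3] - b[1] < 2 || b[4] - b[2] < 2) next
      props[[length(props) + 1]] <- list(box = bounding_box(b[1], b[2], b[3], b[4]),
                                         label = "roi", confidence = obj[i])
    }
    props <- nms(props, 0.7)
    props <- props[seq_len(min(10, length(props)))]
    for (p in props) {
      f2d <- roi_pool_features(fmap, c(p$box$x0, p$box$y0, p$box$x1, p$box$y1),
                               stride, cfg$roi_pool)
      logits <- nn_forward(model$cls_head, matrix(f2d, 1), keep_cache = FALSE)$out
      pc <- nn_softmax(logits)[1, ]
      p_bg <- pc[K + 1]
      if (which.max(pc) == K + 1) next
      cls_probs <- pc[seq_len(K)] / sum(pc[seq_len(K)])
      cand[[length(cand) + 1]] <- list(
        box = p$box,
        label = model$classes[which.max(cls_probs)],
        confidence = p$confidence * (1 - p_bg),
        probabilities = stats::setNames(cls_probs, model$classes),
        obj = p$confidence)
    }
  }
  kept <- if (length(cand) > 0) {
    bm <- t(vapply(cand, function(d) c(d$box$x0, d$box$y0, d$box$x1, d$box$y1),
                   numeric(4)))
    cand[nms_keep_indices(bm, vapply(cand, `[[`, 0, "confidence"), cfg$nms_iou)]
  } else cand
  kept <- Filter(function(d) d$confidence >= cfg$confidence_threshold, kept)
  if (cfg$fusion && length(kept) > 0) {
    if (!scene$cube$calibrated)
      abort_hsd("fusion detection requires a calibrated cube", "hsd_argument_error")
    kept <- lapply(kept, function(d) {
      f2d <- roi_pool_features(fmap, c(d$box$x0, d$box$y0, d$box$x1, d$box$y1),
                               stride, cfg$roi_pool)
      f1d <- extract_features(model$spectral_model,
                              extract_box_spectra(scene$cube, d$box, cfg$bands))
      p <- fused_probs(model, f2d, f1d)
      d$probabilities <- p
      d$label <- model$classes[which.max(p)]
      d$confidence <- d$obj * max(p)
      d
    })
    kept <- Filter(function(d) d$confidence >= cfg$confidence_threshold, kept)
  }
  lapply(kept, function(d) { d$obj <- NULL; d })
}
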