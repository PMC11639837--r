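# Shared tiny training world for the detector unit tests; the
# full-scale performance checks live in test-acceptance.R.
det_world <- local({
  g <- desk_grid(24)
  profs <- default_profiles(g)
  scenes <- lapply(1:4, function(i)
    generate_scene(scene_spec(32, 32, g, n_defects_range = c(1, 2),
                              defect_size_range = c(8, 12), seed = 40 + i), profs))
  bands <- sapply(c(430, 576, 962), function(nm) nearest_band_index(g, nm))
  list(g = g, profs = profs, scenes = scenes, bands = bands)
})
tiny_det_cfg <- function(...) {
  args <- modifyList(list(backbone_channels = c(4, 8, 8), anchor_sizes = c(8, 12),
                          anchor_ratios = 1, bands = det_world$bands, epochs = 2,
                          head_epochs = 4, spectral_epochs = 3, seed = 2),
                     list(...))
  do.call(detector_config, args)
}

test_that("detector configs validate and audit their architecture", {
  expect_error(detector_config(anchor_sizes = c(0, 10)), class = "hsd_config_error")
  expect_error(detector_config(nms_iou = 1.2), class = "hsd_config_error")
  m1 <- build_detector(tiny_det_cfg(architecture = "one_stage"), c("CBC", "CBB"))
  # exactly one detection scale: a single head conv over one feature map
  types <- vapply(m1$head$layers, `[[`, "", "type")
  expect_identical(types, "conv2d")
  expect_equal(ncol(m1$head$layers[[1]]$W), m1$A * (5 + 2))
  m2 <- build_detector(tiny_det_cfg(architecture = "two_stage"), c("CBC", "CBB"))
  expect_equal(ncol(m2$head$layers[[1]]$W), m2$A * 5)  # class-agnostic RPN
  expect_identical(ncol(m2$cls_head$layers[[3]]$W), 3L)    # K + background
})

test_that("fusion toggles the classification head input dimension", {
  sc <- det_world$scenes
  m_on <- train_detector(sc, tiny_det_cfg(architecture = "one_stage", fusion = TRUE))
  m_off <- train_detector(sc, tiny_det_cfg(architecture = "one_stage", fusion = FALSE))
  roi_dim <- m_on$cfg$roi_pool^2 * 8
  expect_equal(nrow(m_on$fusion_head$layers[[1]]$W),
               roi_dim + m_on$spectral_model$cfg$fc_width)
  expect_null(m_off$fusion_head)
  expect_null(m_off$spectral_model)
})

test_that("extract_box_spectra composes ROI extraction with masking", {
  sc <- det_world$scenes[[1]]
  box <- sc$truths[[1]]$box
  s <- extract_box_spectra(sc$cube, box, det_world$bands)
  ref <- apply_band_mask(extract_roi_spectrum(sc$cube, box), det_world$bands)
  expect_equal(s$values, ref$values)
  full <- extract_box_spectra(sc$cube, box, NULL)
  expect_equal(full$values, extract_roi_spectrum(sc$cube, box)$values)
  # a pure stamped ellipse interior tracks its class profile
  cl <- sc$truths[[1]]$label
  prof_curve <- profile_reflectance(det_world$profs[[cl]], det_world$g)
  b2 <- bounding_box(box$x0 + round((box$x1 - box$x0) * 0.3),
                     box$y0 + round((box$y1 - box$y0) * 0.3),
                     box$x1 - round((box$x1 - box$x0) * 0.3),
                     box$y1 - round((box$y1 - box$y0) * 0.3))
  inner <- extract_roi_spectrum(sc$cube, b2)$values
  expect_lt(max(abs(inner - prof_curve)), 6 * det_world$profs[[cl]]$noise_sd)
})

test_that("training smoke contract: loss history, determinism, error on empty truths", {
  sc <- det_world$scenes[1:2]
  m <- train_detector(sc, tiny_det_cfg(architecture = "one_stage", fusion = FALSE))
  expect_length(m$loss_history, 2)
  expect_true(all(is.finite(m$loss_history)))
  m2 <- train_detector(sc, tiny_det_cfg(architecture = "one_stage", fusion = FALSE))
  expect_identical(m$loss_history, m2$loss_history)
  d1 <- detect(m, sc[[1]]); d2 <- detect(m2, sc[[1]])
  expect_identical(d1, d2)
  blank <- generate_scene(scene_spec(32, 32, det_world$g,
                                     n_defects_range = c(0, 0), seed = 1),
                          det_world$profs)
  expect_error(train_detector(list(blank), tiny_det_cfg()),
               class = "hsd_training_error")
})

test_that("two-stage variant trains and detects deterministically", {
  sc <- det_world$scenes
  m <- train_detector(sc, tiny_det_cfg(architecture = "two_stage", fusion = FALSE))
  expect_length(m$loss_history, 2)
  dets <- detect(m, sc[[1]])
  expect_identical(dets, detect(m, sc[[1]]))
  for (d in dets) {
    expect_gte(d$confidence, m$cfg$confidence_threshold)
    expect_true(d$box$x0 >= 0 && d$box$y0 >= 0 &&
                d$box$x1 <= 32 && d$box$y1 <= 32)
    expect_equal(sum(d$probabilities), 1, tolerance = 1e-6)
  }
})

test_that("nms keeps disjoint boxes, collapses duplicates and matches the oracle", {
  d1 <- list(box = bounding_box(0, 0, 10, 10), label = "CBC", confidence = 0.9)
  d2 <- list(box = bounding_box(30, 30, 40, 40), label = "CBC", confidence = 0.8)
  expect_length(nms(list(d1, d2), 0.5), 2)
  dup <- list(box = bounding_box(0, 0, 10, 9), label = "CBC", confidence = 0.8)
  kept <- nms(list(dup, d1), 0.5)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$confidence, 0.9)
  # duplicates of a different class are not suppressed by nms()
  other <- modifyList(dup, list(label = "CBB"))
  expect_length(nms(list(other, d1), 0.5), 2)
  set.seed(61)
  for (i in 1:100) {
    dets <- replicate(sample(2:10, 1), random_detection(), simplify = FALSE)
    got <- nms(dets, 0.4)
    want <- nms_oracle(dets, 0.4)
    expect_equal(got, want, label = sprintf("case %d", i))
  }
})

test_that("detections on a blank scene are empty after confidence filtering", {
  sc <- det_world$scenes
  m <- train_detector(sc, tiny_det_cfg(architecture = "one_stage", fusion = FALSE, epochs = 6))
  blank <- generate_scene(scene_spec(32, 32, det_world$g,
                                     n_defects_range = c(0, 0), seed = 99),
                          det_world$profs)
  dets <- detect(m, blank)
  # a tiny 6-epoch model may emit stragglers; all must sit at/above the
  # configured threshold and none may cover meaningful background area
  for (d in dets) expect_gte(d$confidence, 0.5)
  expect_lte(length(dets), 3)
})
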