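test_that("default profiles encode the stated absorption structure", {
  g <- desk_grid(60)
  profs <- default_profiles(g)
  expect_named(profs, c("CBC", "CBB", "CBBR", "background"))
  # outside all features the curve sits at baseline
  at <- function(p, nm) profile_reflectance(p, wavelength_grid(nm))
  expect_equal(at(profs$CBC, 700), profs$CBC$baseline, tolerance = 1e-4)
  # hemoglobin-band depth ordering CBC > CBBR > CBB at 545 nm
  d545 <- sapply(profs[c("CBC", "CBBR", "CBB")],
                 function(p) p$baseline - at(p, 545))
  expect_true(d545["CBC"] > d545["CBBR"] && d545["CBBR"] > d545["CBB"])
  # water band: reflectance near 962 decreases CBC > CBB > CBBR
  r962 <- sapply(profs[c("CBC", "CBB", "CBBR")], function(p) at(p, 962))
  expect_true(r962["CBC"] > r962["CBB"] && r962["CBB"] > r962["CBBR"])
  for (p in profs)
    expect_true(all(profile_reflectance(p, default_grid()) > 0 &
                    profile_reflectance(p, default_grid()) < 1))
  expect_error(class_profile("x", 0.2,
                             data.frame(center_nm = 500, width_nm = 10, depth = 0.5)),
               class = "hsd_argument_error")
})

test_that("sample_spectrum is seeded, clipped and centered on the closed form", {
  g <- desk_grid(40)
  p <- default_profiles(g)$CBC
  noiseless <- class_profile("CBC", p$baseline, p$features, noise_sd = 0)
  expect_equal(sample_spectrum(noiseless, g, seed = 1)$values,
               profile_reflectance(p, g))
  expect_identical(sample_spectrum(p, g, seed = 9)$values,
                   sample_spectrum(p, g, seed = 9)$values)
  expect_false(identical(sample_spectrum(p, g, seed = 9)$values,
                         sample_spectrum(p, g, seed = 10)$values))
  # Monte-Carlo mean within 3*sd/sqrt(n) of the closed form, per band
  n <- 10000
  draws <- generate_spectrum_dataset(list(CBC = p), n, g, seed = 5)$spectra
  expect_true(all(abs(colMeans(draws) - profile_reflectance(p, g)) <
                  3 * p$noise_sd / sqrt(n) + 1e-6))
})

test_that("spectrum datasets are balanced, shuffled deterministically, and ordered in depth", {
  g <- desk_grid(60)
  profs <- default_profiles(g)
  d1 <- generate_spectrum_dataset(profs, 1, g, seed = 1)
  expect_identical(sort(d1$labels), c("CBB", "CBBR", "CBC"))
  d <- generate_spectrum_dataset(profs, 500, g, seed = 2)
  expect_identical(unname(table(d$labels)["CBC"]), 500L)
  b545 <- nearest_band_index(g, 545)
  m <- tapply(d$spectra[, b545], d$labels, mean)
  expect_true(m[["CBC"]] < m[["CBBR"]] && m[["CBBR"]] < m[["CBB"]])
  d2 <- generate_spectrum_dataset(profs, 500, g, seed = 3)
  expect_false(identical(d$spectra, d2$spectra))
  expect_identical(table(d$labels), table(d2$labels))
  # CSV round trip
  p <- tempfile(fileext = ".csv")
  write_spectrum_csv(d1, p)
  back <- read_spectrum_csv(p)
  expect_equal(unname(back$spectra), unname(d1$spectra), tolerance = 1e-6)
  expect_identical(back$labels, d1$labels)
})

test_that("scenes are deterministic with disjoint in-bounds annotated defects", {
  g <- desk_grid(30)
  spec <- scene_spec(48, 48, g, n_defects_range = c(2, 3), seed = 7)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$cube$values, s2$cube$values)
  expect_identical(s1$truths, s2$truths)
  expect_gte(length(s1$truths), 2)
  boxes <- lapply(s1$truths, `[[`, "box")
  for (b in boxes) expect_true(b$x0 >= 0 && b$y0 >= 0 && b$x1 <= 48 && b$y1 <= 48)
  if (length(boxes) > 1)
    for (i in 1:(length(boxes) - 1)) for (j in (i + 1):length(boxes))
      expect_identical(iou(boxes[[i]], boxes[[j]]), 0)
})

test_that("defect ROIs contrast with background most strongly in the hemoglobin window", {
  g <- desk_grid(60)
  profs <- default_profiles(g)
  spec <- scene_spec(48, 48, g, n_defects_range = c(1, 1),
                     class_mix = c(CBC = 1, CBB = 0, CBBR = 0), seed = 3)
  sc <- generate_scene(spec, profs)
  expect_identical(sc$truths[[1]]$label, "CBC")
  roi <- extract_roi_spectrum(sc$cube, sc$truths[[1]]$box)$values
  bg <- profile_reflectance(profs$background, g)
  contrast <- bg - roi
  w <- g$wavelengths_nm
  in_hemo <- w >= 420 & w <= 600
  # expected contrast from the stamped profile: strongest inside 420-600
  expect_gt(max(contrast[in_hemo]), max(contrast[w > 620 & w < 900]))
})

test_that("empty and impossible placements behave as specified", {
  g <- desk_grid(20)
  empty <- generate_scene(scene_spec(32, 32, g, n_defects_range = c(0, 0), seed = 1))
  expect_length(empty$truths, 0)
  expect_error(
    generate_scene(scene_spec(32, 32, g, n_defects_range = c(50, 50),
                              defect_size_range = c(12, 16), seed = 1)),
    class = "hsd_placement_error")
})

test_that("default synthetic spectra are nearest-centroid separable above 0.90", {
  g <- desk_grid(60)
  d <- generate_spectrum_dataset(default_profiles(g), 300, g, seed = 17)
  n <- nrow(d$spectra)
  idx <- seq_len(n) %% 5 == 0  # 20% held out
  pred <- nearest_centroid_classify(d$spectra[!idx, ], d$labels[!idx],
                                    d$spectra[idx, ])
  expect_gt(mean(pred == d$labels[idx]), 0.90)
})

test_that("planted profiles carry class signal only inside their windows", {
  g <- desk_grid(60)
  win <- list(c(420, 445), c(565, 590), c(950, 975))
  profs <- planted_profiles(g, windows = win)
  curves <- sapply(profs, profile_reflectance, grid = g)
  spread <- apply(curves, 1, function(r) max(r) - min(r))
  w <- g$wavelengths_nm
  centers <- vapply(win, mean, 0)
  sigmas <- vapply(win, function(x) (x[2] - x[1]) / 2.355, 0)
  outside <- sapply(w, function(x) all(abs(x - centers) > 3.5 * sigmas))
  # classes are identical (zero spread) away from every planted feature
  expect_lt(max(spread[outside]), 1e-3)
  expect_gt(max(spread[!outside]), 0.2)
})
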