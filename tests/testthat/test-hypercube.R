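test_that("ENVI round-trip is an identity for all interleaves", {
  cube <- tiny_cube(h = 4, w = 5, nb = 6, calibrated = FALSE, seed = 2)
  for (il in c("bsq", "bil", "bip")) {
    p <- tempfile(fileext = paste0("_", il))
    write_envi(cube, p, interleave = il)
    back <- read_envi(paste0(p, ".hdr"))
    expect_identical(back$values, cube$values, label = il)
    expect_equal(back$grid$wavelengths_nm, cube$grid$wavelengths_nm)
    expect_false(back$calibrated)
  }
})

test_that("ENVI handles single-band cubes and 360-wavelength headers", {
  one <- hypercube(array(1:12 / 12, dim = c(3, 4, 1)), wavelength_grid(500),
                   calibrated = FALSE)
  p <- tempfile()
  write_envi(one, p)
  expect_equal(read_envi(paste0(p, ".hdr"))$values, one$values)

  big <- hypercube(array(runif(2 * 2 * 360), dim = c(2, 2, 360)), default_grid())
  p2 <- tempfile()
  write_envi(big, p2, interleave = "bil")
  expect_length(read_envi(paste0(p2, ".hdr"))$grid, 360)
})

test_that("ENVI errors name the problem", {
  p <- tempfile()
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 3",
               "data type = 5", "interleave = bsq", "byte order = 0"), paste0(p, ".hdr"))
  writeBin(numeric(12), p)
  expect_error(read_envi(paste0(p, ".hdr")), "wavelength", class = "hsd_format_error")

  cube <- tiny_cube(nb = 3)
  cube$grid <- desk_grid(4)  # silently corrupt: grid/values mismatch
  expect_error(write_envi(cube, tempfile()), class = "hsd_dimension_error")
})

test_that("black/white correction satisfies the calibration identities", {
  d <- c(3, 3, 4)
  B <- array(10, dim = d); W <- array(90, dim = d)
  cal <- calibration_pair(B, W)
  mk <- function(vals) hypercube(array(vals, dim = d), desk_grid(4))
  expect_true(all(correct_reflectance(mk(90), cal)$values == 1))
  expect_true(all(correct_reflectance(mk(10), cal)$values == 0))
  expect_true(all(correct_reflectance(mk(50), cal)$values == 0.5))
  expect_true(correct_reflectance(mk(50), cal)$calibrated)
})

test_that("correction is affine-invariant and reports bad references", {
  set.seed(4)
  d <- c(4, 4, 3)
  I <- array(runif(prod(d), 20, 80), dim = d)
  B <- array(runif(prod(d), 0, 10), dim = d)
  W <- array(runif(prod(d), 90, 110), dim = d)
  r1 <- correct_reflectance(hypercube(I, desk_grid(3)), calibration_pair(B, W))
  r2 <- correct_reflectance(hypercube(3.7 * I, desk_grid(3)),
                            calibration_pair(3.7 * B, 3.7 * W))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)

  expect_error(
    correct_reflectance(hypercube(I, desk_grid(3)), calibration_pair(W, B)),
    "48", class = "hsd_calibration_error")  # all 48 elements invalid
  expect_error(correct_reflectance(r1, calibration_pair(B, W)),
               "already", class = "hsd_argument_error")
})

test_that("nearest_band_index matches exhaustive argmin and breaks ties upward", {
  g <- default_grid()
  expect_identical(nearest_band_index(g, 382.3), 1L)
  # 576 nm: derived by argmin over the enumerated grid (index 109, 576.7 nm)
  expect_identical(nearest_band_index(g, 576), which.min(abs(g$wavelengths_nm - 576)))
  expect_identical(nearest_band_index(g, 576), 109L)
  expect_identical(nearest_band_index(g, 962), which.min(abs(g$wavelengths_nm - 962)))
  set.seed(11)
  targets <- runif(1000, min(g$wavelengths_nm), max(g$wavelengths_nm))
  for (t in targets) {
    d <- abs(g$wavelengths_nm - t)
    expect_identical(nearest_band_index(g, t), max(which(d == min(d))))
  }
  # exact half-spacing tie goes to the higher index (clean integer grid,
  # so the two distances are bit-identical)
  expect_identical(nearest_band_index(wavelength_grid(c(425, 435)), 430), 2L)
  expect_error(nearest_band_index(g, 5000), class = "hsd_range_error")
})

test_that("pseudo-color synthesis maps descending wavelength to R,G,B and scales per channel", {
  d <- c(2, 3, 4)
  vals <- array(0.5, dim = d)
  vals[, , 2] <- matrix(seq(0, 1, length.out = 6), 2, 3)  # gradient band
  cube <- hypercube(vals, desk_grid(4), calibrated = TRUE)
  img <- synthesize_pseudocolor(cube, c(2, 1, 4))
  # band 4 (longest) -> R, band 2 -> G, band 1 (shortest) -> B
  expect_identical(attr(img, "bands"), c(4L, 2L, 1L))
  expect_true(all(img[, , 1] == 0))           # constant channel maps to 0
  expect_identical(range(img[, , 2]), c(0L, 255L))  # gradient spans full range
  # hand-computed min-max bytes for the gradient channel
  expect_identical(img[1, 2, 2], as.integer(floor(0.4 * 255 + 0.5)))
  expect_error(synthesize_pseudocolor(cube, c(1, 1, 2)), class = "hsd_argument_error")
})

test_that("ROI spectra are per-band means with the union-weighting property", {
  cube <- tiny_cube(h = 6, w = 6, nb = 5, seed = 3)
  s11 <- extract_roi_spectrum(cube, bounding_box(2, 3, 3, 4))
  expect_equal(s11$values, cube$values[4, 3, ])  # 1x1 box = that pixel
  # hand summation over a 2x2 region
  s22 <- extract_roi_spectrum(cube, bounding_box(0, 0, 2, 2))
  hand <- sapply(1:5, function(b) sum(cube$values[1:2, 1:2, b]) / 4)
  expect_equal(s22$values, hand)
  # disjoint-union property: weighted mean of two boxes
  a <- bounding_box(0, 0, 2, 3); b <- bounding_box(3, 3, 6, 6)
  u <- (6 * extract_roi_spectrum(cube, a)$values +
        9 * extract_roi_spectrum(cube, b)$values) / 15
  both <- sapply(1:5, function(k)
    (sum(cube$values[1:3, 1:2, k]) + sum(cube$values[4:6, 4:6, k])) / 15)
  expect_equal(u, both)
  expect_error(extract_roi_spectrum(cube, bounding_box(0, 0, 99, 2)),
               class = "hsd_argument_error")
})

test_that("annotation JSON and VOC XML importers agree on conventions", {
  truths <- list(list(box = bounding_box(2, 3, 10, 12), label = "CBC"),
                 list(box = bounding_box(0, 0, 4, 4), label = "CBB"))
  p <- tempfile(fileext = ".json")
  write_annotations(truths, p)
  back <- read_annotations(p)
  expect_equal(back, truths)

  xml <- tempfile(fileext = ".xml")
  writeLines(c("<annotation><object><name>CBC</name><bndbox>",
               "<xmin>3</xmin><ymin>4</ymin><xmax>10</xmax><ymax>12</ymax>",
               "</bndbox></object></annotation>"), xml)
  voc <- read_voc_xml(xml)
  expect_equal(voc[[1]]$box, bounding_box(2, 3, 10, 12))  # 1-based closed -> 0-based half-open
})
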