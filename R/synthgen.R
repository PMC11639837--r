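# Synthetic spectra and annotated scenes. Defect classes are modelled
# as a flat skin-like baseline minus Gaussian absorption features:
# hemoglobin bands in the 420-600 nm window (three sub-features near
# 430, 545 and 576 nm) and a water band near 962 nm. Hemoglobin depth
# decreases CBC > CBBR > CBB (blood content); near-960 nm reflectance
# decreases CBC > CBB > CBBR (the air-dried residue is driest by
# composition but the printed curves order reflectance this way; both
# depths are plain parameters).

#' Class spectral profile
#'
#' @param label class label (`"CBC"`, `"CBB"`, `"CBBR"`, `"background"`,
#'   or any string).
#' @param baseline flat baseline reflectance (fraction).
#' @param features data.frame with columns `center_nm`, `width_nm`,
#'   `depth` describing Gaussian absorption features.
#' @param noise_sd per-band Gaussian noise standard deviation.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(label, baseline, features = NULL, noise_sd = 0.02) {
  if (is.null(features))
    features <- data.frame(center_nm = numeric(0), width_nm = numeric(0), depth = numeric(0))
  stopifnot(all(c("center_nm", "width_nm", "depth") %in% names(features)))
  if (any(features$depth < 0 | features$depth >= 1))
    abort_hsd("feature depths must lie in [0, 1)", "hsd_argument_error")
  if (any(features$width_nm <= 0))
    abort_hsd("feature widths must be positive", "hsd_argument_error")
  # positivity at every wavelength: evaluate the curve on a fine grid
  # (overlapping features stack, so the sum of depths alone is too crude)
  if (nrow(features) > 0) {
    wfine <- seq(min(features$center_nm) - 3 * max(features$width_nm),
                 max(features$center_nm) + 3 * max(features$width_nm), by = 1)
    r <- rep(baseline, length(wfine))
    for (j in seq_len(nrow(features)))
      r <- r - features$depth[j] *
        exp(-(wfine - features$center_nm[j])^2 / (2 * features$width_nm[j]^2))
    if (min(r) <= 0)
      abort_hsd("reflectance must stay positive at every wavelength", "hsd_argument_error")
  }
  structure(list(label = label, baseline = baseline, features = features,
                 noise_sd = noise_sd), class = "class_profile")
}

#' Noiseless reflectance curve of a profile
#'
#' `r(w) = baseline - sum_j depth_j * exp(-(w - center_j)^2 / (2 width_j^2))`.
#'
#' @param profile a [class_profile()].
#' @param grid a [wavelength_grid()].
#' @return numeric vector of reflectance over the grid.
#' @export
profile_reflectance <- function(profile, grid) {
  w <- grid$wavelengths_nm
  r <- rep(profile$baseline, length(w))
  ft <- profile$features
  for (j in seq_len(nrow(ft)))
    r <- r - ft$depth[j] * exp(-(w - ft$center_nm[j])^2 / (2 * ft$width_nm[j]^2))
  r
}

hemo_features <- function(scale) {
  data.frame(center_nm = c(430, 545, 576),
             width_nm = c(18, 16, 14),
             depth = scale * c(0.9, 1.0, 0.95))
}

#' Default class profiles
#'
#' Four profiles: three defect classes sharing Gaussian absorption
#' features near 430/545/576 nm (hemoglobin) and 962 nm (water), and a
#' featureless skin-like background. Hemoglobin depths order
#' CBC > CBBR > CBB; water-band depth orders reflectance
#' CBC > CBB > CBBR near 960 nm.
#'
#' @param grid a [wavelength_grid()] (used only for validation).
#' @param noise_sd per-band noise level for all classes.
#' @return named list of [class_profile()] objects
#'   (`CBC`, `CBB`, `CBBR`, `background`).
#' @export
default_profiles <- function(grid = desk_grid(), noise_sd = 0.02) {
  water <- function(depth) data.frame(center_nm = 962, width_nm = 14, depth = depth)
  mk <- function(label, hemo_scale, water_depth)
    class_profile(label, baseline = 0.60,
                  features = rbind(hemo_features(hemo_scale), water(water_depth)),
                  noise_sd = noise_sd)
  profs <- list(
    CBC  = mk("CBC",  0.28, 0.05),
    CBB  = mk("CBB",  0.12, 0.09),
    CBBR = mk("CBBR", 0.20, 0.13),
    background = class_profile("background", baseline = 0.78, noise_sd = noise_sd))
  for (p in profs) stopifnot(all(profile_reflectance(p, grid) > 0))
  profs
}

#' Planted-band profiles for band-selection experiments
#'
#' Classes are identical everywhere except inside the given wavelength
#' windows, so class information exists only in the planted bands.
#' Used to test that band selection recovers informative windows.
#'
#' @param grid a [wavelength_grid()].
#' @param windows list of `c(lo_nm, hi_nm)` windows (default: the
#'   hemoglobin 420-445 and 565-590 nm windows and the 950-975 nm water
#'   window).
#' @param noise_sd per-band noise level.
#' @return named list of three [class_profile()] objects.
#' @export
planted_profiles <- function(grid = desk_grid(),
                             windows = list(c(420, 445), c(565, 590), c(950, 975)),
                             noise_sd = 0.02) {
  centers <- vapply(windows, mean, 0)
  # Gaussian sigma such that the feature's FWHM spans the window
  widths <- vapply(windows, function(w) (w[2] - w[1]) / 2.355, 0)
  mk <- function(label, depths)
    class_profile(label, baseline = 0.60,
                  features = data.frame(center_nm = centers, width_nm = widths,
                                        depth = depths),
                  noise_sd = noise_sd)
  # each window separates exactly one class (the other two share its
  # depth), so any single window caps accuracy near 2/3 and a high
  # score requires covering at least two windows
  list(CBC = mk("CBC", c(0.30, 0.30, 0.05)),
       CBB = mk("CBB", c(0.30, 0.05, 0.30)),
       CBBR = mk("CBBR", c(0.05, 0.30, 0.30)))
}

#' Profiles whose classes differ only spectrally
#'
#' All defect classes share an identical "visibility" absorption
#' feature at `visible_nm` (so they render identically in pseudo-color
#' images built from bands near it) and differ only inside
#' class-specific windows far from `visible_nm`. Used for the fusion
#' ablation: a 2-D-only model cannot tell the classes apart, a
#' spectral-fusion model can.
#'
#' @param grid a [wavelength_grid()].
#' @param visible_nm wavelength of the shared (class-independent)
#'   feature.
#' @param noise_sd per-band noise level.
#' @return named list of four [class_profile()] objects including
#'   `background`.
#' @export
spectral_twin_profiles <- function(grid = desk_grid(), visible_nm = 700,
                                   noise_sd = 0.02) {
  shared <- data.frame(center_nm = visible_nm, width_nm = 40, depth = 0.30)
  own <- function(center) data.frame(center_nm = center, width_nm = 15, depth = 0.25)
  mk <- function(label, center)
    class_profile(label, baseline = 0.70, features = rbind(shared, own(center)),
                  noise_sd = noise_sd)
  list(CBC = mk("CBC", 430), CBB = mk("CBB", 545), CBBR = mk("CBBR", 962),
       background = class_profile("background", baseline = 0.70, noise_sd = noise_sd))
}

new_spectrum <- function(values, grid, label = NULL) {
  if (length(values) != length(grid))
    abort_hsd("spectrum length must equal grid length", "hsd_dimension_error")
  structure(list(values = as.numeric(values), grid = grid, label = label),
            class = "spectrum")
}

#' Sample one noisy spectrum from a profile
#'
#' Noiseless curve plus i.i.d. Gaussian noise of the profile's
#' `noise_sd`, clipped to `[0, 1]`; deterministic given `seed`.
#'
#' @param profile a [class_profile()].
#' @param grid a [wavelength_grid()].
#' @param seed integer seed.
#' @return a `spectrum` object.
#' @export
sample_spectrum <- function(profile, grid, seed = 1) {
  base <- profile_reflectance(profile, grid)
  v <- with_seed(seed, base + rnorm(length(base), sd = profile$noise_sd))
  v[v < 0] <- 0; v[v > 1] <- 1
  new_spectrum(v, grid, label = profile$label)
}

#' Generate a balanced labeled spectrum dataset
#'
#' `n_per_class` noisy draws per profile, deterministically shuffled.
#'
#' @param profiles named list of [class_profile()] objects (any
#'   `background` entry is excluded).
#' @param n_per_class draws per class (>= 1).
#' @param grid a [wavelength_grid()].
#' @param seed integer seed.
#' @return list with `spectra` (matrix, rows = samples, columns =
#'   bands), `labels` (character), and `grid`.
#' @export
generate_spectrum_dataset <- function(profiles, n_per_class, grid = desk_grid(),
                                      seed = 1) {
  stopifnot(n_per_class >= 1)
  profiles <- profiles[setdiff(names(profiles), "background")]
  with_seed(seed, {
    xs <- list(); labs <- character(0)
    for (p in profiles) {
      base <- profile_reflectance(p, grid)
      noise <- matrix(rnorm(n_per_class * length(base), sd = p$noise_sd),
                      nrow = n_per_class)
      m <- sweep(noise, 2, base, `+`)
      m[m < 0] <- 0; m[m > 1] <- 1
      xs[[length(xs) + 1]] <- m
      labs <- c(labs, rep(p$label, n_per_class))
    }
    x <- do.call(rbind, xs)
    ord <- sample.int(nrow(x))
    list(spectra = x[ord, , drop = FALSE], labels = labs[ord], grid = grid)
  })
}

#' Write / read a spectrum dataset as CSV
#'
#' One row per spectrum: `label` then one column per band (named by
#' wavelength).
#'
#' @param dataset as returned by [generate_spectrum_dataset()].
#' @param path CSV file path.
#' @export
write_spectrum_csv <- function(dataset, path) {
  df <- data.frame(label = dataset$labels, dataset$spectra, check.names = FALSE)
  names(df) <- c("label", sprintf("%.3f", dataset$grid$wavelengths_nm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-1])
  list(spectra = as.matrix(df[, -1, drop = FALSE]), labels = as.character(df$label),
       grid = wavelength_grid(wl))
}

#' Scene specification
#'
#' @param height,width scene size in pixels.
#' @param grid a [wavelength_grid()].
#' @param n_defects_range integer range `c(min, max)` of defects per
#'   scene.
#' @param defect_size_range range `c(min, max)` of defect bounding-box
#'   side length in pixels.
#' @param class_mix named numeric vector of class proportions (must sum
#'   to 1).
#' @param seed integer seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64, width = 64, grid = desk_grid(),
                       n_defects_range = c(1, 3), defect_size_range = c(10, 18),
                       class_mix = c(CBC = 1/3, CBB = 1/3, CBBR = 1/3),
                       seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    abort_hsd("class mix proportions must sum to 1", "hsd_argument_error")
  structure(list(height = height, width = width, grid = grid,
                 n_defects_range = n_defects_range,
                 defect_size_range = defect_size_range,
                 class_mix = class_mix, seed = seed),
            class = "scene_spec")
}

#' Generate an annotated synthetic scene
#'
#' Fills the cube with the background profile, then stamps each defect
#' as an axis-aligned ellipse (inscribed in its annotation box) of its
#' class profile. Boxes never overlap; placement failures after bounded
#' retries raise an error. Fully deterministic given the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @param profiles named list of [class_profile()] objects including
#'   `background`.
#' @return list of class `annotated_scene` with `cube` (calibrated
#'   [hypercube()]) and `truths` (list of `list(box, label)`).
#' @export
generate_scene <- function(spec, profiles = default_profiles(spec$grid)) {
  stopifnot(inherits(spec, "scene_spec"), "background" %in% names(profiles))
  h <- spec$height; w <- spec$width; nb <- length(spec$grid)
  with_seed(spec$seed, {
    bg <- profiles$background
    base <- profile_reflectance(bg, spec$grid)
    vals <- array(rnorm(h * w * nb, sd = bg$noise_sd), dim = c(h, w, nb))
    vals <- sweep(vals, 3, base, `+`)
    n_def <- if (spec$n_defects_range[1] == spec$n_defects_range[2]) spec$n_defects_range[1]
             else sample(spec$n_defects_range[1]:spec$n_defects_range[2], 1)
    truths <- list()
    boxes <- list()
    classes <- setdiff(names(profiles), "background")
    mix <- spec$class_mix[classes]
    for (i in seq_len(n_def)) {
      placed <- FALSE
      for (try in 1:200) {
        bw <- sample(spec$defect_size_range[1]:spec$defect_size_range[2], 1)
        bh <- sample(spec$defect_size_range[1]:spec$defect_size_range[2], 1)
        if (bw > w || bh > h) next
        x0 <- sample(0:(w - bw), 1); y0 <- sample(0:(h - bh), 1)
        cand <- bounding_box(x0, y0, x0 + bw, y0 + bh)
        overlap <- any(vapply(boxes, function(b) iou(b, cand) > 0 ||
          (min(b$x1, cand$x1) > max(b$x0, cand$x0) &&
           min(b$y1, cand$y1) > max(b$y0, cand$y0)), TRUE))
        if (!overlap) {
          cl <- sample(classes, 1, prob = mix)
          prof <- profiles[[cl]]
          curve <- profile_reflectance(prof, spec$grid)
          # ellipse inscribed in the box
          cx <- x0 + bw / 2; cy <- y0 + bh / 2
          rows <- (y0 + 1):(y0 + bh); cols <- (x0 + 1):(x0 + bw)
          rr <- outer(rows - 0.5 - cy, rep(1, bw)) / (bh / 2)
          cc <- outer(rep(1, bh), cols - 0.5 - cx) / (bw / 2)
          mask <- rr^2 + cc^2 <= 1
          for (b in seq_len(nb)) {
            plane <- vals[rows, cols, b]
            noise <- matrix(rnorm(bh * bw, sd = prof$noise_sd), bh, bw)
            plane[mask] <- curve[b] + noise[mask]
            vals[rows, cols, b] <- plane
          }
          boxes[[length(boxes) + 1]] <- cand
          truths[[length(truths) + 1]] <- list(box = cand, label = cl)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort_hsd(sprintf("could not place defect %d of %d without overlap", i, n_def),
                  "hsd_placement_error")
    }
    vals[vals < 0] <- 0; vals[vals > 1] <- 1
    structure(list(cube = hypercube(vals, spec$grid, calibrated = TRUE),
                   truths = truths, spec = spec),
              class = "annotated_scene")
  })
}

#' Nearest-centroid spectrum classifier
#'
#' A deliberately simple oracle classifier: class centroids on training
#' spectra, prediction by minimum Euclidean distance. Used to certify
#' that synthetic datasets are separable enough for learning tasks to
#' be well-posed.
#'
#' @param train_x,train_y training spectra matrix and labels.
#' @param test_x spectra to classify.
#' @return character vector of predicted labels.
#' @export
nearest_centroid_classify <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  cent <- t(vapply(classes, function(cl) colMeans(train_x[train_y == cl, , drop = FALSE]),
                   numeric(ncol(train_x))))
  d <- outer(rowSums(test_x^2), rep(1, nrow(cent))) -
    2 * test_x %*% t(cent) + outer(rep(1, nrow(test_x)), rowSums(cent^2))
  classes[max.col(-d)]
}
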