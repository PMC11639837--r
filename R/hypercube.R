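#' Hyperspectral cube
#'
#' A 3-D reflectance (or raw intensity) array indexed `(row, col, band)`
#' together with its [wavelength_grid()]. After black/white calibration
#' (`calibrated = TRUE`) values are dimensionless reflectance fractions
#' clipped to `[0, 1]`.
#'
#' @param values numeric 3-D array `(rows, cols, bands)`.
#' @param grid a [wavelength_grid()]; its length must equal `dim(values)[3]`.
#' @param calibrated logical; `TRUE` once black/white correction has been
#'   applied.
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(values, grid, calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3)
    abort_hsd("values must be a 3-D array (rows, cols, bands)", "hsd_argument_error")
  stopifnot(inherits(grid, "wavelength_grid"))
  if (dim(values)[3] != length(grid))
    abort_hsd(sprintf("band dimension (%d) does not match grid length (%d)",
                      dim(values)[3], length(grid)), "hsd_dimension_error")
  if (calibrated) {
    if (!all(is.finite(values)))
      abort_hsd("calibrated cube must be finite", "hsd_argument_error")
    values[values < 0] <- 0
    values[values > 1] <- 1
  }
  structure(list(values = values, grid = grid, calibrated = calibrated),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands, %s\n",
              d[1], d[2], d[3], if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Axis-aligned bounding box (0-based, half-open)
#'
#' Boxes use 0-based half-open pixel coordinates: the box covers columns
#' `[x0, x1)` and rows `[y0, y1)`, so its pixel area is
#' `(x1 - x0) * (y1 - y0)`. Annotation importers convert other
#' conventions at the boundary.
#'
#' @param x0,y0,x1,y1 pixel coordinates with `x1 > x0`, `y1 > y0`.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  if (!(x1 > x0 && y1 > y0))
    abort_hsd("degenerate box: require x1 > x0 and y1 > y0", "hsd_argument_error")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bounding_box")
}

box_in_bounds <- function(box, n_rows, n_cols) {
  box$x0 >= 0 && box$y0 >= 0 && box$x1 <= n_cols && box$y1 <= n_rows
}

#' Black/white reflectance calibration
#'
#' Converts raw intensity `I` to relative reflectance
#' `R = (I - B) / (W - B)` per element, where `B` is the dark (shutter
#' closed) reference and `W` the white reference. The conventional
#' "x100%" is display formatting only: values are stored as fractions
#' and clipped to `[0, 1]` (specular outliers clip rather than error).
#'
#' @param raw an uncalibrated [hypercube()] of raw intensities.
#' @param cal a [calibration_pair()].
#' @return a calibrated [hypercube()].
#' @export
correct_reflectance <- function(raw, cal) {
  stopifnot(inherits(raw, "hypercube"), inherits(cal, "calibration_pair"))
  if (raw$calibrated)
    abort_hsd("cube is already calibrated", "hsd_argument_error")
  d <- dim(raw$values)
  B <- broadcast_ref(cal$black, d)
  W <- broadcast_ref(cal$white, d)
  denom <- W - B
  n_bad <- sum(denom <= 0)
  if (n_bad > 0)
    abort_hsd(sprintf("white - black <= 0 at %d element(s)", n_bad),
              "hsd_calibration_error")
  hypercube((raw$values - B) / denom, raw$grid, calibrated = TRUE)
}

#' Calibration reference pair
#'
#' @param black,white raw reference arrays: either full cube-shaped 3-D
#'   arrays or per-band vectors (broadcast over pixels).
#' @return an object of class `calibration_pair`.
#' @export
calibration_pair <- function(black, white) {
  structure(list(black = black, white = white), class = "calibration_pair")
}

broadcast_ref <- function(ref, d) {
  if (is.array(ref) && length(dim(ref)) == 3) {
    if (!all(dim(ref) == d))
      abort_hsd("calibration reference shape does not match cube", "hsd_dimension_error")
    return(ref)
  }
  if (is.numeric(ref) && length(ref) == d[3])  # per-band reference
    return(aperm(array(rep(ref, each = d[1] * d[2]), dim = d), c(1, 2, 3)))
  if (is.numeric(ref) && length(ref) == 1)
    return(array(ref, dim = d))
  abort_hsd("calibration reference must be a cube-shaped array, a per-band vector, or a scalar",
            "hsd_dimension_error")
}

#' Mean spectrum over a rectangular region
#'
#' Per-band arithmetic mean of reflectance over all pixels of the
#' half-open box.
#'
#' @param cube a calibrated [hypercube()].
#' @param box a [bounding_box()] within image bounds.
#' @return a `spectrum` object (see [sample_spectrum()]).
#' @export
extract_roi_spectrum <- function(cube, box) {
  stopifnot(inherits(cube, "hypercube"), inherits(box, "bounding_box"))
  if (!cube$calibrated)
    abort_hsd("cube must be calibrated before spectra are extracted", "hsd_argument_error")
  d <- dim(cube$values)
  if (!box_in_bounds(box, d[1], d[2]))
    abort_hsd("box outside image bounds", "hsd_argument_error")
  rows <- (box$y0 + 1):box$y1
  cols <- (box$x0 + 1):box$x1
  sub <- cube$values[rows, cols, , drop = FALSE]
  new_spectrum(apply(sub, 3, mean), cube$grid)
}

#' Pseudo-color synthesis from three bands
#'
#' Builds an 8-bit RGB composite from three distinct bands. Channels are
#' assigned by descending wavelength: the longest-wavelength band maps
#' to red, the middle to green, the shortest to blue. Each channel is
#' independently min-max scaled to `[0, 255]` over the whole image; a
#' zero-range channel maps to 0.
#'
#' @param cube a calibrated [hypercube()].
#' @param bands integer vector of three distinct 1-based band indices.
#' @return integer array `(rows, cols, 3)` with values in `0:255`,
#'   channel order R, G, B; attribute `bands` stores the band index used
#'   per channel.
#' @export
synthesize_pseudocolor <- function(cube, bands) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated)
    abort_hsd("cube must be calibrated", "hsd_argument_error")
  bands <- as.integer(bands)
  if (length(bands) != 3 || anyDuplicated(bands))
    abort_hsd("exactly three distinct band indices are required", "hsd_argument_error")
  if (any(bands < 1 | bands > length(cube$grid)))
    abort_hsd("band index out of range", "hsd_argument_error")
  w <- cube$grid$wavelengths_nm[bands]
  ord <- bands[order(w, decreasing = TRUE)]  # R = longest wavelength
  d <- dim(cube$values)
  out <- array(0L, dim = c(d[1], d[2], 3))
  for (ch in 1:3) {
    plane <- cube$values[, , ord[ch]]
    rng <- range(plane)
    if (rng[2] > rng[1])
      out[, , ch] <- as.integer(floor((plane - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5))
  }
  attr(out, "bands") <- ord
  out
}

#' Write a pseudo-color composite to PNG
#'
#' @param img integer array from [synthesize_pseudocolor()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pseudocolor_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}
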