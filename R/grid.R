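#' Wavelength grid
#'
#' A strictly increasing vector of band-center wavelengths in nanometres.
#' The faithful default mirrors a visible/NIR line-scan instrument: 360
#' bands from 382.3 nm at 1.8 nm spacing (up to 1028.5 nm). A coarser
#' 60-band "desk" grid spanning the same range is provided for fast
#' experimentation and testing.
#'
#' @param wavelengths_nm numeric vector of band centers (nm), strictly
#'   increasing.
#' @return an object of class `wavelength_grid`.
#' @export
#' @examples
#' g <- default_grid()
#' length(g$wavelengths_nm)
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 1 || anyNA(w))
    abort_hsd("wavelength grid must be a non-empty numeric vector", "hsd_argument_error")
  if (length(w) > 1 && any(diff(w) <= 0))
    abort_hsd("wavelength grid must be strictly increasing", "hsd_argument_error")
  structure(list(wavelengths_nm = w), class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @export
default_grid <- function() wavelength_grid(382.3 + 1.8 * (0:359))

#' @rdname wavelength_grid
#' @param n_bands number of bands for the desk-scale grid.
#' @export
desk_grid <- function(n_bands = 60) {
  span <- 382.3 + 1.8 * 359 - 382.3
  wavelength_grid(382.3 + span * (0:(n_bands - 1)) / (n_bands - 1))
}

#' @export
length.wavelength_grid <- function(x) length(x$wavelengths_nm)

#' @export
print.wavelength_grid <- function(x, ...) {
  w <- x$wavelengths_nm
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n", length(w), min(w), max(w)))
  invisible(x)
}

#' Nearest band index for a target wavelength
#'
#' Returns the 1-based index of the grid band whose center is closest to
#' `target_nm`. Exact half-spacing ties break toward the higher index,
#' so the result is deterministic.
#'
#' @param grid a [wavelength_grid()].
#' @param target_nm target wavelength in nm; must lie within the grid
#'   span extended by half the local spacing at each end.
#' @return integer band index (1-based).
#' @export
#' @examples
#' nearest_band_index(default_grid(), 576)  # 109 (0-based 108)
nearest_band_index <- function(grid, target_nm) {
  stopifnot(inherits(grid, "wavelength_grid"))
  w <- grid$wavelengths_nm
  half_lo <- if (length(w) > 1) (w[2] - w[1]) / 2 else 1
  half_hi <- if (length(w) > 1) (w[length(w)] - w[length(w) - 1]) / 2 else 1
  if (target_nm < w[1] - half_lo || target_nm > w[length(w)] + half_hi)
    abort_hsd(sprintf("target %.1f nm outside grid span [%.1f, %.1f]",
                      target_nm, w[1], w[length(w)]), "hsd_range_error")
  d <- abs(w - target_nm)
  # ties (exact half-spacing) break to the higher index
  max(which(d == min(d)))
}
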