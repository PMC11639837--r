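# ENVI-style cube I/O: a plain-text key-value header (.hdr) plus a flat
# little-endian binary file. All three interleaves (BSQ, BIL, BIP) are
# supported; data types 4 (float32) and 5 (float64) are written/read,
# plus 1/2/12 integers on read.

envi_type_size <- c("1" = 1L, "2" = 2L, "4" = 4L, "5" = 8L, "12" = 2L)

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*ENVI\\s*$", lines[1]))
    abort_hsd("not an ENVI header (missing leading 'ENVI' line)", "hsd_format_error")
  keys <- list()
  i <- 2
  while (i <= length(lines)) {
    line <- lines[i]
    i <- i + 1
    if (!grepl("=", line, fixed = TRUE)) next
    eq <- regexpr("=", line, fixed = TRUE)
    key <- tolower(trimws(substr(line, 1, eq - 1)))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    # a braced value may span multiple lines
    while (startsWith(val, "{") && !grepl("}", val, fixed = TRUE) && i <= length(lines)) {
      val <- paste(val, trimws(lines[i]))
      i <- i + 1
    }
    if (nzchar(key)) keys[[key]] <- val
  }
  keys
}

envi_num <- function(keys, name) {
  v <- keys[[name]]
  if (is.null(v)) abort_hsd(sprintf("ENVI header missing field '%s'", name), "hsd_format_error")
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) abort_hsd(sprintf("ENVI header field '%s' is not numeric: %s", name, v), "hsd_format_error")
  n
}

envi_vec <- function(keys, name) {
  v <- keys[[name]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(strsplit(v, ",")[[1]])
}

#' Read an ENVI-style hyperspectral cube
#'
#' Parses the text header (dimensions, interleave, data type, byte
#' order, wavelengths) and maps the binary file into a `(row, col,
#' band)` [hypercube()].
#'
#' @param header_path path to the `.hdr` header; the binary file is the
#'   same path without the `.hdr` extension (or with `.dat`).
#' @return a [hypercube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path))
    abort_hsd(sprintf("header not found: %s", header_path), "hsd_io_error")
  keys <- parse_envi_header(header_path)
  samples <- as.integer(envi_num(keys, "samples"))
  lines_n <- as.integer(envi_num(keys, "lines"))
  bands <- as.integer(envi_num(keys, "bands"))
  dtype <- as.character(as.integer(envi_num(keys, "data type")))
  interleave <- tolower(keys[["interleave"]] %||% "bsq")
  if (!interleave %in% c("bsq", "bil", "bip"))
    abort_hsd(sprintf("ENVI header field 'interleave' invalid: %s", interleave), "hsd_format_error")
  byte_order <- as.integer(keys[["byte order"]] %||% "0")
  endian <- if (byte_order == 0) "little" else "big"
  wl <- envi_vec(keys, "wavelength")
  if (is.null(wl))
    abort_hsd("ENVI header missing field 'wavelength'", "hsd_format_error")
  if (length(wl) != bands)
    abort_hsd(sprintf("wavelength count (%d) does not match bands (%d)",
                      length(wl), bands), "hsd_dimension_error")
  if (!dtype %in% names(envi_type_size))
    abort_hsd(sprintf("unsupported ENVI data type %s", dtype), "hsd_format_error")

  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) bin_path <- paste0(bin_path, ".dat")
  if (!file.exists(bin_path))
    abort_hsd(sprintf("binary cube for %s not found", header_path), "hsd_io_error")
  n <- samples * lines_n * bands
  what <- if (dtype %in% c("4", "5")) "double" else "integer"
  size <- envi_type_size[[dtype]]
  signed <- dtype != "12"
  v <- readBin(bin_path, what = what, n = n, size = size, endian = endian, signed = signed)
  if (length(v) != n)
    abort_hsd(sprintf("binary file has %d values, expected %d", length(v), n), "hsd_format_error")
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(bands, samples, lines_n)), c(3, 2, 1)))
  calibrated <- identical(trimws(keys[["calibrated"]] %||% "0"), "1")
  hypercube(arr, wavelength_grid(wl), calibrated = calibrated)
}

#' Write a hypercube in ENVI format
#'
#' Writes `<path>.hdr` (text header) and `<path>` (flat little-endian
#' binary). Doubles are stored losslessly (data type 5) by default, so
#' `read_envi(write_envi(cube))` is an exact identity.
#'
#' @param cube a [hypercube()].
#' @param path output path for the binary file (header gets `.hdr`).
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 5 (float64, default) or 4
#'   (float32).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  if (d[3] != length(cube$grid))
    abort_hsd("grid/values band mismatch", "hsd_dimension_error")
  hdr_path <- paste0(path, ".hdr")
  wl <- paste(format(cube$grid$wavelengths_nm, trim = TRUE, scientific = FALSE),
              collapse = ", ")
  hdr <- c(
    "ENVI",
    "description = { hsdefect export }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("calibrated = %d", as.integer(cube$calibrated)),
    sprintf("wavelength = { %s }", wl))
  ok <- tryCatch({ writeLines(hdr, hdr_path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) abort_hsd(sprintf("cannot write header %s", hdr_path), "hsd_io_error")
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1))))
  size <- if (data_type == 5) 8L else 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = size, endian = "little")
  invisible(path)
}
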