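# Bounding-box annotation I/O. The native format is a JSON array of
# records {label, x0, y0, x1, y1} in 0-based half-open pixel
# coordinates. A Pascal-VOC XML importer converts that format's 1-based
# closed-interval convention at the boundary.

#' Read / write JSON box annotations
#'
#' @param path file path.
#' @return `read_annotations()` returns a list of `list(box, label)`
#'   records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    abort_hsd(sprintf("annotation file not found: %s", path), "hsd_io_error")
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    list(box = bounding_box(r$x0, r$y0, r$x1, r$y1), label = r$label)
  })
}

#' @rdname read_annotations
#' @param truths list of `list(box, label)` records.
#' @export
write_annotations <- function(truths, path) {
  recs <- lapply(truths, function(t) {
    list(label = t$label, x0 = t$box$x0, y0 = t$box$y0,
         x1 = t$box$x1, y1 = t$box$y1)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import Pascal-VOC XML annotations
#'
#' VOC boxes are 1-based with inclusive max coordinates; they are
#' converted to the package's 0-based half-open convention
#' (`x0 = xmin - 1`, `x1 = xmax`).
#'
#' @param path path to a VOC `.xml` annotation file.
#' @return list of `list(box, label)` records.
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  lapply(objs, function(o) {
    lab <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    num <- function(q) as.numeric(xml2::xml_text(xml2::xml_find_first(o, q)))
    list(box = bounding_box(num("./bndbox/xmin") - 1, num("./bndbox/ymin") - 1,
                            num("./bndbox/xmax"), num("./bndbox/ymax")),
         label = lab)
  })
}

#' Read / write detection records
#'
#' Detections are JSON records `{label, confidence, x0, y0, x1, y1,
#' probabilities?}`.
#'
#' @param path file path.
#' @export
read_detections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    det <- list(box = bounding_box(r$x0, r$y0, r$x1, r$y1),
                label = r$label, confidence = r$confidence)
    if (!is.null(r$probabilities)) det$probabilities <- unlist(r$probabilities)
    det
  })
}

#' @rdname read_detections
#' @param detections list of detection records.
#' @export
write_detections <- function(detections, path) {
  recs <- lapply(detections, function(d) {
    r <- list(label = d$label, confidence = d$confidence,
              x0 = d$box$x0, y0 = d$box$y0, x1 = d$box$x1, y1 = d$box$y1)
    if (!is.null(d$probabilities)) r$probabilities <- as.list(d$probabilities)
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
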