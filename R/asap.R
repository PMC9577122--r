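# ASAP-dialect annotation XML: Annotations/Annotation/Coordinates/Coordinate
# elements with X/Y attributes; the class is the Annotation's PartOfGroup.
# Polygons are reduced to 0-based half-open bounding boxes with a
# floor(min)/ceiling(max) rounding convention on the corner extremes.

#' Read ASAP-dialect region annotations
#'
#' @param xml_path Path to the annotation XML.
#' @return data.frame with `class`, `x0`, `y0`, `x1`, `y1` (0-based,
#'   half-open boxes).  Annotations whose group is not one of the four
#'   classes are skipped with a warning.  Malformed XML raises a parse
#'   error (with line information from the XML parser).
#' @export
read_asap_annotations <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  rows <- list()
  for (a in anns) {
    grp <- xml2::xml_attr(a, "PartOfGroup")
    if (is.na(grp) || !(grp %in% wsi_classes())) {
      warning(sprintf("skipping annotation with unknown group '%s'", grp))
      next
    }
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    if (length(coords) == 0) next
    xs <- as.numeric(xml2::xml_attr(coords, "X"))
    ys <- as.numeric(xml2::xml_attr(coords, "Y"))
    assert_that(!anyNA(xs) && !anyNA(ys), "coordinate with missing X/Y attribute")
    rows[[length(rows) + 1L]] <- data.frame(
      class = grp,
      x0 = as.integer(floor(min(xs))), y0 = as.integer(floor(min(ys))),
      x1 = as.integer(ceiling(max(xs))), y1 = as.integer(ceiling(max(ys))),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(class = character(0), x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write region boxes as ASAP-dialect annotation XML
#'
#' Each box becomes a 4-corner polygon annotation whose corners are the
#' half-open box extremes, so a write/read round trip reproduces the boxes
#' exactly.
#'
#' @param regions data.frame with `class`, `x0`, `y0`, `x1`, `y1`.
#' @param xml_path Output path.
#' @return `xml_path`, invisibly.
#' @export
write_asap_annotations <- function(regions, xml_path) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1L),
                             Type = "Polygon", PartOfGroup = r$class,
                             Color = "#F4FA58")
    cs <- xml2::xml_add_child(a, "Coordinates")
    corners <- list(c(r$x0, r$y0), c(r$x1, r$y0), c(r$x1, r$y1), c(r$x0, r$y1))
    for (k in seq_along(corners))
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(k - 1L),
                          X = format(corners[[k]][1]), Y = format(corners[[k]][2]))
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (cl in unique(regions$class))
    xml2::xml_add_child(groups, "Group", Name = cl, PartOfGroup = "None",
                        Color = "#F4FA58")
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}
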