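#' Construct an annotation set
#'
#' An annotation set carries the labeled polygons of one slide in full-
#' resolution pixel coordinates, plus the slide dimensions and an
#' optional slide-level diagnostic label.
#'
#' @param slide_id Character scalar.
#' @param width,height Slide dimensions in pixels.
#' @param polygons List of polygons, each a list with elements `label`
#'   (one of [label_classes()]), `vertices` (an `n x 2` numeric matrix of
#'   `(x, y)` vertices, `n >= 3`, implicitly closed) and optionally
#'   `tissue` (free-text tissue attribute; `"tumour"` and `"muscle"` are
#'   the two values with meaning to [junction_points()]).
#' @param wsi_label Optional slide-level category, one of
#'   [diagnostic_classes()].
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(slide_id, width, height, polygons = list(),
                           wsi_label = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1,
            length(width) == 1, length(height) == 1,
            width >= 1, height >= 1)
  if (!is.null(wsi_label)) check_label(wsi_label, diagnostic_only = TRUE)
  polygons <- lapply(polygons, function(p) {
    check_label(p$label)
    v <- p$vertices
    if (is.data.frame(v)) v <- as.matrix(v)
    storage.mode(v) <- "double"
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3) {
      stop("polygon vertices must be an n x 2 matrix with n >= 3",
           call. = FALSE)
    }
    if (!all(is.finite(v)) || any(v < 0)) {
      stop("polygon coordinates must be finite and non-negative",
           call. = FALSE)
    }
    if (any(v[, 1] >= width) || any(v[, 2] >= height)) {
      stop("polygon vertices must lie within [0, width) x [0, height)",
           call. = FALSE)
    }
    if (polygon_area(v) <= 0) {
      stop("polygon has zero enclosed area", call. = FALSE)
    }
    dimnames(v) <- NULL
    list(label = p$label, tissue = p$tissue, vertices = v)
  })
  structure(
    list(slide_id = slide_id, width = as.numeric(width),
         height = as.numeric(height), polygons = polygons,
         wsi_label = wsi_label),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> slide '%s' (%d x %d), %d polygon(s)%s\n",
              x$slide_id, as.integer(x$width), as.integer(x$height),
              length(x$polygons),
              if (is.null(x$wsi_label)) "" else
                paste0(", slide label ", x$wsi_label)))
  invisible(x)
}

#' Write polygon annotations to an ASAP-style XML file
#'
#' The dialect is frozen: a UTF-8 `<Annotations>` root with `slide_id`,
#' `width`, `height` and optional `wsi_label` attributes; one
#' `<Annotation>` element per polygon with a `label` attribute (and
#' optional `tissue` attribute); `<Coordinate>` children with 0-based
#' `order` plus `x`/`y` attributes printed with 17 significant digits so
#' doubles round-trip exactly. Output bytes are deterministic for
#' identical input.
#'
#' @param ann An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<Annotations slide_id=\"%s\" width=\"%s\" height=\"%s\"%s>",
            ann$slide_id, fmt(ann$width), fmt(ann$height),
            if (is.null(ann$wsi_label)) "" else
              sprintf(" wsi_label=\"%s\"", ann$wsi_label))
  )
  for (p in ann$polygons) {
    lines <- c(lines, sprintf("  <Annotation label=\"%s\"%s>", p$label,
                              if (is.null(p$tissue)) "" else
                                sprintf(" tissue=\"%s\"", p$tissue)))
    n <- nrow(p$vertices)
    lines <- c(lines, sprintf(
      "    <Coordinate order=\"%d\" x=\"%s\" y=\"%s\"/>",
      seq_len(n) - 1L, fmt(p$vertices[, 1]), fmt(p$vertices[, 2])))
    lines <- c(lines, "  </Annotation>")
  }
  lines <- c(lines, "</Annotations>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read polygon annotations from an ASAP-style XML file
#'
#' Inverse of [write_annotations()]. Malformed XML raises a parse error
#' naming the offending line; a label outside the six-class vocabulary
#' raises a vocabulary error.
#'
#' @param path Path to an annotation XML file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "Annotations") {
    stop("expected <Annotations> root, found <", root, ">", call. = FALSE)
  }
  attr_or <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  polys <- lapply(xml2::xml_find_all(doc, "./Annotation"), function(node) {
    label <- xml2::xml_attr(node, "label")
    check_label(label)
    coords <- xml2::xml_find_all(node, "./Coordinate")
    ord <- as.integer(xml2::xml_attr(coords, "order"))
    v <- cbind(as.numeric(xml2::xml_attr(coords, "x")),
               as.numeric(xml2::xml_attr(coords, "y")))[order(ord), ,
                                                        drop = FALSE]
    list(label = label, tissue = attr_or(node, "tissue"), vertices = v)
  })
  annotation_set(
    slide_id = xml2::xml_attr(doc, "slide_id"),
    width = as.numeric(xml2::xml_attr(doc, "width")),
    height = as.numeric(xml2::xml_attr(doc, "height")),
    polygons = polys,
    wsi_label = attr_or(doc, "wsi_label")
  )
}

#' Rasterize annotations to a label mask
#'
#' Each cell of the downscaled raster takes the channel index of the
#' polygon covering its center, with polygons applied in file order
#' (later polygons overwrite earlier ones). Uncovered cells hold -1.
#' Cell `(r, c)` (1-based) covers the half-open full-resolution square
#' `[(c-1) d, c d) x [(r-1) d, r d)` and its center is
#' `((c - 0.5) d, (r - 0.5) d)`.
#'
#' @param ann An [annotation_set()].
#' @param downscale Positive integer downscale factor.
#' @return An integer matrix of dimension
#'   `ceiling(height / downscale) x ceiling(width / downscale)` with
#'   values in `-1, 0..5`.
#' @export
rasterize_labels <- function(ann, downscale = 1) {
  stopifnot(inherits(ann, "annotation_set"))
  if (length(downscale) != 1 || !is.finite(downscale) || downscale < 1 ||
      downscale != round(downscale)) {
    stop("downscale must be a positive integer", call. = FALSE)
  }
  nr <- as.integer(ceiling(ann$height / downscale))
  nc <- as.integer(ceiling(ann$width / downscale))
  mask <- matrix(-1L, nr, nc)
  if (length(ann$polygons) == 0) return(mask)
  cx <- (seq_len(nc) - 0.5) * downscale
  cy <- (seq_len(nr) - 0.5) * downscale
  gx <- rep(cx, each = nr)
  gy <- rep(cy, times = nc)
  for (p in ann$polygons) {
    inside <- points_in_polygon(gx, gy, p$vertices)
    mask[inside] <- label_channel(p$label)
  }
  mask
}
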