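# Labeled patch extraction: sliding windows fully inside annotation
# polygons for the five region-pure classes, point-centered patches at
# tumor--muscle junctions for HGMI.

#' Patch sampling specification
#'
#' @param size Patch side in pixels at full resolution (default 256).
#' @param stride Sampling stride in pixels (default 256).
#' @param magnification_level Block-mean downscale factor applied at
#'   extraction time; a patch at level `L` covers `size * L` full-
#'   resolution pixels. Default 1 (full resolution).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(size = 256, stride = 256, magnification_level = 1) {
  stopifnot(size > 0, stride > 0, magnification_level >= 1,
            magnification_level == round(magnification_level))
  structure(list(size = as.integer(size), stride = as.integer(stride),
                 magnification_level = as.integer(magnification_level)),
            class = "patch_spec")
}

#' Sliding-window patches inside annotation polygons
#'
#' Enumerates grid positions at the spec stride over each polygon of the
#' requested class (grid anchored at the polygon's bounding-box origin)
#' and keeps a patch iff its full rectangle lies inside the polygon, so
#' every patch comprises a single kind of tissue. Row-major order.
#'
#' HGMI patches are not region-pure (they mix tumor and muscle) and are
#' sampled with [point_patches()] instead.
#'
#' @param ann An [annotation_set()].
#' @param cls Label class, one of HGNMI, LGNMI, IA, NIA, NA.
#' @param spec A [patch_spec()].
#' @return Data frame `slide_id`, `x0`, `y0`, `size`, `label` (one row
#'   per patch; coordinates full-resolution, 0-based).
#' @export
sliding_window_patches <- function(ann, cls, spec = patch_spec()) {
  stopifnot(inherits(ann, "annotation_set"), inherits(spec, "patch_spec"))
  check_label(cls)
  if (cls == "HGMI") {
    stop("HGMI patches are sampled at tumor-muscle junctions; ",
         "use point_patches()", call. = FALSE)
  }
  span <- spec$size * spec$magnification_level
  out <- list()
  for (p in ann$polygons) {
    if (p$label != cls) next
    v <- p$vertices
    bx0 <- ceiling(min(v[, 1]))
    by0 <- ceiling(min(v[, 2]))
    bx1 <- floor(max(v[, 1]))
    by1 <- floor(max(v[, 2]))
    if (bx1 - bx0 < span || by1 - by0 < span) next
    xs <- seq(bx0, bx1 - span, by = spec$stride)
    ys <- seq(by0, by1 - span, by = spec$stride)
    for (y in ys) {
      for (x in xs) {
        if (x + span <= ann$width && y + span <= ann$height &&
            rect_in_polygon(x, y, x + span, y + span, v)) {
          out[[length(out) + 1]] <- c(x, y)
        }
      }
    }
  }
  patch_table(ann$slide_id, out, spec$size, cls,
              level = spec$magnification_level)
}

#' Point-centered HGMI patches
#'
#' One patch per sampling point, centered on it and clamped inward so
#' the rectangle stays within bounds (boundary points are kept, not
#' discarded; junction examples are scarce). Duplicate points yield
#' duplicate patches.
#'
#' @param points `n x 2` matrix (or data frame) of `(x, y)` points.
#' @param spec A [patch_spec()].
#' @param bounds `(width, height)` of the slide.
#' @return Data frame as [sliding_window_patches()], with label HGMI.
#' @export
point_patches <- function(points, spec = patch_spec(), bounds) {
  stopifnot(inherits(spec, "patch_spec"), length(bounds) == 2)
  points <- as.matrix(points)
  span <- spec$size * spec$magnification_level
  if (bounds[1] < span || bounds[2] < span) {
    stop("slide smaller than the patch span", call. = FALSE)
  }
  if (nrow(points) == 0) {
    return(patch_table("slide", list(), spec$size, "HGMI",
                       level = spec$magnification_level))
  }
  if (any(points[, 1] < 0 | points[, 1] >= bounds[1] |
          points[, 2] < 0 | points[, 2] >= bounds[2])) {
    stop("points must lie within bounds", call. = FALSE)
  }
  x0 <- clamp(round(points[, 1] - span / 2), 0, bounds[1] - span)
  y0 <- clamp(round(points[, 2] - span / 2), 0, bounds[2] - span)
  out <- lapply(seq_along(x0), function(i) c(x0[i], y0[i]))
  patch_table("slide", out, spec$size, "HGMI",
              level = spec$magnification_level)
}

patch_table <- function(slide_id, positions, size, label, level = 1) {
  if (length(positions) == 0) {
    return(data.frame(slide_id = character(0), x0 = integer(0),
                      y0 = integer(0), size = integer(0),
                      label = character(0), level = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, positions)
  data.frame(slide_id = slide_id, x0 = as.integer(m[, 1]),
             y0 = as.integer(m[, 2]), size = as.integer(size),
             label = label, level = as.integer(level),
             stringsAsFactors = FALSE)
}

#' Sample the full training patch set of one slide
#'
#' Sliding windows for the five region-pure classes present in the
#' annotations plus point-centered HGMI patches at the tumor--muscle
#' junctions.
#'
#' @param ann An [annotation_set()].
#' @param spec A [patch_spec()].
#' @param junction_spacing Spacing of junction sampling points (px).
#' @return Data frame of labeled patches.
#' @export
sample_slide_patches <- function(ann, spec = patch_spec(),
                                 junction_spacing = 256) {
  parts <- lapply(setdiff(label_classes()$code, "HGMI"), function(cls) {
    sliding_window_patches(ann, cls, spec)
  })
  jp <- junction_points(ann, spacing = junction_spacing)
  if (nrow(jp) > 0) {
    hg <- point_patches(jp, spec, c(ann$width, ann$height))
    hg$slide_id <- ann$slide_id
    parts <- c(parts, list(hg))
  }
  do.call(rbind, parts)
}

#' Stratified train/validation split by slide
#'
#' Slides (never patches) are split within each stratum at the given
#' ratio; per-stratum counts match the ratio to within one slide.
#' Deterministic for a fixed seed.
#'
#' @param slide_ids Character vector of slide identifiers.
#' @param ratio Length-2 positive numeric, `(train, val)`; default 4:1.
#' @param seed Integer seed.
#' @param strata Slide-level label per slide (same length as
#'   `slide_ids`), one of [diagnostic_classes()].
#' @return List with `train` and `val` character vectors (disjoint,
#'   union = `slide_ids`).
#' @export
split_slides <- function(slide_ids, ratio = c(4, 1), seed = 1,
                         strata = NULL) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  if (is.null(strata)) strata <- rep("all", length(slide_ids))
  stopifnot(length(strata) == length(slide_ids))
  if (!all(strata %in% c(diagnostic_classes(), "all"))) {
    stop("unknown stratum: ",
         paste(setdiff(strata, c(diagnostic_classes(), "all")),
               collapse = ", "), call. = FALSE)
  }
  local_seed(seed, {
    train <- character(0)
    val <- character(0)
    for (s in unique(strata)) {
      ids <- slide_ids[strata == s]
      ids <- ids[sample.int(length(ids))]
      n_val <- round(length(ids) * ratio[2] / sum(ratio))
      val <- c(val, ids[seq_len(n_val)])
      train <- c(train, ids[setdiff(seq_along(ids), seq_len(n_val))])
    }
    list(train = train, val = val)
  })
}

#' Write / read a patch table
#'
#' Text table with one patch per line, `slide_id x0 y0 size label`
#' (no header) -- the sampling list consumed by the training loader.
#'
#' @param patches Data frame from the sampling functions.
#' @param path File path.
#' @return `write_patches` returns `path` invisibly; `read_patches`
#'   returns the data frame.
#' @export
write_patches <- function(patches, path) {
  utils::write.table(patches[, c("slide_id", "x0", "y0", "size", "label")],
                     path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("slide_id", "x0", "y0", "size",
                                        "label"),
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character"),
                          na.strings = character(0))
  check_label(unique(df$label))
  df$level <- 1L
  df
}

#' Extract one patch from a slide image
#'
#' @param image `height x width x 3` array, 0--255.
#' @param x0,y0 Top-left corner, 0-based full-resolution pixels.
#' @param size Patch side in output pixels.
#' @param level Block-mean downscale factor (the patch covers
#'   `size * level` full-resolution pixels).
#' @return `size x size x 3` array.
#' @export
extract_patch <- function(image, x0, y0, size, level = 1) {
  span <- size * level
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (x0 < 0 || y0 < 0 || x0 + span > w || y0 + span > h) {
    stop("patch rectangle crosses image bounds", call. = FALSE)
  }
  patch <- image[(y0 + 1):(y0 + span), (x0 + 1):(x0 + span), ,
                 drop = FALSE]
  if (level > 1) patch <- pool_block(patch, level)
  patch
}

# block-mean pooling of an (h, w, c) array by integer factor f
# (h and w must be divisible by f)
pool_block <- function(image, f) {
  d <- dim(image)
  stopifnot(d[1] %% f == 0, d[2] %% f == 0)
  h2 <- d[1] / f
  w2 <- d[2] / f
  x <- array(image, c(f, h2, d[2] * d[3]))
  x <- colMeans(x)                      # (h2, w * c)
  x <- array(x, c(h2, f, w2 * d[3]))
  x <- aperm(x, c(2, 1, 3))             # (f, h2, w2 * c)
  array(colMeans(x), c(h2, w2, d[3]))
}
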