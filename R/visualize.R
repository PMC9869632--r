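# Fig.-3-style overlays: decision masks tinted over the slide, with an
# optional soft mode whose per-pixel opacity follows the class
# probability.

#' Overlay style
#'
#' @param colors Named list/vector of RGB triples (0--255) for the
#'   diagnostic classes. Defaults: HGMI red, HGNMI purple, LGNMI
#'   yellow.
#' @param opacity Blend opacity in `[0, 1]`.
#' @return Object of class `overlay_style`.
#' @export
overlay_style <- function(colors = list(HGMI = c(255, 0, 0),
                                        HGNMI = c(128, 0, 128),
                                        LGNMI = c(255, 255, 0)),
                          opacity = 0.45) {
  stopifnot(setequal(names(colors), diagnostic_classes()),
            opacity >= 0, opacity <= 1)
  key <- vapply(colors, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop("overlay colors must be distinct",
                               call. = FALSE)
  structure(list(colors = colors, opacity = opacity),
            class = "overlay_style")
}

#' Render a decision-map overlay
#'
#' Upscales the decision map to image resolution (nearest neighbor,
#' factor 32) and tints the diagnostic-class regions; IA/NIA/NA and
#' uncovered regions are left untinted. In soft mode the opacity of
#' each pixel is scaled by the class probability from the heatmap.
#'
#' @param image `height x width x 3` array, 0--255.
#' @param d Decision map from [decision_map()].
#' @param style An [overlay_style()].
#' @param h Optional [heatmap_raster()] enabling soft (probability-weighted)
#'   opacity.
#' @return `height x width x 3` array, 0--255.
#' @export
render_overlay <- function(image, d, style = overlay_style(), h = NULL) {
  stopifnot(length(dim(image)) == 3)
  hi <- dim(image)[1]
  wi <- dim(image)[2]
  if (nrow(d) != ceiling(hi / 32) || ncol(d) != ceiling(wi / 32)) {
    stop("decision map dimensions do not match the image", call. = FALSE)
  }
  if (style$opacity == 0) return(image)
  ri <- (seq_len(hi) - 1L) %/% 32L + 1L
  ci <- (seq_len(wi) - 1L) %/% 32L + 1L
  big <- d[ri, ci, drop = FALSE]
  out <- image
  for (cls in diagnostic_classes()) {
    ch_idx <- label_channel(cls)
    mask <- big == ch_idx
    if (!any(mask)) next
    alpha <- style$opacity
    if (!is.null(h)) {
      plane <- matrix(h$probs[, , ch_idx + 1L], nrow(d), ncol(d))
      pbig <- plane[ri, ci, drop = FALSE]
      alpha <- style$opacity * pbig[mask]
    }
    col <- style$colors[[cls]]
    for (k in 1:3) {
      plane <- out[, , k]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * col[k]
      out[, , k] <- plane
    }
  }
  out
}
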