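# Dense tile inference: one patch prediction per stride-32 grid point,
# spliced into a 6-channel probability heatmap at 1/32 of input scale.

HEATMAP_STRIDE <- 32L

#' Construct a heatmap object
#'
#' @param probs `hh x wh x 6` array of class probabilities.
#' @param coverage `hh x wh` logical matrix; uncovered points hold
#'   all-zero probability vectors.
#' @param width,height Full-resolution slide dimensions.
#' @return Object of class `heatmap`.
#' @export
heatmap_raster <- function(probs, coverage, width, height) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[3] == 6,
            all(dim(coverage) == dim(probs)[1:2]))
  structure(list(probs = probs, coverage = coverage,
                 width = as.integer(width), height = as.integer(height),
                 stride = HEATMAP_STRIDE),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> %d x %d x 6 (1/%d of %d x %d), %d/%d covered\n",
              dim(x$probs)[1], dim(x$probs)[2], x$stride,
              x$height, x$width, sum(x$coverage), length(x$coverage)))
  invisible(x)
}

#' Dense heatmap inference
#'
#' For each stride-32 grid point whose center lies inside a retained
#' ROI, evaluates the classifier on the patch centered there (clamped
#' at image borders so the rectangle stays in bounds) and writes the
#' probability vector at the corresponding heatmap point. Points
#' outside retained ROIs are uncovered. The heatmap has spatial
#' dimensions `ceiling(height / 32) x ceiling(width / 32)` and is
#' independent of ROI visit order.
#'
#' Heatmap point `(r, c)` (1-based) corresponds to the full-resolution
#' center `((c - 0.5) * 32, (r - 0.5) * 32)`.
#'
#' @param model A `patch_classifier`.
#' @param image `height x width x 3` array, 0--255.
#' @param manifest An `roi_manifest` for this image (see
#'   [filter_background()]).
#' @param spec A [patch_spec()]; `spec$size` must equal the model input
#'   size. Defaults to the model's size.
#' @return A [heatmap_raster()].
#' @export
infer_heatmap <- function(model, image, manifest, spec = NULL) {
  stopifnot(inherits(model, "patch_classifier"),
            inherits(manifest, "roi_manifest"),
            length(dim(image)) == 3)
  if (is.null(spec)) spec <- patch_spec(size = model$input_size,
                                        stride = HEATMAP_STRIDE)
  if (spec$size != model$input_size) {
    stop("spec$size must match the model input size", call. = FALSE)
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  size <- spec$size
  if (h < size || w < size) {
    stop("image smaller than the patch size", call. = FALSE)
  }
  hh <- as.integer(ceiling(h / HEATMAP_STRIDE))
  wh <- as.integer(ceiling(w / HEATMAP_STRIDE))
  cx <- (seq_len(wh) - 0.5) * HEATMAP_STRIDE
  cy <- (seq_len(hh) - 0.5) * HEATMAP_STRIDE
  covered <- matrix(FALSE, hh, wh)
  if (nrow(manifest$rois) == 0) {
    warning("empty ROI manifest: heatmap is fully uncovered",
            call. = FALSE)
  } else {
    gx <- rep(cx, each = hh)
    gy <- rep(cy, times = wh)
    for (i in seq_len(nrow(manifest$rois))) {
      r <- manifest$rois[i, ]
      x1 <- min(r$x0 + r$size, w)
      y1 <- min(r$y0 + r$size, h)
      covered <- covered | matrix(gx >= r$x0 & gx < x1 &
                                    gy >= r$y0 & gy < y1, hh, wh)
    }
  }
  probs <- array(0, c(hh, wh, 6L))
  pts <- which(covered)
  if (length(pts) > 0) {
    pr <- pts - 1L
    rr <- pr %% hh
    cc <- pr %/% hh
    x0 <- clamp(round((cc + 0.5) * HEATMAP_STRIDE - size / 2), 0, w - size)
    y0 <- clamp(round((rr + 0.5) * HEATMAP_STRIDE - size / 2), 0, h - size)
    f <- model$stem_factor
    hp <- h %/% f
    wp <- w %/% f
    aligned <- all(x0 %% f == 0) && all(y0 %% f == 0) &&
      all((x0 %/% f) %% 2 == 0) && all((y0 %/% f) %% 2 == 0) &&
      hp %% 2 == 0 && wp %% 2 == 0
    if (aligned) {
      # patch offsets align with the stem and pooling grids: compute
      # block statistics and the convolutional features for the whole
      # slide once and read per-point predictions out of the shared
      # feature maps (identical to per-patch evaluation up to
      # floating-point noise)
      cropped <- image[seq_len(hp * f), seq_len(wp * f), , drop = FALSE]
      if (f == 1) {
        pooled <- array(c(cropped, array(0, dim(cropped))),
                        c(hp, wp, 6L))
      } else {
        pm <- pool_block(cropped, f)
        ps <- sqrt(pmax(pool_block(cropped^2, f) - pm^2, 0))
        pooled <- array(c(pm, ps), c(hp, wp, 6L))
      }
      pred <- fast_dense_forward(model$net, pooled, y0 %/% f, x0 %/% f)
    } else {
      X <- matrix(0, NET_IN * NET_IN * NET_CH, length(pts))
      for (i in seq_along(pts)) {
        X[, i] <- stem_features(
          extract_patch(image, x0[i], y0[i], size), f)
      }
      pred <- predict_pooled_net(model$net, X)
    }
    for (k in 1:6) {
      ch <- matrix(0, hh, wh)
      ch[pts] <- pred[k, ]
      probs[, , k] <- ch
    }
  }
  heatmap_raster(probs, covered, width = w, height = h)
}

#' Decision map from a heatmap
#'
#' Argmax class per covered point, ties broken by the lowest channel
#' index; uncovered points hold the sentinel -1.
#'
#' @param h A [heatmap_raster()].
#' @return Integer matrix of the heatmap's spatial dimensions with
#'   values in `-1, 0..5`.
#' @export
decision_map <- function(h) {
  stopifnot(inherits(h, "heatmap"))
  d <- dim(h$probs)
  flat <- matrix(h$probs, d[1] * d[2], d[3])
  dec <- max.col(flat, ties.method = "first") - 1L
  out <- matrix(as.integer(dec), d[1], d[2])
  out[!h$coverage] <- -1L
  out
}

#' Write / read a heatmap as multi-page TIFF
#'
#' Six 32-bit float pages in channel order (HGMI, HGNMI, LGNMI, IA,
#' NIA, NA) followed by one coverage page; probabilities are stored at
#' float32 precision.
#'
#' @param h A [heatmap_raster()].
#' @param path File path (`.tif`/`.tiff`).
#' @return `write_heatmap` returns `path` invisibly; `read_heatmap`
#'   returns a [heatmap_raster()].
#' @export
write_heatmap <- function(h, path) {
  stopifnot(inherits(h, "heatmap"))
  pages <- c(lapply(1:6, function(k) h$probs[, , k]),
             list(h$coverage * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 7) {
    stop("expected 7 pages (6 channels + coverage), found ",
         length(pages), call. = FALSE)
  }
  d <- dim(pages[[1]])
  probs <- array(0, c(d[1], d[2], 6L))
  for (k in 1:6) probs[, , k] <- pages[[k]]
  coverage <- pages[[7]] > 0.5
  heatmap_raster(probs, coverage,
          width = d[2] * HEATMAP_STRIDE, height = d[1] * HEATMAP_STRIDE)
}
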