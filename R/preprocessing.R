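# White-background removal: slide-level Otsu threshold on the luminance
# histogram, then a fixed grid of ROIs retained by tissue fraction.

#' Otsu threshold of a 256-bin grayscale histogram
#'
#' Returns the threshold `t` maximizing the between-class variance of
#' the split into bins `0..t` versus `t+1..255`. Only splits with both
#' classes non-empty are candidates; ties are broken by the smallest
#' maximizing threshold. A histogram with a single occupied bin (no
#' valid split; the variance is zero everywhere) returns that bin's
#' index.
#'
#' @param hist Numeric vector of 256 non-negative bin counts with
#'   positive total.
#' @return Integer threshold in 0--255.
#' @export
otsu_threshold <- function(hist) {
  if (length(hist) != 256 || any(!is.finite(hist)) || any(hist < 0)) {
    stop("hist must be 256 non-negative finite counts", call. = FALSE)
  }
  total <- sum(hist)
  if (total <= 0) stop("histogram is empty", call. = FALSE)
  counts <- cumsum(hist)
  p <- hist / total
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # candidate splits need both classes occupied; use exact counts so
  # floating-point residue in 1 - w0 cannot admit an empty class
  valid <- counts > 0 & counts < total
  if (!any(valid)) {
    return(as.integer(which(hist > 0)[1] - 1L))
  }
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * w1[valid])
  as.integer(which.max(sigma_b) - 1L)
}

#' Rec.601 luminance of an RGB image
#'
#' @param image `height x width x 3` array, 0--255.
#' @return `height x width` matrix, 0--255 (not rounded).
#' @export
rgb_to_gray <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Tissue fraction of a grayscale region
#'
#' Tissue is darker than the white background: the fraction of pixels
#' with gray value less than or equal to the threshold.
#'
#' @param roi_pixels Numeric matrix (or vector) of gray values, 0--255.
#' @param threshold Gray threshold, 0--255.
#' @return Proportion in `[0, 1]`.
#' @export
tissue_fraction <- function(roi_pixels, threshold) {
  if (length(roi_pixels) == 0) stop("empty ROI", call. = FALSE)
  stopifnot(length(threshold) == 1, threshold >= 0, threshold <= 255)
  mean(roi_pixels <= threshold)
}

#' Remove white background over a fixed ROI grid
#'
#' Converts to luminance, takes one global Otsu threshold from the
#' whole-slide histogram, tiles the slide into `roi_size` squares
#' (edge ROIs clipped, fractions computed over actual pixels) and
#' retains ROIs whose tissue fraction reaches `min_fraction`. A slide
#' whose Otsu threshold lands above `white_floor` is treated as
#' tissue-free (an all-white slide has no bimodal histogram for Otsu to
#' split, and would otherwise retain its own noise).
#'
#' @param image `height x width x 3` RGB array, 0--255.
#' @param roi_size ROI side in pixels (default 2048).
#' @param min_fraction Minimum tissue proportion for retention.
#' @param slide_id Identifier recorded in the manifest.
#' @param white_floor Threshold ceiling above which the slide is
#'   considered background-only.
#' @return An object of class `roi_manifest`: list with `slide_id`,
#'   `threshold`, `min_fraction` and `rois` (data frame `grid_row`,
#'   `grid_col`, `x0`, `y0`, `size`, `tissue_fraction`; retained ROIs
#'   only, 0-based grid indices and pixel origins).
#' @export
filter_background <- function(image, roi_size = 2048, min_fraction = 0.1,
                              slide_id = "slide", white_floor = 243) {
  stopifnot(length(dim(image)) == 3, min_fraction > 0, min_fraction <= 1,
            roi_size >= 1)
  gray <- round(rgb_to_gray(image))
  hist <- tabulate(as.integer(gray) + 1L, nbins = 256)
  threshold <- otsu_threshold(hist)
  h <- nrow(gray)
  w <- ncol(gray)
  n_rows <- ceiling(h / roi_size)
  n_cols <- ceiling(w / roi_size)
  rois <- list()
  if (threshold <= white_floor) {
    for (gr in seq_len(n_rows) - 1L) {
      for (gc in seq_len(n_cols) - 1L) {
        y0 <- gr * roi_size
        x0 <- gc * roi_size
        frac <- tissue_fraction(
          gray[(y0 + 1):min(h, y0 + roi_size),
               (x0 + 1):min(w, x0 + roi_size)],
          threshold)
        if (frac >= min_fraction) {
          rois[[length(rois) + 1]] <- data.frame(
            grid_row = gr, grid_col = gc, x0 = x0, y0 = y0,
            size = roi_size, tissue_fraction = frac)
        }
      }
    }
  }
  roi_manifest(slide_id, threshold, min_fraction,
               if (length(rois) > 0) do.call(rbind, rois) else NULL)
}

roi_manifest <- function(slide_id, threshold, min_fraction, rois = NULL) {
  if (is.null(rois)) {
    rois <- data.frame(grid_row = integer(0), grid_col = integer(0),
                       x0 = integer(0), y0 = integer(0),
                       size = integer(0), tissue_fraction = numeric(0))
  }
  rownames(rois) <- NULL
  structure(
    list(slide_id = slide_id, threshold = as.integer(threshold),
         min_fraction = min_fraction, rois = rois),
    class = "roi_manifest"
  )
}

#' @export
print.roi_manifest <- function(x, ...) {
  cat(sprintf(
    "<roi_manifest> slide '%s', threshold %d, min fraction %g, %d ROI(s)\n",
    x$slide_id, x$threshold, x$min_fraction, nrow(x$rois)))
  invisible(x)
}

#' Write / read a retained-ROI manifest
#'
#' Plain whitespace-delimited text: one header line
#' `slide_id threshold min_fraction`, then one line per retained ROI,
#' `grid_row grid_col x0 y0 size tissue_fraction` with the fraction at
#' 6 decimals. Round-trips up to that precision.
#'
#' @param m An `roi_manifest`.
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns an `roi_manifest`.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "roi_manifest"))
  lines <- sprintf("%s %d %.6f", m$slide_id, m$threshold, m$min_fraction)
  if (nrow(m$rois) > 0) {
    lines <- c(lines, sprintf("%d %d %d %d %d %.6f",
                              m$rois$grid_row, m$rois$grid_col,
                              m$rois$x0, m$rois$y0, m$rois$size,
                              m$rois$tissue_fraction))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty manifest file", call. = FALSE)
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head) != 3) {
    stop("manifest line 1: expected 'slide_id threshold min_fraction'",
         call. = FALSE)
  }
  rois <- NULL
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) > 0) {
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 6)
    if (length(bad) > 0) {
      stop("manifest line ", bad[1] + 1,
           ": expected 6 whitespace-delimited fields", call. = FALSE)
    }
    mat <- do.call(rbind, lapply(parts, as.numeric))
    if (any(!is.finite(mat))) {
      stop("manifest line ",
           which(rowSums(!is.finite(mat)) > 0)[1] + 1,
           ": non-numeric field", call. = FALSE)
    }
    rois <- data.frame(grid_row = as.integer(mat[, 1]),
                       grid_col = as.integer(mat[, 2]),
                       x0 = as.integer(mat[, 3]),
                       y0 = as.integer(mat[, 4]),
                       size = as.integer(mat[, 5]),
                       tissue_fraction = mat[, 6])
  }
  roi_manifest(head[1], as.integer(head[2]), as.numeric(head[3]), rois)
}
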