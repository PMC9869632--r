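# Deterministic synthetic slides with six procedurally textured tissue
# classes. The textures are cartoons of H&E appearance: hematoxylin-dark
# nuclei on eosin-pink stroma, with class-specific nucleus density, size
# and stain intensity; muscle is rendered as eosinophilic fibers with
# striping; IA is blurred tumor texture; NA is saturated stain blobs
# without nuclei. Fidelity is deliberately low -- the point is six
# pairwise separable textures with ground truth, not photorealism.

texture_params <- function() {
  list(
    background = list(base = c(248, 247, 248)),
    hg_tumour = list(base = c(200, 155, 190), nucleus = c(110, 70, 140),
                     density = 0.003, radius = c(3.5, 6)),
    lg_tumour = list(base = c(225, 185, 210), nucleus = c(150, 105, 170),
                     density = 0.0015, radius = c(2.5, 4.5)),
    muscle = list(base = c(200, 115, 125), nucleus = c(120, 75, 115),
                  density = 3e-4, radius = c(2, 3.5),
                  stripe_amp = 16, stripe_period = 14),
    nia = list(base = c(235, 205, 220), nucleus = c(160, 120, 170),
               density = 5e-4, radius = c(2, 4)),
    ia = list(blur_sigma = 5),
    na = list(base = c(233, 222, 228), blob = c(70, 55, 40),
              blob_density = 5e-5, blob_radius = c(8, 25))
  )
}

#' Specification of a synthetic slide
#'
#' @param width,height Slide dimensions in pixels (defaults 2048, the
#'   size used for full-pipeline runs; smaller slides are allowed for
#'   unit-scale work).
#' @param wsi_label Diagnostic category to emulate; used to build the
#'   default layout when `layout` is `NULL`.
#' @param layout Optional data frame with columns `role` (one of
#'   `tumour_hg`, `tumour_lg`, `muscle`, `nia`, `ia`, `na`), `x0`, `y0`,
#'   `w`, `h` (pixels). When `NULL` a randomized default layout for
#'   `wsi_label` is drawn from the spec seed.
#' @param noise_sd Gaussian pixel noise, 8-bit intensity units.
#' @param seed Integer seed fixing all randomness of the slide.
#' @param junction_spacing Spacing (px) of tumor--muscle junction
#'   sampling points; defaults to `width / 8`.
#' @param slide_id Identifier carried into the annotation set.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 2048, height = 2048,
                           wsi_label = "HGMI", layout = NULL,
                           noise_sd = 3, seed = 1,
                           junction_spacing = NULL,
                           slide_id = "slide") {
  check_label(wsi_label, diagnostic_only = TRUE)
  stopifnot(width >= 64, height >= 64, noise_sd >= 0)
  if (is.null(junction_spacing)) junction_spacing <- round(width / 8)
  stopifnot(junction_spacing > 0)
  if (!is.null(layout)) validate_layout(layout, width, height)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         wsi_label = wsi_label, layout = layout,
         noise_sd = noise_sd, seed = as.integer(seed),
         junction_spacing = junction_spacing, slide_id = slide_id),
    class = "synthetic_spec"
  )
}

layout_roles <- c("tumour_hg", "tumour_lg", "muscle", "nia", "ia", "na")

validate_layout <- function(layout, width, height) {
  stopifnot(is.data.frame(layout),
            all(c("role", "x0", "y0", "w", "h") %in% names(layout)))
  bad <- setdiff(layout$role, layout_roles)
  if (length(bad) > 0) {
    stop("unknown layout role: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(layout$x0 < 0 | layout$y0 < 0 |
          layout$x0 + layout$w > width |
          layout$y0 + layout$h > height | layout$w < 1 | layout$h < 1)) {
    stop("layout rectangles must lie inside the image", call. = FALSE)
  }
  if (any(layout$role == "tumour_hg") && any(layout$role == "tumour_lg")) {
    stop("high-grade and low-grade tumour regions cannot share a slide",
         call. = FALSE)
  }
  if (!any(layout$role %in% c("tumour_hg", "tumour_lg"))) {
    stop("layout must contain a tumour region", call. = FALSE)
  }
  if (any(layout$role == "muscle")) {
    hg <- layout[layout$role == "tumour_hg", , drop = FALSE]
    mu <- layout[layout$role == "muscle", , drop = FALSE]
    if (nrow(hg) == 0) {
      stop("muscle regions require a high-grade tumour region",
           call. = FALSE)
    }
    for (i in seq_len(nrow(mu))) {
      touches <- any(vapply(seq_len(nrow(hg)), function(j) {
        rects_share_edge(mu[i, ], hg[j, ])
      }, logical(1)))
      if (!touches) {
        stop("each muscle region must abut a high-grade tumour region",
             call. = FALSE)
      }
    }
  }
  invisible(layout)
}

rect_vertices <- function(r) {
  rbind(c(r$x0, r$y0), c(r$x0 + r$w, r$y0),
        c(r$x0 + r$w, r$y0 + r$h), c(r$x0, r$y0 + r$h))
}

rects_share_edge <- function(a, b) {
  va <- rect_vertices(a)
  vb <- rect_vertices(b)
  for (i in 1:4) {
    a1 <- va[i, ]; a2 <- va[c(2:4, 1)[i], ]
    for (j in 1:4) {
      b1 <- vb[j, ]; b2 <- vb[c(2:4, 1)[j], ]
      if (!is.null(collinear_overlap(a1, a2, b1, b2))) return(TRUE)
    }
  }
  FALSE
}

# randomized default layout for a diagnostic category; consumes the
# active RNG stream
slide_layout <- function(wsi_label, width, height) {
  stopifnot(width >= 256, height >= 256)
  j_aux <- round(width / 64)
  j_diag <- round(width / 32)
  s_aux <- round(width / 4)
  m <- round(width * 0.06)
  jit <- function(n, j) round(stats::runif(n, -j, j))
  aux <- data.frame(
    role = c("nia", "ia", "na"),
    x0 = c(m, width - m - s_aux, m) + jit(3, j_aux),
    y0 = c(round(height * 0.05), round(height * 0.05),
           round(height * 0.70)) + jit(3, j_aux),
    w = s_aux, h = s_aux
  )
  dx <- jit(1, j_diag)
  dy <- jit(1, j_diag)
  if (wsi_label == "HGMI") {
    bw <- round(width / 8)
    bh <- round(height * 0.55)
    x0 <- round(width / 2) - round(1.5 * bw) + dx
    y0 <- round(height * 0.375) + dy
    diag <- data.frame(
      role = c("muscle", "tumour_hg", "muscle"),
      x0 = x0 + c(0, bw, 2 * bw), y0 = y0, w = bw, h = bh
    )
  } else {
    side <- round(width * 0.5)
    diag <- data.frame(
      role = if (wsi_label == "HGNMI") "tumour_hg" else "tumour_lg",
      x0 = round(width * 0.375) + dx, y0 = round(height * 0.375) + dy,
      w = side, h = side
    )
  }
  out <- rbind(diag, aux)
  out$x0 <- clamp(out$x0, 0, width - out$w)
  out$y0 <- clamp(out$y0, 0, height - out$h)
  out
}

# -- texture rendering ------------------------------------------------

draw_disks <- function(reg, n, radius, color, alpha) {
  h <- dim(reg)[1]
  w <- dim(reg)[2]
  if (n == 0) return(reg)
  cx <- stats::runif(n, 1, w)
  cy <- stats::runif(n, 1, h)
  rr <- stats::runif(n, radius[1], radius[2])
  for (i in seq_len(n)) {
    xs <- max(1, floor(cx[i] - rr[i])):min(w, ceiling(cx[i] + rr[i]))
    ys <- max(1, floor(cy[i] - rr[i])):min(h, ceiling(cy[i] + rr[i]))
    dx2 <- (xs - cx[i])^2
    dy2 <- (ys - cy[i])^2
    inside <- outer(dy2, dx2, "+") <= rr[i]^2
    for (ch in 1:3) {
      sub <- reg[ys, xs, ch]
      sub[inside] <- (1 - alpha) * sub[inside] + alpha * color[ch]
      reg[ys, xs, ch] <- sub
    }
  }
  reg
}

render_region <- function(role, h, w, pars) {
  base_region <- function(p) {
    array(rep(p$base, each = h * w), c(h, w, 3))
  }
  cellular <- function(p) {
    reg <- base_region(p)
    n <- stats::rpois(1, p$density * h * w)
    draw_disks(reg, n, p$radius, p$nucleus, alpha = 0.9)
  }
  switch(role,
    tumour_hg = cellular(pars$hg_tumour),
    tumour_lg = cellular(pars$lg_tumour),
    nia = cellular(pars$nia),
    muscle = {
      p <- pars$muscle
      reg <- base_region(p)
      phase <- stats::runif(1, 0, p$stripe_period)
      stripe <- p$stripe_amp *
        sin(2 * pi * (seq_len(h) + phase) / p$stripe_period)
      reg <- reg + array(rep(stripe, w * 3), c(h, w, 3))
      n <- stats::rpois(1, p$density * h * w)
      draw_disks(reg, n, p$radius, p$nucleus, alpha = 0.9)
    },
    ia = {
      reg <- cellular(pars$hg_tumour)
      sigma <- pars$ia$blur_sigma
      for (ch in 1:3) {
        reg[, , ch] <- as.numeric(EBImage::gblur(reg[, , ch],
                                                 sigma = sigma))
      }
      reg
    },
    na = {
      p <- pars$na
      reg <- base_region(p)
      n <- stats::rpois(1, p$blob_density * h * w)
      draw_disks(reg, n, p$blob_radius, p$blob, alpha = 1)
    },
    stop("unknown region role: ", role)
  )
}

# -- slide generation -------------------------------------------------

#' Generate a synthetic slide
#'
#' Renders the slide image, its ground-truth annotation polygons, the
#' slide-level label and (on muscle-invasive slides) the tumor--muscle
#' junction sampling points. Fully deterministic for a fixed spec seed.
#'
#' Regions outside all placement rectangles are near-white background.
#' On a muscle-invasive slide the invaded tumour and muscle rectangles
#' are both annotated HGMI, distinguished by a `tissue` attribute
#' (`"tumour"` / `"muscle"`); on other slides the tumour rectangle is
#' annotated HGNMI or LGNMI.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_slide`: a list with elements
#'   `image` (height x width x 3 array, 0--255), `annotations` (an
#'   [annotation_set()]), `wsi_label`, `junction_points` (n x 2 matrix)
#'   and `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    layout <- spec$layout
    if (is.null(layout)) {
      layout <- slide_layout(spec$wsi_label, spec$width, spec$height)
    }
    validate_layout(layout, spec$width, spec$height)
    pars <- texture_params()
    h <- spec$height
    w <- spec$width
    img <- array(rep(pars$background$base, each = h * w), c(h, w, 3))
    for (i in seq_len(nrow(layout))) {
      r <- layout[i, ]
      reg <- render_region(r$role, r$h, r$w, pars)
      img[(r$y0 + 1):(r$y0 + r$h), (r$x0 + 1):(r$x0 + r$w), ] <- reg
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    }
    img <- round(clamp(img, 0, 255))

    has_muscle <- any(layout$role == "muscle")
    wsi_label <- if (any(layout$role == "tumour_hg")) {
      if (has_muscle) "HGMI" else "HGNMI"
    } else "LGNMI"
    polys <- lapply(seq_len(nrow(layout)), function(i) {
      r <- layout[i, ]
      label <- switch(r$role,
        tumour_hg = if (has_muscle) "HGMI" else "HGNMI",
        tumour_lg = "LGNMI",
        muscle = "HGMI",
        nia = "NIA", ia = "IA", na = "NA")
      tissue <- switch(r$role,
        tumour_hg = "tumour", tumour_lg = "tumour", muscle = "muscle",
        NULL)
      # annotation vertices must stay within [0, width) x [0, height)
      v <- rect_vertices(r)
      v[, 1] <- pmin(v[, 1], spec$width - 1e-6)
      v[, 2] <- pmin(v[, 2], spec$height - 1e-6)
      list(label = label, tissue = tissue, vertices = v)
    })
    ann <- annotation_set(spec$slide_id, spec$width, spec$height,
                          polygons = polys, wsi_label = wsi_label)
    jp <- junction_points(ann, spacing = spec$junction_spacing)
    structure(
      list(image = img, annotations = ann, wsi_label = wsi_label,
           junction_points = jp, spec = spec),
      class = "synthetic_slide"
    )
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> '%s' %s (%d x %d), %d junction point(s)\n",
              x$spec$slide_id, x$wsi_label, x$spec$width, x$spec$height,
              nrow(x$junction_points)))
  invisible(x)
}

#' Tumor--muscle junction sampling points
#'
#' Finds shared borders between invaded high-grade tumour polygons
#' (label HGMI, `tissue = "tumour"`) and muscle polygons
#' (`tissue = "muscle"`), and samples points along each shared border
#' segment every `spacing` pixels (the centers of
#' `max(1, floor(length / spacing))` equal subdivisions, so any nonempty
#' border yields at least one point). Straight shared edges are
#' supported, which covers rectangular region layouts.
#'
#' @param ann An [annotation_set()].
#' @param spacing Point spacing in pixels.
#' @return An `n x 2` matrix of `(x, y)` points (0 rows when the slide
#'   has no tumor--muscle border).
#' @export
junction_points <- function(ann, spacing = 256) {
  stopifnot(inherits(ann, "annotation_set"))
  if (length(spacing) != 1 || !is.finite(spacing) || spacing <= 0) {
    stop("spacing must be a positive number", call. = FALSE)
  }
  is_t <- vapply(ann$polygons, function(p) {
    p$label == "HGMI" && identical(p$tissue, "tumour")
  }, logical(1))
  is_m <- vapply(ann$polygons, function(p) {
    identical(p$tissue, "muscle")
  }, logical(1))
  pts <- matrix(numeric(0), ncol = 2)
  for (pt in ann$polygons[is_t]) {
    vt <- pt$vertices
    nt <- nrow(vt)
    for (pm in ann$polygons[is_m]) {
      vm <- pm$vertices
      nm <- nrow(vm)
      for (i in seq_len(nt)) {
        a1 <- vt[i, ]; a2 <- vt[if (i == nt) 1 else i + 1, ]
        for (j in seq_len(nm)) {
          b1 <- vm[j, ]; b2 <- vm[if (j == nm) 1 else j + 1, ]
          seg <- collinear_overlap(a1, a2, b1, b2)
          if (!is.null(seg)) {
            len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
            n <- max(1, floor(len / spacing))
            t <- (seq_len(n) - 0.5) / n
            pts <- rbind(pts, cbind(seg[1, 1] + t * (seg[2, 1] - seg[1, 1]),
                                    seg[1, 2] + t * (seg[2, 2] - seg[1, 2])))
          }
        }
      }
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Specs for a synthetic cohort
#'
#' Builds per-slide [synthetic_spec()]s with derived seeds and
#' randomized layouts, without rendering pixels. Use with
#' [generate_slide()] to realize slides one at a time (a 2048 px slide
#' is ~100 MB in memory).
#'
#' @param n_per_class Integer triple: slides per diagnostic class in the
#'   order HGMI, HGNMI, LGNMI.
#' @param base_spec Template [synthetic_spec()]; per-slide specs inherit
#'   its dimensions, noise and junction spacing.
#' @param seed Cohort seed; per-slide seeds are derived from it.
#' @return List of `synthetic_spec`.
#' @export
cohort_specs <- function(n_per_class, base_spec = synthetic_spec(),
                         seed = 1) {
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0))
  labels <- rep(diagnostic_classes(), times = n_per_class)
  n <- length(labels)
  if (n == 0) return(list())
  seeds <- local_seed(seed, sample.int(.Machine$integer.max, n))
  lapply(seq_len(n), function(i) {
    synthetic_spec(
      width = base_spec$width, height = base_spec$height,
      wsi_label = labels[i], layout = NULL,
      noise_sd = base_spec$noise_sd, seed = seeds[i],
      junction_spacing = base_spec$junction_spacing,
      slide_id = sprintf("slide_%03d", i)
    )
  })
}

#' Generate a synthetic cohort
#'
#' Realizes [cohort_specs()] into a list of slides. Class counts are
#' exact and two calls with the same seed yield identical cohorts.
#'
#' @inheritParams cohort_specs
#' @return List of `synthetic_slide`.
#' @export
generate_cohort <- function(n_per_class, base_spec = synthetic_spec(),
                            seed = 1) {
  lapply(cohort_specs(n_per_class, base_spec, seed), generate_slide)
}

#' Write a cohort to disk
#'
#' Writes one PNG image and one annotation XML per slide plus a
#' tab-separated index (`slide_id`, `image`, `annotations`,
#' `wsi_label`). Accepts realized slides or specs (specs are rendered
#' one at a time, keeping memory flat).
#'
#' @param slides List of `synthetic_slide` or `synthetic_spec`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the index file path.
#' @export
write_cohort <- function(slides, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(slides, function(s) {
    if (inherits(s, "synthetic_spec")) s <- generate_slide(s)
    id <- s$spec$slide_id
    img_path <- file.path(dir, paste0(id, ".png"))
    ann_path <- file.path(dir, paste0(id, ".xml"))
    write_slide_image(s$image, img_path)
    write_annotations(s$annotations, ann_path)
    data.frame(slide_id = id, image = img_path, annotations = ann_path,
               wsi_label = s$wsi_label, stringsAsFactors = FALSE)
  })
  index <- do.call(rbind, rows)
  index_path <- file.path(dir, "index.tsv")
  utils::write.table(index, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(index_path)
}
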