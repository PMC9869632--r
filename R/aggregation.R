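# Slide-level confidence: connected decision regions ("contours") per
# class, the area-weighted mean probability P_k over them, and the
# softmax confidence Prob_k = e^{P_k} / sum e^{P_k} across the three
# diagnostic categories.

#' Extract per-class contours from a decision map
#'
#' For each class, the 8-connected components of that class's decision
#' region on the heatmap grid; each component is summarized by its area
#' `a_i` (number of heatmap points) and `p_i`, the mean of that class's
#' probability channel over the component. Components are enumerated in
#' scanline order (row-major by first-encountered point); minimum
#' contour area is one point.
#'
#' @param d Decision map from [decision_map()].
#' @param h The [heatmap_raster()] the decision map was derived from.
#' @return Data frame `label`, `channel`, `contour`, `area`,
#'   `mean_prob` (zero rows when nothing is covered).
#' @export
extract_contours <- function(d, h) {
  stopifnot(inherits(h, "heatmap"), all(dim(d) == dim(h$probs)[1:2]))
  nr <- nrow(d)
  nc <- ncol(d)
  comp <- matrix(0L, nr, nc)
  rows <- list()
  next_id <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (d[r, c] < 0 || comp[r, c] != 0L) next
      next_id <- next_id + 1L
      cls <- d[r, c]
      # breadth-first flood fill over the 8-neighborhood, queue of
      # linear cell indices
      queue <- integer(nr * nc)
      queue[1] <- r + (c - 1L) * nr
      head <- 1L
      tail <- 1L
      comp[r, c] <- next_id
      while (head <= tail) {
        cur <- queue[head]
        head <- head + 1L
        rr0 <- (cur - 1L) %% nr + 1L
        cc0 <- (cur - 1L) %/% nr + 1L
        for (dr in -1:1) {
          rr <- rr0 + dr
          if (rr < 1 || rr > nr) next
          for (dc in -1:1) {
            cc <- cc0 + dc
            if (cc < 1 || cc > nc) next
            if (comp[rr, cc] == 0L && d[rr, cc] == cls) {
              comp[rr, cc] <- next_id
              tail <- tail + 1L
              queue[tail] <- rr + (cc - 1L) * nr
            }
          }
        }
      }
      cells <- queue[seq_len(tail)]
      pk <- matrix(h$probs, nr * nc, 6)[cells, cls + 1L]
      rows[[next_id]] <- data.frame(
        label = channel_label(cls), channel = cls, contour = next_id,
        area = length(cells), mean_prob = mean(pk))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(label = character(0), channel = integer(0),
                      contour = integer(0), area = integer(0),
                      mean_prob = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Area-weighted class score P_k
#'
#' `P_k = sum(a_i * p_i) / sum(a_i)` over the contours of one class;
#' undefined (NA) when the class has no contours.
#'
#' @param contours Data frame rows from [extract_contours()], all of a
#'   single class.
#' @return List with `label`, `m` (number of contours) and `P`.
#' @export
class_score <- function(contours) {
  if (nrow(contours) == 0) {
    return(list(label = NA_character_, m = 0L, P = NA_real_))
  }
  if (length(unique(contours$label)) != 1) {
    stop("contours must all belong to one class", call. = FALSE)
  }
  list(label = contours$label[1], m = nrow(contours),
       P = sum(contours$area * contours$mean_prob) / sum(contours$area))
}

#' Slide-level confidence from class scores
#'
#' Softmax of `e^{P_k}` over the diagnostic classes with defined
#' scores; classes without contours receive probability 0 and are
#' excluded from the denominator (scoring an absent class `P_k = 0`
#' would grant it baseline weight `e^0`). The predicted label is the
#' argmax; `mibc_score` is the muscle-invasion confidence (Prob_HGMI)
#' and `high_grade_score` the high-grade confidence
#' (Prob_HGMI + Prob_HGNMI, since all muscle-invasive disease is
#' high-grade).
#'
#' @param scores Named numeric vector of `P_k` for the diagnostic
#'   classes (`NA` = undefined), or a list of [class_score()] results.
#' @return Object of class `wsi_confidence`: list with `P`, `prob`,
#'   `n` (classes in the softmax), `predicted_label`, `mibc_score`,
#'   `high_grade_score`.
#' @export
wsi_confidence <- function(scores) {
  diag_cls <- diagnostic_classes()
  if (is.list(scores) && !is.numeric(scores)) {
    P <- stats::setNames(rep(NA_real_, 3), diag_cls)
    for (s in scores) {
      if (!is.na(s$label) && s$label %in% diag_cls) P[s$label] <- s$P
    }
  } else {
    stopifnot(!is.null(names(scores)))
    P <- stats::setNames(rep(NA_real_, 3), diag_cls)
    P[names(scores)] <- scores
  }
  defined <- !is.na(P)
  if (!any(defined)) {
    stop("classification failure: no diagnostic class has contours",
         call. = FALSE)
  }
  e <- exp(P[defined])
  prob <- stats::setNames(rep(0, 3), diag_cls)
  prob[defined] <- e / sum(e)
  structure(
    list(P = P, prob = prob, n = sum(defined),
         predicted_label = diag_cls[which.max(prob)],
         mibc_score = unname(prob["HGMI"]),
         high_grade_score = unname(prob["HGMI"] + prob["HGNMI"])),
    class = "wsi_confidence"
  )
}

#' @export
print.wsi_confidence <- function(x, ...) {
  cat(sprintf(
    "<wsi_confidence> predicted %s (Prob: %s; MIBC %.3f, high-grade %.3f)\n",
    x$predicted_label,
    paste(sprintf("%s %.3f", names(x$prob), x$prob), collapse = ", "),
    x$mibc_score, x$high_grade_score))
  invisible(x)
}

#' Classify a slide end to end
#'
#' Composition of the pipeline stages: white-background filtering,
#' dense heatmap inference, decision map, contour extraction,
#' area-weighted class scores and softmax slide confidence. A slide
#' with no retained tissue (or whose contours contain no diagnostic
#' class) raises a classification-failure error.
#'
#' @param model A trained `patch_classifier`.
#' @param image `height x width x 3` array, 0--255.
#' @param slide_id Identifier for reports.
#' @param roi_size,min_fraction Passed to [filter_background()].
#' @param manifest Optional precomputed `roi_manifest` (skips
#'   preprocessing).
#' @param keep_heatmap Attach the heatmap and decision map to the
#'   result (large; off by default).
#' @return A [wsi_confidence()] with additional elements `slide_id`,
#'   `contours` (the contour table) and, when requested, `heatmap` and
#'   `decision`.
#' @export
classify_slide <- function(model, image, slide_id = "slide",
                           roi_size = 2048, min_fraction = 0.1,
                           manifest = NULL, keep_heatmap = FALSE) {
  if (is.null(manifest)) {
    manifest <- filter_background(image, roi_size = roi_size,
                                  min_fraction = min_fraction,
                                  slide_id = slide_id)
  }
  if (nrow(manifest$rois) == 0) {
    stop("classification failure: no tissue ROIs retained on slide '",
         slide_id, "'", call. = FALSE)
  }
  h <- infer_heatmap(model, image, manifest)
  d <- decision_map(h)
  contours <- extract_contours(d, h)
  scores <- lapply(diagnostic_classes(), function(k) {
    class_score(contours[contours$label == k, , drop = FALSE])
  })
  conf <- wsi_confidence(scores)
  conf$slide_id <- slide_id
  conf$contours <- contours
  if (keep_heatmap) {
    conf$heatmap <- h
    conf$decision <- d
  }
  conf
}

#' Write a per-slide JSON report
#'
#' Records `P_k`, `Prob_k`, the predicted label, the derived binary
#' scores and the contour table.
#'
#' @param conf A [wsi_confidence()] (typically from [classify_slide()]).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_wsi_report <- function(conf, path) {
  stopifnot(inherits(conf, "wsi_confidence"))
  report <- list(
    slide_id = if (is.null(conf$slide_id)) NA else conf$slide_id,
    predicted_label = conf$predicted_label,
    P = as.list(conf$P),
    prob = as.list(conf$prob),
    n = conf$n,
    mibc_score = conf$mibc_score,
    high_grade_score = conf$high_grade_score,
    contours = if (is.null(conf$contours)) NULL else
      conf$contours[, c("label", "area", "mean_prob")]
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
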