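# Shared fixtures and independent oracles used across the suite.

# even-odd ray-casting point-in-polygon, written independently of the
# package's pracma-based test (boundary-inclusive within eps)
oracle_point_in_polygon <- function(px, py, vertices, eps = 1e-9) {
  n <- nrow(vertices)
  vapply(seq_along(px), function(i) {
    x <- px[i]
    y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
      x2 <- vertices[k, 1]; y2 <- vertices[k, 2]
      # boundary check on segment
      d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
      len2 <- (x2 - x1)^2 + (y2 - y1)^2
      if (len2 > 0 && d^2 <= eps * len2) {
        t <- ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / len2
        if (t >= -eps && t <= 1 + eps) return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xi) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

# exhaustive between-class-variance maximization (candidate thresholds
# need both classes occupied; single occupied bin falls back to it)
oracle_otsu <- function(hist) {
  total <- sum(hist)
  p <- hist / total
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:255) {
    if (sum(hist[seq_len(t + 1)]) == 0 || sum(hist[seq_len(t + 1)]) == total) next
    w0 <- sum(p[seq_len(t + 1)])
    w1 <- 1 - w0
    mu0 <- sum(p[seq_len(t + 1)] * (0:t)) / w0
    mu1 <- sum(p[(t + 2):256] * ((t + 1):255)) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      best_t <- t
    }
  }
  if (is.na(best_t)) best_t <- which(hist > 0)[1] - 1L
  as.integer(best_t)
}

# brute-force pairwise AUC with tie half-credit
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# small axis-aligned rectangle polygon helper
rect_poly <- function(label, x0, y0, w, h, tissue = NULL) {
  list(label = label, tissue = tissue,
       vertices = rbind(c(x0, y0), c(x0 + w, y0),
                        c(x0 + w, y0 + h), c(x0, y0 + h)))
}

# small slide spec used by several integration tests
small_spec <- function(wsi_label, seed) {
  synthetic_spec(width = 512, height = 512, wsi_label = wsi_label,
                 seed = seed, junction_spacing = 64,
                 slide_id = paste0("s", seed))
}

# independent slide-score oracle: recompute the decision map, find
# connected regions with igraph on the 8-neighbor grid graph, and apply
# the two printed formulas directly
oracle_class_scores <- function(h) {
  nr <- dim(h$probs)[1]
  nc <- dim(h$probs)[2]
  flat <- matrix(h$probs, nr * nc, 6)
  dec <- apply(flat, 1, which.max) - 1L
  dec[!as.vector(h$coverage)] <- -1L
  P <- stats::setNames(rep(NA_real_, 3), diagnostic_classes())
  for (k in 0:2) {
    cells <- which(dec == k)
    if (length(cells) == 0) next
    rr <- (cells - 1) %% nr + 1
    cc <- (cells - 1) %/% nr + 1
    edges <- integer(0)
    for (i in seq_along(cells)) {
      for (j in seq_along(cells)) {
        if (i < j && abs(rr[i] - rr[j]) <= 1 && abs(cc[i] - cc[j]) <= 1) {
          edges <- c(edges, i, j)
        }
      }
    }
    g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    a <- as.vector(table(comp))
    p <- vapply(seq_len(max(comp)), function(m) {
      mean(flat[cells[comp == m], k + 1])
    }, numeric(1))
    P[k + 1] <- sum(a * p) / sum(a)
  }
  P
}


# a small trained classifier shared across integration tests (built on
# first use; 6 slides at 512 px, short schedule)
tiny_model <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      specs <- cohort_specs(
        c(2, 2, 2),
        synthetic_spec(width = 512, height = 512, junction_spacing = 64),
        seed = 314)
      cfg <- train_config(epochs = 10, milestones = c(7, 9), seed = 314,
                          batch_size = 32,
                          augmentations = c("flipping", "rotation"))
      cached <<- train_from_specs(specs, cfg, patch_size = 64,
                                  split_seed = 314)
    }
    cached
  }
})
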