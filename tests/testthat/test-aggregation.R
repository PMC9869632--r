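make_heatmap <- function(decision, prob_value = 0.8) {
  nr <- nrow(decision)
  nc <- ncol(decision)
  probs <- array(0, c(nr, nc, 6))
  cov <- decision >= 0
  rest <- (1 - prob_value) / 5
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (decision[r, c] < 0) next
      probs[r, c, ] <- rest
      probs[r, c, decision[r, c] + 1] <- prob_value
    }
  }
  heatmap_raster(probs, cov, nc * 32, nr * 32)
}

test_that("contours are 8-connected components with per-class stats", {
  d <- matrix(-1L, 5, 6)
  d[2, 2:4] <- 2L
  d[3, 3:4] <- 2L
  d[1, 6] <- 2L            # separate component, same class
  d[5, 1] <- 4L
  h <- make_heatmap(d, prob_value = 0.8)
  ct <- extract_contours(decision_map(h), h)
  lg <- ct[ct$label == "LGNMI", ]
  expect_equal(nrow(lg), 2)
  expect_equal(sort(lg$area), c(1, 5))
  expect_true(all(abs(lg$mean_prob - 0.8) < 1e-12))
  expect_equal(ct$area[ct$label == "NIA"], 1)

  # diagonal touch merges under 8-connectivity
  dd <- matrix(-1L, 4, 4)
  dd[1, 1] <- 0L
  dd[2, 2] <- 0L
  hh <- make_heatmap(dd)
  cc <- extract_contours(decision_map(hh), hh)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$area, 2)

  # empty map
  he <- make_heatmap(matrix(-1L, 3, 3))
  expect_equal(nrow(extract_contours(decision_map(he), he)), 0)
})

test_that("class scores are area-weighted means", {
  one <- data.frame(label = "HGMI", channel = 0L, contour = 1L,
                    area = 4L, mean_prob = 0.7)
  expect_equal(class_score(one)$P, 0.7)

  two <- data.frame(label = c("HGMI", "HGMI"), channel = 0L,
                    contour = 1:2, area = c(2L, 3L),
                    mean_prob = c(0.5, 1.0))
  s <- class_score(two)
  expect_equal(s$P, (2 * 0.5 + 3 * 1.0) / 5)   # 0.8 by hand
  expect_equal(s$m, 2)
  expect_gte(s$P, min(two$mean_prob))
  expect_lte(s$P, max(two$mean_prob))

  none <- class_score(two[0, ])
  expect_equal(none$m, 0)
  expect_true(is.na(none$P))

  mixed <- data.frame(label = c("HGMI", "NIA"), channel = c(0L, 4L),
                      contour = 1:2, area = 1L, mean_prob = 0.5)
  expect_error(class_score(mixed), "one class")
})

test_that("P_k is invariant under splitting a contour", {
  set.seed(33)
  for (trial in 1:20) {
    m <- sample(1:5, 1)
    areas <- sample(1:50, m, replace = TRUE)
    probs <- runif(m)
    ct <- data.frame(label = "HGNMI", channel = 1L, contour = seq_len(m),
                     area = areas, mean_prob = probs)
    p_full <- class_score(ct)$P
    # split the largest contour into two parts with the same pointwise
    # mean
    i <- which.max(areas)
    a1 <- sample(seq_len(areas[i]), 1)
    split <- rbind(ct[-i, ],
                   data.frame(label = "HGNMI", channel = 1L,
                              contour = m + 1:2,
                              area = c(a1, areas[i] - a1 + 1) - c(0, 1),
                              mean_prob = probs[i]))
    split <- split[split$area > 0, ]
    expect_equal(class_score(split)$P, p_full, tolerance = 1e-12)
  }
})

test_that("wsi confidence is the softmax over defined classes", {
  conf <- wsi_confidence(c(HGMI = 0.9, HGNMI = 0.5, LGNMI = 0.1))
  e <- exp(c(0.9, 0.5, 0.1))
  expect_equal(unname(conf$prob), e / sum(e), tolerance = 1e-12)
  expect_equal(unname(conf$prob), c(0.4718, 0.3163, 0.2120),
               tolerance = 5e-4)
  expect_equal(conf$predicted_label, "HGMI")
  expect_equal(conf$n, 3)
  expect_equal(sum(conf$prob), 1, tolerance = 1e-9)
  expect_equal(conf$mibc_score, conf$prob[["HGMI"]])
  expect_equal(conf$high_grade_score,
               conf$prob[["HGMI"]] + conf$prob[["HGNMI"]])

  eq <- wsi_confidence(c(HGMI = 0.4, HGNMI = 0.4, LGNMI = 0.4))
  expect_equal(unname(eq$prob), rep(1 / 3, 3), tolerance = 1e-12)

  only <- wsi_confidence(c(HGMI = 0.7, HGNMI = NA, LGNMI = NA))
  expect_equal(unname(only$prob), c(1, 0, 0))
  expect_equal(only$predicted_label, "HGMI")
  expect_equal(only$mibc_score, 1)
  expect_equal(only$n, 1)

  expect_error(wsi_confidence(c(HGMI = NA, HGNMI = NA, LGNMI = NA)),
               "classification failure")

  # softmax preserves the ordering of P
  set.seed(9)
  for (i in 1:20) {
    P <- runif(3)
    names(P) <- diagnostic_classes()
    cf <- wsi_confidence(P)
    expect_equal(order(cf$prob), order(P))
  }
})

test_that("classify_slide composes the stages and is deterministic", {
  s <- generate_slide(small_spec("LGNMI", 41))
  model <- tiny_model()
  c1 <- classify_slide(model, s$image, slide_id = "x", roi_size = 512)
  c2 <- classify_slide(model, s$image, slide_id = "x", roi_size = 512)
  expect_equal(c1$P, c2$P)
  expect_equal(c1$prob, c2$prob)
  expect_s3_class(c1, "wsi_confidence")
  expect_true(c1$predicted_label %in% diagnostic_classes())
  expect_true(is.data.frame(c1$contours))

  white <- array(248, c(512, 512, 3)) +
    array(wsipath:::local_seed(2, rnorm(512 * 512 * 3, sd = 3)),
          c(512, 512, 3))
  expect_error(classify_slide(model, white, roi_size = 512),
               "classification failure")
})

test_that("slide scores recompute from the persisted heatmap", {
  skip_if_not_installed("igraph")
  s <- generate_slide(small_spec("HGMI", 61))
  model <- init_classifier(64, seed = 8)
  hm <- infer_heatmap(model, s$image,
                      filter_background(s$image, roi_size = 512))
  path <- withr::local_tempfile(fileext = ".tif")
  write_heatmap(hm, path)
  back <- read_heatmap(path)

  # pipeline side, from the same persisted values
  d <- decision_map(back)
  ct <- extract_contours(d, back)
  P_pipe <- vapply(diagnostic_classes(), function(k) {
    class_score(ct[ct$label == k, , drop = FALSE])$P
  }, numeric(1))

  # independent brute force: igraph components on the 8-neighbor grid
  P_oracle <- oracle_class_scores(back)
  expect_equal(is.na(P_pipe), is.na(P_oracle))
  defined <- !is.na(P_oracle)
  expect_equal(P_pipe[defined], P_oracle[defined], tolerance = 1e-9)
  if (any(defined)) {
    prob_oracle <- exp(P_oracle[defined]) / sum(exp(P_oracle[defined]))
    conf2 <- wsi_confidence(P_pipe)
    expect_equal(conf2$prob[names(prob_oracle)], prob_oracle,
                 tolerance = 1e-9)
  }
})
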