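test_that("slide generation is deterministic and labeled by layout", {
  s1 <- generate_slide(small_spec("HGMI", 21))
  s2 <- generate_slide(small_spec("HGMI", 21))
  expect_identical(s1$image, s2$image)
  expect_equal(s1$wsi_label, "HGMI")
  expect_gt(nrow(s1$junction_points), 0)
  # junction points sit on the shared tumour-muscle borders
  lay <- s1$annotations$polygons
  tumour <- Filter(function(p) identical(p$tissue, "tumour"), lay)[[1]]
  xs <- range(tumour$vertices[, 1])
  expect_true(all(s1$junction_points[, 1] %in% xs))

  s3 <- generate_slide(small_spec("LGNMI", 22))
  expect_equal(s3$wsi_label, "LGNMI")
  expect_equal(nrow(s3$junction_points), 0)
  expect_true(any(vapply(s3$annotations$polygons,
                         function(p) p$label == "LGNMI", logical(1))))

  s4 <- generate_slide(small_spec("HGNMI", 23))
  expect_equal(s4$wsi_label, "HGNMI")
  expect_equal(nrow(s4$junction_points), 0)
})

test_that("background is near-white and regions are textured", {
  s <- generate_slide(small_spec("HGNMI", 31))
  mask <- rasterize_labels(s$annotations, 1)
  bg <- wsipath:::rgb_to_gray(s$image)[mask == -1]
  expect_gt(mean(bg), 240)
  tumour <- wsipath:::rgb_to_gray(s$image)[mask == label_channel("HGNMI")]
  expect_lt(mean(tumour), 220)
})

test_that("mixed-grade and detached-muscle layouts are rejected", {
  bad <- data.frame(role = c("tumour_hg", "tumour_lg"),
                    x0 = c(0, 300), y0 = c(0, 300), w = 100, h = 100)
  expect_error(synthetic_spec(width = 512, height = 512, layout = bad),
               "high-grade and low-grade")
  detached <- data.frame(role = c("tumour_hg", "muscle"),
                         x0 = c(0, 300), y0 = c(0, 300), w = 100, h = 100)
  expect_error(synthetic_spec(width = 512, height = 512,
                              layout = detached), "abut")
})

test_that("junction points are spaced along shared borders", {
  ann <- annotation_set("j", 2048, 2048, polygons = list(
    rect_poly("HGMI", 0, 0, 512, 1024, tissue = "tumour"),
    rect_poly("HGMI", 512, 0, 512, 1024, tissue = "muscle")))
  pts <- junction_points(ann, spacing = 256)
  expect_equal(nrow(pts), 4)  # 1024 / 256 segments
  expect_true(all(pts[, 1] == 512))
  expect_equal(sort(pts[, 2]), c(128, 384, 640, 896))

  # disjoint regions -> no junction
  far <- annotation_set("j", 2048, 2048, polygons = list(
    rect_poly("HGMI", 0, 0, 512, 1024, tissue = "tumour"),
    rect_poly("HGMI", 612, 0, 512, 1024, tissue = "muscle")))
  expect_equal(nrow(junction_points(far, 256)), 0)

  # spacing larger than the border -> single midpoint
  pts1 <- junction_points(ann, spacing = 4096)
  expect_equal(nrow(pts1), 1)
  expect_equal(unname(pts1[1, ]), c(512, 512))

  expect_error(junction_points(ann, spacing = 0), "positive")
})

test_that("cohorts have exact counts, derived seeds and determinism", {
  base <- synthetic_spec(width = 512, height = 512)
  specs <- cohort_specs(c(2, 1, 3), base, seed = 5)
  expect_length(specs, 6)
  expect_equal(vapply(specs, function(s) s$wsi_label, character(1)),
               c("HGMI", "HGMI", "HGNMI", "LGNMI", "LGNMI", "LGNMI"))
  expect_length(cohort_specs(c(0, 0, 1), base, seed = 5), 1)
  c1 <- generate_cohort(c(1, 0, 1), base, seed = 9)
  c2 <- generate_cohort(c(1, 0, 1), base, seed = 9)
  expect_identical(lapply(c1, `[[`, "image"), lapply(c2, `[[`, "image"))
})

test_that("the six textures are 1-NN separable on simple features", {
  skip_if_not_installed("class")
  pspec <- patch_spec(size = 64, stride = 32)
  feats <- list()
  labs <- character(0)
  per_class <- 100
  seeds <- list(HGMI = c(101, 102, 103, 108),
                HGNMI = c(104, 105, 109, 111),
                LGNMI = c(106, 107, 110, 112))
  for (lab in names(seeds)) {
    for (sd in seeds[[lab]]) {
      s <- generate_slide(small_spec(lab, sd))
      pt <- sample_slide_patches(s$annotations, pspec,
                                 junction_spacing = 16)
      for (i in seq_len(nrow(pt))) {
        cls <- pt$label[i]
        if (sum(labs == cls) >= per_class) next
        p <- extract_patch(s$image, pt$x0[i], pt$y0[i], 64)
        g <- wsipath:::rgb_to_gray(p)
        feats[[length(feats) + 1]] <- c(
          mean(p[, , 1]), mean(p[, , 2]), mean(p[, , 3]),
          stats::sd(g), mean(g < 150))
        labs <- c(labs, cls)
      }
    }
  }
  counts <- table(labs)
  expect_true(all(counts[label_classes()$code] == per_class))
  x <- scale(do.call(rbind, feats))
  idx_train <- unlist(lapply(unique(labs), function(cls) {
    w <- which(labs == cls)
    w[seq_len(floor(length(w) / 2))]
  }))
  idx_test <- setdiff(seq_along(labs), idx_train)
  pred <- class::knn(x[idx_train, ], x[idx_test, ], labs[idx_train],
                     k = 1)
  expect_gte(mean(pred == labs[idx_test]), 0.9)
})

test_that("cohorts round-trip through the on-disk index", {
  dir <- withr::local_tempdir()
  base <- synthetic_spec(width = 512, height = 512)
  index_path <- write_cohort(cohort_specs(c(1, 1, 0), base, seed = 3),
                             dir)
  index <- utils::read.delim(index_path, stringsAsFactors = FALSE)
  expect_equal(nrow(index), 2)
  expect_true(all(file.exists(index$image)))
  img <- read_slide_image(index$image[1])
  slide <- generate_slide(cohort_specs(c(1, 1, 0), base, seed = 3)[[1]])
  expect_equal(img, slide$image)  # PNG round-trip is exact for 8-bit
  ann <- read_annotations(index$annotations[1])
  expect_equal(ann$wsi_label, index$wsi_label[1])
})
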