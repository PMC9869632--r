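test_that("sliding windows enumerate fully contained grid rectangles", {
  ann <- annotation_set("s", 256, 256, polygons = list(
    rect_poly("HGNMI", 0, 0, 100, 100)))
  p32 <- sliding_window_patches(ann, "HGNMI", patch_spec(32, 32))
  expect_equal(nrow(p32), 9)
  expect_equal(sort(unique(p32$x0)), c(0, 32, 64))
  expect_equal(sort(unique(p32$y0)), c(0, 32, 64))

  p16 <- sliding_window_patches(ann, "HGNMI", patch_spec(32, 16))
  expect_equal(nrow(p16), 25)
  expect_equal(sort(unique(p16$x0)), c(0, 16, 32, 48, 64))

  tiny <- annotation_set("s", 256, 256, polygons = list(
    rect_poly("NIA", 0, 0, 20, 20)))
  expect_equal(nrow(sliding_window_patches(tiny, "NIA",
                                           patch_spec(32, 32))), 0)

  expect_error(sliding_window_patches(ann, "HGMI", patch_spec(32, 32)),
               "point_patches")
})

test_that("sliding-window counts match the closed-form grid count", {
  spec_cases <- expand.grid(w = c(96, 150, 257), hgt = c(100, 200),
                            size = c(32, 64), stride = c(32, 48))
  for (i in seq_len(nrow(spec_cases))) {
    cs <- spec_cases[i, ]
    ann <- annotation_set("s", 1024, 1024, polygons = list(
      rect_poly("LGNMI", 10, 20, cs$w, cs$hgt)))
    got <- nrow(sliding_window_patches(
      ann, "LGNMI", patch_spec(cs$size, cs$stride)))
    nx <- if (cs$w >= cs$size) floor((cs$w - cs$size) / cs$stride) + 1
      else 0
    ny <- if (cs$hgt >= cs$size) floor((cs$hgt - cs$size) / cs$stride) + 1
      else 0
    expect_equal(got, nx * ny)
  }
})

test_that("every sliding-window patch passes the containment oracle", {
  set.seed(5)
  for (trial in 1:6) {
    cx <- runif(1, 150, 350)
    cy <- runif(1, 150, 350)
    ang <- sort(runif(sample(5:8, 1), 0, 2 * pi))
    r <- runif(length(ang), 60, 140)
    poly <- list(label = "IA", tissue = NULL,
                 vertices = cbind(cx + r * cos(ang), cy + r * sin(ang)))
    ann <- annotation_set("s", 512, 512, polygons = list(poly))
    pt <- sliding_window_patches(ann, "IA", patch_spec(32, 32))
    for (i in seq_len(nrow(pt))) {
      xs <- c(pt$x0[i], pt$x0[i] + 32, pt$x0[i] + 32, pt$x0[i],
              pt$x0[i] + 16)
      ys <- c(pt$y0[i], pt$y0[i], pt$y0[i] + 32, pt$y0[i] + 32,
              pt$y0[i] + 16)
      expect_true(all(oracle_point_in_polygon(xs, ys, poly$vertices)))
    }
    expect_true(all(pt$x0 >= 0 & pt$x0 + pt$size <= 512))
    expect_true(all(pt$y0 >= 0 & pt$y0 + pt$size <= 512))
  }
})

test_that("point patches are centered, clamped, and keep duplicates", {
  spec <- patch_spec(size = 256)
  pts <- rbind(c(500, 600), c(800, 900), c(1000, 1000))
  pp <- point_patches(pts, spec, c(2048, 2048))
  expect_equal(nrow(pp), 3)
  expect_equal(pp$x0, c(372, 672, 872))
  expect_equal(pp$y0, c(472, 772, 872))
  expect_true(all(pp$label == "HGMI"))

  edge <- point_patches(rbind(c(0, 0)), spec, c(2048, 2048))
  expect_equal(c(edge$x0, edge$y0), c(0, 0))

  dup <- point_patches(rbind(c(500, 500), c(500, 500)), spec,
                       c(2048, 2048))
  expect_equal(nrow(dup), 2)
  expect_equal(dup$x0[1], dup$x0[2])

  expect_equal(nrow(point_patches(matrix(numeric(0), ncol = 2), spec,
                                  c(2048, 2048))), 0)
  expect_error(point_patches(rbind(c(-5, 10)), spec, c(2048, 2048)),
               "within bounds")
})

test_that("slide splits are stratified, disjoint and deterministic", {
  ids <- sprintf("s%03d", 1:100)
  strata <- rep(diagnostic_classes(), c(40, 30, 30))
  sp <- split_slides(ids, c(4, 1), seed = 7, strata = strata)
  expect_length(sp$train, 80)
  expect_length(sp$val, 20)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  for (s in unique(strata)) {
    in_val <- sum(ids[strata == s] %in% sp$val)
    expect_equal(in_val, round(sum(strata == s) / 5))
  }
  sp2 <- split_slides(ids, c(4, 1), seed = 7, strata = strata)
  expect_identical(sp, sp2)

  one <- split_slides(sprintf("t%d", 1:10), c(4, 1), seed = 1,
                      strata = rep("HGMI", 10))
  expect_length(one$train, 8)
  expect_length(one$val, 2)

  expect_error(split_slides(ids, c(4, 1), 1, rep("bladder", 100)),
               "unknown stratum")
})

test_that("patch tables round-trip through the text format", {
  ann <- annotation_set("sl", 256, 256, polygons = list(
    rect_poly("NA", 0, 0, 100, 100)))
  pt <- sliding_window_patches(ann, "NA", patch_spec(32, 32))
  path <- withr::local_tempfile(fileext = ".txt")
  write_patches(pt, path)
  back <- read_patches(path)
  expect_equal(back[, c("slide_id", "x0", "y0", "size", "label")],
               pt[, c("slide_id", "x0", "y0", "size", "label")])
})

test_that("extract_patch honors bounds and magnification level", {
  img <- array(seq_len(64 * 64 * 3), c(64, 64, 3))
  p <- extract_patch(img, 8, 16, 32)
  expect_equal(dim(p), c(32, 32, 3))
  expect_equal(p[1, 1, 1], img[17, 9, 1])
  expect_error(extract_patch(img, 40, 40, 32), "bounds")
  lv <- extract_patch(img, 0, 0, 16, level = 2)
  expect_equal(dim(lv), c(16, 16, 3))
  expect_equal(lv[1, 1, 1], mean(img[1:2, 1:2, 1]))
})
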