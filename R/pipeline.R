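# End-to-end pipeline on a synthetic cohort: generate, preprocess,
# sample, train, infer, aggregate, evaluate. Slides are realized one at
# a time to keep memory flat (a 2048 px slide is ~100 MB).

#' Train a classifier from synthetic slide specs
#'
#' Realizes each training slide, samples its labeled patches (sliding
#' windows for the five region-pure classes, junction points for HGMI),
#' pools them into a patch dataset and trains the reference network.
#' The slide list is split 4:1 into fit and tune subsets, stratified by
#' slide category.
#'
#' @param specs List of [synthetic_spec()] for the training slides.
#' @param cfg A [train_config()].
#' @param patch_size Patch side in pixels (multiple of 32).
#' @param split_seed Seed of the stratified 4:1 fit/tune split.
#' @param verbose Print progress.
#' @return A trained `patch_classifier`.
#' @export
train_from_specs <- function(specs, cfg = train_config(),
                             patch_size = 256, split_seed = 1,
                             verbose = FALSE) {
  pspec <- patch_spec(size = patch_size, stride = patch_size)
  ids <- vapply(specs, function(s) s$slide_id, character(1))
  labels <- vapply(specs, function(s) s$wsi_label, character(1))
  split <- split_slides(ids, ratio = c(4, 1), seed = split_seed,
                        strata = labels)
  harvest <- function(subset_ids) {
    xs <- list()
    ys <- list()
    for (s in specs[ids %in% subset_ids]) {
      slide <- generate_slide(s)
      patches <- sample_slide_patches(slide$annotations, pspec,
                                      junction_spacing =
                                        s$junction_spacing)
      if (nrow(patches) == 0) next
      ds <- build_patch_dataset(patches,
                                function(id) slide$image)
      xs[[length(xs) + 1]] <- ds$x
      ys[[length(ys) + 1]] <- ds$y
      if (verbose) {
        message(sprintf("  sampled %3d patches from %s (%s)",
                        nrow(patches), s$slide_id, s$wsi_label))
      }
    }
    if (length(xs) == 0) return(NULL)
    structure(list(x = do.call(cbind, xs), y = unlist(ys),
                   size = as.integer(patch_size)),
              class = "patch_dataset")
  }
  if (verbose) message("collecting fit patches ...")
  fit <- harvest(split$train)
  if (verbose) message("collecting tune patches ...")
  tune <- harvest(split$val)
  if (verbose) {
    message(sprintf("training on %d patches (%d tune) ...",
                    ncol(fit$x), ncol(tune$x)))
  }
  train_classifier(fit, tune, cfg)
}

#' Run the full pipeline on a seeded synthetic cohort
#'
#' Generates a training cohort and a test cohort, trains the reference
#' classifier with the published recipe, classifies every test slide
#' (preprocess, dense inference, contour aggregation) and evaluates the
#' slide-level predictions.
#'
#' @param seed Master seed; cohort seeds, the fit/tune split and the
#'   training seed are derived from it.
#' @param n_train,n_test Slides per diagnostic class (HGMI, HGNMI,
#'   LGNMI) in the training and test cohorts.
#' @param width,height Slide dimensions in pixels.
#' @param patch_size Patch side in pixels.
#' @param epochs Training epochs (`NULL` = the full 30-epoch recipe).
#' @param verbose Print progress.
#' @return List with `model`, `report` (an `eval_report`),
#'   `predictions` (list of [wsi_confidence()]), `truth` and
#'   `predicted` label vectors.
#' @export
run_end_to_end <- function(seed = 1, n_train = c(20, 20, 20),
                           n_test = c(10, 10, 10),
                           width = 2048, height = 2048,
                           patch_size = 256, epochs = NULL,
                           verbose = FALSE) {
  seeds <- local_seed(seed, sample.int(.Machine$integer.max, 4))
  base <- synthetic_spec(width = width, height = height)
  cfg <- if (is.null(epochs)) {
    train_config(seed = seeds[3])
  } else {
    train_config(seed = seeds[3], epochs = epochs,
                 milestones = intersect(c(18, 24), seq_len(epochs)))
  }
  train_specs <- cohort_specs(n_train, base, seed = seeds[1])
  model <- train_from_specs(train_specs, cfg, patch_size = patch_size,
                            split_seed = seeds[4], verbose = verbose)
  test_specs <- cohort_specs(n_test, base, seed = seeds[2])
  preds <- vector("list", length(test_specs))
  truth <- character(length(test_specs))
  for (i in seq_along(test_specs)) {
    slide <- generate_slide(test_specs[i][[1]])
    truth[i] <- slide$wsi_label
    preds[[i]] <- classify_slide(model, slide$image,
                                 slide_id = slide$spec$slide_id)
    if (verbose) {
      message(sprintf("  %s: truth %s, predicted %s",
                      slide$spec$slide_id, truth[i],
                      preds[[i]]$predicted_label))
    }
  }
  report <- evaluate_wsi(preds, truth)
  list(model = model, report = report, predictions = preds,
       truth = truth,
       predicted = vapply(preds, function(p) p$predicted_label,
                          character(1)))
}
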