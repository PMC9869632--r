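# Six-class probabilistic patch classifier: training configuration,
# augmentation, the reference network trainer and prediction.

#' Training configuration
#'
#' The published optimization recipe: SGD with momentum 0.9 and weight
#' decay 1e-4, cross-entropy loss, initial learning rate 0.01 multiplied
#' by 0.1 at the 18th and 24th epochs, 30 epochs in total. Milestones
#' are 1-based epoch numbers and a drop takes effect at that epoch.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_factor Multiplicative decay at each milestone.
#' @param milestones Integer epochs at which the rate drops.
#' @param epochs Total training epochs.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on weights (not biases).
#' @param batch_size Patches per batch.
#' @param seed Seed fixing initialization, batch order and augmentation.
#' @param augmentations Character subset of `translation`, `rotation`,
#'   `scaling`, `flipping`, `colour_jitter`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, lr_factor = 0.1,
                         milestones = c(18L, 24L), epochs = 30L,
                         momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 64L, seed = 1L,
                         augmentations = c("translation", "rotation",
                                           "scaling", "flipping",
                                           "colour_jitter")) {
  stopifnot(initial_lr > 0, lr_factor > 0, epochs >= 1,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1)
  if (length(milestones) > 0 &&
      (any(milestones < 1) || any(milestones > epochs))) {
    stop("milestones must lie in [1, epochs]", call. = FALSE)
  }
  known <- c("translation", "rotation", "scaling", "flipping",
             "colour_jitter")
  bad <- setdiff(augmentations, known)
  if (length(bad) > 0) {
    stop("unknown augmentation family: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 milestones = sort(as.integer(milestones)),
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augmentations = augmentations),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `initial_lr * lr_factor ^ (number of milestones <= epoch)`.
#'
#' @param epoch 1-based epoch number, within `[1, cfg$epochs]`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' learning_rate(1, train_config())   # 0.01
#' learning_rate(18, train_config())  # 0.001
#' learning_rate(24, train_config())  # 0.0001
learning_rate <- function(epoch, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(epoch) != 1 || epoch < 1 || epoch > cfg$epochs ||
      epoch != round(epoch)) {
    stop("epoch must be an integer in [1, ", cfg$epochs, "]",
         call. = FALSE)
  }
  cfg$initial_lr * cfg$lr_factor^sum(cfg$milestones <= epoch)
}

flip_patch <- function(patch, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) patch <- patch[, rev(seq_len(dim(patch)[2])), ,
                                 drop = FALSE]
  if (vertical) patch <- patch[rev(seq_len(dim(patch)[1])), , ,
                               drop = FALSE]
  patch
}

rotate90_patch <- function(patch, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    patch <- aperm(patch, c(2, 1, 3))[, rev(seq_len(dim(patch)[1])), ,
                                      drop = FALSE]
  }
  patch
}

shift_patch <- function(patch, dx, dy) {
  h <- dim(patch)[1]
  w <- dim(patch)[2]
  patch[clamp(seq_len(h) - dy, 1, h), clamp(seq_len(w) - dx, 1, w), ,
        drop = FALSE]
}

scale_patch <- function(patch, s) {
  h <- dim(patch)[1]
  w <- dim(patch)[2]
  nh <- max(2L, round(h * s))
  nw <- max(2L, round(w * s))
  resized <- EBImage::resize(patch, w = nh, h = nw)
  r0 <- floor((nh - h) / 2)
  c0 <- floor((nw - w) / 2)
  resized[clamp(r0 + seq_len(h), 1, nh), clamp(c0 + seq_len(w), 1, nw), ,
          drop = FALSE]
}

#' Randomly augment a patch
#'
#' Applies one independently sampled transform from each enabled family
#' (translation up to 10% of the side with edge replication, quarter-
#' turn rotation, scaling in 0.9--1.1 with center crop/pad, horizontal
#' and vertical flips, and colour jitter as per-channel gain 0.95--1.05
#' plus a brightness offset of up to 8 intensity units). The output
#' has the same shape; randomness comes from the active RNG stream, so
#' the result is deterministic for a fixed RNG state. With no enabled
#' families the patch is returned unchanged.
#'
#' @param patch Square `h x h x 3` RGB array, 0--255 (internally the
#'   trainer also passes 6-channel block-statistic rasters; extra
#'   channels receive the geometric transforms and the jitter gain but
#'   not the brightness offset).
#' @param cfg A [train_config()]; `cfg$augmentations` selects families.
#' @return Augmented patch of the same shape.
#' @export
augment <- function(patch, cfg = train_config()) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[1] == dim(patch)[2])
  fams <- cfg$augmentations
  h <- dim(patch)[1]
  if ("translation" %in% fams) {
    r <- round(h * 0.1)
    patch <- shift_patch(patch, sample(seq(-r, r), 1),
                         sample(seq(-r, r), 1))
  }
  if ("rotation" %in% fams) {
    patch <- rotate90_patch(patch, sample(0:3, 1))
  }
  if ("scaling" %in% fams) {
    patch <- scale_patch(patch, stats::runif(1, 0.9, 1.1))
  }
  if ("flipping" %in% fams) {
    patch <- flip_patch(patch, stats::runif(1) < 0.5,
                        stats::runif(1) < 0.5)
  }
  if ("colour_jitter" %in% fams) {
    gains <- stats::runif(3, 0.95, 1.05)
    offset <- stats::runif(1, -8, 8)
    nch <- dim(patch)[3]
    for (ch in seq_len(nch)) {
      g <- gains[(ch - 1) %% 3 + 1]
      # channels beyond the first three hold block SDs: gain applies,
      # the brightness offset does not
      patch[, , ch] <- patch[, , ch] * g +
        if (ch <= 3) offset else 0
    }
    patch[, , 1:3] <- clamp(patch[, , 1:3], 0, 255)
    if (nch > 3) patch[, , -(1:3)] <- pmax(patch[, , -(1:3)], 0)
  }
  patch
}

#' Build a patch dataset from sampled patches
#'
#' Extracts each patch from its slide and reduces it to the network's
#' 32 x 32 x 6 input (block mean and block SD of each RGB channel at
#' stem factor `size / 32`), stored as one column of a feature matrix.
#' Patch size must be a multiple of 32.
#'
#' @param patches Data frame from the sampling functions (`slide_id`,
#'   `x0`, `y0`, `size`, `label`, optionally `level`).
#' @param images Either a named list of slide images or a function
#'   `function(slide_id)` returning the image array.
#' @return Object of class `patch_dataset`: list with `x`
#'   (`6144 x n` matrix of stem features), `y` (character labels),
#'   `size` (patch size).
#' @export
build_patch_dataset <- function(patches, images) {
  stopifnot(nrow(patches) > 0)
  size <- unique(patches$size)
  stopifnot(length(size) == 1)
  if (size %% NET_IN != 0) {
    stop("patch size must be a multiple of ", NET_IN, call. = FALSE)
  }
  level <- if ("level" %in% names(patches)) patches$level else
    rep(1L, nrow(patches))
  get_image <- if (is.function(images)) images else {
    function(id) images[[id]]
  }
  f <- size %/% NET_IN
  x <- matrix(0, NET_IN * NET_IN * NET_CH, nrow(patches))
  for (id in unique(patches$slide_id)) {
    img <- get_image(id)
    rows <- which(patches$slide_id == id)
    for (i in rows) {
      p <- extract_patch(img, patches$x0[i], patches$y0[i], size,
                         level[i])
      x[, i] <- stem_features(p, f)
    }
  }
  structure(list(x = x, y = patches$label, size = as.integer(size)),
            class = "patch_dataset")
}

# dataset columns back to a 32 x 32 x 6 array
dataset_patch <- function(ds, i) {
  array(ds$x[, i], c(NET_IN, NET_IN, NET_CH))
}

#' Initialize an untrained classifier
#'
#' Random weights with a fixed seed; useful as a stand-in model for
#' geometry and plumbing work (predictions are valid probabilities but
#' carry no signal).
#'
#' @param input_size Patch side in pixels; must be a multiple of 32.
#' @param seed Initialization seed.
#' @param cfg A [train_config()] stored with the model.
#' @return Object of class `patch_classifier`.
#' @export
init_classifier <- function(input_size = 256L, seed = 1L,
                            cfg = train_config(seed = seed)) {
  if (input_size %% NET_IN != 0) {
    stop("input_size must be a multiple of ", NET_IN, call. = FALSE)
  }
  structure(
    list(net = net_init(seed), input_size = as.integer(input_size),
         stem_factor = as.integer(input_size %/% NET_IN),
         classes = label_classes()$code, cfg = cfg, history = NULL),
    class = "patch_classifier"
  )
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf(
    "<patch_classifier> 6-class, input %d px (stem /%d)%s\n",
    x$input_size, x$stem_factor,
    if (is.null(x$history)) ", untrained" else
      sprintf(", trained %d epochs (final tune acc %.3f)",
              nrow(x$history), utils::tail(x$history$tune_acc, 1))))
  invisible(x)
}

#' Train the reference patch classifier
#'
#' Minimizes cross-entropy with SGD (momentum, weight decay, multistep
#' learning-rate schedule from `cfg`) for `cfg$epochs` epochs. Batches
#' are drawn class-uniformly (each slot samples a class uniformly, then
#' a patch of that class), which counters the scarcity of point-sampled
#' HGMI patches. Per-epoch train loss/accuracy and held-out tune
#' accuracy are recorded as learning curves in `$history`. Fully
#' deterministic for a fixed `cfg$seed`.
#'
#' @param train A [build_patch_dataset()] result containing at least one
#'   patch of every class.
#' @param tune Optional held-out `patch_dataset` for the tune-accuracy
#'   curve.
#' @param cfg A [train_config()].
#' @return A trained `patch_classifier` (final-epoch weights).
#' @export
train_classifier <- function(train, tune = NULL, cfg = train_config()) {
  stopifnot(inherits(train, "patch_dataset"),
            inherits(cfg, "train_config"))
  if (!is.null(tune) && (is.null(tune$x) || ncol(tune$x) == 0)) {
    tune <- NULL
  }
  classes <- label_classes()$code
  missing <- setdiff(classes, unique(train$y))
  if (length(missing) > 0) {
    stop("training data lack class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  geom <- net_geometry()
  y_all <- match(train$y, classes)
  cls_idx <- lapply(seq_along(classes), function(k) which(y_all == k))
  n <- ncol(train$x)
  n_batches <- max(1L, ceiling(n / cfg$batch_size))
  do_augment <- length(cfg$augmentations) > 0
  local_seed(cfg$seed, {
    net <- net_init(sample.int(.Machine$integer.max, 1))
    vel <- lapply(net, function(w) w * 0)
    history <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- learning_rate(epoch, cfg)
      loss_sum <- 0
      acc_sum <- 0
      for (b in seq_len(n_batches)) {
        ks <- sample.int(6L, cfg$batch_size, replace = TRUE)
        idx <- vapply(ks, function(k) {
          v <- cls_idx[[k]]
          v[sample.int(length(v), 1L)]
        }, integer(1))
        X <- train$x[, idx, drop = FALSE]
        if (do_augment) {
          for (j in seq_along(idx)) {
            X[, j] <- as.vector(augment(
              array(X[, j], c(NET_IN, NET_IN, NET_CH)), cfg))
          }
        }
        y <- y_all[idx]
        fw <- net_forward(net, X, geom, cache = TRUE)
        pr <- fw$probs[cbind(y, seq_along(y))]
        loss_sum <- loss_sum + mean(-log(pmax(pr, 1e-12)))
        acc_sum <- acc_sum + mean(max.col(t(fw$probs),
                                          ties.method = "first") == y)
        gr <- net_backward(net, fw, y, geom)
        for (nm in names(net)) {
          g <- gr[[nm]]
          if (nm %in% c("W1", "W2", "Wd")) {
            g <- g + cfg$weight_decay * net[[nm]]
          }
          vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * g
          net[[nm]] <- net[[nm]] + vel[[nm]]
        }
      }
      tune_acc <- NA_real_
      if (!is.null(tune)) {
        pred <- predict_pooled_net(net, tune$x, geom)
        tune_acc <- mean(classes[max.col(t(pred), ties.method = "first")]
                         == tune$y)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = loss_sum / n_batches,
        train_acc = acc_sum / n_batches, tune_acc = tune_acc)
    }
    structure(
      list(net = net, input_size = train$size,
           stem_factor = as.integer(train$size %/% NET_IN),
           classes = classes, cfg = cfg,
           history = do.call(rbind, history)),
      class = "patch_classifier"
    )
  })
}

# batched probabilities for pooled inputs (3072 x n), chunked to bound
# im2col memory
predict_pooled_net <- function(net, X, geom = net_geometry(),
                               chunk = 256L) {
  n <- ncol(X)
  out <- matrix(0, 6L, n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[, i:j] <- net_forward(net, X[, i:j, drop = FALSE], geom)
    i <- j + 1L
  }
  out
}

#' Classify one patch
#'
#' @param model A `patch_classifier`.
#' @param patch `size x size x 3` array (0--255) matching the model's
#'   configured input size.
#' @return Named probability vector over the six classes (sums to 1).
#' @export
predict_patch <- function(model, patch) {
  stopifnot(inherits(model, "patch_classifier"))
  d <- dim(patch)
  if (length(d) != 3 || d[1] != model$input_size ||
      d[2] != model$input_size || d[3] != 3) {
    stop("patch must be ", model$input_size, " x ", model$input_size,
         " x 3", call. = FALSE)
  }
  x <- stem_features(patch, model$stem_factor)
  p <- net_forward(model$net, matrix(x, ncol = 1))
  stats::setNames(as.vector(p), model$classes)
}

#' Save / load a classifier
#'
#' Single self-describing file (weights plus embedded configuration and
#' training history); a loaded model reproduces predictions bitwise.
#'
#' @param model A `patch_classifier`.
#' @param path File path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "patch_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "patch_classifier"))
  model
}

#' Write a training log as CSV
#'
#' Columns `epoch`, `lr`, `train_loss`, `train_acc`, `tune_acc`.
#'
#' @param model A trained `patch_classifier`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(model, path) {
  stopifnot(inherits(model, "patch_classifier"),
            !is.null(model$history))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
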