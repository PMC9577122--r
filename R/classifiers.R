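# One-vs-rest patch classifiers.
#
# Each of the four histologic classes gets its own binary classifier
# trained on a binary relabelling of the annotated patches (positives =
# target class, negatives = the union of the other three).  Batches are
# drawn with a weighted random sampler (per-example weight proportional to
# inverse class frequency), the loss is cross-entropy, and the learning
# rate decays exponentially per epoch.
#
# The desk-scale backbone ("small_cnn") is a seeded 3-conv-block network
# operating on a block-averaged, rescaled copy of the 224x224 patch; an
# 18-layer residual backbone is accepted as a configuration identifier but
# is not available in this build (no deep-learning framework in the
# supported stack).

#' Training configuration for the patch classifiers
#'
#' @param epochs Training epochs (default 100; desk tests use far fewer).
#' @param initial_lr Initial learning rate (default 0.005).
#' @param lr_decay_per_epoch Multiplicative decay applied each epoch
#'   (default 0.9): the learning rate at 0-based epoch `k` is
#'   `initial_lr * lr_decay_per_epoch^k`.
#' @param batch_size Minibatch size (default 64; not stated by the source
#'   method, configurable).
#' @param momentum SGD momentum (default 0.9).
#' @param val_slide_fraction Fraction of slides held out for per-epoch
#'   validation (default 0.1).
#' @param positive_threshold Probability threshold for the positive label;
#'   `p >= threshold` is positive (default 0.5).
#' @param seed Integer seed governing initialization, sampling and
#'   augmentation.
#' @param backbone `"small_cnn"` (available) or `"resnet18"` (identifier
#'   only; errors at train time in this build).
#' @param input_side Side of the backbone input after block-average
#'   downsampling; must divide the patch size and be a multiple of 4
#'   (default 28, i.e. 8x downsampling of a 224 patch).
#' @param channels Channel widths of the three conv blocks.
#' @param augment Apply seeded flip/rotation/colour-jitter augmentation to
#'   training batches (default TRUE).
#' @param jitter Colour-jitter factor half-width (default 0.1).
#' @return A `wsi_train_config` list.
#' @export
train_config <- function(epochs = 100L, initial_lr = 0.005,
                         lr_decay_per_epoch = 0.9, batch_size = 64L,
                         momentum = 0.9, val_slide_fraction = 0.1,
                         positive_threshold = 0.5, seed = 1L,
                         backbone = "small_cnn", input_side = 28L,
                         channels = c(8L, 16L, 32L), augment = TRUE,
                         jitter = 0.1) {
  assert_that(lr_decay_per_epoch > 0 && lr_decay_per_epoch <= 1,
              "lr_decay_per_epoch must lie in (0, 1]")
  assert_that(val_slide_fraction > 0 && val_slide_fraction < 1,
              "val_slide_fraction must lie in (0, 1)")
  assert_that(input_side %% 4L == 0L, "input_side must be a multiple of 4")
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_decay_per_epoch = lr_decay_per_epoch,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 val_slide_fraction = val_slide_fraction,
                 positive_threshold = positive_threshold,
                 seed = as.integer(seed), backbone = backbone,
                 input_side = as.integer(input_side),
                 channels = as.integer(channels), augment = augment,
                 jitter = jitter),
            class = "wsi_train_config")
}

#' Learning rate at a given epoch
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return `initial_lr * lr_decay_per_epoch^epoch`.
#' @export
lr_schedule <- function(epoch, config) {
  config$initial_lr * config$lr_decay_per_epoch^epoch
}

#' Slide-level train/validation split
#'
#' All patches of a slide fall on one side of the split.  The validation
#' set holds `max(1, round(fraction * n))` slides.
#'
#' @param slide_ids Character vector of slide ids (at least 2).
#' @param fraction Validation fraction (default 0.1).
#' @param seed Integer seed.
#' @return List with `train` and `val` id vectors (disjoint, exhaustive).
#' @export
split_train_validation <- function(slide_ids, fraction = 0.1, seed = 1L) {
  slide_ids <- unique(slide_ids)
  n <- length(slide_ids)
  assert_that(n >= 2, "need at least 2 slides to split")
  n_val <- max(1L, round(fraction * n))
  assert_that(n_val < n, "validation fraction leaves no training slides")
  with_seed(seed, {
    val <- sort(sample(slide_ids, n_val))
    list(train = setdiff(slide_ids, val), val = val)
  })
}

#' Class-balanced batch sampling indices
#'
#' Draws `n_batches` minibatches of indices with replacement, each example
#' weighted proportionally to the inverse frequency of its binary class, so
#' batches are balanced in expectation even under heavy imbalance.
#'
#' @param labels Logical or 0/1 vector (positive class membership).
#' @param batch_size Batch size.
#' @param n_batches Number of batches.
#' @return List of integer index vectors.  Draws from the current RNG
#'   stream (seed it with the caller's substream).
#' @export
balanced_batches <- function(labels, batch_size, n_batches) {
  labels <- as.logical(labels)
  n <- length(labels)
  n_pos <- sum(labels)
  assert_that(n_pos > 0 && n_pos < n, "both classes must be present")
  w <- ifelse(labels, 1 / n_pos, 1 / (n - n_pos))
  lapply(seq_len(n_batches), function(i) sample.int(n, batch_size, replace = TRUE, prob = w))
}

# --- prepared patch features -------------------------------------------------

# The backbone consumes a "prepared" patch: normalized colour, block-average
# downsampled to input_side, rescaled to roughly unit range.  Prepared sets
# are plain matrices (features x n) plus per-column metadata, so a training
# corpus of thousands of patches stays small in memory.

prepare_patch_array <- function(arr, input_side) {
  d <- dim(arr)
  assert_that(d[1] == d[2], "patch must be square")
  assert_that(d[1] %% input_side == 0, "input_side must divide the patch size")
  f <- d[1] %/% input_side
  small <- .block_mean(as.numeric(arr), d[1], d[2], 3L, f)
  # centre/scale to roughly unit variance (channel stats are pinned by the
  # colour normalizer, so fixed constants suffice)
  (small - 165) / 45
}

#' Convert patches into a prepared feature set for training/prediction
#'
#' Patches are colour-normalized ([normalize_patch()]), block-average
#' downsampled to the backbone input side and rescaled.
#'
#' @param patches List of `wsi_patch` objects.
#' @param input_side Backbone input side (see [train_config()]).
#' @return A `wsi_patch_set`: list with `x` (features x n matrix),
#'   `class` (annotation class per column), `slide_id`, and `input_side`.
#' @export
prepare_patches <- function(patches, input_side = 28L) {
  n <- length(patches)
  x <- matrix(0, nrow = 3L * input_side^2, ncol = n)
  cls <- character(n); sid <- character(n)
  for (i in seq_len(n)) {
    p <- patches[[i]]
    x[, i] <- prepare_patch_array(normalize_patch(p$pixels), input_side)
    cls[i] <- p$annotation_class %||% NA_character_
    sid[i] <- p$slide_id
  }
  structure(list(x = x, class = cls, slide_id = sid,
                 input_side = as.integer(input_side)),
            class = "wsi_patch_set")
}

init_weights <- function(channels, input_side) {
  # He-style Gaussian for conv layers, small Gaussian (sd 0.01) for the head
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  he <- function(nout, nin) matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
  list(W1 = he(c1, 9 * 3),  b1 = rep(0, c1),
       W2 = he(c2, 9 * c1), b2 = rep(0, c2),
       W3 = he(c3, 9 * c2), b3 = rep(0, c3),
       W4 = matrix(rnorm(2 * c3, sd = 0.01), nrow = 2), b4 = rep(0, 2))
}

binary_f1 <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Validation score: balanced accuracy (robust to skewed validation splits;
# classes absent from the split contribute nothing).
balanced_accuracy <- function(truth, pred) {
  parts <- c(if (any(truth)) mean(pred[truth]),
             if (any(!truth)) mean(!pred[!truth]))
  mean(parts)
}

# Seeded augmentation of a prepared (downsampled) patch column.  Flips and
# 90-degree rotations commute with block-average pooling, and the colour
# jitter is an affine map per channel, so augmenting in the downsampled
# space is equivalent to augmenting the full patch first (see vignette).
augment_prepared <- function(v, input_side, seed, jitter) {
  arr <- array(v, dim = c(input_side, input_side, 3L))
  as.numeric(augment_patch(arr, seed = seed, jitter = jitter))
}

#' Train a one-vs-rest binary patch classifier
#'
#' Trains the configured backbone with cross-entropy on the binary
#' relabelling (positives = `target_class`), class-balanced sampling,
#' SGD with momentum and an exponential per-epoch learning-rate decay.
#' Validation F1 is logged every epoch on a held-out slide split and the
#' best-epoch weights are kept.
#'
#' @param patches List of `wsi_patch` objects with `annotation_class` set,
#'   or a prepared `wsi_patch_set` from [prepare_patches()].
#' @param target_class One of [wsi_classes()].
#' @param config A [train_config()].
#' @return A `wsi_patch_model`: list with `target_class`, `weights`,
#'   `config`, `input_side`, `log` (data.frame `epoch`, `loss`,
#'   `val_metric`, `lr`) and `best_epoch`.
#' @export
train_binary_classifier <- function(patches, target_class, config = train_config()) {
  assert_that(target_class %in% wsi_classes(),
              paste("unknown target class:", target_class))
  if (config$backbone != "small_cnn")
    stop(sprintf("backbone '%s' is not available in this build; use 'small_cnn'",
                 config$backbone), call. = FALSE)
  set <- if (inherits(patches, "wsi_patch_set")) patches
         else prepare_patches(patches, config$input_side)
  keep <- !is.na(set$class)
  x <- set$x[, keep, drop = FALSE]
  cls <- set$class[keep]
  sid <- set$slide_id[keep]
  pos <- cls == target_class
  missing <- setdiff(wsi_classes(), unique(cls))
  if (!any(pos))
    stop(sprintf("no annotated patches of class '%s' in the training set", target_class),
         call. = FALSE)
  if (all(pos))
    stop(sprintf("no negative examples (all patches are '%s')", target_class),
         call. = FALSE)

  # held-out validation at slide level when possible; fall back to a
  # stratified patch-level split when the slide split loses a class
  slides <- unique(sid)
  val_idx <- NULL
  if (length(slides) >= 2) {
    sp <- split_train_validation(slides, config$val_slide_fraction,
                                 substream_seed(config$seed, "valsplit"))
    val_idx <- which(sid %in% sp$val)
    tr_idx <- which(sid %in% sp$train)
    if (length(val_idx) == 0 || !any(pos[tr_idx]) || all(pos[tr_idx]))
      val_idx <- NULL
  }
  if (is.null(val_idx)) {
    with_seed(substream_seed(config$seed, "valsplit"), {
      n <- length(pos)
      take <- function(ix) {
        k <- max(1L, round(config$val_slide_fraction * length(ix)))
        if (length(ix) <= 1) ix else sample(ix, k)
      }
      val_idx <- sort(c(take(which(pos)), take(which(!pos))))
      tr_idx <- setdiff(seq_len(n), val_idx)
    })
  }
  xt <- x[, tr_idx, drop = FALSE]; yt <- pos[tr_idx]
  xv <- x[, val_idx, drop = FALSE]; yv <- pos[val_idx]
  assert_that(any(yt) && !all(yt), "training split lost one of the classes")

  side <- set$input_side
  W <- with_seed(substream_seed(config$seed, "init"),
                 init_weights(config$channels, side))
  V <- lapply(W, function(w) w * 0)  # momentum buffers
  # epoch length under balanced sampling: enough draws that each class is
  # expected to be visited fully once per epoch
  n_batches <- max(1L, ceiling(2 * max(sum(yt), sum(!yt)) / config$batch_size))
  log_rows <- vector("list", config$epochs)
  best <- list(metric = -Inf, weights = W, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    batches <- with_seed(substream_seed(config$seed, paste0("sampler", epoch)),
                         balanced_batches(yt, config$batch_size, n_batches))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xb <- xt[, idx, drop = FALSE]
      if (config$augment) {
        aseed <- substream_seed(config$seed, sprintf("aug%d_%d", epoch, bi))
        for (j in seq_len(ncol(xb)))
          xb[, j] <- augment_prepared(xb[, j], side, aseed + j, config$jitter)
      }
      lg <- .cnn_loss_grad(W, xb, as.integer(yt[idx]), side, numeric(0))
      if (!is.finite(lg$loss))
        stop(sprintf("NaN/Inf loss at epoch %d batch %d (lr=%.4g); aborting",
                     epoch, bi, lr), call. = FALSE)
      ep_loss <- ep_loss + lg$loss
      for (nm in names(W)) {
        V[[nm]] <- config$momentum * V[[nm]] - lr * lg$grads[[nm]]
        W[[nm]] <- W[[nm]] + V[[nm]]
      }
    }
    pv <- .cnn_forward(W, xv, side)[2, ]
    val_acc <- balanced_accuracy(yv, pv >= config$positive_threshold)
    log_rows[[epoch + 1L]] <- data.frame(epoch = epoch,
                                         loss = ep_loss / n_batches,
                                         val_metric = val_acc, lr = lr)
    # >= : on plateaus prefer the later (longer-trained) checkpoint
    if (val_acc >= best$metric) best <- list(metric = val_acc, weights = W, epoch = epoch)
  }

  structure(list(target_class = target_class, weights = best$weights,
                 config = config, input_side = side,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch,
                 missing_classes = missing),
            class = "wsi_patch_model")
}

#' Predict the positive-class probability for patches
#'
#' Patches must be colour-normalized first (the prediction path applies the
#' same preparation as training).  Batched and single calls use the same
#' code path and agree exactly.
#'
#' @param model A `wsi_patch_model`.
#' @param patch A single `wsi_patch`/array, a list of them, or a prepared
#'   `wsi_patch_set`.
#' @param prepared Set TRUE when `patch` columns are already prepared
#'   feature vectors (internal use).
#' @return For a single patch, a list `(probability, binary_label)`;
#'   for a batch, a data.frame with columns `probability`, `binary_label`.
#' @export
predict_patch <- function(model, patch, prepared = FALSE) {
  stopifnot(inherits(model, "wsi_patch_model"))
  single <- FALSE
  if (inherits(patch, "wsi_patch_set")) {
    x <- patch$x
  } else if (prepared && is.matrix(patch)) {
    x <- patch
  } else {
    if (inherits(patch, "wsi_patch") || is.array(patch)) {
      patch <- list(patch)
      single <- TRUE
    }
    arrs <- lapply(patch, function(p) if (inherits(p, "wsi_patch")) p$pixels else p)
    for (a in arrs) {
      assert_rgb(a)
      if (dim(a)[1] != dim(a)[2] || dim(a)[1] %% model$input_side != 0)
        stop("patch shape incompatible with the model input", call. = FALSE)
    }
    x <- vapply(arrs, prepare_patch_array, numeric(3 * model$input_side^2),
                input_side = model$input_side)
    x <- matrix(x, nrow = 3 * model$input_side^2)
  }
  if (nrow(x) != 3 * model$input_side^2)
    stop("feature dimension mismatch", call. = FALSE)
  p <- .cnn_forward(model$weights, x, model$input_side)[2, ]
  lab <- p >= model$config$positive_threshold
  if (single) list(probability = p[1], binary_label = lab[1])
  else data.frame(probability = p, binary_label = lab)
}

#' Save a patch model as a single JSON checkpoint
#' @param model A `wsi_patch_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_patch_model <- function(model, path) {
  stopifnot(inherits(model, "wsi_patch_model"))
  payload <- list(target_class = model$target_class,
                  input_side = model$input_side,
                  best_epoch = model$best_epoch,
                  config = unclass(model$config),
                  weights = lapply(model$weights, function(w)
                    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                    else list(dim = length(w), data = as.numeric(w))),
                  log = model$log)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a patch model saved by [save_patch_model()]
#' @param path Checkpoint path.
#' @return A `wsi_patch_model`.
#' @export
load_patch_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, nrow = w$dim[1]) else as.numeric(w$data)
  })
  cfg <- p$config
  cfg$marker_hue_windows <- NULL
  config <- do.call(train_config, cfg[names(cfg) %in% names(formals(train_config))])
  structure(list(target_class = p$target_class, weights = weights,
                 config = config, input_side = as.integer(p$input_side),
                 log = as.data.frame(p$log), best_epoch = p$best_epoch,
                 missing_classes = character(0)),
            class = "wsi_patch_model")
}

#' Train the full four-classifier ensemble
#'
#' @param patches Patches or a prepared `wsi_patch_set` (see
#'   [train_binary_classifier()]); must contain all four classes.
#' @param config A [train_config()]; each class trains with a seed derived
#'   from `config$seed` and the class name.
#' @return Named list of four `wsi_patch_model`s in [wsi_classes()] order.
#' @export
train_classifier_ensemble <- function(patches, config = train_config()) {
  set <- if (inherits(patches, "wsi_patch_set")) patches
         else prepare_patches(patches, config$input_side)
  present <- unique(set$class[!is.na(set$class)])
  absent <- setdiff(wsi_classes(), present)
  if (length(absent) > 0)
    stop(paste("class absent from the training patches:",
               paste(absent, collapse = ", ")), call. = FALSE)
  models <- lapply(wsi_classes(), function(cl) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("train_", cl))
    train_binary_classifier(set, cl, cfg)
  })
  names(models) <- wsi_classes()
  models
}
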