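# One-vs-rest patch classifiers: splitting, sampling, schedule, training,
# prediction, serialization.

test_that("slide-level split is disjoint, exhaustive, sized and seeded", {
  ids <- sprintf("S%02d", 1:10)
  sp <- split_train_validation(ids, 0.1, seed = 4)
  expect_length(sp$val, 1)       # 10% of 10 whole-slide images
  expect_length(sp$train, 9)
  for (s in 1:50) {
    n <- sample(2:40, 1)
    idr <- sprintf("T%03d", seq_len(n))
    spl <- split_train_validation(idr, 0.2, seed = s)
    expect_length(intersect(spl$train, spl$val), 0)
    expect_setequal(c(spl$train, spl$val), idr)
  }
  expect_identical(split_train_validation(ids, 0.1, seed = 7),
                   split_train_validation(ids, 0.1, seed = 7))
  expect_error(split_train_validation("only_one", 0.1), "at least 2")
})

test_that("learning rate decays exponentially from 0.005 by 0.9 per epoch", {
  cfg <- train_config()
  for (k in 0:20)
    expect_lt(abs(lr_schedule(k, cfg) - 0.005 * 0.9^k), 1e-12)
  # and the training log records exactly that schedule
  log <- trained_high_grade_model()$log
  expect_lt(max(abs(log$lr - 0.005 * 0.9^log$epoch)), 1e-12)
})

test_that("balanced sampler yields ~50% positives under 1:9 imbalance", {
  labels <- rep(c(TRUE, FALSE), c(100, 900))
  set.seed(11)
  batches <- balanced_batches(labels, 64, 200)
  frac_pos <- mean(labels[unlist(batches)])
  expect_lt(abs(frac_pos - 0.5), 0.05)
  expect_error(balanced_batches(rep(TRUE, 5), 4, 1), "both classes")
})

test_that("each one-vs-rest task reaches 0.90 held-out patch accuracy", {
  # reduced-scale version of the full desk test (see acceptance suite for
  # the end-to-end slide-level criterion)
  tr <- train_patch_set()
  te <- test_patch_set()
  for (cl in wsi_classes()) {
    m <- train_binary_classifier(tr, cl, train_config(epochs = 10, seed = 42))
    pr <- predict_patch(m, te)
    expect_gte(mean((te$class == cl) == pr$binary_label), 0.90)
  }
})

test_that("training is reproducible given the seed and validates inputs", {
  tr <- train_patch_set()
  cfg <- train_config(epochs = 2, seed = 17)
  m1 <- train_binary_classifier(tr, "PUNLMP", cfg)
  m2 <- train_binary_classifier(tr, "PUNLMP", cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$log, m2$log)

  # absent classes are named in errors
  only_two <- tr
  keep <- only_two$class %in% c("PUNLMP", "low_grade")
  only_two$x <- only_two$x[, keep]; only_two$class <- only_two$class[keep]
  only_two$slide_id <- only_two$slide_id[keep]
  expect_error(train_binary_classifier(only_two, "invasive", cfg), "invasive")
  expect_error(train_classifier_ensemble(only_two, cfg), "invasive")
  expect_error(train_binary_classifier(tr, "stroma", cfg), "stroma")
  expect_error(train_binary_classifier(tr, "PUNLMP",
                                       train_config(backbone = "resnet18")),
               "not available")
})

test_that("identical textures across classes give chance-level validation", {
  # guards against label leakage: relabel one class's patches randomly
  base <- single_class_patches(4, 303)
  base <- Filter(function(p) p$annotation_class == "low_grade", base)
  set.seed(21)
  for (i in seq_along(base)) {
    base[[i]]$annotation_class <- sample(c("PUNLMP", "low_grade"), 1)
    base[[i]]$slide_id <- sprintf("FAKE%02d", i %% 8)
  }
  m <- train_binary_classifier(prepare_patches(base), "PUNLMP",
                               train_config(epochs = 4, seed = 2,
                                            val_slide_fraction = 0.3))
  te <- Filter(function(p) p$annotation_class == "low_grade",
               single_class_patches(4, 404))
  set.seed(22)
  truth <- sample(c(TRUE, FALSE), length(te), replace = TRUE)
  pr <- predict_patch(m, prepare_patches(te))
  expect_lt(abs(mean(truth == pr$binary_label) - 0.5), 0.08)
})

test_that("predictions are bounded, thresholded at >=, batch==single", {
  m <- trained_high_grade_model()
  te <- test_patch_set()
  pr <- predict_patch(m, te)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$binary_label, pr$probability >= 0.5)

  # boundary convention: probability equal to the threshold is positive
  m_thr <- m
  m_thr$config$positive_threshold <- pr$probability[1]
  pr_thr <- predict_patch(m_thr, te)
  expect_true(pr_thr$binary_label[1])

  # batch and single calls agree
  idx <- seq_len(24)
  single <- vapply(idx, function(i) {
    arr <- array(0, c(m$input_side, m$input_side, 3))
    predict_patch(m, te$x[, i, drop = FALSE], prepared = TRUE)$probability
  }, numeric(1))
  expect_lt(max(abs(single - pr$probability[idx])), 1e-6)

  expect_error(predict_patch(m, random_rgb(50, 50)), "incompatible")
})

test_that("model checkpoints round-trip through JSON", {
  m <- trained_high_grade_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_patch_model(m, f)
  back <- load_patch_model(f)
  expect_identical(back$target_class, m$target_class)
  te <- test_patch_set()
  p1 <- predict_patch(m, te)$probability
  p2 <- predict_patch(back, te)$probability
  expect_lt(max(abs(p1 - p2)), 1e-6)
})
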