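# Pipeline orchestration: tile -> classify -> fuse -> ratio -> GP ->
# evaluate -> survival, with every stage writing its artifact under
# out_dir.  A rerun with the same config and seed reproduces all outputs
# bit-for-bit (the run manifest deliberately records no wall-clock state).

read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "path", "patient_id", "label", "split")
  assert_that(all(need %in% names(m)),
              paste("manifest must have columns:", paste(need, collapse = ", ")))
  m
}

slide_ratio_row <- function(ratio, slide_id) {
  data.frame(slide_id = slide_id,
             r_punlmp = ratio$ratios[["PUNLMP"]],
             r_low = ratio$ratios[["low_grade"]],
             r_high = ratio$ratios[["high_grade"]],
             r_inv = ratio$ratios[["invasive"]],
             n_patches = ratio$n_patches, n_eliminated = ratio$n_eliminated,
             stringsAsFactors = FALSE)
}

ratio_from_row <- function(row, denominator_mode = "all") {
  structure(list(ratios = c(PUNLMP = row$r_punlmp, low_grade = row$r_low,
                            high_grade = row$r_high, invasive = row$r_inv),
                 low_risk_ratio = row$r_punlmp + row$r_low,
                 high_risk_ratio = row$r_high + row$r_inv,
                 n_patches = row$n_patches, n_eliminated = row$n_eliminated,
                 denominator_mode = denominator_mode),
            class = "wsi_ratio")
}

# Classify one slide: tissue patches -> four probabilities -> fates -> ratio.
infer_slide_ratio <- function(image, models, config, slide_id = "") {
  mask <- tissue_mask(image, config$tiling)
  patches <- extract_patches(image, mask, config$tiling, slide_id = slide_id)
  if (length(patches) == 0)
    stop(sprintf("unclassifiable slide '%s': no tissue patches", slide_id),
         call. = FALSE)
  set <- prepare_patches(patches, config$train$input_side)
  labels <- vapply(models, function(m)
    predict_patch(m, set)$binary_label, logical(length(patches)))
  labels <- matrix(labels, ncol = 4)
  fates <- resolve_patch_labels(labels)
  compute_ratio_vector(fates, config$denominator_mode)
}

# Collect annotated training patches of one slide as a prepared set.
slide_training_set <- function(image, regions, config, slide_id = "") {
  mask <- tissue_mask(image, config$tiling)
  patches <- extract_patches(image, mask, config$tiling, slide_id = slide_id,
                             regions = regions)
  patches <- Filter(function(p) !is.na(p$annotation_class), patches)
  if (length(patches) == 0) return(NULL)
  prepare_patches(patches, config$train$input_side)
}

cat_patch_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  assert_that(length(sets) > 0, "no annotated training patches found")
  structure(list(x = do.call(cbind, lapply(sets, `[[`, "x")),
                 class = do.call(c, lapply(sets, `[[`, "class")),
                 slide_id = do.call(c, lapply(sets, `[[`, "slide_id")),
                 input_side = sets[[1]]$input_side),
            class = "wsi_patch_set")
}

#' Run the full slide-classification pipeline
#'
#' Executes tile -> train (four one-vs-rest patch classifiers) -> infer
#' (patch fusion and ratio vectors) -> GP slide classifier -> evaluation ->
#' survival stratification, writing each stage's artifact under
#' `config$out_dir`: model checkpoints and training logs, `ratios.csv`,
#' `predictions.csv`, `patient_predictions.csv`, `metrics.json`,
#' `survival.json` and `run_manifest.json`.
#'
#' @param config A [pipeline_config()] with `data_dir` and `out_dir` set.
#' @param manifest Optional manifest data.frame (otherwise
#'   `data_dir/manifest.csv` is read).  Needs columns `slide_id`, `path`,
#'   `xml_path` (for training slides), `patient_id`, `label`, `split`.
#' @param quiet Suppress per-stage progress messages.
#' @return List with `predictions`, `patient_predictions`, `metrics`,
#'   `survival`, `models`, `gp`, invisibly.
#' @export
run_pipeline <- function(config, manifest = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "wsi_pipeline_config"))
  assert_that(!is.null(config$data_dir) && !is.null(config$out_dir),
              "config must set data_dir and out_dir")
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(manifest))
    manifest <- read_manifest(file.path(config$data_dir, "manifest.csv"))
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files) > 0)
    stop(paste("stage tile: slide file(s) not found:",
               paste(head(missing_files, 3), collapse = ", ")), call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  train_rows <- which(manifest$split == "train")
  test_rows <- which(manifest$split == "test")
  assert_that(length(train_rows) > 0, "stage train: no training slides in manifest")

  # ---- tile + train -------------------------------------------------------
  say("stage train: tiling %d training slides", length(train_rows))
  sets <- vector("list", length(train_rows))
  for (k in seq_along(train_rows)) {
    i <- train_rows[k]
    img <- read_png_rgb(manifest$path[i])
    regions <- if (!is.null(manifest$xml_path) && nzchar(manifest$xml_path[i]))
      read_asap_annotations(manifest$xml_path[i]) else NULL
    assert_that(!is.null(regions),
                sprintf("stage train: slide '%s' has no annotation XML",
                        manifest$slide_id[i]))
    sets[[k]] <- slide_training_set(img, regions, config, manifest$slide_id[i])
  }
  train_set <- cat_patch_sets(sets)
  say("stage train: %d annotated patches; training 4 classifiers", ncol(train_set$x))
  tcfg <- config$train
  tcfg$seed <- substream_seed(config$seed, "train")
  models <- train_classifier_ensemble(train_set, tcfg)
  model_dir <- file.path(config$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  for (cl in names(models)) {
    save_patch_model(models[[cl]], file.path(model_dir, paste0(cl, ".json")))
    write.csv(models[[cl]]$log, file.path(model_dir, paste0(cl, "_log.csv")),
              row.names = FALSE)
  }

  # ---- infer: ratio vectors for every slide -------------------------------
  say("stage infer: classifying %d slides", nrow(manifest))
  ratio_rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_png_rgb(manifest$path[i])
    ratio <- infer_slide_ratio(img, models, config, manifest$slide_id[i])
    ratio_rows[[i]] <- slide_ratio_row(ratio, manifest$slide_id[i])
  }
  ratios_df <- do.call(rbind, ratio_rows)
  write.csv(ratios_df, file.path(config$out_dir, "ratios.csv"), row.names = FALSE)

  # ---- GP slide classifier ------------------------------------------------
  say("stage gp: fitting the slide-risk classifier")
  ratios <- lapply(seq_len(nrow(ratios_df)), function(i)
    ratio_from_row(ratios_df[i, ], config$denominator_mode))
  gp <- fit_slide_classifier(ratios[train_rows], manifest$label[train_rows],
                             feature_mode = config$feature_mode,
                             seed = substream_seed(config$seed, "gp"))
  save_slide_classifier(gp, file.path(config$out_dir, "gp_model.json"))
  pred <- predict_slide(gp, ratios, slide_id = manifest$slide_id)
  pred <- cbind(ratios_df, pred[, c("prob_high", "risk")])
  pred$split <- manifest$split
  pred$truth <- manifest$label
  pred$patient_id <- manifest$patient_id
  write.csv(pred, file.path(config$out_dir, "predictions.csv"), row.names = FALSE)

  patient_pred <- aggregate_patient(pred[pred$split == "test", , drop = FALSE])
  write.csv(patient_pred, file.path(config$out_dir, "patient_predictions.csv"),
            row.names = FALSE)

  # ---- evaluation on the test split ---------------------------------------
  metrics <- NULL
  if (length(test_rows) > 0) {
    say("stage evaluate: %d test slides", length(test_rows))
    metrics <- metrics_report(pred$truth[test_rows], pred$risk[test_rows],
                              iterations = config$eval_iterations,
                              seed = substream_seed(config$seed, "bootstrap"))
    jsonlite::write_json(
      list(confusion = metrics$confusion, per_class = metrics$per_class,
           accuracy = metrics$accuracy, weighted = as.list(metrics$weighted),
           ci = metrics$ci),
      file.path(config$out_dir, "metrics.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }

  # ---- survival stratification -------------------------------------------
  surv_out <- NULL
  surv_path <- file.path(config$data_dir, "survival.csv")
  if (file.exists(surv_path) && nrow(patient_pred) > 0) {
    say("stage survival: stratifying predicted risk groups")
    surv <- read.csv(surv_path, stringsAsFactors = FALSE)
    joined <- merge(surv, patient_pred, by = "patient_id")
    if (nrow(joined) > 0 && length(unique(joined$risk)) == 2) {
      joined$group <- joined$risk
      surv_out <- survival_report(joined, horizon = config$survival_horizon)
      jsonlite::write_json(
        list(median_low = surv_out$median_low, median_high = surv_out$median_high,
             logrank = surv_out$logrank,
             cox = if (inherits(surv_out$cox, "wsi_cox"))
               unclass(surv_out$cox)[c("beta", "hr", "ci", "se", "p_value",
                                       "n", "n_events", "ties")]
             else list(error = surv_out$cox),
             km_low = surv_out$km_low$curve, km_high = surv_out$km_high$curve),
        file.path(config$out_dir, "survival.json"),
        digits = NA, auto_unbox = TRUE, pretty = TRUE)
    } else {
      say("stage survival: skipped (single predicted group or empty join)")
    }
  }

  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("wsirisk")),
         n_slides = nrow(manifest), n_train = length(train_rows),
         n_test = length(test_rows)),
    file.path(config$out_dir, "run_manifest.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(predictions = pred, patient_predictions = patient_pred,
                 metrics = metrics, survival = surv_out,
                 models = models, gp = gp))
}
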