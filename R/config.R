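# Pipeline configuration: one nested, human-readable JSON document holding
# every stage's parameters plus the single global seed all substreams
# derive from.

#' Pipeline configuration
#'
#' @param tiling A [tiling_config()].
#' @param train A [train_config()].
#' @param feature_mode Slide-classifier feature space: `"combined"` or
#'   `"per_class"` (see [ratio_features()]).
#' @param denominator_mode Ratio denominator: `"all"` or `"resolved"`.
#' @param survival_horizon Optional truncation for survival analysis
#'   (months; `NULL` = none).
#' @param eval_iterations Bootstrap iterations for metric CIs.
#' @param seed Global seed; all stage randomness derives from it via named
#'   substreams ([substream_seed()]).
#' @param data_dir Directory with slides, annotations, `manifest.csv` and
#'   `survival.csv`.
#' @param out_dir Directory for stage artifacts.
#' @return A `wsi_pipeline_config` list.
#' @export
pipeline_config <- function(tiling = tiling_config(), train = train_config(),
                            feature_mode = "combined",
                            denominator_mode = "all",
                            survival_horizon = NULL,
                            eval_iterations = 10000L, seed = 1L,
                            data_dir = NULL, out_dir = NULL) {
  stopifnot(inherits(tiling, "wsi_tiling_config"), inherits(train, "wsi_train_config"))
  assert_that(feature_mode %in% c("combined", "per_class"), "bad feature_mode")
  assert_that(denominator_mode %in% c("all", "resolved"), "bad denominator_mode")
  structure(list(tiling = tiling, train = train, feature_mode = feature_mode,
                 denominator_mode = denominator_mode,
                 survival_horizon = survival_horizon,
                 eval_iterations = as.integer(eval_iterations),
                 seed = as.integer(seed),
                 data_dir = data_dir, out_dir = out_dir),
            class = "wsi_pipeline_config")
}

#' Serialize / parse a pipeline configuration (lossless JSON round trip)
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly; `load_config` returns the config.
#' @export
save_config <- function(config, path) {
  payload <- list(tiling = unclass(config$tiling),
                  train = unclass(config$train),
                  feature_mode = config$feature_mode,
                  denominator_mode = config$denominator_mode,
                  survival_horizon = config$survival_horizon,
                  eval_iterations = config$eval_iterations,
                  seed = config$seed,
                  data_dir = config$data_dir, out_dir = config$out_dir)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tl <- p$tiling
  tl$marker_hue_windows <- lapply(tl$marker_hue_windows, as.numeric)
  tiling <- do.call(tiling_config, tl)
  train <- do.call(train_config, p$train[names(p$train) %in% names(formals(train_config))])
  pipeline_config(tiling = tiling, train = train,
                  feature_mode = p$feature_mode,
                  denominator_mode = p$denominator_mode,
                  survival_horizon = p$survival_horizon,
                  eval_iterations = p$eval_iterations, seed = p$seed,
                  data_dir = p$data_dir, out_dir = p$out_dir)
}

# Hash of the scientific configuration; paths are excluded so that runs of
# the same analysis into different directories share a hash.
config_hash <- function(config) {
  core <- unclass(config)
  core$data_dir <- NULL
  core$out_dir <- NULL
  json <- jsonlite::toJSON(core, digits = NA, auto_unbox = TRUE,
                           force = TRUE)
  sprintf("%08x", as.integer(.crc32(charToRaw(as.character(json)), 0) %% 2^31))
}
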