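# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Patches cut from single-class slides (annotated), as a plain list.
single_class_patches <- function(n_slides_per_class, seed0, side = 672L) {
  out <- list()
  cfg <- tiling_config()
  for (cl in wsi_classes()) {
    for (i in seq_len(n_slides_per_class)) {
      sp <- slide_spec(sprintf("%s_%d_%d", cl, i, seed0), side, side,
                       stats::setNames(1, cl),
                       seed = substream_seed(seed0, paste0(cl, i)))
      sl <- generate_slide(sp)
      out <- c(out, extract_patches(sl$image, tissue_mask(sl$image, cfg), cfg,
                                    slide_id = sp$slide_id, regions = sl$regions))
    }
  }
  out
}

train_patch_set <- function() {
  fixture("train_patch_set", function() prepare_patches(single_class_patches(10, 101)))
}

test_patch_set <- function() {
  fixture("test_patch_set", function() prepare_patches(single_class_patches(3, 909)))
}

# One trained binary model on the shared corpus (reused across tests).
trained_high_grade_model <- function() {
  fixture("trained_high_grade_model", function()
    train_binary_classifier(train_patch_set(), "high_grade",
                            train_config(epochs = 10, seed = 42)))
}

# A small mixed slide reused by tiling tests.
mixed_slide <- function() {
  fixture("mixed_slide", function() {
    sp <- slide_spec("MIX1", 640, 640,
                     c(low_grade = 0.5, high_grade = 0.2),
                     background_fraction = 0.3, marker = "green", seed = 77)
    generate_slide(sp)
  })
}

random_rgb <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
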