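# Tiling: tissue/marker masking, sliding-window patch extraction, colour
# normalization and training-time augmentation.
#
# Coordinates are 0-based and half-open throughout; a patch origin (x, y)
# is the top-left pixel, x indexing columns and y rows.

#' Tiling configuration
#'
#' @param patch_size Patch side in pixels (default 224).
#' @param overlap Fractional overlap between adjacent windows (default 1/3);
#'   the stride is `floor(patch_size * (1 - overlap))`, i.e. 149 at the
#'   defaults.
#' @param background_rgb_min A pixel is background when all three channels
#'   are at least this 8-bit value (default 220).
#' @param background_patch_fraction Patches whose background/marker fraction
#'   strictly exceeds this are dropped (default 0.5).
#' @param marker_saturation_min Minimum HSV saturation for marker ink
#'   (default 0.55).
#' @param marker_value_min Minimum HSV value for marker ink (default 0.6):
#'   ink is bright, so dark chromatic tissue (nuclei) is not flagged.
#' @param marker_hue_windows List of `c(lo, hi)` hue windows in degrees
#'   (default: green and blue ink).
#' @return A `wsi_tiling_config` list.
#' @export
tiling_config <- function(patch_size = 224L, overlap = 1 / 3,
                          background_rgb_min = 220L,
                          background_patch_fraction = 0.5,
                          marker_saturation_min = 0.55,
                          marker_value_min = 0.6,
                          marker_hue_windows = list(green = c(70, 190),
                                                    blue = c(190, 290))) {
  assert_that(patch_size >= 1, "patch_size must be at least 1")
  assert_that(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 background_rgb_min = background_rgb_min,
                 background_patch_fraction = background_patch_fraction,
                 marker_saturation_min = marker_saturation_min,
                 marker_value_min = marker_value_min,
                 marker_hue_windows = marker_hue_windows),
            class = "wsi_tiling_config")
}

#' Sliding-window stride implied by a tiling configuration
#' @param config A [tiling_config()].
#' @return Integer stride, `floor(patch_size * (1 - overlap))`.
#' @export
tiling_stride <- function(config) {
  max(1L, as.integer(floor(config$patch_size * (1 - config$overlap))))
}

#' Compute the tissue mask of a slide image
#'
#' A pixel is tissue when it is neither white background (all channels at or
#' above `background_rgb_min`) nor marker ink (HSV saturation at or above
#' `marker_saturation_min` with hue inside one of the configured windows).
#'
#' @param image H x W x 3 RGB array, 8-bit values.
#' @param config A [tiling_config()].
#' @return Logical H x W matrix, TRUE where tissue.
#' @export
tissue_mask <- function(image, config = tiling_config()) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  background <- (r >= config$background_rgb_min) &
                (g >= config$background_rgb_min) &
                (b >= config$background_rgb_min)
  hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g), b = as.vector(b),
                            maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]
  marker <- rep(FALSE, length(hue))
  for (wdw in config$marker_hue_windows)
    marker <- marker | (sat >= config$marker_saturation_min &
                        val >= (config$marker_value_min %||% 0) &
                        hue >= wdw[1] & hue < wdw[2])
  mask <- !background & !matrix(marker, nrow = h, ncol = w)
  mask
}

#' Sliding-window grid origins along one axis
#'
#' Origins are the multiples of the stride for which the full window fits:
#' `0, s, 2s, ...` with `origin + patch_size <= extent`.
#'
#' @param extent Axis length in pixels.
#' @param config A [tiling_config()].
#' @return Integer vector of 0-based origins (possibly empty).
#' @export
grid_origins <- function(extent, config = tiling_config()) {
  if (extent < config$patch_size) return(integer(0))
  s <- tiling_stride(config)
  seq.int(0L, extent - config$patch_size, by = s)
}

#' Extract tissue patches from a slide image
#'
#' Windows are placed on a stride grid along both axes (row-major order);
#' a window is kept when its background/marker fraction, per the mask, does
#' not exceed `background_patch_fraction`.  When `regions` is supplied,
#' each kept patch is assigned the class of the region covering the largest
#' share of its area, provided that share is at least `min_region_cover`;
#' otherwise its `annotation_class` is `NA`.
#'
#' @param image H x W x 3 RGB array.
#' @param mask Logical tissue mask from [tissue_mask()] (same H x W).
#' @param config A [tiling_config()].
#' @param slide_id Slide identifier carried on each patch.
#' @param regions Optional annotation data.frame (`class`, `x0`, `y0`,
#'   `x1`, `y1`, 0-based half-open).
#' @param min_region_cover Minimum fraction of patch area inside the
#'   best-covering region for a class assignment (default 0.6).
#' @return List of `wsi_patch` objects (`slide_id`, `x`, `y`, `pixels`,
#'   `annotation_class`).
#' @export
extract_patches <- function(image, mask, config = tiling_config(),
                            slide_id = "", regions = NULL,
                            min_region_cover = 0.6) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  assert_that(is.matrix(mask) && all(dim(mask) == c(h, w)),
              "mask must match the image extent")
  ps <- config$patch_size
  xs <- grid_origins(w, config)
  ys <- grid_origins(h, config)
  if (length(xs) == 0 || length(ys) == 0) {
    warning("image smaller than patch_size; no patches extracted")
    return(list())
  }
  out <- list()
  for (y in ys) {
    for (x in xs) {
      sub <- mask[(y + 1L):(y + ps), (x + 1L):(x + ps)]
      bg_frac <- 1 - mean(sub)
      if (bg_frac > config$background_patch_fraction) next
      cls <- NA_character_
      if (!is.null(regions) && nrow(regions) > 0) {
        ix0 <- pmax(regions$x0, x); ix1 <- pmin(regions$x1, x + ps)
        iy0 <- pmax(regions$y0, y); iy1 <- pmin(regions$y1, y + ps)
        cover <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0) / (ps * ps)
        k <- which.max(cover)
        if (length(k) && cover[k] >= min_region_cover) cls <- regions$class[k]
      }
      out[[length(out) + 1L]] <- structure(
        list(slide_id = slide_id, x = as.integer(x), y = as.integer(y),
             pixels = image[(y + 1L):(y + ps), (x + 1L):(x + ps), , drop = FALSE],
             annotation_class = cls),
        class = "wsi_patch")
    }
  }
  out
}

# Reference channel statistics the normalizer maps every patch onto
# (0-255 scale; chosen once to sit in the pink H&E-like range).
norm_reference <- function() {
  list(mean = c(182, 146, 167), sd = c(38, 42, 40))
}

#' Normalize patch colour intensity
#'
#' Per-channel affine map onto fixed reference statistics: each channel is
#' centred and rescaled to the reference mean and standard deviation.  A
#' zero-variance channel is centred only (no division by zero).  The map is
#' idempotent up to floating-point error.
#'
#' @param patch A `wsi_patch` or a raw H x W x 3 array.
#' @return Same type as the input, with numeric (double) pixels.
#' @export
normalize_patch <- function(patch) {
  arr <- if (inherits(patch, "wsi_patch")) patch$pixels else patch
  assert_rgb(arr)
  ref <- norm_reference()
  out <- array(0, dim = dim(arr))
  for (ch in 1:3) {
    v <- as.numeric(arr[, , ch])
    m <- mean(v); s <- sd(v)
    out[, , ch] <- if (is.na(s) || s < 1e-12) (v - m) + ref$mean[ch]
                   else (v - m) / s * ref$sd[ch] + ref$mean[ch]
  }
  if (inherits(patch, "wsi_patch")) { patch$pixels <- out; patch } else out
}

rot90_arr <- function(arr, k) {
  k <- k %% 4L
  if (k == 0L) return(arr)
  for (i in seq_len(k)) {
    # 90 degrees counter-clockwise: transpose then reverse rows
    arr <- aperm(arr, c(2, 1, 3))
    arr <- arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
  }
  arr
}

#' Seeded training-time patch augmentation
#'
#' Applies, in order: a random horizontal flip, a random vertical flip, a
#' random rotation by a multiple of 90 degrees, and bounded colour jitter
#' (brightness, contrast and saturation factors drawn uniformly from
#' `[1 - jitter, 1 + jitter]`).  The same patch and seed always give the
#' same output; shape and storage mode are preserved.
#'
#' @param patch A `wsi_patch` or H x W x 3 array (square for rotations).
#' @param seed Integer seed.
#' @param jitter Half-width of the colour-jitter factor range (default 0.1;
#'   0 disables jitter).
#' @return Same type as the input.
#' @export
augment_patch <- function(patch, seed, jitter = 0.1) {
  arr <- if (inherits(patch, "wsi_patch")) patch$pixels else patch
  assert_rgb(arr)
  was_int <- is.integer(arr)
  with_seed(seed, {
    if (runif(1) < 0.5) arr <- arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
    if (runif(1) < 0.5) arr <- arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
    k <- sample(0:3, 1)
    if (k > 0L) {
      assert_that(dim(arr)[1] == dim(arr)[2], "rotation requires a square patch")
      arr <- rot90_arr(arr, k)
    }
    if (jitter > 0) {
      f <- runif(3, 1 - jitter, 1 + jitter)  # brightness, contrast, saturation
      arr <- arr * f[1]
      m <- mean(arr)
      arr <- (arr - m) * f[2] + m
      luma <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      for (ch in 1:3) arr[, , ch] <- luma + (arr[, , ch] - luma) * f[3]
    }
  })
  if (was_int) {
    arr <- array(as.integer(pmin(pmax(round(arr), 0), 255)), dim = dim(arr))
  }
  if (inherits(patch, "wsi_patch")) { patch$pixels <- arr; patch } else arr
}

#' Persist a patch set as PNGs plus a CSV index
#'
#' @param patches List of `wsi_patch` objects (integer pixels).
#' @param dir Output directory.
#' @return The index data.frame (`file`, `slide_id`, `x`, `y`, `class`),
#'   invisibly; also written as `index.csv`.
#' @export
write_patch_set <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(file = character(length(patches)),
                    slide_id = character(length(patches)),
                    x = integer(length(patches)), y = integer(length(patches)),
                    class = character(length(patches)), stringsAsFactors = FALSE)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    f <- sprintf("%s_%d_%d.png", p$slide_id, p$x, p$y)
    write_png_rgb(p$pixels, file.path(dir, f))
    idx[i, ] <- list(f, p$slide_id, p$x, p$y,
                     ifelse(is.na(p$annotation_class), "", p$annotation_class))
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read back a patch set written by [write_patch_set()]
#' @param dir Directory holding `index.csv` and the patch PNGs.
#' @return List of `wsi_patch` objects.
#' @export
read_patch_set <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE,
                  colClasses = c(class = "character"))
  lapply(seq_len(nrow(idx)), function(i) {
    structure(list(slide_id = idx$slide_id[i], x = idx$x[i], y = idx$y[i],
                   pixels = read_png_rgb(file.path(dir, idx$file[i])),
                   annotation_class = if (nzchar(idx$class[i])) idx$class[i]
                                      else NA_character_),
              class = "wsi_patch")
  })
}
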