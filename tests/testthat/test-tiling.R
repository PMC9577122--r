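# Masking, sliding-window extraction, normalization, augmentation.

test_that("tissue mask rejects background and marker, keeps tissue", {
  cfg <- tiling_config()
  white <- array(255L, dim = c(32, 32, 3))
  expect_true(all(!tissue_mask(white, cfg)))
  expect_error(tissue_mask(matrix(0, 4, 4), cfg), "RGB")

  sl <- mixed_slide()
  m <- tissue_mask(sl$image, cfg)
  tb <- sl$tissue_box
  tissue_px <- m[(tb["y0"] + 1):tb["y1"], (tb["x0"] + 1):tb["x1"]]
  expect_gte(mean(tissue_px), 0.90)  # painted tissue mostly masked TRUE
  mb <- sl$marker_box
  marker_px <- m[(mb["y0"] + 1):mb["y1"], (mb["x0"] + 1):mb["x1"]]
  expect_true(all(!marker_px))       # marker stripe masked FALSE
})

test_that("masking is anti-monotone in the background threshold", {
  sl <- mixed_slide()
  areas <- vapply(c(180, 210, 240), function(th)
    sum(tissue_mask(sl$image, tiling_config(background_rgb_min = th))),
    numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("grid placement follows the stride closed form", {
  cfg <- tiling_config()
  expect_identical(tiling_stride(cfg), 149L)  # floor(224 * 2/3)
  full <- function(n) array(0L, dim = c(n, n, 3))
  ones <- function(n) matrix(TRUE, n, n)

  p1 <- extract_patches(full(224), ones(224), cfg)
  expect_length(p1, 1)
  expect_identical(c(p1[[1]]$x, p1[[1]]$y), c(0L, 0L))

  p16 <- extract_patches(full(672), ones(672), cfg)
  expect_length(p16, 16)
  expect_identical(sort(unique(vapply(p16, `[[`, 0L, "x"))), c(0L, 149L, 298L, 447L))
  # adjacent origins differ by the stride; footprints overlap by 75 px
  expect_identical(unique(diff(c(0L, 149L, 298L, 447L))), 149L)
  expect_identical(224L - tiling_stride(cfg), 75L)

  expect_warning(p0 <- extract_patches(full(100), ones(100), cfg), "smaller")
  expect_length(p0, 0)
  # fully-background image yields no patches
  expect_length(extract_patches(full(300), !ones(300), cfg), 0)
})

test_that("grid-count closed form matches brute-force origin enumeration", {
  set.seed(404)
  for (i in 1:50) {
    ps <- sample(16:64, 1)
    ov <- runif(1, 0, 0.9)
    w <- sample(ps:(6 * ps), 1)
    cfg <- tiling_config(patch_size = ps, overlap = ov)
    s <- tiling_stride(cfg)
    brute <- Filter(function(o) o + ps <= w, seq(0, w, by = s))
    expect_identical(grid_origins(w, cfg), as.integer(brute))
    expect_length(grid_origins(w, cfg), floor((w - ps) / s) + 1)
  }
})

test_that("normalization hits the reference statistics and is idempotent", {
  ref <- wsirisk:::norm_reference()
  set.seed(8)
  for (i in 1:100) {
    p <- random_rgb(32, 32)
    n1 <- normalize_patch(p)
    for (ch in 1:3) {
      expect_lt(abs(mean(n1[, , ch]) - ref$mean[ch]), 1e-6)
      expect_lt(abs(sd(n1[, , ch]) - ref$sd[ch]), 1e-6)
    }
    n2 <- normalize_patch(n1)
    expect_lt(max(abs(n2 - n1)), 1e-6)
  }
  # zero-variance channel: centred only, stable under re-application
  gray <- array(128, dim = c(16, 16, 3))
  g1 <- normalize_patch(gray)
  expect_equal(as.numeric(g1[1, 1, ]), ref$mean)
  expect_lt(max(abs(normalize_patch(g1) - g1)), 1e-12)
})

test_that("augmentation is seeded, shape/dtype preserving, group-closed", {
  p <- random_rgb(28, 28, seed = 5)
  a1 <- augment_patch(p, seed = 123)
  a2 <- augment_patch(p, seed = 123)
  expect_identical(a1, a2)
  for (s in 1:100) {
    a <- augment_patch(p, seed = s)
    expect_identical(dim(a), dim(p))
    expect_identical(typeof(a), typeof(p))
  }
  # four quarter-turns compose to the identity
  expect_identical(wsirisk:::rot90_arr(p, 4), p)
  expect_identical(wsirisk:::rot90_arr(wsirisk:::rot90_arr(p, 1), 3), p)
  # with zero jitter the output is one of the 8 dihedral transforms
  dihedral <- list()
  for (k in 0:3) {
    r <- wsirisk:::rot90_arr(p, k)
    dihedral <- c(dihedral, list(r, r[, rev(seq_len(dim(r)[2])), , drop = FALSE]))
  }
  a0 <- augment_patch(p, seed = 9, jitter = 0)
  expect_true(any(vapply(dihedral, identical, logical(1), a0)))
})

test_that("patch sets round-trip bit-exactly through PNG + CSV", {
  sl <- mixed_slide()
  cfg <- tiling_config()
  patches <- extract_patches(sl$image, tissue_mask(sl$image, cfg), cfg,
                             slide_id = "MIX1", regions = sl$regions)
  dir <- withr::local_tempdir()
  write_patch_set(patches, dir)
  back <- read_patch_set(dir)
  expect_length(back, length(patches))
  for (i in seq_along(patches)) {
    expect_identical(back[[i]]$pixels, patches[[i]]$pixels)
    expect_identical(back[[i]]$annotation_class, patches[[i]]$annotation_class)
    expect_identical(c(back[[i]]$x, back[[i]]$y), c(patches[[i]]$x, patches[[i]]$y))
  }
})
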