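# Synthetic pseudo-WSI generator.
#
# Slides are desk-scale stand-ins for scanned urothelial-lesion sections:
# a white background, a horizontal band of "tissue" split into one
# contiguous vertical strip per histologic class present, and optionally a
# saturated ink-marker stripe in the background.  Class textures are
# procedural -- a pink-ish base tone plus seeded dark "nuclei" discs whose
# density, radius and chromaticity differ by class -- so the four classes
# are separable by simple statistics, which is the contract the downstream
# pipeline needs (not histologic realism).

texture_params <- function() {
  # Coverage (1 - exp(-density * pi * radius^2)) and blob scale are the
  # class signals that survive per-patch colour normalization and 8x
  # downsampling: roughly 2% / 13% / 40% / 93% nuclear coverage at
  # increasing blob radius (invasive is near-confluent dark tissue).
  list(
    PUNLMP     = list(base = c(242, 205, 215), blob = c(170, 120, 170),
                      density = 0.00012, radius = 8L),
    low_grade  = list(base = c(228, 175, 198), blob = c(130,  85, 150),
                      density = 0.00070, radius = 8L),
    high_grade = list(base = c(210, 150, 190), blob = c( 95,  55, 125),
                      density = 0.00065, radius = 16L),
    invasive   = list(base = c(188, 132, 165), blob = c( 70,  40,  95),
                      density = 0.00150, radius = 24L))
}

marker_colors <- function() list(green = c(10L, 205L, 80L), blue = c(30L, 60L, 220L))

#' Specify a synthetic slide
#'
#' @param slide_id Slide identifier string.
#' @param width,height Raster size in pixels; each must be at least
#'   `min_size` (the downstream patch size).
#' @param composition Named numeric vector of per-class area fractions of
#'   the *whole image* (names from [wsi_classes()]); together with
#'   `background_fraction` they must sum to 1.
#' @param background_fraction Fraction of the image that is white background.
#' @param marker Optional marker-artifact colour, `"green"` or `"blue"`.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   raster.
#' @param patient_id Patient identifier (defaults to one patient per slide).
#' @param min_size Minimum allowed raster side (default 224).
#' @return A `wsi_slide_spec` list.
#' @export
slide_spec <- function(slide_id, width, height, composition,
                       background_fraction = 0, marker = NULL, seed = 1L,
                       patient_id = paste0("PT-", slide_id), min_size = 224L) {
  assert_that(length(composition) >= 1 && !is.null(names(composition)),
              "composition must be a named vector of class fractions")
  assert_that(all(names(composition) %in% wsi_classes()),
              paste("composition names must be among:", paste(wsi_classes(), collapse = ", ")))
  assert_that(all(composition >= 0) && background_fraction >= 0,
              "fractions must be nonnegative")
  total <- sum(composition) + background_fraction
  if (abs(total - 1) > 1e-9)
    stop(sprintf("class fractions + background_fraction must sum to 1 (got %.12f)", total),
         call. = FALSE)
  if (width < min_size || height < min_size)
    stop(sprintf("slide of %dx%d is smaller than the patch size (%d)", width, height, min_size),
         call. = FALSE)
  if (!is.null(marker))
    assert_that(marker %in% names(marker_colors()), "marker must be 'green' or 'blue'")
  structure(list(slide_id = as.character(slide_id), width = as.integer(width),
                 height = as.integer(height), composition = composition,
                 background_fraction = background_fraction, marker = marker,
                 seed = as.integer(seed), patient_id = patient_id),
            class = "wsi_slide_spec")
}

# Integer strip widths proportional to fractions, summing exactly to w
# (largest-remainder apportionment; deterministic).
apportion <- function(fracs, w) {
  raw <- fracs / sum(fracs) * w
  base <- floor(raw)
  rem <- w - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Apply the 5 percent high-grade rule to a slide composition
#'
#' A slide is high-risk when the high-grade plus invasive area, as a
#' fraction of tissue area (background excluded), is at least 0.05.
#'
#' @param composition Named class-fraction vector (any normalization).
#' @return `"high_risk"` or `"low_risk"`.
#' @export
truth_label_rule <- function(composition) {
  tissue <- sum(composition)
  assert_that(tissue > 0, "composition has no tissue")
  hg <- sum(composition[names(composition) %in% c("high_grade", "invasive")])
  if (hg / tissue >= 0.05 - 1e-12) "high_risk" else "low_risk"
}

#' Generate a synthetic slide from a spec
#'
#' Paints one contiguous textured strip per nonzero class fraction inside a
#' centred tissue band, white background elsewhere, and an optional marker
#' stripe in the background.  The ground-truth risk label follows
#' [truth_label_rule()].  Identical spec and seed give a bit-identical
#' raster.
#'
#' @param spec A [slide_spec()].
#' @return A `wsi_slide` list with elements `slide_id`, `image` (H x W x 3
#'   integer array), `regions` (data.frame `class`, `x0`, `y0`, `x1`, `y1`;
#'   0-based half-open pixel boxes), `truth_label`, `patient_id`,
#'   `tissue_box`, and `marker_box` (NULL if absent).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "wsi_slide_spec"))
  w <- spec$width; h <- spec$height
  comp <- spec$composition[spec$composition > 0]
  tissue_frac <- sum(comp)
  assert_that(tissue_frac > 0, "slide has no tissue")
  tp <- texture_params()

  with_seed(spec$seed, {
    img <- array(255L, dim = c(h, w, 3L))
    th <- as.integer(max(1L, round(tissue_frac * h)))
    r0 <- (h - th) %/% 2L                       # 0-based first tissue row
    widths <- apportion(comp, w)
    x0s <- cumsum(c(0L, widths[-length(widths)]))

    regions <- data.frame(class = names(comp), x0 = x0s, y0 = r0,
                          x1 = x0s + widths, y1 = r0 + th,
                          stringsAsFactors = FALSE)
    regions <- regions[widths > 0, , drop = FALSE]

    for (k in seq_along(comp)) {
      if (widths[k] == 0L) next
      cls <- names(comp)[k]
      p <- tp[[cls]]
      rows <- (r0 + 1L):(r0 + th)
      cols <- (x0s[k] + 1L):(x0s[k] + widths[k])
      area <- length(rows) * length(cols)
      # base tone with mild per-pixel noise (keeps channel variance nonzero)
      for (ch in 1:3) {
        noise <- sample.int(13L, area, replace = TRUE) - 7L
        img[rows, cols, ch] <- as.integer(pmin(pmax(p$base[ch] + noise, 0L), 255L))
      }
      nblob <- round(p$density * area)
      if (nblob > 0) {
        rmax <- p$radius + 1L
        if (widths[k] > 2L * rmax + 2L && th > 2L * rmax + 2L) {
          cx <- sample((x0s[k] + rmax + 1L):(x0s[k] + widths[k] - rmax), nblob, replace = TRUE)
          cy <- sample((r0 + rmax + 1L):(r0 + th - rmax), nblob, replace = TRUE)
          rad <- sample((p$radius - 1L):(p$radius + 1L), nblob, replace = TRUE)
          jit <- matrix(sample.int(21L, 3L * nblob, replace = TRUE) - 11L, ncol = 3L)
          colm <- sweep(jit, 2L, p$blob, "+")
          colm <- pmin(pmax(colm, 0L), 255L)
          storage.mode(colm) <- "integer"
          img <- array(.paint_discs(img, h, w, cx, cy, rad, colm), dim = dim(img))
        }
      }
    }

    marker_box <- NULL
    if (!is.null(spec$marker)) {
      if (r0 >= 6L) {
        mh <- min(18L, r0 - 2L)
        m0 <- (r0 - mh) %/% 2L
        mcol <- marker_colors()[[spec$marker]]
        mx0 <- round(w * 0.1); mx1 <- round(w * 0.9)
        for (ch in 1:3) img[(m0 + 1L):(m0 + mh), (mx0 + 1L):mx1, ch] <- mcol[ch]
        marker_box <- c(x0 = mx0, y0 = m0, x1 = mx1, y1 = m0 + mh)
      } else {
        warning("no background band available for the marker stripe; skipped")
      }
    }

    structure(list(slide_id = spec$slide_id, image = img, regions = regions,
                   truth_label = truth_label_rule(comp),
                   patient_id = spec$patient_id,
                   tissue_box = c(x0 = 0L, y0 = r0, x1 = w, y1 = r0 + th),
                   marker_box = marker_box, spec = spec),
              class = "wsi_slide")
  })
}

#' Specify a synthetic survival cohort
#'
#' @param n_patients Number of patients.
#' @param high_risk_fraction Fraction assigned to the high-risk group when
#'   labels are simulated.
#' @param baseline_hazard Event hazard (events/month) in the low-risk group.
#' @param hazard_ratio Multiplier applied to the hazard in the high-risk
#'   group.
#' @param censor_time_max Administrative censoring drawn uniformly on
#'   `(0, censor_time_max)` months.
#' @param seed Integer seed.
#' @return A `wsi_cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, high_risk_fraction = 0.5,
                        baseline_hazard = 0.01, hazard_ratio = 2,
                        censor_time_max = 120, seed = 1L) {
  assert_that(n_patients >= 0, "n_patients must be nonnegative")
  assert_that(baseline_hazard > 0, "baseline_hazard must be positive")
  assert_that(hazard_ratio > 0, "hazard_ratio must be positive")
  assert_that(censor_time_max >= 0, "censor_time_max must be nonnegative")
  assert_that(high_risk_fraction >= 0 && high_risk_fraction <= 1,
              "high_risk_fraction must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 high_risk_fraction = high_risk_fraction,
                 baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
                 censor_time_max = censor_time_max, seed = as.integer(seed)),
            class = "wsi_cohort_spec")
}

#' Simulate follow-up for a cohort of risk-labelled patients
#'
#' Event times are exponential with hazard `baseline_hazard` (low-risk) or
#' `baseline_hazard * hazard_ratio` (high-risk); censoring times are uniform
#' on `(0, censor_time_max)`; the observed time is the minimum, with the
#' event indicator set accordingly.
#'
#' @param spec A [cohort_spec()].
#' @param truth_labels Optional named character vector mapping patient id to
#'   `"low_risk"`/`"high_risk"`.  When omitted, `n_patients` patients are
#'   created and labelled by `high_risk_fraction`.
#' @return data.frame with columns `patient_id`, `time_months`, `event`
#'   (1 death / 0 censored) and `risk_group`.
#' @export
generate_cohort <- function(spec, truth_labels = NULL) {
  stopifnot(inherits(spec, "wsi_cohort_spec"))
  with_seed(spec$seed, {
    if (is.null(truth_labels)) {
      n <- spec$n_patients
      if (n == 0L)
        return(data.frame(patient_id = character(0), time_months = numeric(0),
                          event = integer(0), risk_group = character(0)))
      ids <- sprintf("PT-%04d", seq_len(n))
      n_high <- round(spec$high_risk_fraction * n)
      risk <- rep("low_risk", n)
      if (n_high > 0) risk[sample.int(n, n_high)] <- "high_risk"
    } else {
      assert_that(!is.null(names(truth_labels)) && all(nzchar(names(truth_labels))),
                  "truth_labels must be named by patient id")
      assert_that(all(truth_labels %in% wsi_risk_levels()),
                  "truth_labels must be 'low_risk' or 'high_risk'")
      ids <- names(truth_labels)
      risk <- unname(truth_labels)
      n <- length(ids)
      if (n == 0L)
        return(data.frame(patient_id = character(0), time_months = numeric(0),
                          event = integer(0), risk_group = character(0)))
    }
    rate <- spec$baseline_hazard * ifelse(risk == "high_risk", spec$hazard_ratio, 1)
    t_event <- rexp(n, rate = rate)
    t_cens <- runif(n, 0, max(spec$censor_time_max, .Machine$double.eps))
    time <- pmax(pmin(t_event, t_cens), 1e-9)
    data.frame(patient_id = ids, time_months = time,
               event = as.integer(t_event <= t_cens), risk_group = risk,
               stringsAsFactors = FALSE)
  })
}

#' Draw a set of random slide specs emulating a mixed cohort
#'
#' Low-risk slides mix PUNLMP and low-grade tissue (sometimes with a
#' sub-threshold high-grade admixture, always below the 5 percent rule);
#' high-risk slides carry a high-grade plus invasive share of tissue drawn
#' from U(0.15, 0.7).  Threshold-adjacent compositions are exercised by the
#' label-rule tests directly: at desk scale a 5 percent lesion is smaller
#' than one patch, so such slides are not part of the default stated world
#' (see the methods vignette).
#'
#' @param n Number of slides.
#' @param width,height Slide raster size.
#' @param seed Integer seed.
#' @param high_risk_fraction Fraction of slides that are high-risk.
#' @param marker_prob Probability a slide carries a marker stripe.
#' @param prefix Slide-id prefix.
#' @param slides_per_patient Consecutive slides sharing one patient id.
#' @return List of [slide_spec()] objects.
#' @export
make_slide_specs <- function(n, width = 1024L, height = 1024L, seed = 1L,
                             high_risk_fraction = 0.5, marker_prob = 0.3,
                             prefix = "S", slides_per_patient = 1L) {
  with_seed(seed, {
    specs <- vector("list", n)
    n_high <- round(high_risk_fraction * n)
    is_high <- rep(FALSE, n)
    if (n_high > 0) is_high[sample.int(n, n_high)] <- TRUE
    for (i in seq_len(n)) {
      bg <- runif(1, 0.2, 0.35)
      tissue <- 1 - bg
      if (is_high[i]) {
        if (runif(1) < 0.25) {
          tf <- stats::setNames(1, sample(c("high_grade", "invasive"), 1))
        } else {
          hg_share <- runif(1, 0.15, 0.7)
          inv_part <- runif(1, 0, 0.6)
          low_part <- runif(1, 0.2, 0.8)
          tf <- c(PUNLMP = (1 - hg_share) * (1 - low_part),
                  low_grade = (1 - hg_share) * low_part,
                  high_grade = hg_share * (1 - inv_part),
                  invasive = hg_share * inv_part)
        }
      } else {
        pun <- runif(1, 0.25, 0.75)
        hg_adm <- if (runif(1) < 0.3) runif(1, 0, 0.04) else 0
        if (runif(1) < 0.25) {
          tf <- if (runif(1) < 0.5) c(PUNLMP = 1) else c(low_grade = 1)
        } else {
          tf <- c(PUNLMP = pun * (1 - hg_adm), low_grade = (1 - pun) * (1 - hg_adm),
                  high_grade = hg_adm)
        }
      }
      comp <- tf / sum(tf) * tissue
      marker <- if (runif(1) < marker_prob)
        sample(names(marker_colors()), 1) else NULL
      sid <- sprintf("%s%03d", prefix, i)
      pid <- sprintf("%s-PT%03d", prefix, ((i - 1L) %/% slides_per_patient) + 1L)
      specs[[i]] <- slide_spec(sid, width, height, comp,
                               background_fraction = bg, marker = marker,
                               seed = substream_seed(seed, sid),
                               patient_id = pid)
    }
    # well-posedness guarantee: every class must be trainable, i.e. appear
    # as a dominant share on at least one slide.  A random draw can miss a
    # class; when that happens the last slide of the matching risk group is
    # converted to a pure slide of the missing class (label-preserving).
    share_of <- function(sp, cl) {
      s <- sp$composition[cl]
      if (is.na(s)) 0 else unname(s / sum(sp$composition))
    }
    for (cl in wsi_classes()) {
      if (any(vapply(specs, share_of, numeric(1), cl = cl) >= 0.25)) next
      want_high <- cl %in% c("high_grade", "invasive")
      for (i in rev(seq_len(n))) {
        sp <- specs[[i]]
        if ((truth_label_rule(sp$composition) == "high_risk") == want_high &&
            share_of(sp, cl) < 0.25) {
          tissue_i <- sum(sp$composition)
          specs[[i]] <- slide_spec(sp$slide_id, width, height,
                                   stats::setNames(tissue_i, cl),
                                   background_fraction = sp$background_fraction,
                                   marker = sp$marker, seed = sp$seed,
                                   patient_id = sp$patient_id)
          break
        }
      }
    }
    specs
  })
}

#' Write a full synthetic dataset to disk
#'
#' Renders every spec to a PNG slide with an ASAP-dialect annotation XML,
#' writes a slide manifest CSV (`slide_id`, `path`, `xml_path`,
#' `patient_id`, `label`, `split`) and a linked survival CSV
#' (`patient_id`, `time_months`, `event`), with survival driven by the
#' patient-level truth label (a patient is high-risk if any slide is).
#'
#' @param dir Output directory (created if needed).
#' @param specs_train,specs_test Lists of [slide_spec()] objects.
#' @param cspec A [cohort_spec()]; its `n_patients`/`high_risk_fraction` are
#'   ignored in favour of the slide-derived truth labels.
#' @return Invisibly, a list with `manifest` and `survival` data.frames.
#' @export
simulate_dataset <- function(dir, specs_train, specs_test, cspec = cohort_spec(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_specs <- c(specs_train, specs_test)
  split <- rep(c("train", "test"), c(length(specs_train), length(specs_test)))
  rows <- vector("list", length(all_specs))
  patient_label <- character(0)
  for (i in seq_along(all_specs)) {
    sl <- generate_slide(all_specs[[i]])
    png_path <- file.path(dir, paste0(sl$slide_id, ".png"))
    xml_path <- file.path(dir, paste0(sl$slide_id, ".xml"))
    write_png_rgb(sl$image, png_path)
    write_asap_annotations(sl$regions, xml_path)
    rows[[i]] <- data.frame(slide_id = sl$slide_id, path = png_path,
                            xml_path = xml_path, patient_id = sl$patient_id,
                            label = sl$truth_label, split = split[i],
                            stringsAsFactors = FALSE)
    prev <- patient_label[sl$patient_id]
    patient_label[sl$patient_id] <-
      if (!is.na(prev) && prev == "high_risk") "high_risk" else sl$truth_label
  }
  manifest <- do.call(rbind, rows)
  surv <- generate_cohort(cspec, truth_labels = patient_label)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, survival = surv))
}
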