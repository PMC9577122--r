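# Synthetic slide and cohort generator.

test_that("slide_spec validates composition and size", {
  expect_error(slide_spec("a", 512, 512, c(PUNLMP = 0.8)), "sum to 1")
  expect_error(slide_spec("a", 512, 512, c(PUNLMP = 0.5, low_grade = 0.6)),
               "sum to 1")
  expect_error(slide_spec("a", 100, 512, c(PUNLMP = 1)), "smaller than the patch size")
  expect_error(slide_spec("a", 512, 512, c(bogus = 1)), "must be among")
})

test_that("single-class slide is low risk with one region", {
  sl <- generate_slide(slide_spec("s", 256, 256, c(PUNLMP = 1), seed = 3))
  expect_identical(sl$truth_label, "low_risk")
  expect_identical(nrow(sl$regions), 1L)
  expect_identical(sl$regions$class, "PUNLMP")
  # region lies inside the image (0-based, half-open)
  expect_true(all(sl$regions$x0 >= 0 & sl$regions$x1 <= 256 &
                  sl$regions$y0 >= 0 & sl$regions$y1 <= 256))
})

test_that("the 5 percent high-grade rule sets the truth label", {
  # 6% high-grade of tissue => high risk
  sl <- generate_slide(slide_spec("s", 512, 512,
                                  c(low_grade = 0.94, high_grade = 0.06), seed = 1))
  expect_identical(sl$truth_label, "high_risk")
  # the rule is a pure function of composition and flips exactly at 5%
  expect_identical(truth_label_rule(c(low_grade = 0.951, high_grade = 0.049)),
                   "low_risk")
  expect_identical(truth_label_rule(c(low_grade = 0.95, high_grade = 0.05)),
                   "high_risk")
  expect_identical(truth_label_rule(c(low_grade = 0.949, high_grade = 0.051)),
                   "high_risk")
  # background does not dilute the rule (fractions are relative to tissue)
  expect_identical(truth_label_rule(c(low_grade = 0.475, high_grade = 0.025)),
                   "high_risk")
})

test_that("identical spec and seed give bit-identical rasters", {
  sp <- slide_spec("det", 384, 384, c(high_grade = 0.6, invasive = 0.2),
                   background_fraction = 0.2, marker = "blue", seed = 11)
  a <- generate_slide(sp)
  b <- generate_slide(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$regions, b$regions)
})

test_that("class textures are separable by trivial pixel statistics", {
  # nearest-centroid on (mean R, mean G, mean B, dark-spot fraction),
  # centroids from one corpus, evaluated on a fresh one
  featurize <- function(patches) {
    t(vapply(patches, function(p) {
      px <- p$pixels
      c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]),
        mean(px[, , 2] < 120))
    }, numeric(4)))
  }
  tr <- single_class_patches(2, 5)
  te <- single_class_patches(1, 55)
  ftr <- featurize(tr); fte <- featurize(te)
  ytr <- vapply(tr, `[[`, "", "annotation_class")
  yte <- vapply(te, `[[`, "", "annotation_class")
  mu <- apply(ftr, 2, function(col) tapply(col, ytr, mean))
  scale_ <- apply(ftr, 2, sd)
  pred <- apply(fte, 1, function(f) {
    d <- colSums(((t(mu) - f) / scale_)^2)
    rownames(mu)[which.min(d)]
  })
  expect_gte(mean(pred == yte), 0.95)
})

test_that("cohort generation is seeded, validated, and degenerate-safe", {
  expect_error(cohort_spec(10, baseline_hazard = 0), "positive")
  expect_error(cohort_spec(10, hazard_ratio = -1), "positive")
  expect_identical(nrow(generate_cohort(cohort_spec(0))), 0L)

  cs <- cohort_spec(50, seed = 9)
  a <- generate_cohort(cs); b <- generate_cohort(cs)
  expect_identical(a, b)

  # censor_time_max -> 0: everyone censored at ~0
  cz <- generate_cohort(cohort_spec(40, censor_time_max = 1e-12, seed = 2))
  expect_true(all(cz$event == 0))
  expect_true(all(cz$time_months <= 1e-9 * 1.0001))
  expect_true(all(cz$time_months > 0))
})

test_that("higher hazard ratio gives more events in the high-risk arm", {
  n <- 2000
  labels <- stats::setNames(rep(c("low_risk", "high_risk"), each = n / 2),
                            sprintf("P%04d", seq_len(n)))
  ev_rate <- function(hr) {
    co <- generate_cohort(cohort_spec(n, baseline_hazard = 0.01, hazard_ratio = hr,
                                      censor_time_max = 120, seed = 31), labels)
    mean(co$event[co$risk_group == "high_risk"])
  }
  r1 <- ev_rate(1); r2 <- ev_rate(2); r4 <- ev_rate(4)
  expect_lt(r1, r2)
  expect_lt(r2, r4)
})

test_that("dataset simulation writes slides, annotations and linked tables", {
  dir <- withr::local_tempdir()
  tr <- make_slide_specs(3, 256, 256, seed = 1, prefix = "A")
  te <- make_slide_specs(2, 256, 256, seed = 2, prefix = "B")
  sim <- simulate_dataset(dir, tr, te, cohort_spec(0, seed = 3))
  expect_identical(nrow(sim$manifest), 5L)
  expect_true(all(file.exists(sim$manifest$path)))
  expect_true(all(file.exists(sim$manifest$xml_path)))
  expect_identical(sort(unique(sim$manifest$split)), c("test", "train"))
  # survival table covers every patient with positive times
  expect_setequal(sim$survival$patient_id, unique(sim$manifest$patient_id))
  expect_true(all(sim$survival$time_months > 0))
  # XML round trip matches the painted regions
  sl <- generate_slide(tr[[1]])
  got <- read_asap_annotations(sim$manifest$xml_path[1])
  expect_identical(got[order(got$x0), ], sl$regions[order(sl$regions$x0), ],
                   ignore_attr = TRUE)
})
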