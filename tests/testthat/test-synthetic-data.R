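# The procedural texture and cohort generators.

test_that("patch generator honours the class archetypes", {
  p <- texture_params(seed = 1L)
  back <- generate_patch("BACK", p)
  expect_equal(dim(back), c(224L, 224L, 3L))
  expect_true(all(back >= 0 & back <= 255))
  expect_gt(mean(back), 230)           # background is near-white

  gray <- function(x) (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  lym <- generate_patch("LYM", p)
  adi <- generate_patch("ADI", p)
  dark_lym <- mean(gray(lym) < 100)
  dark_adi <- mean(gray(adi) < 100)
  expect_gte(dark_lym - dark_adi, 0.10)  # lymphocytes are dense dark blobs

  expect_error(generate_patch("TUMOR", p), "valid codes")
})

test_that("patches are bit-identical under a fixed seed", {
  p <- texture_params(seed = 11L)
  expect_identical(generate_patch("LYM", p), generate_patch("LYM", p))
  expect_false(identical(generate_patch("LYM", p),
                         generate_patch("LYM", texture_params(seed = 12L))))
})

test_that("region generator honours composition and mask ground truth", {
  p <- texture_params(seed = 2L)
  r1 <- generate_region(c(TUM = 1.0), p, size = 600L, block = 150L)
  expect_equal(sort(unique(as.vector(r1$mask))),
               match("TUM", tissue_classes()))

  r2 <- generate_region(c(TUM = 0.5, STR = 0.5), p)
  fr <- table(factor(r2$mask, levels = 1:9)) / length(r2$mask)
  expect_true(fr[match("TUM", tissue_classes())] >= 0.48)
  expect_true(fr[match("TUM", tissue_classes())] <= 0.52)
  expect_true(fr[match("STR", tissue_classes())] >= 0.48)
  expect_true(fr[match("STR", tissue_classes())] <= 0.52)

  expect_error(generate_region(c(TUM = 0.5, STR = 0.6), p), "sum to 1")
  expect_identical(generate_region(c(TUM = 0.5, STR = 0.5), p),
                   generate_region(c(TUM = 0.5, STR = 0.5), p))
})

test_that("cohort tables have the promised shape and are deterministic", {
  cfg <- cohort_config(n = 50L, endpoints = c("OS", "DSS"), seed = 3L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 50L)
  expect_true(all(c("time_OS", "event_OS", "time_DSS", "event_DSS",
                    paste0("a_", tissue_classes())) %in% names(co)))
  expect_true(all(co$stage %in% 1:4))
  expect_true(all(co$sex %in% 0:1))
  expect_true(all(co$age >= 30 & co$age <= 95))
  expect_true(all(co$time_OS > 0))
  expect_identical(co, generate_cohort(cfg))
  expect_error(cohort_config(n = 1L), "at least 2")
})

test_that("per-region activation draws live on the simplex", {
  co <- generate_cohort(cohort_config(n = 200L, regions_per_patient = 1L,
                                      seed = 4L))
  A <- as.matrix(co[paste0("a_", tissue_classes())])
  expect_true(all(A >= 0))
  expect_true(all(abs(rowSums(A) - 1) < 1e-9))
  # pooled vectors dominate single draws componentwise but stay in [0, 1]
  co2 <- generate_cohort(cohort_config(n = 200L, regions_per_patient = 3L,
                                       seed = 4L))
  A2 <- as.matrix(co2[paste0("a_", tissue_classes())])
  expect_true(all(A2 >= 0 & A2 <= 1))
})

test_that("censoring fraction decreases as the horizon grows", {
  fr <- vapply(c(30, 60, 120, 240), function(C) {
    co <- generate_cohort(cohort_config(n = 800L, censor_horizon = C,
                                        seed = 5L))
    mean(co$event_OS == 0)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("planted univariable hazard ratios are recovered", {
  for (k in c(2, 6)) {
    b <- stats::setNames(numeric(9), tissue_classes())
    b["DEB"] <- log(k)
    co <- generate_cohort(cohort_config(n = 2000L, beta = b, h0 = 0.06,
                                        seed = 40L + k))
    expect_gte(mean(co$event_OS), 0.7)
    hr <- univariable_hr(co$a_DEB, co$time_OS, co$event_OS)
    expect_gte(hr, k / 1.4)
    expect_lte(hr, k * 1.4)
  }
})

test_that("null cohorts give near-unit hazard ratios for every class", {
  co <- generate_cohort(cohort_config(n = 2000L, censor_horizon = 1e4,
                                      seed = 101L))
  for (cl in tissue_classes()) {
    hr <- univariable_hr(co[[paste0("a_", cl)]], co$time_OS, co$event_OS)
    expect_gte(hr, 0.8)
    expect_lte(hr, 1.25)
  }
})
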