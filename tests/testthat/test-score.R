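# Youden cutoffs, the deep stroma score, and the survival models around it.

test_that("youden cutoff solves the textbook cases", {
  tau <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(tau), 0.5)
  expect_equal(attr(tau, "youden"), 1)

  # tie at J = 0.5 between candidates 1.5 and 3.5, both equidistant from the
  # median 2.5; the smaller cutoff wins
  tau2 <- youden_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(as.numeric(tau2), 1.5)
  expect_equal(attr(tau2, "youden"), 0.5)

  expect_error(youden_cutoff(c(1, 2, 3), c(1, 1, 1)), "both label classes")
  expect_error(youden_cutoff(c(2, 2, 2), c(0, 1, 0)), "distinct values")
})

test_that("youden cutoff matches the brute-force oracle on random instances", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    values <- round(stats::runif(n), sample(1:3, 1))
    labels <- stats::rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2 || length(unique(values)) < 2) next
    expect_equal(as.numeric(youden_cutoff(values, labels)),
                 oracle_youden(values, labels))
  }
})

test_that("univariable hazard ratios recover planted and null effects", {
  b <- stats::setNames(numeric(9), tissue_classes())
  b["STR"] <- log(2)
  co <- generate_cohort(cohort_config(n = 2000L, beta = b, h0 = 0.06,
                                      seed = 61L))
  expect_gte(univariable_hr(co$a_STR, co$time_OS, co$event_OS), 1.6)
  expect_lte(univariable_hr(co$a_STR, co$time_OS, co$event_OS), 2.5)
  hr_null <- univariable_hr(co$a_MUC, co$time_OS, co$event_OS)
  expect_gte(hr_null, 0.8)
  expect_lte(hr_null, 1.25)
  expect_error(univariable_hr(co$a_STR, co$time_OS, rep(0, nrow(co))),
               "no events")
  expect_error(univariable_hr(rep(0.5, nrow(co)), co$time_OS, co$event_OS),
               "non-identifiable")
})

test_that("score model building selects planted harmful classes", {
  co <- fixture_planted_cohort()
  sm <- build_score_model(co)
  expect_true(all(c("DEB", "MUS") %in% sm$selected))
  expect_false("MUC" %in% sm$selected)
  expect_false("TUM" %in% sm$selected)
  expect_true(all(sm$hr[sm$selected] > 1))
  # cutoffs inside the observed activation range
  for (cl in sm$selected) {
    a <- co[[paste0("a_", cl)]]
    expect_gt(sm$cutoff[[cl]], min(a))
    expect_lt(sm$cutoff[[cl]], max(a))
  }
  expect_identical(sm, build_score_model(fixture_planted_cohort()))
})

test_that("protective-only cohorts cannot support a score", {
  # hand-built cohort with independent activations so every class is
  # unambiguously protective (compositional coupling would blur this)
  set.seed(71)
  n <- 400L
  A <- matrix(stats::runif(n * 9), n, 9,
              dimnames = list(NULL, paste0("a_", tissue_classes())))
  lp <- -2 * (rowSums(A) - 4.5)   # centred so events stay plentiful
  tt <- stats::rexp(n, 0.1 * exp(lp))
  co <- data.frame(stage = sample(1:4, n, TRUE), sex = 0L, age = 65, A,
                   time_OS = pmin(tt, 120), event_OS = as.integer(tt <= 120))
  expect_error(build_score_model(co), "no class with HR > 1")
})

test_that("published constants give the printed worked examples", {
  sm <- published_score_model()
  expect_equal(sm$selected, c("ADI", "DEB", "LYM", "MUS", "STR"))
  a <- sm$cutoff / 2
  a[c("DEB", "LYM", "STR")] <- sm$cutoff[c("DEB", "LYM", "STR")] * 1.5
  expect_equal(compute_score(sm, a), 5.967 + 1.226 + 1.154)
  expect_equal(compute_score(sm, a), 8.347)

  a5 <- sm$cutoff / 2
  a5[sm$selected] <- sm$cutoff[sm$selected] * 1.5
  expect_equal(compute_score(sm, a5), 13.258)

  expect_equal(compute_score(sm, sm$cutoff / 2), 0)
})

test_that("the score is monotone in selected classes, blind to the rest", {
  sm <- published_score_model()
  set.seed(3)
  for (i in 1:20) {
    a <- stats::runif(9); names(a) <- tissue_classes()
    s0 <- compute_score(sm, a)
    a_up <- a; a_up[sm$selected] <- pmin(a_up[sm$selected] * 2, 1)
    expect_gte(compute_score(sm, a_up), s0)
    a_ns <- a; a_ns[setdiff(names(a), sm$selected)] <- stats::runif(4)
    expect_equal(compute_score(sm, a_ns), s0)
  }
})

test_that("dichotomization is strict and frozen", {
  sm <- published_score_model()
  expect_equal(as.character(dichotomize(sm, c(8.347, 8.347))),
               c("low", "low"))
  expect_equal(as.character(dichotomize(sm, c(8.348, 0))), c("high", "low"))

  co <- fixture_planted_cohort()
  sm2 <- build_score_model(co)
  grp <- dichotomize(sm2, compute_score(sm2, co))
  expect_lte(abs(mean(grp == "high") - 0.5), 0.15)

  # frozen median: validation labels do not depend on their own distribution
  co_val <- fixture_planted_cohort(n = 300L, seed = 99L)
  s_val <- compute_score(sm2, co_val)
  expect_equal(as.character(dichotomize(sm2, s_val)),
               ifelse(s_val > sm2$median, "high", "low"))
})

test_that("score models survive JSON freezing bit-exactly", {
  co <- fixture_planted_cohort()
  sm <- build_score_model(co)
  path <- tempfile(fileext = ".json")
  write_score_model(sm, path)
  sm2 <- read_score_model(path)
  expect_identical(compute_score(sm, co), compute_score(sm2, co))
  expect_identical(dichotomize(sm, compute_score(sm, co)),
                   dichotomize(sm2, compute_score(sm2, co)))
  unlink(path)
})

test_that("multivariable Cox recovers a planted group effect", {
  set.seed(55)
  n <- 1000L
  co <- generate_cohort(cohort_config(n = n, h0 = 0.05, seed = 81L))
  grp <- stats::rbinom(n, 1, 0.5)
  lp <- log(2) * grp
  tt <- stats::rexp(n, 0.05 * exp(lp))
  cc <- stats::runif(n, 0, 120)
  co$time_OS <- pmin(tt, cc)
  co$event_OS <- as.integer(tt <= cc)
  res <- multivariable_cox(co, grp)
  g <- res[res$term == "group", ]
  expect_gte(g$hr, 1.6)
  expect_lte(g$hr, 2.5)
  expect_gt(g$ci_low, 1)
  expect_error(multivariable_cox(co, grp, endpoint = "DSS"), "lacks columns")
  co$event_OS <- 0L
  expect_error(multivariable_cox(co, grp), "no events")
})

test_that("null group effects are covered by the confidence interval", {
  hits <- 0L
  for (i in 1:30) {
    co <- generate_cohort(cohort_config(n = 400L, h0 = 0.05,
                                        seed = 300L + i))
    set.seed(400 + i)
    grp <- stats::rbinom(nrow(co), 1, 0.5)
    res <- multivariable_cox(co, grp)
    g <- res[res$term == "group", ]
    hits <- hits + (g$ci_low <= 1 && 1 <= g$ci_high)
  }
  expect_gte(hits / 30, 0.9)
})

test_that("per-stage models localise a stage-specific effect", {
  set.seed(66)
  n <- 2000L
  co <- generate_cohort(cohort_config(n = n, h0 = 0.05, seed = 91L))
  grp <- stats::rbinom(n, 1, 0.5)
  lp <- ifelse(co$stage == 4, log(3), 0) * grp
  tt <- stats::rexp(n, 0.05 * exp(lp))
  cc <- stats::runif(n, 0, 120)
  co$time_OS <- pmin(tt, cc)
  co$event_OS <- as.integer(tt <= cc)
  ps <- per_stage_models(co, grp)
  expect_named(ps, paste0("stage_", 1:4))
  g4 <- ps$stage_4[ps$stage_4$term == "group", ]
  expect_gt(g4$ci_low, 1)
  g1 <- ps$stage_1[ps$stage_1$term == "group", ]
  expect_true(g1$ci_low <= 1 && 1 <= g1$ci_high)

  co1 <- co[co$stage != 1, ]
  ps1 <- per_stage_models(co1, grp[co$stage != 1])
  expect_equal(ps1$stage_1, "insufficient events")
})

test_that("CAF scores are plain signature means", {
  expr <- matrix(5, nrow = 3, ncol = 4,
                 dimnames = list(c("g1", "g2", "g3"), paste0("p", 1:4)))
  expect_equal(unname(caf_score(expr, c("g1", "g2", "g3"))), rep(5, 4))
  expr2 <- rbind(g1 = c(2, 2), g2 = c(4, 6))
  colnames(expr2) <- c("pA", "pB")
  expect_equal(unname(caf_score(expr2, c("g1", "g2"))), c(3, 4))
  expect_equal(caf_score(expr2, c("g1", "g2")),
               caf_score(expr2, c("g2", "g1")))
  expect_message(caf_score(expr2, c("g1", "g2", "gX")), "absent")
  expect_error(caf_score(expr2, "nope"), "no signature gene")
  expect_error(caf_score(expr2, character(0)), "empty gene list")
})

test_that("score comparisons recover a planted STR-CAF correlation", {
  co <- generate_cohort(cohort_config(n = 500L, caf_rho = 0.3,
                                      path_stroma = TRUE, h0 = 0.05,
                                      seed = 111L))
  b <- stats::setNames(numeric(9), tissue_classes()); b["DEB"] <- log(3)
  co2 <- generate_cohort(cohort_config(n = 500L, beta = b, caf_rho = 0.3,
                                       path_stroma = TRUE, h0 = 0.05,
                                       seed = 112L))
  sm <- build_score_model(co2)
  rep <- compare_scores(sm, co2)
  r <- rep$correlations
  str_caf <- r$pearson_r[r$comparison == "str_activation_vs_caf"]
  expect_gte(str_caf, 0.15)
  expect_lte(str_caf, 0.45)
  expect_true(all(c("deep_stroma", "caf_score", "path_stroma_pct") %in%
                    names(rep$models)))
  expect_true(any(grepl("tumor_purity", rep$skipped)))

  # missing caf column: comparison skipped, remaining models reported
  co3 <- co2; co3$caf_score <- NULL
  rep3 <- compare_scores(sm, co3)
  expect_false("caf_score" %in% names(rep3$models))
  expect_true(any(grepl("caf_score", rep3$skipped)))

  # identical columns correlate perfectly
  co4 <- co2; co4$caf_score <- compute_score(sm, co4)
  rep4 <- compare_scores(sm, co4)
  expect_equal(rep4$correlations$pearson_r[
    rep4$correlations$comparison == "deep_stroma_vs_caf"], 1)
})

test_that("rows with missing endpoint data are excluded, never imputed", {
  co <- fixture_planted_cohort(n = 300L, seed = 131L)
  co$time_OS[1:10] <- NA
  sm <- build_score_model(co)
  expect_equal(sm$n, 290L)
  expect_equal(sm$dropped_missing, 10L)
  res <- multivariable_cox(co, stats::rbinom(nrow(co), 1, 0.5))
  expect_equal(attr(res, "n"), 290L)
})
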