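test_that("CV uses the sample standard deviation and guards degenerate input", {
  expect_equal(cv_stats(c(5, 5, 5, 5))$cv, 0)
  r <- cv_stats(c(1, 2, 3, 4))
  expect_equal(r$mean, 2.5)
  expect_equal(r$sd, sqrt(5 / 3))
  expect_equal(r$cv, sqrt(5 / 3) / 2.5)
  expect_equal(r$flag, "ok")
  expect_identical(cv_stats(c(-2, 2))$flag, "undefined_mean_zero")
  expect_true(is.na(cv_stats(c(-2, 2))$cv))
  expect_identical(cv_stats(c(3, NA))$flag, "insufficient_n")
  # negative mean uses |mu|
  expect_equal(cv_stats(c(-1, -2, -3, -4))$cv, sqrt(5 / 3) / 2.5)
})

test_that("CV is scale-invariant and survives sample duplication", {
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(sample(3:11, 1), mean = runif(1, 1, 50), sd = runif(1, 0.1, 5))
    c1 <- cv_stats(x)$cv
    expect_equal(cv_stats(x * runif(1, 0.01, 100))$cv, c1)
    # duplication oracle: exact recomputation on the duplicated sample
    xx <- c(x, x)
    expect_equal(cv_stats(xx)$cv, sd(xx) / abs(mean(xx)))
  }
})

test_that("per-feature CV tables cover the registry with pairwise NA drops", {
  ph <- small_phantom()
  coh <- generate_cohort(ph$structs, "reproducibility", base_seed = 3)
  tabs <- extract_cohort(coh, ph$structs, study = "reproducibility")
  cvr <- feature_cv_table(tabs$PTV)
  expect_identical(nrow(cvr), 212L)
  expect_identical(unique(cvr$study), "reproducibility")
  expect_true(all(cvr$n_used[cvr$flag == "ok"] >= 2))
  expect_true(all(cvr$cv[cvr$flag == "ok"] >= 0))
  # a constant feature is stable at any positive threshold
  tb <- tabs$PTV
  tb[1, ] <- 42
  cvr2 <- feature_cv_table(tb)
  expect_equal(cvr2$cv[1], 0)
  # NA cells are dropped pairwise with n_used recorded
  tb[2, 1] <- NA
  cvr3 <- feature_cv_table(tb)
  expect_identical(cvr3$n_used[2], 3L)
})

test_that("threshold selection uses strict inequalities and is monotone", {
  reg <- default_registry()
  mk <- function(cv) data.frame(feature_id = reg$feature_id, cv = cv)
  cvs <- rep(NA_real_, 212)
  cvs[1:10] <- 0.2; cvs[11] <- 0.3; cvs[12:145] <- 0.1
  cvs[146:150] <- 1.5; cvs[151] <- 1.0; cvs[152:211] <- 0.5
  sel <- select_features(list(stability = mk(cvs)), 0.3, 1.0)
  # cv == threshold is excluded on both sides; NA belongs to neither set
  expect_identical(length(sel$sets$stable_stability), 144L)
  expect_false(reg$feature_id[11] %in% sel$sets$stable_stability)
  expect_identical(length(sel$sets$sensitive_stability_gt1), 5L)
  expect_false(reg$feature_id[151] %in% sel$sets$sensitive_stability_gt1)
  # 134 of 212 -> 63.2%
  cvs2 <- rep(NA_real_, 212); cvs2[1:134] <- 0.1
  sel2 <- select_features(list(repro = mk(cvs2)), 0.3, 1.0)
  expect_equal(sel2$percentages$percent[sel2$percentages$set == "stable_repro"], 63.2)
  # monotonicity over random CV vectors
  set.seed(51)
  for (rep in 1:10) {
    cv <- runif(212, 0, 2)
    lo <- select_features(list(s = mk(cv)), 0.2, 0.7)
    hi <- select_features(list(s = mk(cv)), 0.4, 1.3)
    expect_true(all(lo$sets$stable_s %in% hi$sets$stable_s))
    expect_true(all(hi$sets$sensitive_s_gt1.3 %in% lo$sets$sensitive_s_gt0.7))
  }
  expect_error(select_features(list(s = mk(cvs)), -0.3, 1), "positive")
})

test_that("family summaries match direct recomputation", {
  rec <- data.frame(study = "s", roi = "PTV",
                    family = c("GLCM", "GLCM", "GLRLM", "GLRLM", "GLRLM"),
                    cv = c(0.1, 0.3, 0.2, NA, 0.6))
  fs <- family_summary(rec)
  glcm <- fs[fs$family == "GLCM", ]
  expect_equal(glcm$mean_cv, 0.2)
  expect_equal(glcm$median, 0.2)
  glrlm <- fs[fs$family == "GLRLM", ]
  expect_identical(glrlm$n_defined, 2L)
  expect_equal(glrlm$mean_cv, 0.4)
  # sorted-middle oracle on a random family
  set.seed(8)
  cv <- runif(63)
  fs2 <- family_summary(data.frame(study = "s", roi = "r", family = "GLRLM", cv = cv))
  expect_equal(fs2$median, sort(cv)[32])
  # all-undefined family flagged empty
  fs3 <- family_summary(data.frame(study = "s", roi = "r", family = "GLSZM",
                                   cv = NA_real_))
  expect_true(fs3$empty)
})

test_that("ICC reproduces perfect agreement and the ANOVA oracle", {
  expect_equal(icc(matrix(c(1, 2, 3, 1, 2, 3), 3, 2))$icc, 1)
  m <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40, 10, 20, 30, 40), 4, 3)
  expect_equal(icc(m)$icc, 1)
  # random matrix vs an aov-based mean-squares oracle
  set.seed(14)
  x <- matrix(rnorm(12, 10, 2), 4, 3)
  got <- icc(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(1:4, 3)), rater = factor(rep(1:3, each = 4)))
  ms <- summary(aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  vs <- max(0, (ms[1] - ms[3]) / 3)
  vr <- max(0, (ms[2] - ms[3]) / 4)
  expect_equal(got$icc, vs / (vs + vr + ms[3]), tolerance = 1e-10)
  expect_equal(got$MSE, ms[3], tolerance = 1e-10)
  expect_identical(icc(matrix(5, 3, 3))$flag, "zero_total_variance")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(icc(matrix(1:3, 3, 1)), "2 subjects|raters")
})

test_that("family-level ICC treats ROIs as subjects and plans as raters", {
  ph <- small_phantom()
  coh <- generate_cohort(ph$structs, "reproducibility", base_seed = 6)
  tabs <- extract_cohort(coh, ph$structs, study = "reproducibility")
  res <- icc_study(tabs, family = "STAT")
  expect_setequal(unique(res$group), c("all", "high_dose", "low_dose"))
  expect_identical(sum(res$group == "all"), 17L)
  ok <- res$flag == "ok"
  expect_true(any(ok))
  expect_true(all(res$icc[ok] <= 1 + 1e-12))
  expect_true(all(res$icc[ok] >= 0))
  expect_match(attr(res, "note"), "heterogeneity")
  # hand check one feature against icc() directly
  id <- "STAT_mean"
  m <- t(sapply(c("PTV", "parotid_L", "parotid_R", "spinal_canal", "trachea",
                  "RING"), function(r) tabs[[r]][id, ]))
  expect_equal(res$icc[res$group == "all" & res$feature_id == id], icc(m)$icc)
  expect_error(icc_study(tabs, family = "NOPE"), "unknown family")
})

test_that("extraction comparisons localise discrepancies", {
  ph <- small_phantom()
  fm <- extract_all(small_plan(), ph$structs)
  a <- do.call(cbind, fm$features)
  expect_identical(compare_extractions(a, a)$max_abs_diff, 0)
  b <- a
  b["GLCM_contrast_3D_merge", "PTV"] <- b["GLCM_contrast_3D_merge", "PTV"] + 1e-3
  cmp <- compare_extractions(a, b)
  expect_equal(cmp$max_abs_diff, 1e-3)
  expect_identical(nrow(cmp$mismatches), 1L)
  expect_identical(cmp$mismatches$feature_id, "GLCM_contrast_3D_merge")
  expect_identical(cmp$mismatches$plan, "PTV")
  expect_error(compare_extractions(a, a[, 1:3]), "dimensions")
})
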