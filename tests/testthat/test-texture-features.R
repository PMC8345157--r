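test_that("the default registry counts 17/100/63/32 = 212", {
  reg <- default_registry()
  cnt <- registry_counts(reg)
  expect_identical(cnt[["STAT"]], 17L)
  expect_identical(cnt[["GLCM"]], 100L)
  expect_identical(cnt[["GLRLM"]], 63L)
  expect_identical(cnt[["GLSZM"]], 32L)
  expect_identical(cnt[["total"]], 212L)
  expect_false(anyDuplicated(reg$feature_id) > 0)
  # the dropped run-length entry is configurable
  reg2 <- default_registry(glrlm_drop = c("run_percentage", "3D_merge"))
  expect_identical(registry_counts(reg2)[["GLRLM"]], 63L)
  expect_false("GLRLM_run_percentage_3D_merge" %in% reg2$feature_id)
  expect_true("GLRLM_run_entropy_2D_avg" %in% reg2$feature_id)
  expect_error(default_registry(glrlm_drop = c("nope", "3D_avg")), "glrlm_drop")
})

test_that("a uniform ROI collapses texture to its degenerate values", {
  disc <- fake_disc(array(7L, c(3, 3, 2)), G = 10)
  g <- glcm_features(disc)
  expect_length(g, 100)
  for (agg in c("2D_avg", "2D_merge", "3D_avg", "3D_merge")) {
    expect_equal(unname(g[paste0("GLCM_contrast_", agg)]), 0)
    expect_equal(unname(g[paste0("GLCM_joint_entropy_", agg)]), 0)
    expect_true(is.na(g[paste0("GLCM_correlation_", agg)]))
    expect_true(is.na(g[paste0("GLCM_information_correlation_1_", agg)]))
  }
  # uniform 1D ROI: the along-run direction carries a single run, so its
  # run-length non-uniformity is 1^2 / 1 = 1
  uni1d <- array(2L, c(5, 1, 1))
  runs <- dosetex:::run_lengths(uni1d, c(1, 0, 0))
  f1 <- dosetex:::rl_features_sparse(runs$level, runs$length,
                                     rep(1, nrow(runs)), Nv = 5, "run")
  expect_equal(unname(f1["run_length_non_uniformity"]), 1)
  expect_equal(unname(f1["run_percentage"]), 1 / 5)
  z <- sizezone_features(fake_disc(array(2L, c(3, 3, 3)), G = 3))
  expect_equal(unname(z["GLSZM_zone_size_non_uniformity_3D"]), 1)
  expect_equal(unname(z["GLSZM_grey_level_non_uniformity_3D"]), 1)
})

test_that("merged 2D contrast equals a brute-force pair-enumeration oracle", {
  lev <- array(c(1L, 1L, 2L,
                 1L, 2L, 2L,
                 2L, 2L, 2L), c(3, 3, 1))
  disc <- fake_disc(lev, G = 2)
  # oracle: enumerate all in-slice neighbour pairs in both orders
  num <- 0; den <- 0
  for (x in 1:3) for (y in 1:3) for (k in seq_len(nrow(dosetex:::DIRS2))) {
    d <- dosetex:::DIRS2[k, ]
    for (s in c(1, -1)) {
      xx <- x + s * d[1]; yy <- y + s * d[2]
      if (xx >= 1 && xx <= 3 && yy >= 1 && yy <= 3) {
        num <- num + (lev[x, y, 1] - lev[xx, yy, 1])^2
        den <- den + 1
      }
    }
  }
  g <- glcm_features(disc)
  expect_equal(unname(g["GLCM_contrast_2D_merge"]), num / den)
})

test_that("run-length features follow the matrix definitions", {
  # [1,1,1] along x: N_runs = 1, so SRE = 1/9, LRE = 9, RLNU = 1
  lev <- array(1L, c(3, 1, 1))
  r <- runlength_features(fake_disc(lev, G = 2))
  expect_equal(unname(r["GLRLM_short_run_emphasis_3D_avg"]),
               mean(c(1 / 9, rep(1, 12))))  # x-run of 3; other 12 dirs: 3 runs of 1
  expect_equal(unname(r["GLRLM_run_percentage_3D_avg"]),
               mean(c(1 / 3, rep(1, 12))))
})

test_that("feature vectors are complete, deterministic and scale-invariant", {
  ph <- small_phantom()
  d <- small_plan(seed = 21)
  fm <- extract_all(d, ph$structs)
  expect_length(fm$features, 6)
  for (v in fm$features) expect_length(v, 212)
  expect_identical(sum(vapply(fm$features, length, 1L)), 1272L)
  # repeated extraction is bit-identical
  fm2 <- extract_all(d, ph$structs)
  cmp <- compare_extractions(do.call(cbind, fm$features),
                             do.call(cbind, fm2$features))
  expect_identical(cmp$max_abs_diff, 0)
  # doubling dose: texture families unchanged (roi_max), STAT mean doubles
  d2 <- dose_grid(d$values * 2, d$spacing_mm, d$origin_mm)
  fm3 <- extract_all(d2, ph$structs)
  for (nm in names(fm$features)) {
    a <- fm$features[[nm]]; b <- fm3$features[[nm]]
    tex <- !startsWith(names(a), "STAT")
    expect_identical(a[tex], b[tex])
    expect_equal(unname(b["STAT_mean"]), unname(2 * a["STAT_mean"]))
    expect_equal(unname(b["STAT_variance"]), unname(4 * a["STAT_variance"]))
  }
})

test_that("undersized ROIs are skipped with explicit error records", {
  ph <- small_phantom()
  st <- ph$structs
  st$rois$trachea$mask[] <- FALSE
  st$rois$trachea$mask[1, 1, 1] <- TRUE
  fm <- extract_all(small_plan(), st)
  expect_false("trachea" %in% names(fm$features))
  expect_identical(fm$errors$roi, "trachea")
  expect_match(fm$errors$reason, "voxels")
  expect_error(extract_all(small_plan(), ph$structs, rois = "no_such_roi"),
               "unknown ROI")
})

test_that("normalised texture matrices sum to one", {
  set.seed(404)
  for (rep in 1:10) {
    lev <- random_level_array(c(4, 4, 3), G = 5)
    if (sum(lev > 0) < 4) next
    disc <- fake_disc(lev, G = 5)
    tm <- cooccurrence_matrix(disc, c(1, 0, 0), normalise = TRUE)
    if (!tm$empty) expect_equal(sum(tm$matrix), 1)
  }
})
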