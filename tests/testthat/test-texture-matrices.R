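test_that("co-occurrence matrices match hand-enumerated examples", {
  # uniform 2x2x1 ROI at level 5, in-plane offset: symmetrised count 4 at (5,5)
  lev <- array(5L, c(2, 2, 1))
  disc <- fake_disc(lev, G = 6)
  tm <- cooccurrence_matrix(disc, c(1, 0, 0))
  expect_equal(sum(tm$matrix), 4)
  expect_equal(tm$matrix[5, 5], 4)
  tmn <- cooccurrence_matrix(disc, c(1, 0, 0), normalise = TRUE)
  expect_equal(tmn$matrix[5, 5], 1)
  expect_equal(sum(tmn$matrix), 1)
  # 1x2 slice [1, 2]: one scan pair -> entries (1,2) and (2,1) each 1
  lev2 <- array(c(1L, 2L), c(2, 1, 1))
  tm2 <- cooccurrence_matrix(fake_disc(lev2, G = 2), c(1, 0, 0))
  expect_equal(tm2$matrix, matrix(c(0, 1, 1, 0), 2, 2))
  # offsets must have Chebyshev norm 1
  expect_error(cooccurrence_matrix(disc, c(2, 0, 0)), "Chebyshev")
  expect_error(cooccurrence_matrix(disc, c(0, 0, 1), mode = "2D_slice"), "in-slice")
  # no valid pair -> flagged zero matrix
  iso <- array(0L, c(3, 3, 3)); iso[2, 2, 2] <- 1L
  tm3 <- cooccurrence_matrix(fake_disc(iso, G = 2), c(1, 0, 0))
  expect_true(tm3$empty)
  expect_equal(sum(tm3$matrix), 0)
})

test_that("co-occurrence counts equal the brute-force oracle on random arrays", {
  set.seed(101)
  for (rep in 1:80) {
    dims <- sample(2:4, 3, replace = TRUE)
    lev <- random_level_array(dims, G = 4)
    if (!any(lev > 0)) next
    disc <- fake_disc(lev, G = 4)
    for (k in sample(nrow(dosetex:::DIRS3), 4)) {
      d <- dosetex:::DIRS3[k, ]
      tm <- cooccurrence_matrix(disc, d)
      expect_equal(tm$matrix, o_glcm(lev, d, 4),
                   label = sprintf("rep %d dir (%d,%d,%d)", rep, d[1], d[2], d[3]))
      # symmetry always holds
      expect_identical(tm$matrix, t(tm$matrix))
    }
  }
})

test_that("run enumeration matches the oracle and truncates at mask gaps", {
  # row of three equal levels: one run of length 3
  r3 <- array(1L, c(3, 1, 1))
  runs <- dosetex:::run_lengths(r3, c(1, 0, 0))
  expect_equal(runs$level, 1)
  expect_equal(runs$length, 3)
  # excluded middle voxel splits the run: [1,1,_,1,1] -> two runs of 2
  gap <- array(1L, c(5, 1, 1)); gap[3, 1, 1] <- 0L
  runs2 <- dosetex:::run_lengths(gap, c(1, 0, 0))
  expect_equal(sort(runs2$length), c(2, 2))
  # random arrays, all 13 directions
  set.seed(202)
  for (rep in 1:60) {
    dims <- sample(2:4, 3, replace = TRUE)
    lev <- random_level_array(dims, G = 3)
    for (k in sample(nrow(dosetex:::DIRS3), 5)) {
      d <- dosetex:::DIRS3[k, ]
      got <- dosetex:::run_lengths(lev, d)
      got <- got[order(got$level, got$length), c("level", "length")]
      rownames(got) <- NULL
      want <- o_runs(lev, d); rownames(want) <- NULL
      expect_equal(got, want,
                   label = sprintf("rep %d dir (%d,%d,%d)", rep, d[1], d[2], d[3]))
    }
  }
})

test_that("zone labelling matches the flood-fill oracle", {
  # 2D checkerboard: diagonal connectivity merges each level into one zone
  chk <- array(0L, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) chk[x, y, 1] <- 1L + (x + y) %% 2L
  z <- dosetex:::size_zones(chk, "2D")
  expect_equal(nrow(z), 2)
  expect_equal(sort(z$size), c(8, 8))
  # two disjoint blobs of one level, sizes 3 and 5
  blob <- array(0L, c(10, 1, 1))
  blob[1:3, 1, 1] <- 2L; blob[6:10, 1, 1] <- 2L
  z2 <- dosetex:::size_zones(blob, "3D")
  expect_equal(sort(z2$size), c(3, 5))
  # uniform ROI: a single zone covering all voxels
  uni <- array(3L, c(3, 3, 3))
  z3 <- dosetex:::size_zones(uni, "3D")
  expect_equal(z3$size, 27)
  # random arrays vs oracle, 3D (26-conn) and per-slice 2D (8-conn)
  set.seed(303)
  for (rep in 1:60) {
    dims <- sample(2:4, 3, replace = TRUE)
    lev <- random_level_array(dims, G = 3)
    for (mode in c("3D", "2D")) {
      got <- dosetex:::size_zones(lev, mode)
      got <- got[order(got$level, got$size), , drop = FALSE]
      rownames(got) <- NULL
      conn <- if (mode == "3D") dosetex:::DIRS3 else dosetex:::DIRS2
      want <- o_zones(lev, conn); rownames(want) <- NULL
      expect_equal(got, want, label = sprintf("rep %d mode %s", rep, mode))
    }
  }
})
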