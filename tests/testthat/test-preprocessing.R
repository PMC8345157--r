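test_that("discretisation boundary behaviour and the 100-level contract", {
  g <- grid_geometry(c(3, 2, 2), c(1, 1, 1))
  v <- array(0, g$dim)
  v[1, 1, 1] <- 0; v[2, 1, 1] <- 33; v[3, 1, 1] <- 66
  v[, , 2] <- 10
  roi <- roi_mask(array(TRUE, g$dim), "r", g$spacing_mm)
  disc <- discretise(dose_grid(v, g$spacing_mm), roi, G = 100)
  expect_identical(disc$levels[1, 1, 1], 1L)    # zero dose -> level 1
  expect_identical(disc$levels[2, 1, 1], 51L)   # 33/66 -> floor(50)+1
  expect_identical(disc$levels[3, 1, 1], 100L)  # max -> top level
  expect_equal(disc$reference_max_Gy, 66)
  expect_equal(disc$level_width_Gy, 0.66)
  # every masked voxel gets exactly one level in [1, G]
  lv <- disc$levels[roi$mask]
  expect_true(all(lv >= 1 & lv <= 100))
  expect_identical(sum(tabulate(lv, 100)), sum(roi$mask))
})

test_that("discretisation is monotone and scale-invariant under roi_max", {
  set.seed(31)
  g <- grid_geometry(c(4, 4, 4), c(1, 1, 1))
  v <- array(runif(64, 0, 70), g$dim)
  roi <- roi_mask(array(runif(64) < 0.8, g$dim), "r", g$spacing_mm)
  d1 <- discretise(dose_grid(v, g$spacing_mm), roi, G = 100)
  d2 <- discretise(dose_grid(v * 2.7, g$spacing_mm), roi, G = 100)
  expect_identical(d1$levels, d2$levels)
  ord <- order(v[roi$mask])
  expect_true(all(diff(d1$levels[roi$mask][ord]) >= 0))
})

test_that("degenerate discretisation inputs are rejected", {
  g <- grid_geometry(c(2, 2, 2), c(1, 1, 1))
  zero <- dose_grid(array(0, g$dim), g$spacing_mm)
  roi <- roi_mask(array(TRUE, g$dim), "r", g$spacing_mm)
  expect_error(discretise(zero, roi), "all-zero")
  empty <- roi_mask(array(FALSE, g$dim), "r", g$spacing_mm)
  expect_error(discretise(dose_grid(array(1, g$dim), g$spacing_mm), empty), "empty")
})

test_that("resampling reproduces constants and affine fields exactly", {
  g <- grid_geometry(c(11, 11, 11), c(1, 1, 1), c(0, 0, 0))
  # identity resample returns values unchanged
  d <- small_plan(seed = 4)
  same <- resample_dose(d, grid_of(d))
  expect_identical(same$values, d$values)
  # constant field stays constant on any overlapping grid
  cst <- dose_grid(array(10, g$dim), g$spacing_mm, g$origin_mm)
  tg <- grid_geometry(c(5, 5, 5), c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_true(all(abs(resample_dose(cst, tg)$values - 10) < 1e-12))
  # linear ramp: trilinear interpolation is exact for affine fields
  xs <- 0:10
  ramp <- array(0, g$dim)
  for (x in 1:11) for (y in 1:11) for (z in 1:11)
    ramp[x, y, z] <- 1 + 2 * xs[x] + 0.5 * xs[y] - 0.25 * xs[z] + 10
  rg <- dose_grid(ramp, g$spacing_mm, g$origin_mm)
  out <- resample_dose(rg, tg)
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    px <- 0.5 + (x - 1) * 2; py <- 0.5 + (y - 1) * 2; pz <- 0.5 + (z - 1) * 2
    expect_equal(out$values[x, y, z], 1 + 2 * px + 0.5 * py - 0.25 * pz + 10,
                 tolerance = 1e-12)
  }
  # out-of-extent voxels become 0 and are reported in coverage
  big <- grid_geometry(c(5, 5, 5), c(10, 10, 10), c(-10, -10, -10))
  out2 <- resample_dose(cst, big)
  expect_lt(attr(out2, "coverage"), 1)
  expect_error(resample_dose(cst, grid_geometry(c(2, 2, 2), 1, c(500, 500, 500))),
               "overlap")
})

test_that("contour rasterization matches the point-in-polygon oracle", {
  g <- grid_geometry(c(16, 16, 3), c(1, 1, 1), c(0, 0, 0))
  # 10 x 10 mm square with edges between voxel centres -> exactly 100 voxels
  sq <- cbind(c(2.5, 12.5, 12.5, 2.5), c(2.5, 2.5, 12.5, 12.5), 1)
  m <- rasterize_contours(list(name = "sq", contours = list(sq)), g)
  expect_identical(sum(m$mask), 100L)
  expect_identical(sum(m$mask[, , 2]), 100L)
  # winding order is irrelevant under the even-odd rule
  m2 <- rasterize_contours(list(name = "sq", contours = list(sq[4:1, ])), g)
  expect_identical(m$mask, m2$mask)
  # random polygons agree with the independent crossing oracle
  set.seed(77)
  for (rep in 1:5) {
    k <- sample(3:7, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 2, 7)
    vx <- 7.5 + r * cos(ang); vy <- 7.5 + r * sin(ang)
    poly <- cbind(vx, vy, 0)
    got <- rasterize_contours(list(name = "p", contours = list(poly)), g)$mask[, , 1]
    for (x in 1:16) for (y in 1:16) {
      expect_identical(got[x, y], o_pip(x - 1, y - 1, vx, vy),
                       label = sprintf("rep %d voxel (%d,%d)", rep, x, y))
    }
  }
  # holes: outer square minus inner square (even-odd)
  outer_sq <- cbind(c(1.5, 13.5, 13.5, 1.5), c(1.5, 1.5, 13.5, 13.5), 0)
  inner_sq <- cbind(c(5.5, 9.5, 9.5, 5.5), c(5.5, 5.5, 9.5, 9.5), 0)
  hole <- rasterize_contours(list(name = "h", contours = list(outer_sq, inner_sq)), g)
  expect_identical(sum(hole$mask), 12L * 12L - 4L * 4L)
  # empty contour list warns and returns an empty mask
  expect_warning(e <- rasterize_contours(list(name = "e", contours = list()), g),
                 "no contours")
  expect_false(any(e$mask))
  # contour plane off every slice is an error
  off <- cbind(c(1, 5, 5), c(1, 1, 5), 7.7)
  expect_error(rasterize_contours(list(name = "o", contours = list(off)), g),
               "slice")
})
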