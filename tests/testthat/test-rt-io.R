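test_that("RT-Dose round trip preserves dose within quantisation", {
  d <- small_plan(seed = 2)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(d, path)
  d2 <- read_rtdose(path)
  expect_identical(dim(d2$values), dim(d$values))
  expect_equal(d2$spacing_mm, d$spacing_mm)
  expect_equal(d2$origin_mm, d$origin_mm)
  expect_lt(max(abs(d2$values - d$values)), 0.001)
})

test_that("stored-value scaling semantics hold and zero grids survive", {
  g <- array(66, c(2, 2, 2))
  path <- withr::local_tempfile(fileext = ".dcm")
  # with scaling 0.01 a 66 Gy voxel must be stored as integer 6600
  write_rtdose(dose_grid(g, c(1, 1, 1)), path, scaling = 0.01)
  ds <- dosetex:::dcm_parse(path)
  pix <- dosetex:::dcm_get(ds, "7FE0,0010")
  stored <- readBin(pix, "integer", n = 8, size = 4, endian = "little")
  expect_identical(stored, rep(6600L, 8))
  expect_equal(read_rtdose(path)$values, g)
  # all-zero grid round trips
  write_rtdose(dose_grid(array(0, c(2, 2, 2)), c(1, 1, 1)), path)
  expect_true(all(read_rtdose(path)$values == 0))
})

test_that("invalid dose objects are rejected", {
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), "non-negative")
  d <- small_plan()
  path <- withr::local_tempfile(fileext = ".dcm")
  expect_error(write_rtdose(d, path, scaling = 1e-12), "representable")
  # a non-dose modality file is refused by read_rtdose
  ct <- c(dosetex:::el_str(0x0008, 0x0016, "UI", dosetex:::UID_CT),
          dosetex:::el_str(0x0008, 0x0018, "UI", "1.2.3.4"),
          dosetex:::el_str(0x0008, 0x0060, "CS", "CT"))
  dosetex:::dcm_file(dosetex:::UID_CT, "1.2.3.4", ct, path)
  expect_error(read_rtdose(path), "modality")
  expect_error(read_rtstruct(path), "modality")
  expect_error(read_rtdose(withr::local_tempfile(lines = "plain text")),
               "DICOM")
})

test_that("RT Structure Set round trip preserves ROI names and vertices", {
  ph <- small_phantom()
  one <- structure_set(list(PTV = ph$structs$rois$PTV))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(one, path)
  cs <- read_rtstruct(path)
  expect_named(cs$rois, "PTV")
  orig <- dosetex:::mask_to_contours(ph$structs$rois$PTV)
  expect_length(cs$rois$PTV$contours, length(orig))
  for (k in seq_along(orig))
    expect_identical(nrow(cs$rois$PTV$contours[[k]]), nrow(orig[[k]]))
})

test_that("mask -> contours -> mask recovers the mask within the boundary", {
  # irregular synthetic blob on a 20^3 grid
  g <- grid_geometry(c(20, 20, 20), c(1, 1, 1))
  m <- array(FALSE, g$dim)
  cx <- 10.3; cy <- 9.6
  for (z in 6:14) {
    r <- 5 - 0.3 * abs(z - 10)
    for (x in 1:20) for (y in 1:20)
      if ((x - cx)^2 + (y - cy)^2 / 1.4 <= r^2) m[x, y, z] <- TRUE
  }
  roi <- roi_mask(m, "blob", g$spacing_mm, g$origin_mm)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(roi, path)
  cs <- read_rtstruct(path)
  rec <- rasterize_contours(cs$rois$blob, g)
  mismatch <- which(rec$mask != m)
  # discrepancies confined to the boundary shell (<= 1 voxel)
  interior <- m & !o_dilate(!m, 1.01, c(1, 1, 1))
  shell <- o_dilate(m, 1.01, c(1, 1, 1)) & !interior
  expect_true(all(shell[mismatch]))
})

test_that("internal compressed-array format round trips exactly", {
  d <- small_plan(seed = 9)
  path <- withr::local_tempfile(fileext = ".bin.gz")
  write_dose_internal(d, path)
  d2 <- read_dose_internal(path)
  expect_identical(d2$values, d$values)
  expect_equal(d2$spacing_mm, d$spacing_mm)
  expect_equal(d2$origin_mm, d$origin_mm)
})
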