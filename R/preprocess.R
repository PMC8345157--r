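#' Resample a dose grid onto a target grid
#'
#' Trilinear interpolation at the target voxel centres. Target voxels whose
#' centres fall outside the source extent are set to 0 Gy and counted in a
#' coverage attribute.
#'
#' @param dose a [dose_grid()].
#' @param target_grid a [grid_geometry()] (or object carrying one).
#' @param method interpolation method; only `"trilinear"` is supported.
#' @return A [dose_grid()] on the target geometry, with attribute
#'   `coverage` = fraction of target voxels inside the source extent.
#' @export
resample_dose <- function(dose, target_grid, method = "trilinear") {
  if (!inherits(dose, "dose_grid")) stop("`dose` must be a dose_grid")
  method <- match.arg(method, "trilinear")
  tg <- grid_of(target_grid)
  if (same_grid(dose, tg)) {
    out <- dose
    attr(out, "coverage") <- 1
    return(out)
  }
  nd <- tg$dim
  # fractional voxel indices of target centres in the source grid
  coord <- function(ax) tg$origin_mm[ax] + (seq_len(nd[ax]) - 1) * tg$spacing_mm[ax]
  fx <- (coord(1) - dose$origin_mm[1]) / dose$spacing_mm[1] + 1
  fy <- (coord(2) - dose$origin_mm[2]) / dose$spacing_mm[2] + 1
  fz <- (coord(3) - dose$origin_mm[3]) / dose$spacing_mm[3] + 1
  FX <- rep(fx, times = nd[2] * nd[3])
  FY <- rep(rep(fy, each = nd[1]), times = nd[3])
  FZ <- rep(fz, each = nd[1] * nd[2])
  v <- trilinear(dose$values, FX, FY, FZ)
  n_in <- sum(!is.na(v))
  if (n_in == 0) stop("target grid does not overlap the dose grid")
  v[is.na(v)] <- 0
  out <- dose_grid(array(v, nd), tg$spacing_mm, tg$origin_mm)
  attr(out, "coverage") <- n_in / length(v)
  out
}

#' Discretise ROI dose into grey levels
#'
#' Maps absolute dose to `G` integer grey levels from zero to the maximum
#' dose: `level(d) = min(G, floor(d / d_max * G) + 1)`, so `d = 0` falls in
#' level 1 and `d = d_max` in level `G`. The reference maximum is the ROI
#' maximum (`range_mode = "roi_max"`, default) or the whole-grid maximum
#' (`"global_max"`).
#'
#' @param dose a [dose_grid()].
#' @param roi a [roi_mask()] on the same grid.
#' @param G number of grey levels (default 100).
#' @param range_mode `"roi_max"` or `"global_max"`.
#' @return An object of class `discretised_roi`: `levels` (integer array,
#'   0 outside the mask), `mask`, `G`, `level_width_Gy`, `reference_max_Gy`,
#'   `roi_name`.
#' @export
discretise <- function(dose, roi, G = 100L, range_mode = c("roi_max", "global_max")) {
  if (!inherits(dose, "dose_grid")) stop("`dose` must be a dose_grid")
  if (!inherits(roi, "roi_mask")) stop("`roi` must be a roi_mask")
  range_mode <- match.arg(range_mode)
  G <- as.integer(G)
  if (G < 2L) stop("`G` must be at least 2")
  if (!identical(dim(dose$values), dim(roi$mask)))
    stop("dose and ROI are on different grids; resample first")
  if (!any(roi$mask)) stop("ROI '", roi$roi_name, "' is empty")
  dmax <- if (range_mode == "roi_max") max(dose$values[roi$mask]) else max(dose$values)
  if (dmax <= 0)
    stop("all-zero dose in range for ROI '", roi$roi_name,
         "': discretisation range undefined")
  lev <- array(0L, dim(dose$values))
  dv <- dose$values[roi$mask]
  lev[roi$mask] <- as.integer(pmin(G, floor(dv / dmax * G) + 1))
  structure(list(levels = lev, mask = roi$mask, G = G,
                 level_width_Gy = dmax / G, reference_max_Gy = dmax,
                 range_mode = range_mode, roi_name = roi$roi_name),
            class = "discretised_roi")
}

# Even-odd point-in-polygon test, vectorised over points. Points exactly on
# an edge follow the half-open crossing rule (deterministic).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Rasterize planar contours to a voxel mask
#'
#' A voxel belongs to the mask iff its centre lies inside the ROI's polygon
#' set (even-odd rule, so holes and disjoint parts work and winding order is
#' irrelevant) on the slice nearest to the contour plane. Contour planes
#' must match a grid slice within half a slice spacing.
#'
#' @param contours one ROI entry of a [read_rtstruct()] contour set: a list
#'   with `name` and `contours` (each a matrix with columns x, y, z in mm).
#' @param grid a [grid_geometry()].
#' @return A [roi_mask()].
#' @export
rasterize_contours <- function(contours, grid) {
  grid <- grid_of(grid)
  nd <- grid$dim
  mask <- array(FALSE, nd)
  polys <- contours$contours
  if (length(polys) == 0) {
    warning("ROI '", contours$name %||% "?", "' has no contours; empty mask")
    return(roi_mask(mask, contours$name %||% "unknown", grid$spacing_mm, grid$origin_mm))
  }
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  PX <- rep(xs, times = nd[2])
  PY <- rep(ys, each = nd[1])
  for (poly in polys) {
    if (nrow(poly) < 3) stop("polygon with fewer than 3 vertices")
    z <- poly[1, 3]
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > grid$spacing_mm[3] / 2 + 1e-6)
      stop("contour plane z = ", z, " matches no grid slice")
    inside <- points_in_polygon(PX, PY, poly[, 1], poly[, 2])
    sl <- mask[, , k]
    sl <- xor(sl, matrix(inside, nd[1], nd[2]))  # even-odd across polygons
    mask[, , k] <- sl
  }
  roi_mask(mask, contours$name %||% "unknown", grid$spacing_mm, grid$origin_mm)
}
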