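#' Phantom specification
#'
#' Describes the synthetic cylindrical heterogeneous phantom: a PMMA-like
#' cylinder carrying four rectangular tissue-equivalent inserts (lung, bone,
#' muscle, adipose) on which a head-and-neck-like structure set is contoured.
#' `scale_factor` shrinks every geometric length (cylinder, ROI positions
#' and sizes, RING margin) so a full cohort runs quickly at test scale; the
#' 4 mm PRV margin around the spinal canal is a clinical margin and is kept
#' in absolute mm.
#'
#' @param cylinder_radius_mm cylinder radius at scale 1 (mm).
#' @param cylinder_length_mm cylinder length at scale 1 (mm).
#' @param voxel_spacing_mm grid spacing, scalar or `c(dx, dy, dz)` (mm).
#' @param insert_densities named relative electron densities for the four
#'   inserts `lung`, `bone`, `muscle`, `adipose`.
#' @param scale_factor geometric shrink factor in (0, 1].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(cylinder_radius_mm = 100,
                         cylinder_length_mm = 160,
                         voxel_spacing_mm = c(3, 3, 3),
                         insert_densities = c(lung = 0.30, bone = 1.50,
                                              muscle = 1.05, adipose = 0.95),
                         scale_factor = 0.5) {
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) == 1L) voxel_spacing_mm <- rep(voxel_spacing_mm, 3L)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("`voxel_spacing_mm` must be 3 positive lengths")
  if (!is.numeric(scale_factor) || scale_factor <= 0 || scale_factor > 1)
    stop("`scale_factor` must lie in (0, 1]")
  if (cylinder_radius_mm <= 0 || cylinder_length_mm <= 0)
    stop("cylinder dimensions must be positive")
  need <- c("lung", "bone", "muscle", "adipose")
  if (!all(need %in% names(insert_densities)))
    stop("`insert_densities` must name all of: ", paste(need, collapse = ", "))
  structure(list(cylinder_radius_mm = cylinder_radius_mm,
                 cylinder_length_mm = cylinder_length_mm,
                 voxel_spacing_mm = voxel_spacing_mm,
                 insert_densities = insert_densities[need],
                 scale_factor = scale_factor),
            class = "phantom_spec")
}

# Analytic ROI primitives at scale 1 (mm, phantom-centred coordinates;
# z along the cylinder axis). The PTV sits mono-laterally, abutting the
# right parotid so that one parotid and the RING live in the dose-gradient
# region while the left parotid, spinal canal and trachea see low dose.
phantom_geometry <- function(spec) {
  sf <- spec$scale_factor
  halfz <- 0.45 * spec$cylinder_length_mm * sf
  list(
    PTV = list(type = "ellipsoid", center = c(24, 0, 0) * sf,
               semi = c(26, 26, 36) * sf),
    parotid_R = list(type = "ellipsoid", center = c(68, -20, 0) * sf,
                     semi = c(14, 14, 22) * sf),
    parotid_L = list(type = "ellipsoid", center = c(-68, -20, 0) * sf,
                     semi = c(14, 14, 22) * sf),
    spinal_canal = list(type = "cylinder", center = c(0, -70, 0) * sf,
                        radius = 10 * sf, halfz = halfz),
    trachea = list(type = "cylinder", center = c(0, 30, 0) * sf,
                   radius = 12 * sf, halfz = halfz),
    ring_expansion_mm = 30 * sf,
    prv_margin_mm = 4
  )
}

# Normalised shape coordinate u: u <= 1 inside the primitive, growing
# roughly linearly with distance outside. Vectorised over voxel centres.
shape_u <- function(prim, X, Y, Z) {
  c0 <- prim$center
  if (prim$type == "ellipsoid") {
    sqrt(((X - c0[1]) / prim$semi[1])^2 +
         ((Y - c0[2]) / prim$semi[2])^2 +
         ((Z - c0[3]) / prim$semi[3])^2)
  } else {
    r <- sqrt(((X - c0[1]) / prim$radius)^2 + ((Y - c0[2]) / prim$radius)^2)
    pmax(r, abs(Z - c0[3]) / prim$halfz)
  }
}

# Smallest semi-axis, used to convert (u - 1) into an approximate mm
# distance outside the primitive surface.
shape_scale <- function(prim) {
  if (prim$type == "ellipsoid") min(prim$semi) else min(prim$radius, prim$halfz)
}

#' Build the synthetic phantom and its structure set
#'
#' Generates the density grid (PMMA cylinder with four rectangular
#' tissue-equivalent inserts) and the seven-ROI structure set: PTV, left and
#' right parotid, spinal canal, PRV_SC (isotropic 4 mm expansion of the
#' spinal canal), trachea and RING (expansion of the PTV cropped at its
#' surface; see [make_ring()]).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `density` (a [dose_grid()]-shaped array container for
#'   relative electron density), `structs` (a [structure_set()] whose
#'   `geometry` field carries the analytic ROI primitives used by
#'   [simulate_plan()]).
#' @export
build_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  geo <- phantom_geometry(spec)
  sf <- spec$scale_factor
  R <- spec$cylinder_radius_mm * sf
  halfL <- spec$cylinder_length_mm * sf / 2
  margin <- 6
  ext <- c(R + margin, R + margin, halfL + margin)
  sp <- spec$voxel_spacing_mm
  nd <- pmax(as.integer(ceiling(2 * ext / sp)), 2L)
  origin <- -ext + sp / 2
  grid <- grid_geometry(nd, sp, origin)

  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  X <- array(rep(xs, times = nd[2] * nd[3]), nd)
  Y <- array(rep(rep(ys, each = nd[1]), times = nd[3]), nd)
  Z <- array(rep(zs, each = nd[1] * nd[2]), nd)

  in_cyl <- (X^2 + Y^2 <= R^2) & (abs(Z) <= halfL)
  density <- array(0.001, nd)          # air background
  density[in_cyl] <- 1.15              # PMMA-like
  ins_pos <- list(lung = c(-0.5, 0.5), bone = c(0.5, 0.5),
                  muscle = c(-0.5, -0.5), adipose = c(0.5, -0.5))
  for (nm in names(ins_pos)) {
    cx <- ins_pos[[nm]][1] * R; cy <- ins_pos[[nm]][2] * R
    box <- abs(X - cx) <= 0.16 * R & abs(Y - cy) <= 0.16 * R &
      abs(Z) <= 0.7 * halfL & in_cyl
    density[box] <- spec$insert_densities[[nm]]
  }

  mk <- function(prim, name) {
    m <- array(shape_u(prim, X, Y, Z) <= 1, nd)
    roi_mask(m, name, sp, origin)
  }
  rois <- list(
    PTV = mk(geo$PTV, "PTV"),
    parotid_L = mk(geo$parotid_L, "parotid_L"),
    parotid_R = mk(geo$parotid_R, "parotid_R"),
    spinal_canal = mk(geo$spinal_canal, "spinal_canal"),
    trachea = mk(geo$trachea, "trachea")
  )
  for (nm in names(rois)) {
    if (sum(rois[[nm]]$mask) < 2L)
      stop("voxel spacing too coarse: ROI '", nm,
           "' would have fewer than 2 voxels")
  }
  rois$PRV_SC <- roi_mask(
    dilate3(rois$spinal_canal$mask, geo$prv_margin_mm, sp),
    "PRV_SC", sp, origin)
  rois$RING <- make_ring(rois$PTV, expansion_mm = geo$ring_expansion_mm,
                         crop_mm = 0)
  if (sum(rois$RING$mask) < 2L || sum(rois$PRV_SC$mask) < 2L)
    stop("voxel spacing too coarse: derived ROI would have fewer than 2 voxels")
  structs <- structure_set(rois, grid,
                           geometry = c(geo, list(prescription_ref = NULL)))
  list(density = density, structs = structs, grid = grid, spec = spec)
}

# Rebuild the analytic structure set on another grid (used by DVH QA so
# that metrics are evaluated on the dose calculation grid instead of
# blurring the dose onto the reference grid). Derived ROIs (PRV, RING) are
# re-derived on the target grid.
structs_on_grid <- function(structs, grid) {
  if (same_grid(structs, grid)) return(structs)
  geo <- structs$geometry
  if (is.null(geo) || is.null(geo$PTV))
    stop("cannot rebuild structures without analytic geometry")
  grid <- grid_of(grid)
  nd <- grid$dim; sp <- grid$spacing_mm
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  X <- array(rep(xs, times = nd[2] * nd[3]), nd)
  Y <- array(rep(rep(ys, each = nd[1]), times = nd[3]), nd)
  Z <- array(rep(zs, each = nd[1] * nd[2]), nd)
  mk <- function(prim, name)
    roi_mask(array(shape_u(prim, X, Y, Z) <= 1, nd), name, sp, grid$origin_mm)
  rois <- list(
    PTV = mk(geo$PTV, "PTV"),
    parotid_L = mk(geo$parotid_L, "parotid_L"),
    parotid_R = mk(geo$parotid_R, "parotid_R"),
    spinal_canal = mk(geo$spinal_canal, "spinal_canal"),
    trachea = mk(geo$trachea, "trachea"))
  rois$PRV_SC <- roi_mask(
    dilate3(rois$spinal_canal$mask, geo$prv_margin_mm, sp),
    "PRV_SC", sp, grid$origin_mm)
  rois$RING <- make_ring(rois$PTV, expansion_mm = geo$ring_expansion_mm, crop_mm = 0)
  structure_set(rois, grid, geometry = geo)
}

#' Ring (shell) structure around a target volume
#'
#' Builds the shell `dilate(ptv, expansion_mm) \ dilate(ptv, crop_mm)`.
#' With `crop_mm = 0` the ring abuts the target surface and excludes all
#' target voxels, capturing the dose-gradient region outside the PTV.
#' Dilation uses a Euclidean ball in mm (anisotropic spacing honoured).
#'
#' @param ptv a [roi_mask()]; must be non-empty.
#' @param expansion_mm outer expansion in mm; must exceed `crop_mm` and be at
#'   least one voxel.
#' @param crop_mm inner crop in mm, `>= 0`.
#' @return A [roi_mask()] named `RING`.
#' @export
make_ring <- function(ptv, expansion_mm, crop_mm = 0) {
  if (!inherits(ptv, "roi_mask")) stop("`ptv` must be a roi_mask")
  if (!any(ptv$mask)) stop("PTV mask is empty")
  if (crop_mm < 0 || expansion_mm <= crop_mm)
    stop("need expansion_mm > crop_mm >= 0")
  if (expansion_mm < min(ptv$spacing_mm))
    stop("expansion smaller than one voxel")
  outer_m <- dilate3(ptv$mask, expansion_mm, ptv$spacing_mm)
  inner_m <- if (crop_mm > 0) dilate3(ptv$mask, crop_mm, ptv$spacing_mm) else ptv$mask
  roi_mask(outer_m & !inner_m, "RING", ptv$spacing_mm, ptv$origin_mm)
}
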