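#' Dose grid container
#'
#' A `dose_grid` holds a 3D array of absolute dose in Gy together with its
#' geometry. Values are stored as `values[x, y, z]` (column-major, 1-based,
#' the natural R layout); `spacing_mm` and `origin_mm` are `c(x, y, z)`
#' vectors, with the origin at the centre of the first voxel in patient
#' coordinates (mm).
#'
#' @param values 3D numeric array of dose in Gy; all finite and >= 0.
#' @param spacing_mm positive voxel spacing, `c(dx, dy, dz)` in mm.
#' @param origin_mm position of the first voxel centre, `c(x, y, z)` in mm.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 2L))
    stop("dose grid must have at least 2 voxels along every axis")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must all be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing %s mm\n  dose range [%.3f, %.3f] Gy\n",
    d[1], d[2], d[3], paste(format(x$spacing_mm, digits = 4), collapse = " x "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Grid geometry descriptor
#'
#' Lightweight geometry (no voxel data): dimensions, spacing and origin.
#' Used as the resampling target and as the reference grid of a
#' [structure_set()].
#'
#' @param dim integer dimensions `c(nx, ny, nz)`.
#' @param spacing_mm voxel spacing `c(dx, dy, dz)` in mm.
#' @param origin_mm first voxel centre `c(x, y, z)` in mm.
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(dim, spacing_mm, origin_mm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 2L)) stop("`dim` must be 3 integers >= 2")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  structure(list(dim = dim, spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
            class = "grid_geometry")
}

grid_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (inherits(x, "dose_grid"))
    return(grid_geometry(dim(x$values), x$spacing_mm, x$origin_mm))
  if (inherits(x, "roi_mask"))
    return(grid_geometry(dim(x$mask), x$spacing_mm, x$origin_mm))
  if (inherits(x, "structure_set")) return(x$grid)
  stop("cannot extract a grid from object of class ", paste(class(x), collapse = "/"))
}

#' Voxel-centre coordinates along one axis
#' @noRd
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing_mm[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  a <- grid_of(a); b <- grid_of(b)
  identical(a$dim, b$dim) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' ROI voxel mask
#'
#' Boolean mask of one named structure on a reference grid.
#'
#' @param mask 3D logical array (`[x, y, z]`).
#' @param roi_name structure name.
#' @param spacing_mm,origin_mm grid geometry, as in [dose_grid()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, roi_name, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3D logical array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(
    list(mask = mask, roi_name = as.character(roi_name),
         spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (%.1f cm^3)\n", x$roi_name,
              sum(x$mask), sum(x$mask) * prod(x$spacing_mm) / 1000))
  invisible(x)
}

#' Structure set
#'
#' Named collection of [roi_mask()]s sharing one reference grid. The
#' canonical synthetic phantom carries exactly the seven structures
#' PTV, parotid_L, parotid_R, spinal_canal, PRV_SC, trachea and RING.
#'
#' @param rois named list of `roi_mask` objects on a common grid.
#' @param grid a [grid_geometry()] (defaults to the grid of the first ROI).
#' @param geometry optional analytic ROI geometry (used by the plan
#'   simulator); see [build_phantom()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(rois, grid = NULL, geometry = NULL) {
  if (length(rois) == 0) stop("`rois` must be a non-empty named list")
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("every ROI must be named")
  if (is.null(grid)) grid <- grid_of(rois[[1]])
  for (nm in names(rois)) {
    if (!inherits(rois[[nm]], "roi_mask")) stop("ROI '", nm, "' is not a roi_mask")
    if (!identical(dim(rois[[nm]]$mask), grid$dim))
      stop("ROI '", nm, "' does not match the reference grid shape")
  }
  structure(list(grid = grid, rois = rois, geometry = geometry),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROIs on a %s grid (%s mm spacing)\n",
              length(x$rois), paste(x$grid$dim, collapse = "x"),
              paste(format(x$grid$spacing_mm, digits = 3), collapse = "x")))
  for (nm in names(x$rois))
    cat(sprintf("  %-12s %6d voxels\n", nm, sum(x$rois[[nm]]$mask)))
  invisible(x)
}

# The six ROIs features are extracted from (PRV_SC is QA-only, as in the
# source study design).
FEATURE_ROIS <- c("PTV", "parotid_L", "parotid_R", "spinal_canal", "trachea", "RING")

PHANTOM_ROIS <- c(FEATURE_ROIS, "PRV_SC")
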