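#' Write a dose grid as a DICOM RT-Dose object
#'
#' Explicit-VR little-endian RT-Dose with 32-bit unsigned pixel data.
#' The dose-grid scaling is chosen so quantisation error stays below
#' 0.001 Gy (default: `max dose / (2^31 - 1)`).
#'
#' @param dose a [dose_grid()].
#' @param path output file path.
#' @param scaling optional dose-grid scaling (Gy per stored unit); values
#'   that would not be representable raise an error.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, scaling = NULL) {
  if (!inherits(dose, "dose_grid")) stop("`dose` must be a dose_grid")
  dmax <- max(dose$values)
  if (is.null(scaling))
    scaling <- if (dmax > 0) dmax / (2^31 - 1) else 1e-6
  if (scaling <= 0) stop("`scaling` must be positive")
  ints <- round(dose$values / scaling)
  if (any(ints > 2^31 - 1))
    stop("dose exceeds the representable range at this scaling")
  nd <- dim(dose$values)
  sp <- dose$spacing_mm
  uid <- content_uid("1.2.826.0.1.3680043.10.1432.2",
                     c(nd, sp, dose$origin_mm, sum(dose$values)))
  offsets <- (seq_len(nd[3]) - 1) * sp[3]
  # pixel data: frames = z, rows = y, columns = x; x fastest == R layout
  pix <- writeBin(as.integer(ints), raw(), size = 4, endian = "little")
  ds <- c(
    el_str(0x0008, 0x0016, "UI", UID_RTDOSE),
    el_str(0x0008, 0x0018, "UI", uid),
    el_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x0032, "DS", dcm_ds(dose$origin_mm)),
    dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    el_us(0x0028, 0x0002, 1),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", dcm_is(nd[3])),
    el_us(0x0028, 0x0010, nd[2]),            # Rows = y
    el_us(0x0028, 0x0011, nd[1]),            # Columns = x
    dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(sp[2], sp[1]))),  # row\col
    el_us(0x0028, 0x0100, 32),
    el_us(0x0028, 0x0101, 32),
    el_us(0x0028, 0x0102, 31),
    el_us(0x0028, 0x0103, 0),
    el_str(0x3004, 0x0002, "CS", "GY"),
    el_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    el_str(0x3004, 0x000A, "CS", "PLAN"),
    dcm_element(0x3004, 0x000C, "DS", dcm_ds(offsets)),
    dcm_element(0x3004, 0x000E, "DS", dcm_str_payload(sprintf("%.10e", scaling), "DS")),
    dcm_element(0x7FE0, 0x0010, "OW", pix))
  dcm_file(UID_RTDOSE, uid, ds, path)
}

#' Read a DICOM RT-Dose object
#'
#' Returns dose in Gy (stored integers times the dose-grid scaling) with
#' geometry taken from the image position/orientation, pixel spacing and
#' grid frame offset vector. Non-dose modalities, dose units other than Gy,
#' missing scaling, tilted orientations and non-uniform frame offsets are
#' rejected.
#'
#' @param path file path.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path) {
  ds <- dcm_parse(path)
  modality <- dcm_get(ds, "0008,0060", required = TRUE, "Modality")
  if (!identical(modality, "RTDOSE"))
    stop("not an RT-Dose object (modality '", modality, "')")
  units <- dcm_get(ds, "3004,0002", required = TRUE, "DoseUnits")
  if (!identical(units, "GY"))
    stop("unsupported dose units '", units, "' (only GY)")
  scaling <- dcm_get(ds, "3004,000E", required = TRUE, "DoseGridScaling")
  orient <- dcm_get(ds, "0020,0037", required = TRUE, "ImageOrientationPatient")
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("unsupported image orientation (only axis-aligned axial grids)")
  rows <- dcm_get(ds, "0028,0010", required = TRUE, "Rows")
  cols <- dcm_get(ds, "0028,0011", required = TRUE, "Columns")
  nfrm <- dcm_get(ds, "0028,0008", required = TRUE, "NumberOfFrames")
  ps <- dcm_get(ds, "0028,0030", required = TRUE, "PixelSpacing")
  off <- dcm_get(ds, "3004,000C", required = TRUE, "GridFrameOffsetVector")
  if (length(off) != nfrm) stop("GridFrameOffsetVector length mismatch")
  dz <- diff(off)
  if (length(dz) && (any(abs(dz - dz[1]) > 1e-4) || dz[1] <= 0))
    stop("non-uniform frame offsets are not supported")
  origin <- dcm_get(ds, "0020,0032", required = TRUE, "ImagePositionPatient")
  pix <- dcm_get(ds, "7FE0,0010", required = TRUE, "PixelData")
  ba <- dcm_get(ds, "0028,0100", required = TRUE, "BitsAllocated")
  if (ba != 32) stop("only 32-bit dose pixel data supported")
  n <- rows * cols * nfrm
  v <- readBin(pix, "integer", n = n, size = 4, endian = "little")
  v <- ifelse(v < 0, as.numeric(v) + 4294967296, as.numeric(v))
  vals <- array(v * scaling, dim = c(cols, rows, nfrm))
  dose_grid(vals, spacing_mm = c(ps[2], ps[1], if (length(dz)) dz[1] else 1),
            origin_mm = origin + c(0, 0, off[1]))
}

# Closed planar polygons tracing the 0.5-level boundary of a mask, slice by
# slice (marching squares via grDevices::contourLines on a zero-padded
# slice). Returns list of n x 3 matrices (x, y, z in mm).
mask_to_contours <- function(roi) {
  nd <- dim(roi$mask)
  g <- grid_of(roi)
  xs <- c(g$origin_mm[1] - g$spacing_mm[1], axis_coords(g, 1),
          g$origin_mm[1] + nd[1] * g$spacing_mm[1])
  ys <- c(g$origin_mm[2] - g$spacing_mm[2], axis_coords(g, 2),
          g$origin_mm[2] + nd[2] * g$spacing_mm[2])
  zs <- axis_coords(g, 3)
  polys <- list()
  for (k in seq_len(nd[3])) {
    if (!any(roi$mask[, , k])) next
    sl <- matrix(0, nd[1] + 2, nd[2] + 2)
    sl[2:(nd[1] + 1), 2:(nd[2] + 1)] <- roi$mask[, , k]
    cl <- grDevices::contourLines(xs, ys, sl, levels = 0.5)
    for (cc in cl) {
      m <- cbind(cc$x, cc$y, zs[k])
      # drop duplicated closing vertex if present
      if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-9))
        m <- m[-nrow(m), , drop = FALSE]
      if (nrow(m) >= 3) polys[[length(polys) + 1L]] <- m
    }
  }
  polys
}

#' Write a DICOM RT Structure Set
#'
#' Emits closed planar contours (traced from the voxel masks, marching
#' squares per slice) for every ROI of a structure set, or passes through
#' contour sets read with [read_rtstruct()].
#'
#' @param structs a [structure_set()], a single [roi_mask()], or a contour
#'   set as returned by [read_rtstruct()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(structs, path) {
  if (inherits(structs, "roi_mask"))
    structs <- structure_set(stats::setNames(list(structs), structs$roi_name))
  if (inherits(structs, "structure_set")) {
    rois <- lapply(names(structs$rois), function(nm)
      list(name = nm, contours = mask_to_contours(structs$rois[[nm]])))
    names(rois) <- names(structs$rois)
  } else if (is.list(structs) && !is.null(structs$rois)) {
    rois <- structs$rois
  } else stop("`structs` must be a structure_set, roi_mask or contour set")

  ssroi_items <- list(); cont_items <- list()
  for (k in seq_along(rois)) {
    nm <- rois[[k]]$name %||% names(rois)[k]
    if (!length(rois[[k]]$contours))
      warning("ROI '", nm, "' has no contours")
    ssroi_items[[k]] <- c(
      dcm_element(0x3006, 0x0022, "IS", dcm_is(k)),
      el_str(0x3006, 0x0026, "LO", nm))
    poly_items <- lapply(rois[[k]]$contours, function(m) {
      c(el_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", dcm_is(nrow(m))),
        dcm_element(0x3006, 0x0050, "DS", dcm_ds(as.vector(t(m)))))
    })
    cont_items[[k]] <- c(
      if (length(poly_items)) dcm_sequence(0x3006, 0x0040, poly_items) else raw(0),
      dcm_element(0x3006, 0x0084, "IS", dcm_is(k)))
  }
  uid <- content_uid("1.2.826.0.1.3680043.10.1432.3",
                     c(length(rois), vapply(rois, function(r) length(r$contours), 0)))
  dset <- c(
    el_str(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    el_str(0x0008, 0x0018, "UI", uid),
    el_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el_str(0x3006, 0x0002, "SH", "dosetex"),
    dcm_sequence(0x3006, 0x0020, ssroi_items),
    dcm_sequence(0x3006, 0x0039, cont_items))
  dcm_file(UID_RTSTRUCT, uid, dset, path)
}

#' Read a DICOM RT Structure Set
#'
#' @param path file path.
#' @return A contour set: list with `rois`, a named list of
#'   `list(name, number, contours)` where each contour is an n x 3 matrix
#'   of x, y, z vertex coordinates in mm. ROIs without contours yield a
#'   warning and an empty entry.
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_parse(path)
  modality <- dcm_get(ds, "0008,0060", required = TRUE, "Modality")
  if (!identical(modality, "RTSTRUCT"))
    stop("not an RT Structure Set (modality '", modality, "')")
  ssroi <- dcm_get(ds, "3006,0020", required = TRUE, "StructureSetROISequence")
  names_by_number <- list()
  for (it in ssroi) {
    num <- dcm_get(it, "3006,0022", required = TRUE, "ROINumber")
    names_by_number[[as.character(num)]] <-
      dcm_get(it, "3006,0026", required = TRUE, "ROIName")
  }
  rc <- dcm_get(ds, "3006,0039") %||% list()
  rois <- list()
  for (it in rc) {
    num <- dcm_get(it, "3006,0084", required = TRUE, "ReferencedROINumber")
    nm <- names_by_number[[as.character(num)]] %||% paste0("ROI_", num)
    polys <- lapply(dcm_get(it, "3006,0040") %||% list(), function(ci) {
      cd <- dcm_get(ci, "3006,0050", required = TRUE, "ContourData")
      matrix(cd, ncol = 3, byrow = TRUE)
    })
    if (!length(polys)) warning("ROI '", nm, "' has no contours")
    rois[[nm]] <- list(name = nm, number = num, contours = polys)
  }
  # named ROIs with no contour entry at all
  for (num in names(names_by_number)) {
    nm <- names_by_number[[num]]
    if (is.null(rois[[nm]])) {
      warning("ROI '", nm, "' has no contours")
      rois[[nm]] <- list(name = nm, number = as.integer(num), contours = list())
    }
  }
  list(rois = rois)
}

#' Internal compressed-array dose format
#'
#' Lossless container: gzip-compressed IEEE doubles plus a JSON geometry
#' sidecar (`<path>.json`). Round trips are exact.
#'
#' @param dose a [dose_grid()].
#' @param path output path (conventionally `*.bin.gz`).
#' @return `path`, invisibly.
#' @export
write_dose_internal <- function(dose, path) {
  if (!inherits(dose, "dose_grid")) stop("`dose` must be a dose_grid")
  con <- gzfile(path, "wb")
  writeBin(as.vector(dose$values), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dim = dim(dose$values), spacing_mm = dose$spacing_mm,
         origin_mm = dose$origin_mm, dtype = "float64le"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_internal
#' @export
read_dose_internal <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "rb")
  v <- readBin(con, "double", n = prod(meta$dim), size = 8, endian = "little")
  close(con)
  dose_grid(array(v, meta$dim), meta$spacing_mm, meta$origin_mm)
}
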