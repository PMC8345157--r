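#' Extract the full dosiomics panel from one dose distribution
#'
#' Per ROI: align the dose to the structure grid (trilinear resampling when
#' the grids differ; masks are never interpolated), compute the 17 STAT
#' features on raw dose in Gy, discretise into `G` grey levels and compute
#' the GLCM / GLRLM / GLSZM families, then subset and order by the registry.
#' Deterministic: repeated runs are bit-identical.
#'
#' @param dose a [dose_grid()].
#' @param structs a [structure_set()].
#' @param registry a [default_registry()]-style feature registry.
#' @param G number of grey levels (default 100).
#' @param range_mode discretisation range, see [discretise()].
#' @param rois ROI names to extract from (default: the six feature ROIs).
#' @param min_voxels ROIs below this voxel count are skipped with an error
#'   record (never silently).
#' @return An object of class `feature_map`: list with `features` (named
#'   list ROI -> named numeric vector of `nrow(registry)` values, `NA` for
#'   undefined entries) and `errors` (data frame of skipped ROIs).
#' @export
extract_all <- function(dose, structs, registry = default_registry(),
                        G = 100L, range_mode = "roi_max",
                        rois = intersect(FEATURE_ROIS, names(structs$rois)),
                        min_voxels = 2L) {
  if (!inherits(dose, "dose_grid")) stop("`dose` must be a dose_grid")
  if (!inherits(structs, "structure_set")) stop("`structs` must be a structure_set")
  miss <- setdiff(rois, names(structs$rois))
  if (length(miss)) stop("unknown ROI(s): ", paste(miss, collapse = ", "))
  if (!same_grid(dose, structs)) dose <- resample_dose(dose, structs$grid)
  feats <- list()
  errors <- data.frame(roi = character(), reason = character())
  for (nm in rois) {
    roi <- structs$rois[[nm]]
    nv <- sum(roi$mask)
    if (nv < min_voxels) {
      errors <- rbind(errors, data.frame(
        roi = nm, reason = sprintf("only %d voxels (minimum %d)", nv, min_voxels)))
      next
    }
    dv <- dose$values[roi$mask]
    if (max(dv) <= 0) {
      errors <- rbind(errors, data.frame(roi = nm, reason = "all-zero dose"))
      next
    }
    disc <- discretise(dose, roi, G = G, range_mode = range_mode)
    all_vals <- c(stat_features(dv),
                  glcm_features(disc),
                  runlength_features(disc),
                  sizezone_features(disc))
    v <- all_vals[registry$feature_id]
    names(v) <- registry$feature_id
    feats[[nm]] <- v
  }
  structure(list(features = feats, errors = errors),
            class = "feature_map",
            registry = registry, G = G, range_mode = range_mode)
}

#' Per-ROI feature tables for a plan cohort
#'
#' Runs [extract_all()] on every plan of a [generate_cohort()] cohort and
#' assembles, for each ROI, a features-by-plans matrix.
#'
#' @param cohort list of plan records from [generate_cohort()] (optionally
#'   filtered to one resolution).
#' @param structs the [structure_set()] the cohort was generated on.
#' @param study study tag stored on each table (e.g. `"reproducibility"`).
#' @param ... passed to [extract_all()].
#' @return Named list (by ROI) of `feature_table` objects: numeric matrices
#'   `registry x plans` with attributes `roi`, `study`, `registry`.
#' @export
extract_cohort <- function(cohort, structs, study = "study", ...) {
  if (!length(cohort)) stop("empty cohort")
  maps <- lapply(cohort, function(pl) extract_all(pl$dose, structs, ...))
  labels <- vapply(cohort, function(pl) {
    if (!is.null(pl$resolution) && pl$resolution != "reference")
      paste(pl$label, pl$resolution, sep = "_") else pl$label
  }, character(1))
  rois <- names(maps[[1]]$features)
  out <- lapply(rois, function(nm) {
    m <- vapply(maps, function(mp) mp$features[[nm]], numeric(length(maps[[1]]$features[[nm]])))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    colnames(m) <- labels
    structure(m, class = c("feature_table", class(m)),
              roi = nm, study = study,
              registry = attr(maps[[1]], "registry"))
  })
  names(out) <- rois
  out
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %d ROIs x %d features\n",
              length(x$features), nrow(attr(x, "registry"))))
  if (nrow(x$errors)) {
    cat("skipped ROIs:\n"); print.data.frame(x$errors, row.names = FALSE)
  }
  invisible(x)
}
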