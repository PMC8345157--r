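#' Run configuration
#'
#' Collects every knob of an end-to-end study run. Defaults reproduce the
#' canonical study conditions: 66 Gy prescription, 100 grey levels, ROI-max
#' discretisation, stability threshold CV < 0.3, sensitivity thresholds
#' CV > 1.0 and CV > 0.8.
#'
#' @param phantom a [phantom_spec()].
#' @param designs subset of `c("reproducibility", "stability", "sensitivity")`.
#' @param G number of grey levels.
#' @param range_mode discretisation range mode.
#' @param stable_th,sensitive_th CV thresholds (positive).
#' @param prescription_Gy prescribed PTV dose.
#' @param seed base seed; all per-plan seeds derive from it.
#' @param rois ROI names to extract features from.
#' @param glrlm_drop registry configuration, see [default_registry()].
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = phantom_spec(),
                       designs = c("reproducibility", "stability", "sensitivity"),
                       G = 100L, range_mode = "roi_max",
                       stable_th = 0.3, sensitive_th = c(1.0, 0.8),
                       prescription_Gy = 66, seed = 1L,
                       rois = FEATURE_ROIS,
                       glrlm_drop = c("run_entropy", "2D_avg")) {
  cfg <- list(phantom = phantom, designs = designs, G = as.integer(G),
              range_mode = range_mode, stable_th = stable_th,
              sensitive_th = sensitive_th, prescription_Gy = prescription_Gy,
              seed = as.integer(seed), rois = rois, glrlm_drop = glrlm_drop)
  class(cfg) <- "run_config"
  diag <- validate_inputs(cfg)
  if (nrow(diag)) stop("invalid run configuration:\n",
                       paste(" -", diag$message, collapse = "\n"))
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()]
#' arguments (`phantom:` holds [phantom_spec()] fields).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_spec, c(y$phantom %||% list(),
                                if (!is.null(y$phantom$insert_densities))
                                  list(insert_densities = unlist(y$phantom$insert_densities))))
  args <- y[setdiff(names(y), "phantom")]
  do.call(run_config, c(list(phantom = ph), args))
}

#' Validate a run configuration or run directory
#'
#' Fail-fast checks before any computation: known designs and ROI names,
#' positive thresholds, registry integrity (family counts 17/100/63/32),
#' grid sanity. Each failed check yields one coded diagnostic row; a fully
#' valid input yields an empty data frame.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return Data frame with columns `code` and `message` (0 rows when valid).
#' @export
validate_inputs <- function(config) {
  d <- data.frame(code = character(), message = character())
  add <- function(code, msg) rbind(d, data.frame(code = code, message = msg))
  known <- c("reproducibility", "stability", "sensitivity")
  bad <- setdiff(config$designs %||% character(), known)
  if (length(bad))
    d <- add("unknown_design", paste("unknown design(s):", paste(bad, collapse = ", ")))
  if (any(c(config$stable_th, config$sensitive_th) <= 0))
    d <- add("bad_threshold", "CV thresholds must be positive")
  bad_roi <- setdiff(config$rois %||% character(), PHANTOM_ROIS)
  if (length(bad_roi))
    d <- add("unknown_roi", paste("unknown ROI(s):", paste(bad_roi, collapse = ", ")))
  reg <- tryCatch(default_registry(config$glrlm_drop %||% c("run_entropy", "2D_avg")),
                  error = function(e) NULL)
  if (is.null(reg)) {
    d <- add("bad_registry", "registry configuration is invalid")
  } else {
    cnt <- registry_counts(reg)
    if (!identical(cnt, EXPECTED_COUNTS))
      d <- add("registry_count_mismatch",
               paste0("registry counts ", paste(cnt, collapse = "/"),
                      " differ from 17/100/63/32/212"))
  }
  if ((config$G %||% 100L) < 2L)
    d <- add("bad_levels", "G must be at least 2")
  d
}

#' Validate a registry object directly
#' @noRd
check_registry <- function(registry) {
  cnt <- registry_counts(registry)
  if (!identical(cnt, EXPECTED_COUNTS))
    data.frame(code = "registry_count_mismatch",
               message = paste0("registry counts ",
                                paste(cnt, collapse = "/"),
                                " differ from 17/100/63/32/212"))
  else data.frame(code = character(), message = character())
}

#' Run the full study end to end
#'
#' Generate the configured cohorts, extract the full feature panel per ROI
#' and study, run the CV analysis, threshold selection, intersection and
#' family summaries, the plan QA and the software-reproducibility check,
#' and write every table plus a run manifest to `out_dir`. Re-running with
#' the same configuration reproduces all outputs exactly.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with cohorts' QA, feature tables, CV records,
#'   selections, summaries, the software check and the manifest.
#' @export
run_study <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  diag <- validate_inputs(config)
  if (nrow(diag)) stop("invalid run configuration:\n",
                       paste(" -", diag$message, collapse = "\n"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  registry <- default_registry(config$glrlm_drop)
  say("building phantom (scale %.2f, %s mm grid)", config$phantom$scale_factor,
      paste(config$phantom$voxel_spacing_mm, collapse = "x"))
  ph <- build_phantom(config$phantom)
  structs <- ph$structs

  cohorts <- list(); tables <- list(); qa <- list()
  for (design in config$designs) {
    say("generating %s cohort", design)
    coh <- generate_cohort(structs, design, base_seed = config$seed,
                           prescription_Gy = config$prescription_Gy)
    qa_rows <- lapply(coh, function(pl) {
      r <- check_constraints(pl$dose, structs, config$prescription_Gy)
      r$plan <- pl$label; r$resolution <- pl$resolution; r$design <- design
      r
    })
    qa[[design]] <- do.call(rbind, qa_rows)
    if (design == "sensitivity") {
      for (rn in c("fine", "coarse")) {
        sub <- Filter(function(pl) pl$resolution == rn, coh)
        st <- paste0("sensitivity_", rn)
        say("extracting features: %s (%d plans)", st, length(sub))
        tables[[st]] <- extract_cohort(sub, structs, study = st,
                                       registry = registry, G = config$G,
                                       range_mode = config$range_mode,
                                       rois = config$rois)
      }
    } else {
      say("extracting features: %s (%d plans)", design, length(coh))
      tables[[design]] <- extract_cohort(coh, structs, study = design,
                                         registry = registry, G = config$G,
                                         range_mode = config$range_mode,
                                         rois = config$rois)
    }
    cohorts[[design]] <- coh
  }

  say("CV analysis")
  cv_records <- do.call(rbind, unlist(lapply(tables, function(tt)
    lapply(tt, feature_cv_table)), recursive = FALSE))
  rownames(cv_records) <- NULL
  fam <- family_summary(cv_records)
  selections <- list()
  for (r in unique(cv_records$roi)) {
    recs <- lapply(names(tables), function(st)
      cv_records[cv_records$roi == r & cv_records$study == st, ])
    names(recs) <- names(tables)
    selections[[r]] <- select_features(recs, config$stable_th, config$sensitive_th)
  }
  common <- if (all(c("reproducibility", "stability", "sensitivity_fine",
                      "sensitivity_coarse") %in% names(tables)))
    common_feature_summary(cv_records, config$stable_th, max(config$sensitive_th))
  else NULL

  say("software reproducibility check")
  sw <- software_reproducibility_check(structs, seed = config$seed,
                                       registry = registry, G = config$G,
                                       range_mode = config$range_mode,
                                       rois = config$rois)

  manifest <- list(
    package = "dosetex",
    version = as.character(utils::packageVersion("dosetex")),
    seed = config$seed,
    designs = config$designs,
    registry_counts = as.list(registry_counts(registry)),
    glrlm_drop = config$glrlm_drop,
    G = config$G, range_mode = config$range_mode,
    thresholds = list(stable = config$stable_th, sensitive = config$sensitive_th),
    prescription_Gy = config$prescription_Gy,
    phantom = config$phantom[c("cylinder_radius_mm", "cylinder_length_mm",
                               "voxel_spacing_mm", "scale_factor")],
    n_plans = lapply(cohorts, length),
    cv_sd_convention = "sample (n-1) standard deviation",
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  res <- list(structs = structs, cohorts = cohorts, qa = qa, tables = tables,
              cv_records = cv_records, family_summary = fam,
              selections = selections, common_features = common,
              software_check = sw, manifest = manifest, registry = registry)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    feats_long <- do.call(rbind, unlist(lapply(names(tables), function(st)
      lapply(tables[[st]], function(tb) {
        data.frame(study = st, roi = attr(tb, "roi"),
                   registry[c("family", "name", "aggregation", "feature_id")],
                   plan = rep(colnames(tb), each = nrow(tb)),
                   value = as.vector(tb))
      })), recursive = FALSE))
    wr(feats_long, "feature_values.csv")
    wr(cv_records, "cv_records.csv")
    wr(fam, "family_summary.csv")
    wr(do.call(rbind, unname(qa)), "plan_qa.csv")
    if (!is.null(common)) wr(common, "common_features.csv")
    sel_pct <- do.call(rbind, lapply(names(selections), function(r)
      cbind(roi = r, selections[[r]]$percentages)))
    wr(sel_pct, "selection_percentages.csv")
    jsonlite::write_json(
      lapply(selections, function(s) c(s$sets, s$intersections)),
      file.path(out_dir, "selection_sets.json"), auto_unbox = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote outputs to %s", out_dir)
  }
  invisible(res)
}
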