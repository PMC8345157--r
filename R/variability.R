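#' Coefficient of variation of a feature across plans
#'
#' `cv = sd / |mean|` with the sample (n-1) standard deviation. Missing
#' values are dropped; fewer than 2 remaining values flags
#' `insufficient_n`, a zero mean flags `undefined_mean_zero`; in both cases
#' `cv` is `NA`.
#'
#' @param values numeric vector of one feature's values across plans.
#' @return List with `mean`, `sd`, `cv`, `n_used`, `flag` (`"ok"` or the
#'   flag name).
#' @export
cv_stats <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2)
    return(list(mean = if (n) mean(v) else NA_real_, sd = NA_real_,
                cv = NA_real_, n_used = n, flag = "insufficient_n"))
  mu <- mean(v); s <- stats::sd(v)
  if (mu == 0)
    return(list(mean = mu, sd = s, cv = NA_real_, n_used = n,
                flag = "undefined_mean_zero"))
  list(mean = mu, sd = s, cv = s / abs(mu), n_used = n, flag = "ok")
}

#' Per-feature CV table for one ROI's feature table
#'
#' One record per registry feature, with missing cells dropped pairwise and
#' the number of plans actually used recorded.
#'
#' @param table a `feature_table` from [extract_cohort()].
#' @return Data frame: `roi`, `study`, `family`, `name`, `aggregation`,
#'   `feature_id`, `mean`, `sd`, `cv`, `n_used`, `flag`.
#' @export
feature_cv_table <- function(table) {
  reg <- attr(table, "registry")
  if (is.null(reg)) stop("`table` carries no registry")
  recs <- lapply(seq_len(nrow(table)), function(r) cv_stats(table[r, ]))
  data.frame(
    roi = attr(table, "roi") %||% NA_character_,
    study = attr(table, "study") %||% NA_character_,
    family = reg$family, name = reg$name, aggregation = reg$aggregation,
    feature_id = reg$feature_id,
    mean = vapply(recs, `[[`, numeric(1), "mean"),
    sd = vapply(recs, `[[`, numeric(1), "sd"),
    cv = vapply(recs, `[[`, numeric(1), "cv"),
    n_used = vapply(recs, `[[`, integer(1), "n_used"),
    flag = vapply(recs, `[[`, character(1), "flag"))
}

#' Threshold-based stable/sensitive feature selection
#'
#' Strict thresholds as in the study protocol: a feature is *stable* in a
#' study when `cv < stable_th` (default 0.3) and *sensitive* when
#' `cv > sensitive_th` (defaults 1.0 and 0.8). Features with undefined CV
#' belong to neither set. Intersections are computed across studies and
#' percentages always use the full registry size as denominator.
#'
#' @param records named list of CV tables (from [feature_cv_table()]) for
#'   one ROI, keyed by study (e.g. `reproducibility`, `stability`,
#'   `sensitivity_fine`, `sensitivity_coarse`).
#' @param stable_th stability threshold (> 0).
#' @param sensitive_th one or more sensitivity thresholds (> 0).
#' @return A `selection_result`: per-study stable/sensitive sets, all
#'   pairwise intersection sets, percentages (1 decimal) and bookkeeping.
#' @export
select_features <- function(records, stable_th = 0.3, sensitive_th = c(1.0, 0.8)) {
  if (!is.list(records) || is.data.frame(records))
    records <- list(study = records)
  if (any(c(stable_th, sensitive_th) <= 0)) stop("thresholds must be positive")
  reg_size <- nrow(records[[1]])
  pct <- function(set) round(100 * length(set) / reg_size, 1)
  sets <- list()
  for (st in names(records)) {
    df <- records[[st]]
    ok <- !is.na(df$cv)
    sets[[paste0("stable_", st)]] <- df$feature_id[ok & df$cv < stable_th]
    for (th in sensitive_th)
      sets[[sprintf("sensitive_%s_gt%g", st, th)]] <-
        df$feature_id[ok & df$cv > th]
  }
  inter <- list()
  nm <- names(sets)
  if (length(nm) > 1) {
    for (a in seq_along(nm)[-length(nm)]) for (b in (a + 1):length(nm)) {
      inter[[paste(nm[a], nm[b], sep = " & ")]] <-
        intersect(sets[[nm[a]]], sets[[nm[b]]])
    }
  }
  pcts <- data.frame(set = c(names(sets), names(inter)),
                     n = c(vapply(sets, length, integer(1)),
                           vapply(inter, length, integer(1))))
  pcts$percent <- round(100 * pcts$n / reg_size, 1)
  rownames(pcts) <- NULL
  structure(list(sets = sets, intersections = inter, percentages = pcts,
                 registry_size = reg_size, stable_th = stable_th,
                 sensitive_th = sensitive_th),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> registry size %d; stable CV < %g; sensitive CV > %s\n",
              x$registry_size, x$stable_th,
              paste(x$sensitive_th, collapse = ", ")))
  print.data.frame(x$percentages, row.names = FALSE)
  invisible(x)
}

#' Common-feature percentage summary across studies
#'
#' For each ROI, the percentage of registry features shared between study
#' pairs: reproducibility-stable and stability-stable (both `cv <
#' stable_th`), sensitive at both grid resolutions (`cv > sensitive_th`),
#' and stability-stable yet resolution-sensitive. Percentages use the full
#' registry size and one decimal.
#'
#' @param cv_records data frame of stacked [feature_cv_table()] rows over
#'   ROIs and studies; `study` must contain `reproducibility`, `stability`,
#'   `sensitivity_fine`, `sensitivity_coarse`.
#' @param stable_th,sensitive_th thresholds as in [select_features()].
#' @return Data frame, one row per ROI, four percentage columns.
#' @export
common_feature_summary <- function(cv_records, stable_th = 0.3, sensitive_th = 1.0) {
  need <- c("reproducibility", "stability", "sensitivity_fine", "sensitivity_coarse")
  miss <- setdiff(need, unique(cv_records$study))
  if (length(miss)) stop("missing studies: ", paste(miss, collapse = ", "))
  rois <- unique(cv_records$roi)
  rows <- lapply(rois, function(r) {
    sub <- cv_records[cv_records$roi == r, ]
    reg_size <- sum(sub$study == "stability")
    setof <- function(st, op, th) {
      df <- sub[sub$study == st, ]
      ok <- !is.na(df$cv)
      if (op == "<") df$feature_id[ok & df$cv < th] else df$feature_id[ok & df$cv > th]
    }
    pct <- function(s) round(100 * length(s) / reg_size, 1)
    data.frame(
      roi = r,
      repro_stable_and_stab_stable = pct(intersect(
        setof("reproducibility", "<", stable_th), setof("stability", "<", stable_th))),
      sens_fine_and_sens_coarse = pct(intersect(
        setof("sensitivity_fine", ">", sensitive_th),
        setof("sensitivity_coarse", ">", sensitive_th))),
      stab_stable_and_sens_fine = pct(intersect(
        setof("stability", "<", stable_th), setof("sensitivity_fine", ">", sensitive_th))),
      stab_stable_and_sens_coarse = pct(intersect(
        setof("stability", "<", stable_th), setof("sensitivity_coarse", ">", sensitive_th))))
  })
  do.call(rbind, rows)
}

#' Per-family CV summary (means and box-plot statistics)
#'
#' Mean CV per feature family plus Tukey box statistics (median, quartiles,
#' 1.5 x IQR whiskers) over the defined CVs; exports plotting data, not
#' figures. Families with no defined CV are flagged empty.
#'
#' @param records a [feature_cv_table()] data frame (or several rbind-ed).
#' @return Data frame, one row per (study, roi, family).
#' @export
family_summary <- function(records) {
  key <- interaction(records$study, records$roi, records$family, drop = TRUE)
  rows <- lapply(split(records, key), function(df) {
    cv <- df$cv[!is.na(df$cv)]
    base <- data.frame(study = df$study[1], roi = df$roi[1], family = df$family[1],
                       n_total = nrow(df), n_defined = length(cv))
    if (!length(cv))
      return(cbind(base, mean_cv = NA_real_, median = NA_real_, q1 = NA_real_,
                   q3 = NA_real_, whisker_low = NA_real_, whisker_high = NA_real_,
                   empty = TRUE))
    q <- stats::quantile(cv, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    cbind(base, mean_cv = mean(cv), median = q[2], q1 = q[1], q3 = q[3],
          whisker_low = min(cv[cv >= q[1] - 1.5 * iqr]),
          whisker_high = max(cv[cv <= q[3] + 1.5 * iqr]),
          empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intraclass correlation (two-way random effects, absolute agreement)
#'
#' Decomposes a complete subjects-by-raters matrix into subject, rater and
#' residual variance components from the two-way ANOVA mean squares
#' (components truncated at zero) and returns
#' `icc = var_subject / (var_subject + var_rater + var_residual)` —
#' the single-rater absolute-agreement ICC(2,1).
#'
#' @param mat numeric matrix, subjects in rows, raters in columns; at least
#'   2 of each, no missing values.
#' @return An `icc_result`: `icc`, `var_subject`, `var_rater`,
#'   `var_residual`, mean squares and a flag for degenerate input.
#' @export
icc <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("ICC requires a complete matrix")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  g <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  MSR <- k * sum((rm_ - g)^2) / (n - 1)
  MSC <- n * sum((cm - g)^2) / (k - 1)
  resid <- mat - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  var_s <- max(0, (MSR - MSE) / k)
  var_r <- max(0, (MSC - MSE) / n)
  var_e <- MSE
  tot <- var_s + var_r + var_e
  structure(list(icc = if (tot > 0) var_s / tot else NA_real_,
                 var_subject = var_s, var_rater = var_r, var_residual = var_e,
                 MSR = MSR, MSC = MSC, MSE = MSE,
                 n_subjects = n, n_raters = k,
                 flag = if (tot > 0) "ok" else "zero_total_variance",
                 model = "two-way random, absolute agreement, single rater"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.4f (%s)\n  var: subject %.4g, rater %.4g, residual %.4g\n",
              x$icc, x$model, x$var_subject, x$var_rater, x$var_residual))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' ICC of one feature family across ROI groups
#'
#' Secondary reliability analysis: for every feature of `family`, the ROIs
#' of a group act as subjects and the plans as raters, and [icc()] is
#' computed on the resulting subjects-by-raters matrix. Three conventional
#' groups are evaluated by default: all feature ROIs, the high-dose /
#' gradient ROIs and the low-dose ROIs.
#'
#' Because the ROIs carry very different dose distributions (high versus
#' low dose, uniform versus gradient), between-subject heterogeneity can
#' dominate and bias the ICC upward; the returned object carries this
#' caution in its `note` attribute and the CV analysis remains the primary
#' metric.
#'
#' @param tables named list (by ROI) of `feature_table`s for one study, as
#'   returned by [extract_cohort()].
#' @param family feature family to analyse (default `"STAT"`).
#' @param groups named list of ROI-name vectors.
#' @return Data frame with `group`, `feature_id`, `icc`, `var_subject`,
#'   `var_rater`, `var_residual`, `flag`.
#' @export
icc_study <- function(tables, family = "STAT",
                      groups = list(
                        all = FEATURE_ROIS,
                        high_dose = c("PTV", "parotid_R", "RING"),
                        low_dose = c("parotid_L", "spinal_canal", "trachea"))) {
  reg <- attr(tables[[1]], "registry")
  ids <- reg$feature_id[reg$family == family]
  if (!length(ids)) stop("unknown family '", family, "'")
  rows <- list()
  for (g in names(groups)) {
    rois <- intersect(groups[[g]], names(tables))
    if (length(rois) < 2) next
    for (id in ids) {
      m <- t(vapply(rois, function(r) tables[[r]][id, ], numeric(ncol(tables[[1]]))))
      if (anyNA(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, feature_id = id, icc = NA_real_, var_subject = NA_real_,
          var_rater = NA_real_, var_residual = NA_real_, flag = "missing_values")
        next
      }
      r <- icc(m)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, feature_id = id, icc = r$icc, var_subject = r$var_subject,
        var_rater = r$var_rater, var_residual = r$var_residual, flag = r$flag)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "note") <- paste(
    "ICC treats ROIs as subjects and plans as raters; strong between-ROI",
    "dose heterogeneity can inflate the subject variance and bias the ICC",
    "upward. Interpret alongside the per-feature CV analysis.")
  out
}

#' Compare two extraction runs feature by feature
#'
#' Elementwise differences between two feature tables over the same
#' registry and plans; the headline number is the maximum absolute
#' difference (0 when the software is reproducible). `NA` in both runs
#' counts as agreement; `NA` in one only is reported as a discrepancy.
#'
#' @param tableA,tableB `feature_table` matrices from [extract_cohort()],
#'   or plain feature vectors/matrices with identical dimnames.
#' @return List: `max_abs_diff`, `n_compared`, `mismatches` (data frame of
#'   features with non-zero or one-sided-NA differences).
#' @export
compare_extractions <- function(tableA, tableB) {
  a <- as.matrix(tableA); b <- as.matrix(tableB)
  ra <- attr(tableA, "registry"); rb <- attr(tableB, "registry")
  if (!is.null(ra) && !is.null(rb) && !identical(ra$feature_id, rb$feature_id))
    stop("feature registries differ")
  if (!identical(dim(a), dim(b)))
    stop("tables have different dimensions")
  d <- abs(a - b)
  onesided <- xor(is.na(a), is.na(b))
  d[is.na(a) & is.na(b)] <- 0
  d[onesided] <- Inf
  mism <- which(d > 0, arr.ind = TRUE)
  ids <- if (!is.null(ra)) ra$feature_id else rownames(a) %||% as.character(seq_len(nrow(a)))
  mismatches <- data.frame(
    feature_id = ids[mism[, 1]],
    plan = (colnames(a) %||% as.character(seq_len(ncol(a))))[mism[, 2]],
    diff = d[mism])
  list(max_abs_diff = max(d), n_compared = length(d), mismatches = mismatches)
}

#' Software-reproducibility check on one plan
#'
#' Mirrors the two-centre software check: extract the full panel twice,
#' independently, from the same dose distribution rendered at the fine and
#' the coarse grid resolution, and difference the runs feature by feature.
#'
#' @param structs a [structure_set()] from [build_phantom()].
#' @param seed integer seed for the single plan used.
#' @param resolutions_mm fine/coarse resolution pair; defaults as in
#'   [generate_cohort()].
#' @param ... passed to [extract_all()].
#' @return List: `max_abs_diff` over all ROIs and both resolutions,
#'   `n_features_compared` (registry size x number of resolutions, 424 for
#'   the default panel) and the per-resolution comparison details.
#' @export
software_reproducibility_check <- function(structs, seed = 1L,
                                           resolutions_mm = NULL, ...) {
  if (is.null(resolutions_mm)) {
    fine <- max(structs$grid$spacing_mm)
    resolutions_mm <- c(fine = fine, coarse = 2 * fine)
  }
  details <- list()
  maxd <- 0; nfeat <- 0L
  for (rn in names(resolutions_mm)) {
    spec <- plan_sim_spec(grid_resolution_mm = resolutions_mm[[rn]],
                          noise_sd_Gy = 0.4, seed = seed)
    dose <- simulate_plan(structs, spec)
    run1 <- extract_all(dose, structs, ...)
    run2 <- extract_all(dose, structs, ...)
    m1 <- do.call(cbind, run1$features)
    m2 <- do.call(cbind, run2$features)
    cmp <- compare_extractions(m1, m2)
    details[[rn]] <- cmp
    maxd <- max(maxd, cmp$max_abs_diff)
    nfeat <- nfeat + nrow(m1)
  }
  list(max_abs_diff = maxd, n_features_compared = nfeat, details = details)
}
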