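#' Scalar DVH metrics for one ROI
#'
#' Computes mean dose, maximum dose, `Dq%` (minimum dose covering q percent
#' of the ROI volume, i.e. the (100-q)-th dose percentile by inverse ECDF)
#' and `Vx` (percent of the ROI volume receiving at least `x` Gy).
#'
#' @param dose_values numeric vector of ROI voxel doses (Gy).
#' @param d_coverage_pct volume percentages q for which to report Dq%.
#' @param v_threshold_Gy dose thresholds x (Gy) for which to report Vx (%).
#' @return Named list of metrics.
#' @export
dvh_metrics <- function(dose_values, d_coverage_pct = 98, v_threshold_Gy = numeric()) {
  if (length(dose_values) == 0) stop("empty ROI")
  out <- list(Dmean = mean(dose_values), Dmax = max(dose_values))
  for (q in d_coverage_pct) {
    out[[sprintf("D%g%%", q)]] <-
      as.numeric(stats::quantile(dose_values, 1 - q / 100, type = 1, names = FALSE))
  }
  for (x in v_threshold_Gy) {
    out[[sprintf("V%gGy", x)]] <- 100 * mean(dose_values >= x)
  }
  out
}

#' Plan quality assurance against the planning constraints
#'
#' Evaluates the planning protocol used to generate comparable dose
#' distributions: PTV D98% > 95% of prescription and V105% < 10%; Dmax of
#' spinal canal and PRV below 45 Gy; RING Dmax below 95% of prescription;
#' mean dose below 50 Gy for trachea and 25 Gy for the parotids. If the
#' dose grid differs from the structure grid the dose is resampled first.
#'
#' @param dose a [dose_grid()].
#' @param structs a [structure_set()] with the seven phantom ROIs.
#' @param prescription_Gy prescribed PTV dose (Gy), default 66.
#' @return A data frame of class `plan_qa` with one row per constraint:
#'   `roi`, `metric`, `value`, `limit`, `direction` and logical `pass`.
#'   Empty ROIs yield an explicit error row (`pass = NA`), never a silent
#'   pass.
#' @export
check_constraints <- function(dose, structs, prescription_Gy = 66) {
  if (!same_grid(dose, structs)) {
    # evaluate DVH metrics on the dose calculation grid: rebuild the
    # structures there when analytic geometry is available, otherwise
    # fall back to resampling the dose onto the structure grid
    rebuilt <- tryCatch(structs_on_grid(structs, grid_of(dose)),
                        error = function(e) NULL)
    if (is.null(rebuilt)) {
      dose <- resample_dose(dose, structs$grid)
    } else {
      structs <- rebuilt
    }
  }
  P <- prescription_Gy
  cons <- list(
    list(roi = "PTV", metric = "D98%", limit = 0.95 * P, dir = ">"),
    list(roi = "PTV", metric = "V105%", limit = 10, dir = "<"),
    list(roi = "spinal_canal", metric = "Dmax", limit = 45, dir = "<"),
    list(roi = "PRV_SC", metric = "Dmax", limit = 45, dir = "<"),
    list(roi = "RING", metric = "Dmax", limit = 0.95 * P, dir = "<"),
    list(roi = "trachea", metric = "Dmean", limit = 50, dir = "<"),
    list(roi = "parotid_L", metric = "Dmean", limit = 25, dir = "<"),
    list(roi = "parotid_R", metric = "Dmean", limit = 25, dir = "<")
  )
  rows <- lapply(cons, function(cc) {
    roi <- structs$rois[[cc$roi]]
    if (is.null(roi) || !any(roi$mask)) {
      return(data.frame(roi = cc$roi, metric = cc$metric, value = NA_real_,
                        limit = cc$limit, direction = cc$dir, pass = NA,
                        note = "empty or missing ROI"))
    }
    dv <- dose$values[roi$mask]
    value <- switch(cc$metric,
                    "D98%" = dvh_metrics(dv, d_coverage_pct = 98)[["D98%"]],
                    "V105%" = 100 * mean(dv >= 1.05 * P),
                    "Dmax" = max(dv),
                    "Dmean" = mean(dv))
    pass <- if (cc$dir == "<") value < cc$limit else value > cc$limit
    data.frame(roi = cc$roi, metric = cc$metric, value = value,
               limit = cc$limit, direction = cc$dir, pass = pass, note = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("plan_qa", "data.frame")
  out
}

#' @export
print.plan_qa <- function(x, ...) {
  df <- as.data.frame(x)
  df$value <- round(df$value, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
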