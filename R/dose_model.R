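#' Plan simulation specification
#'
#' Parameters of one synthetic dose distribution. The model is a sum of
#' separable smooth fields, not beam transport: prescription plateau inside
#' the PTV, technique-specific exponential fall-off outside (length scale
#' `gradient_scale_mm`), multiplicative organ-sparing attenuation around the
#' OARs, and spatially correlated Gaussian noise (sd `noise_sd_Gy`,
#' correlation length `texture_corr_len_mm`). Deterministic given `seed`.
#'
#' @param prescription_Gy prescribed PTV dose (Gy); default 66.
#' @param fraction_dose_Gy dose per fraction (Gy); default 2.2 (metadata).
#' @param technique_id label selecting a fall-off/texture kernel; see
#'   [technique_params()].
#' @param gradient_scale_mm dose fall-off length scale outside the PTV; if
#'   `NULL`, the technique default is used.
#' @param noise_sd_Gy standard deviation of the correlated voxel noise (Gy).
#' @param texture_corr_len_mm correlation length of the noise field (mm).
#' @param grid_resolution_mm isotropic dose-grid spacing; `NULL` renders on
#'   the structure-set reference grid.
#' @param seed integer RNG seed.
#' @return A `plan_sim_spec` list.
#' @export
plan_sim_spec <- function(prescription_Gy = 66,
                          fraction_dose_Gy = 2.2,
                          technique_id = "imrt_aaa",
                          gradient_scale_mm = NULL,
                          noise_sd_Gy = 0.4,
                          texture_corr_len_mm = 6,
                          grid_resolution_mm = NULL,
                          seed = 1L) {
  if (prescription_Gy <= 0) stop("`prescription_Gy` must be positive")
  if (noise_sd_Gy < 0) stop("`noise_sd_Gy` must be non-negative")
  if (texture_corr_len_mm <= 0) stop("`texture_corr_len_mm` must be positive")
  tp <- technique_params(technique_id)
  if (is.null(gradient_scale_mm)) gradient_scale_mm <- tp$gradient_scale_mm
  if (gradient_scale_mm <= 0) stop("`gradient_scale_mm` must be positive")
  structure(list(prescription_Gy = prescription_Gy,
                 fraction_dose_Gy = fraction_dose_Gy,
                 technique_id = technique_id,
                 gradient_scale_mm = gradient_scale_mm,
                 noise_sd_Gy = noise_sd_Gy,
                 texture_corr_len_mm = texture_corr_len_mm,
                 grid_resolution_mm = grid_resolution_mm,
                 seed = as.integer(seed)),
            class = "plan_sim_spec")
}

#' Technique kernel library
#'
#' Each technique id maps to a default fall-off length, penumbra offset,
#' OAR-sparing strengths and a PTV heterogeneity pattern, standing in for
#' the distinct delivery techniques / dose engines of a multi-centre cohort.
#'
#' @param technique_id one of the known labels (call with no args to list).
#' @return A named parameter list.
#' @export
technique_params <- function(technique_id = NULL) {
  lib <- list(
    imrt_aaa     = list(gradient_scale_mm = 8,  penumbra_mm = 3.0,
                        sparing = c(parotid_R = 0.30, parotid_L = 0.10,
                                    spinal_canal = 0.40, trachea = 0.30),
                        ptv_boost = 1.01, het_amp = 0.004, het_len_mm = 18),
    vmat_aaa     = list(gradient_scale_mm = 7,  penumbra_mm = 3.0,
                        sparing = c(parotid_R = 0.35, parotid_L = 0.10,
                                    spinal_canal = 0.45, trachea = 0.30),
                        ptv_boost = 1.01, het_amp = 0.004, het_len_mm = 16),
    vmat_acuros  = list(gradient_scale_mm = 8.5, penumbra_mm = 2.6,
                        sparing = c(parotid_R = 0.40, parotid_L = 0.12,
                                    spinal_canal = 0.45, trachea = 0.32),
                        ptv_boost = 1.008, het_amp = 0.006, het_len_mm = 14),
    pinnacle_cc  = list(gradient_scale_mm = 10, penumbra_mm = 3.4,
                        sparing = c(parotid_R = 0.45, parotid_L = 0.15,
                                    spinal_canal = 0.50, trachea = 0.35),
                        ptv_boost = 1.012, het_amp = 0.007, het_len_mm = 20),
    raystation_mc = list(gradient_scale_mm = 11.5, penumbra_mm = 3.0,
                        sparing = c(parotid_R = 0.50, parotid_L = 0.15,
                                    spinal_canal = 0.55, trachea = 0.35),
                        ptv_boost = 1.006, het_amp = 0.009, het_len_mm = 12),
    tomo_cc      = list(gradient_scale_mm = 13, penumbra_mm = 3.6,
                        sparing = c(parotid_R = 0.55, parotid_L = 0.18,
                                    spinal_canal = 0.60, trachea = 0.40),
                        ptv_boost = 1.010, het_amp = 0.006, het_len_mm = 24),
    impt_mc      = list(gradient_scale_mm = 6,  penumbra_mm = 2.2,
                        sparing = c(parotid_R = 0.25, parotid_L = 0.08,
                                    spinal_canal = 0.35, trachea = 0.25),
                        ptv_boost = 1.005, het_amp = 0.010, het_len_mm = 10)
  )
  if (is.null(technique_id)) return(lib)
  if (!technique_id %in% names(lib))
    stop("unknown technique_id '", technique_id, "'; known: ",
         paste(names(lib), collapse = ", "))
  lib[[technique_id]]
}

#' Simulate one 3D dose distribution
#'
#' Renders the analytic dose model of a `plan_sim_spec` on the structure
#' set's reference grid (or an isotropic grid of `grid_resolution_mm` over
#' the same physical extent). Requires a structure set produced by
#' [build_phantom()] (the analytic ROI geometry drives the model).
#'
#' @param structs a [structure_set()] with analytic geometry.
#' @param spec a [plan_sim_spec()].
#' @return A [dose_grid()] of absolute dose in Gy; non-negative, finite and
#'   bitwise-reproducible for a fixed spec.
#' @export
simulate_plan <- function(structs, spec) {
  if (!inherits(structs, "structure_set")) stop("`structs` must be a structure_set")
  if (!inherits(spec, "plan_sim_spec")) stop("`spec` must be a plan_sim_spec")
  geo <- structs$geometry
  if (is.null(geo) || is.null(geo$PTV))
    stop("structure set has no analytic geometry; simulate_plan only supports ",
         "phantoms from build_phantom()")
  ref <- structs$grid
  if (is.null(spec$grid_resolution_mm)) {
    grid <- ref
  } else {
    res <- spec$grid_resolution_mm
    ext_lo <- ref$origin_mm - ref$spacing_mm / 2
    ext_hi <- ref$origin_mm + (ref$dim - 0.5) * ref$spacing_mm
    nd <- pmax(as.integer(ceiling((ext_hi - ext_lo) / res)), 2L)
    grid <- grid_geometry(nd, rep(res, 3), ext_lo + res / 2)
  }
  nd <- grid$dim
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  X <- array(rep(xs, times = nd[2] * nd[3]), nd)
  Y <- array(rep(rep(ys, each = nd[1]), times = nd[3]), nd)
  Z <- array(rep(zs, each = nd[1] * nd[2]), nd)

  tp <- technique_params(spec$technique_id)
  P <- spec$prescription_Gy
  u_ptv <- shape_u(geo$PTV, X, Y, Z)
  s_mm <- pmax(u_ptv - 1, 0) * shape_scale(geo$PTV)
  inside <- u_ptv <= 1

  # plateau with mild technique-specific heterogeneity inside the PTV
  het <- tp$het_amp * sin(2 * pi * X / tp$het_len_mm) *
    sin(2 * pi * Y / tp$het_len_mm) * cos(2 * pi * Z / (1.7 * tp$het_len_mm))
  dose <- array(0, nd)
  dose[inside] <- P * tp$ptv_boost * (1 + het[inside])

  # penumbra + exponential fall-off outside, attenuated near spared OARs
  fall <- P * exp(-(s_mm + tp$penumbra_mm) / spec$gradient_scale_mm)
  spare <- rep(1, length(fall))
  for (nm in names(tp$sparing)) {
    prim <- geo[[nm]]
    if (is.null(prim)) next
    u_k <- shape_u(prim, X, Y, Z) / 1.6   # widened sparing bump
    spare <- spare * (1 - tp$sparing[[nm]] * exp(-u_k^2))
  }
  dose[!inside] <- (fall * spare)[!inside]

  if (spec$noise_sd_Gy > 0) {
    noise <- with_seed(spec$seed, array(stats::rnorm(prod(nd)), nd))
    sig_vox <- spec$texture_corr_len_mm / (2 * grid$spacing_mm)
    noise <- gauss_smooth3(noise, sig_vox)
    noise <- noise / stats::sd(noise) * spec$noise_sd_Gy
    envelope <- 0.15 + 0.85 * dose / (P * tp$ptv_boost)
    dose <- dose + noise * envelope
  }
  dose <- pmax(dose, 0)
  dose_grid(dose, grid$spacing_mm, grid$origin_mm)
}

#' Generate a study cohort of synthetic dose distributions
#'
#' Emulates the three study regimes: `reproducibility` (4 plans, one
#' technique, near-identical settings), `stability` (8 plans = the 4
#' reproducibility plans plus 4 with per-plan fall-off jitter, mirroring a
#' same-technique multi-machine cohort), and `sensitivity` (11 plans across
#' >= 4 distinct techniques, each rendered at a fine and a coarse dose-grid
#' resolution, 22 grids).
#'
#' @param structs a [structure_set()] from [build_phantom()].
#' @param design one of `"reproducibility"`, `"stability"`, `"sensitivity"`.
#' @param base_seed integer; all per-plan seeds derive from it.
#' @param prescription_Gy prescribed dose, default 66 Gy.
#' @param resolutions_mm fine/coarse grid spacings for the sensitivity
#'   design; defaults to the reference spacing and twice it.
#' @return A list of plan records `list(label, technique_id, resolution,
#'   seed, spec, dose)`; lengths 4 / 8 / 22.
#' @export
generate_cohort <- function(structs, design, base_seed = 1L,
                            prescription_Gy = 66,
                            resolutions_mm = NULL) {
  designs <- c("reproducibility", "stability", "sensitivity")
  if (length(design) != 1L || !design %in% designs)
    stop("unknown design '", design, "'; must be one of: ",
         paste(designs, collapse = ", "))

  base_gs <- technique_params("imrt_aaa")$gradient_scale_mm
  stab_plan <- function(i) {
    # plans 1-4: reproducibility set (tiny inter-centre jitter, low noise);
    # plans 5-8: same technique on different machines (larger jitter + noise)
    sd_i <- plan_seed(base_seed, i)
    jit <- with_seed(sd_i, stats::runif(1, -1, 1))
    if (i <= 4) {
      gs <- base_gs * (1 + 0.02 * jit); noise <- 0.4
    } else {
      gs <- base_gs * (1 + 0.10 * jit); noise <- 0.8
    }
    spec <- plan_sim_spec(prescription_Gy = prescription_Gy,
                          technique_id = "imrt_aaa", gradient_scale_mm = gs,
                          noise_sd_Gy = noise, seed = sd_i)
    list(label = sprintf("P%d", i), technique_id = "imrt_aaa",
         resolution = "reference", seed = sd_i, spec = spec,
         dose = simulate_plan(structs, spec))
  }

  if (design == "reproducibility") return(lapply(1:4, stab_plan))
  if (design == "stability") return(lapply(1:8, stab_plan))

  # sensitivity: 11 plans over 6 techniques x 2 resolutions
  if (is.null(resolutions_mm)) {
    fine <- max(structs$grid$spacing_mm)
    resolutions_mm <- c(fine = fine, coarse = 2 * fine)
  }
  if (is.null(names(resolutions_mm))) names(resolutions_mm) <- c("fine", "coarse")
  techs <- c("vmat_aaa", "vmat_acuros", "impt_mc", "pinnacle_cc",
             "raystation_mc", "tomo_cc")
  out <- list()
  for (i in 1:11) {
    tech <- techs[(i - 1) %% length(techs) + 1]
    sd_i <- plan_seed(base_seed, 100 + i)
    jit <- with_seed(sd_i, stats::runif(1, -1, 1))
    gs <- technique_params(tech)$gradient_scale_mm * (1 + 0.05 * jit)
    for (rn in names(resolutions_mm)) {
      spec <- plan_sim_spec(prescription_Gy = prescription_Gy,
                            technique_id = tech, gradient_scale_mm = gs,
                            noise_sd_Gy = 1.0,
                            grid_resolution_mm = resolutions_mm[[rn]],
                            seed = sd_i)
      out[[length(out) + 1L]] <- list(
        label = sprintf("S%d", i), technique_id = tech, resolution = rn,
        seed = sd_i, spec = spec, dose = simulate_plan(structs, spec))
    }
  }
  out
}
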