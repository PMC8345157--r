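# Feature formulas for the three matrix families, computed from sparse
# (index, index, probability/count) triplets, plus the per-family
# aggregation drivers.

log2s <- function(x) ifelse(x > 0, log2(x), 0)

# marginal over grey levels
marg <- function(w, idx, G) {
  out <- numeric(G)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# 25 co-occurrence features from normalised symmetric triplets (i, j, p).
glcm_features_sparse <- function(i, j, p, G) {
  pm <- marg(p, i, G)                      # row marginal (= column, symmetric)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  dif <- abs(i - j); sm <- i + j
  pd <- rowsum(p, dif); pdk <- as.integer(rownames(pd)); pdv <- pd[, 1]
  ps <- rowsum(p, sm);  psk <- as.integer(rownames(ps)); psv <- ps[, 1]
  da <- sum(pdk * pdv)
  sa <- sum(psk * psv)
  HXY <- -sum(p * log2(p))
  pmnz <- pm[pm > 0]
  HX <- -sum(pmnz * log2(pmnz))
  HXY1 <- -sum(p * log2(pm[i] * pm[j]))
  oo <- outer(pmnz, pmnz)
  HXY2 <- -sum(oo * log2(oo))
  single_level <- length(pmnz) < 2L
  corr <- if (single_level) NA_real_ else (sum(i * j * p) - mu^2) / sig2
  ic1 <- if (single_level || HX == 0) NA_real_ else (HXY - HXY1) / HX
  ic2 <- if (single_level) NA_real_ else sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  base <- c(joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sig2,
    joint_entropy = HXY,
    difference_average = da,
    difference_variance = sum((pdk - da)^2 * pdv),
    difference_entropy = -sum(pdv * log2(pdv)),
    sum_average = sa,
    sum_variance = sum((psk - sa)^2 * psv),
    sum_entropy = -sum(psv * log2(psv)),
    angular_second_moment = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(dif * p),
    inverse_difference = sum(p / (1 + dif)),
    inverse_difference_normalised = sum(p / (1 + dif / G)),
    inverse_difference_moment = sum(p / (1 + dif^2)),
    inverse_difference_moment_normalised = sum(p / (1 + dif^2 / G^2)),
    inverse_variance = sum(p[dif > 0] / dif[dif > 0]^2),
    correlation = corr,
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p))
  out <- c(base, information_correlation_1 = ic1, information_correlation_2 = ic2)
  out[GLCM_NAMES]
}

# 16 run-length (or size-zone) features from counts r at (level i, size j).
# `Nv` is the number of voxels covered by the matrix (per IBSI, summed over
# merged matrices for run-length merging).
rl_features_sparse <- function(i, j, r, Nv, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  # aggregate duplicate (level, size) cells so entropy sees true matrix cells
  W <- max(j)
  key <- (i - 1) * W + j
  s <- rowsum(r, key)
  k <- as.numeric(rownames(s))
  i <- (k - 1) %/% W + 1
  j <- (k - 1) %% W + 1
  r <- s[, 1]
  Ns <- sum(r)
  p <- r / Ns
  gi <- rowsum(r, i)[, 1]
  rj <- rowsum(r, j)[, 1]
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(
    sum(r / j^2) / Ns,                 # short emphasis
    sum(r * j^2) / Ns,                 # long/large emphasis
    sum(r / i^2) / Ns,
    sum(r * i^2) / Ns,
    sum(r / (i^2 * j^2)) / Ns,
    sum(r * i^2 / j^2) / Ns,
    sum(r * j^2 / i^2) / Ns,
    sum(r * i^2 * j^2) / Ns,
    sum(gi^2) / Ns,                    # grey level non-uniformity
    sum(gi^2) / Ns^2,
    sum(rj^2) / Ns,                    # run length / zone size non-uniformity
    sum(rj^2) / Ns^2,
    Ns / Nv,                           # run/zone percentage
    sum((i - mu_i)^2 * p),             # grey level variance
    sum((j - mu_j)^2 * p),             # run length / zone size variance
    -sum(p * log2(p)))                 # entropy
  names(vals) <- if (prefix == "run") GLRLM_NAMES else GLSZM_NAMES
  vals
}

# Average feature vectors over components (directions/slices), skipping
# NA entries component-wise; all-NA stays NA.
avg_feats <- function(mat) {
  if (is.null(dim(mat))) return(mat)
  apply(mat, 2, function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
}

#' Co-occurrence features (100 values)
#'
#' The 25 co-occurrence features under the four aggregation schemes:
#' per-slice per-direction averaged (`2D_avg`), per-slice direction-merged
#' then slice-averaged (`2D_merge`), per-direction over the full volume then
#' averaged (`3D_avg`), and all 13 unique 3D directions merged (`3D_merge`).
#' Distance-1 symmetric pairs throughout. Correlation-type features of a
#' single-level matrix are returned as `NA`.
#'
#' @param levels a [discretise()]d ROI.
#' @return Named numeric vector of 100 values (`GLCM_<name>_<aggregation>`).
#' @export
glcm_features <- function(levels) {
  if (!inherits(levels, "discretised_roi")) stop("`levels` must be a discretised_roi")
  lev <- levels$levels; G <- levels$G
  sp2 <- glcm_sparse(lev, DIRS2, G, by_slice = TRUE)
  sp3 <- glcm_sparse(lev, DIRS3, G, by_slice = FALSE)
  feat_of <- function(df) {
    tot <- sum(df$n)
    if (tot == 0) return(rep(NA_real_, length(GLCM_NAMES)))
    # aggregate duplicate (i, j) cells arising from merged directions/slices
    key <- (df$i - 1L) * G + df$j
    s <- rowsum(df$n, key)
    k <- as.integer(rownames(s))
    i <- (k - 1L) %/% G + 1L
    j <- (k - 1L) %% G + 1L
    glcm_features_sparse(i, j, s[, 1] / tot, G)
  }
  by_groups <- function(df, by) {
    if (!nrow(df)) return(matrix(NA_real_, 1, length(GLCM_NAMES)))
    key <- interaction(df[by], drop = TRUE)
    groups <- split(seq_len(nrow(df)), key)
    t(vapply(groups, function(ix) feat_of(df[ix, , drop = FALSE]),
             numeric(length(GLCM_NAMES))))
  }
  v2a <- avg_feats(by_groups(sp2, c("group", "dir")))
  v2m <- avg_feats(by_groups(sp2, "group"))
  v3a <- avg_feats(by_groups(sp3, "dir"))
  v3m <- feat_of(sp3)
  out <- c(v2a, v2m, v3a, v3m)
  names(out) <- c(paste0("GLCM_", GLCM_NAMES, "_2D_avg"),
                  paste0("GLCM_", GLCM_NAMES, "_2D_merge"),
                  paste0("GLCM_", GLCM_NAMES, "_3D_avg"),
                  paste0("GLCM_", GLCM_NAMES, "_3D_merge"))
  out
}

#' Run-length features (64 values before registry subsetting)
#'
#' Maximal runs of equal grey level along each direction, truncated at the
#' mask boundary, summarised by the 16 run-length features under the four
#' aggregation schemes (as in [glcm_features()]). The default registry keeps
#' 63 of the 64 values.
#'
#' @param levels a [discretise()]d ROI.
#' @return Named numeric vector of 64 values (`GLRLM_<name>_<aggregation>`).
#' @export
runlength_features <- function(levels) {
  if (!inherits(levels, "discretised_roi")) stop("`levels` must be a discretised_roi")
  lev <- levels$levels
  nvox <- sum(lev > 0L)
  slice_n <- tabulate(arrayInd(which(lev > 0L), dim(lev))[, 3], dim(lev)[3])

  runs2 <- lapply(seq_len(nrow(DIRS2)), function(k) run_lengths(lev, DIRS2[k, ]))
  runs3 <- lapply(seq_len(nrow(DIRS3)), function(k) run_lengths(lev, DIRS3[k, ]))

  f_of <- function(df, Nv) {
    if (!nrow(df)) return(rep(NA_real_, length(GLRLM_NAMES)))
    rl_features_sparse(df$level, df$length, rep(1, nrow(df)), Nv, "run")
  }
  # 2D per (slice, direction)
  m2a <- list(); m2m <- list()
  slices <- which(slice_n > 0)
  for (s in slices) {
    per_dir <- lapply(runs2, function(df) df[df$slice == s, , drop = FALSE])
    m2a[[length(m2a) + 1L]] <-
      t(vapply(per_dir, f_of, numeric(length(GLRLM_NAMES)), Nv = slice_n[s]))
    merged <- do.call(rbind, per_dir)
    m2m[[length(m2m) + 1L]] <- f_of(merged, Nv = slice_n[s] * nrow(DIRS2))
  }
  v2a <- avg_feats(do.call(rbind, m2a))
  v2m <- avg_feats(do.call(rbind, m2m))
  v3a <- avg_feats(t(vapply(runs3, f_of, numeric(length(GLRLM_NAMES)), Nv = nvox)))
  v3m <- f_of(do.call(rbind, runs3), Nv = nvox * nrow(DIRS3))
  out <- c(v2a, v2m, v3a, v3m)
  names(out) <- c(paste0("GLRLM_", GLRLM_NAMES, "_2D_avg"),
                  paste0("GLRLM_", GLRLM_NAMES, "_2D_merge"),
                  paste0("GLRLM_", GLRLM_NAMES, "_3D_avg"),
                  paste0("GLRLM_", GLRLM_NAMES, "_3D_merge"))
  out
}

#' Size-zone features (32 values)
#'
#' Zones are connected components of equal grey level (26-connectivity in
#' 3D, 8-connectivity within slices in 2D), summarised by the 16 size-zone
#' features under two aggregations: all per-slice matrices merged
#' (`2D_merge`) and the single 3D matrix (`3D`).
#'
#' @param levels a [discretise()]d ROI.
#' @return Named numeric vector of 32 values (`GLSZM_<name>_<aggregation>`).
#' @export
sizezone_features <- function(levels) {
  if (!inherits(levels, "discretised_roi")) stop("`levels` must be a discretised_roi")
  lev <- levels$levels
  nvox <- sum(lev > 0L)
  z2 <- size_zones(lev, "2D")
  z3 <- size_zones(lev, "3D")
  f_of <- function(df, Nv) {
    if (!nrow(df)) return(rep(NA_real_, length(GLSZM_NAMES)))
    rl_features_sparse(df$level, df$size, rep(1, nrow(df)), Nv, "zone")
  }
  out <- c(f_of(z2, nvox), f_of(z3, nvox))
  names(out) <- c(paste0("GLSZM_", GLSZM_NAMES, "_2D_merge"),
                  paste0("GLSZM_", GLSZM_NAMES, "_3D"))
  out
}
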