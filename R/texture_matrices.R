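# Texture-matrix engines shared by the GLCM / GLRLM / GLSZM families.
#
# Levels are carried as an integer 3D array with 0 outside the ROI mask.
# Offsets follow the canonical convention: first non-zero component
# positive; the symmetric counterpart is implied.

# 13 unique 3D directions at Chebyshev distance 1
DIRS3 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# 4 unique in-slice (axial) directions
DIRS2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))

# Scan pairs of a level array for one offset: every unordered neighbour
# pair appears once. Returns i, j (levels) and the slice index of the
# first voxel (for in-plane offsets both voxels share the slice).
offset_range <- function(n, s) {
  lo <- max(1, 1 - s); hi <- min(n, n - s)
  if (hi < lo) integer(0) else lo:hi
}

level_pairs <- function(lev, d) {
  nd <- dim(lev)
  xa <- offset_range(nd[1], d[1])
  ya <- offset_range(nd[2], d[2])
  za <- offset_range(nd[3], d[3])
  if (!length(xa) || !length(ya) || !length(za))
    return(list(i = integer(), j = integer(), slice = integer()))
  A <- lev[xa, ya, za, drop = FALSE]
  B <- lev[xa + d[1], ya + d[2], za + d[3], drop = FALSE]
  keep <- A > 0L & B > 0L
  sl <- array(rep(za, each = length(xa) * length(ya)), dim(A))
  list(i = A[keep], j = B[keep], slice = sl[keep])
}

# Symmetrised sparse co-occurrence triplets (i, j, count) per group
# (group = slice index, or 0 for whole-volume). Each scan pair contributes
# (i,j) and (j,i). Aggregated with an integer key + tabulate for speed.
glcm_sparse <- function(lev, dirs, G, by_slice = FALSE) {
  nz <- dim(lev)[3]
  ndir <- nrow(dirs)
  keys <- list()
  for (k in seq_len(ndir)) {
    pr <- level_pairs(lev, dirs[k, ])
    if (!length(pr$i)) next
    g <- if (by_slice) pr$slice else rep(1L, length(pr$i))
    i2 <- c(pr$i, pr$j); j2 <- c(pr$j, pr$i); g2 <- c(g, g)
    keys[[length(keys) + 1L]] <-
      (((k - 1) * nz + (g2 - 1)) * G + (i2 - 1)) * G + j2
  }
  if (!length(keys))
    return(data.frame(dir = integer(), group = integer(), i = integer(),
                      j = integer(), n = numeric()))
  key <- unlist(keys, use.names = FALSE)
  tab <- tabulate(key, nbins = ndir * nz * G * G)
  nzk <- which(tab > 0)
  k0 <- nzk - 1L
  j <- k0 %% G + 1L; k0 <- k0 %/% G
  i <- k0 %% G + 1L; k0 <- k0 %/% G
  group <- k0 %% nz + 1L
  dir <- k0 %/% nz + 1L
  data.frame(dir = dir, group = group, i = i, j = j, n = tab[nzk])
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered grey-level pairs for voxel pairs inside the ROI mask
#' separated by a unit Chebyshev offset, symmetrised by adding the
#' transpose. In `"2D_slice"` mode only in-slice offsets are allowed and
#' counts accumulate over slices.
#'
#' @param levels a [discretise()]d ROI.
#' @param offset integer voxel displacement `c(dx, dy, dz)` with Chebyshev
#'   norm 1.
#' @param mode `"3D"` or `"2D_slice"`.
#' @param normalise if `TRUE` the matrix is scaled to sum to 1.
#' @return A `texture_matrix`: `G x G` matrix plus provenance fields. A mask
#'   with no valid pair yields a zero matrix flagged `empty = TRUE`.
#' @export
cooccurrence_matrix <- function(levels, offset, mode = c("3D", "2D_slice"),
                                normalise = FALSE) {
  if (!inherits(levels, "discretised_roi")) stop("`levels` must be a discretised_roi")
  mode <- match.arg(mode)
  offset <- as.integer(offset)
  if (length(offset) != 3L || max(abs(offset)) != 1L)
    stop("`offset` must be a voxel displacement with Chebyshev norm 1")
  if (mode == "2D_slice" && offset[3] != 0L)
    stop("2D_slice mode requires an in-slice offset (dz = 0)")
  G <- levels$G
  pr <- level_pairs(levels$levels, offset)
  M <- matrix(0, G, G)
  if (length(pr$i)) {
    idx <- c((pr$i - 1L) * G + pr$j, (pr$j - 1L) * G + pr$i)
    tab <- tabulate(idx, nbins = G * G)
    M <- matrix(tab, G, G, byrow = TRUE)  # idx encodes (row i, col j)
  }
  empty <- sum(M) == 0
  if (normalise && !empty) M <- M / sum(M)
  structure(list(kind = "cooccurrence", matrix = M, G = G, offset = offset,
                 mode = mode, normalised = normalise && !empty, empty = empty),
            class = "texture_matrix")
}

# --- run-length engine ------------------------------------------------------

# Enumerate maximal runs of equal level along direction `d`. Runs truncate
# at mask boundaries/gaps. Returns data.frame(level, length, slice) where
# `slice` is meaningful for in-plane directions.
run_lengths <- function(lev, d) {
  idx <- which(lev > 0L)
  if (!length(idx))
    return(data.frame(level = integer(), length = integer(), slice = integer()))
  nd <- dim(lev)
  co <- arrayInd(idx, nd)
  v <- lev[idx]
  a <- which(d != 0)[1]            # leading axis (component +1 by convention)
  k <- co[, a]
  lk <- co - outer(k, d)           # line anchor (constant along the line)
  ord <- order(lk[, 1], lk[, 2], lk[, 3], k)
  k <- k[ord]; v <- v[ord]; lk <- lk[ord, , drop = FALSE]; co <- co[ord, , drop = FALSE]
  n <- length(k)
  if (n == 1L) {
    new_run <- TRUE
  } else {
    same_line <- lk[-1, 1] == lk[-n, 1] & lk[-1, 2] == lk[-n, 2] &
      lk[-1, 3] == lk[-n, 3]
    contig <- diff(k) == 1L
    same_lev <- v[-1] == v[-n]
    new_run <- c(TRUE, !(same_line & contig & same_lev))
  }
  run_id <- cumsum(new_run)
  data.frame(level = v[new_run],
             length = tabulate(run_id),
             slice = co[new_run, 3])
}

# --- size-zone engine -------------------------------------------------------

# Connected components of equal level: 26-connectivity in 3D, 8-connectivity
# within slices in 2D (zones never cross slices). Returns
# data.frame(level, size).
size_zones <- function(lev, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  dirs <- if (mode == "3D") DIRS3 else DIRS2
  idx <- which(lev > 0L)
  if (!length(idx)) return(data.frame(level = integer(), size = integer()))
  nd <- dim(lev)
  vid <- array(0L, nd)
  vid[idx] <- seq_along(idx)
  edges <- list()
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    xa <- offset_range(nd[1], d[1])
    ya <- offset_range(nd[2], d[2])
    za <- offset_range(nd[3], d[3])
    if (!length(xa) || !length(ya) || !length(za)) next
    A <- lev[xa, ya, za, drop = FALSE]
    B <- lev[xa + d[1], ya + d[2], za + d[3], drop = FALSE]
    keep <- A > 0L & B > 0L & A == B
    if (!any(keep)) next
    IA <- vid[xa, ya, za, drop = FALSE][keep]
    IB <- vid[xa + d[1], ya + d[2], za + d[3], drop = FALSE][keep]
    edges[[length(edges) + 1L]] <- rbind(IA, IB)
  }
  n <- length(idx)
  if (length(edges)) {
    ev <- as.vector(do.call(cbind, edges))
    g <- igraph::make_graph(edges = ev, n = n, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
  }
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  # level of each zone = level of its first member voxel
  first <- match(seq_len(comp$no), comp$membership)
  data.frame(level = lev[idx][first], size = sizes)
}
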