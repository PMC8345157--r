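# Independent brute-force oracles. Deliberately naive: plain loops and
# recursion, no sharing with the package implementations.

# Euclidean dilation: voxel included iff within radius_mm of any mask voxel.
o_dilate <- function(mask, radius_mm, spacing_mm) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    dist2 <- ((x - src[, 1]) * spacing_mm[1])^2 +
             ((y - src[, 2]) * spacing_mm[2])^2 +
             ((z - src[, 3]) * spacing_mm[3])^2
    if (any(dist2 <= radius_mm^2 + 1e-9)) out[x, y, z] <- TRUE
  }
  out
}

# Symmetrised co-occurrence counts for one offset over a level array
# (0 = outside mask). Dense G x G.
o_glcm <- function(lev, d, G) {
  M <- matrix(0, G, G)
  nd <- dim(lev)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
    if (xx < 1 || xx > nd[1] || yy < 1 || yy > nd[2] || zz < 1 || zz > nd[3]) next
    j <- lev[xx, yy, zz]
    if (j == 0) next
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  M
}

# Maximal runs of equal level along direction d: data.frame(level, length),
# sorted for comparability.
o_runs <- function(lev, d) {
  nd <- dim(lev)
  inb <- function(p) all(p >= 1) && all(p <= nd)
  res <- list()
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    p <- c(x, y, z)
    v <- lev[x, y, z]
    if (v == 0) next
    prev <- p - d
    if (inb(prev) && lev[prev[1], prev[2], prev[3]] == v) next  # not a run start
    len <- 1
    q <- p + d
    while (inb(q) && lev[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + d
    }
    res[[length(res) + 1L]] <- c(v, len)
  }
  if (!length(res)) return(data.frame(level = integer(), length = integer()))
  m <- do.call(rbind, res)
  df <- data.frame(level = m[, 1], length = m[, 2])
  df[order(df$level, df$length), , drop = FALSE]
}

# Connected zones of equal level by recursive flood fill.
# conn: matrix of neighbour offsets (symmetric closure applied here).
o_zones <- function(lev, conn) {
  conn <- rbind(conn, -conn)
  nd <- dim(lev)
  seen <- array(FALSE, nd)
  zones <- list()
  inb <- function(p) all(p >= 1) && all(p <= nd)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    v <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(conn))) {
        q <- p + conn[k, ]
        if (inb(q) && !seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == v) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(v, size)
  }
  if (!length(zones)) return(data.frame(level = integer(), size = integer()))
  m <- do.call(rbind, zones)
  df <- data.frame(level = m[, 1], size = m[, 2])
  df[order(df$level, df$size), , drop = FALSE]
}

# Point-in-polygon by counting proper segment intersections of the ray from
# the point to a far external point (with a tie-avoiding slope).
o_pip <- function(px, py, vx, vy) {
  far <- c(max(vx) + 17.03, max(vy) + 23.11)
  n <- length(vx)
  cross <- 0
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (seg_int(c(px, py), far, c(vx[i], vy[i]), c(vx[j], vy[j])))
      cross <- cross + 1
  }
  cross %% 2 == 1
}

# Build a discretised_roi directly from an integer level array (0 = outside).
fake_disc <- function(lev, G = max(lev)) {
  lev <- array(as.integer(lev), dim(lev))
  structure(list(levels = lev, mask = lev > 0L, G = as.integer(G),
                 level_width_Gy = 1, reference_max_Gy = G,
                 range_mode = "roi_max", roi_name = "test"),
            class = "discretised_roi")
}

# Random masked level array for property tests.
random_level_array <- function(dims, G = 4, p_mask = 0.7) {
  lev <- array(0L, dims)
  n <- prod(dims)
  sel <- stats::runif(n) < p_mask
  lev[sel] <- sample.int(G, sum(sel), replace = TRUE)
  lev
}
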