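# Independent oracles: deliberately simple, brute-force implementations
# used only to check the package's fast paths.

# Distance-to-segment rasterization over every voxel (no bounding boxes).
brute_rasterize <- function(segments, volume_shape, voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  grid <- as.matrix(expand.grid(
    z = (seq_len(volume_shape[1]) - 0.5) * voxel_size[1],
    y = (seq_len(volume_shape[2]) - 0.5) * voxel_size[2],
    x = (seq_len(volume_shape[3]) - 0.5) * voxel_size[3]))
  fg <- rep(FALSE, nrow(grid))
  for (s in segments) {
    cl <- s$centerline
    for (i in seq_len(nrow(cl) - 1L)) {
      a <- cl[i, ]; b <- cl[i + 1L, ]
      d <- b - a
      len2 <- sum(d^2)
      ap <- sweep(grid, 2, a)
      tt <- if (len2 > 0) pmin(pmax(ap %*% d / len2, 0), 1) else 0
      e <- ap - tt %*% t(d)
      fg <- fg | (rowSums(e^2) <= s$radius^2)
    }
  }
  array(fg, volume_shape)
}

# Pure-R flood fill connected-component labeling.
flood_fill_labels <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  if (connectivity == 6L) offsets <- offsets[rowSums(abs(offsets)) == 1, ]
  labels <- array(0L, dims)
  nxt <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, dims)
      for (o in seq_len(nrow(offsets))) {
        nb <- co + offsets[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        ni <- nb[1] + dims[1] * ((nb[2] - 1) + dims[2] * (nb[3] - 1))
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
    }
  }
  labels
}

# Exhaustive rank-permutation two-sided p for the Mann-Whitney statistic
# (number of (a_i, b_j) pairs with a_i > b_j), tie-free data only.
mw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">"))
  }
  obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  p_lo <- mean(us <= obs)
  p_hi <- mean(us >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exhaustive between-class-variance threshold over the upper edges of a
# small fixed-bin histogram.
otsu_brute <- function(x, levels) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  best <- -Inf; best_thr <- br[2]
  for (k in seq_len(levels - 1L)) {
    thr <- br[k + 1L]
    lo <- x[x < thr]; hi <- x[x >= thr]
    if (!length(lo) || !length(hi)) next
    # class means on bin midpoints, as the histogram method sees them
    mid <- (br[-1] + br[-(levels + 1L)]) / 2
    bin <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), levels)
    xm <- mid[bin]
    lo_m <- xm[bin <= k]; hi_m <- xm[bin > k]
    if (!length(lo_m) || !length(hi_m)) next
    v <- length(lo_m) * length(hi_m) * (mean(lo_m) - mean(hi_m))^2
    if (v > best) { best <- v; best_thr <- thr }
  }
  best_thr
}

# One straight segment helper.
make_segment <- function(p0, p1, radius,
                         caliber_class = "capillary_venule") {
  list(centerline = rbind(p0, p1), radius = radius,
       caliber_class = caliber_class)
}

# Small, fast Doppler truth for unit tests.
quick_truth <- function(nz = 8, nx = 8, n_frames = 64, cbv = 0.5, ...) {
  doppler_truth(matrix(cbv, nz, nx), n_frames = n_frames, ...)
}
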