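# 3D vessel-stack quantification: automatic thresholding, connected
# component volumetry, vessel volume fraction, volume quartiles.

#' Automatic threshold by between-class variance maximization
#'
#' Otsu's method on a fixed-bin histogram of the full 3D stack: the
#' threshold is the histogram cut maximizing the between-class variance of
#' the two resulting intensity classes.
#'
#' @param x numeric array or vector of intensities (non-constant).
#' @param levels number of histogram bins.
#' @return the threshold intensity; voxels with intensity `>=` threshold
#'   are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    stop("cannot threshold a constant stack: no separable classes")
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- as.numeric(tabulate(
    pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), levels),
    nbins = levels))
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  w <- cumsum(counts)                 # class-0 count up to bin k
  s <- cumsum(counts * mids)          # class-0 intensity sum up to bin k
  n <- w[levels]
  stot <- s[levels]
  w0 <- w[-levels]
  s0 <- s[-levels]
  valid <- w0 > 0 & w0 < n
  sigma_b <- rep(-Inf, levels - 1L)
  m0 <- s0[valid] / w0[valid]
  m1 <- (stot - s0[valid]) / (n - w0[valid])
  sigma_b[valid] <- w0[valid] * (n - w0[valid]) * (m0 - m1)^2
  k <- which.max(sigma_b)
  br[k + 1L]   # upper edge of bin k: foreground is the upper class
}

#' Binarize a confocal stack with the automatic threshold
#'
#' @param stack a `confocal_stack` or a numeric 3D array.
#' @param invert analyze inverted contrast (dark vessels on bright
#'   background); the resulting mask matches the non-inverted convention.
#' @param levels histogram bins for [otsu_threshold()].
#' @return object of class `binary_volume`: list with `mask` (logical 3D
#'   array), `voxel_size`, `threshold_used`, `source`.
#' @export
binarize <- function(stack, invert = FALSE, levels = 256L) {
  if (inherits(stack, "confocal_stack")) {
    x <- stack$intensity
    vox <- stack$voxel_size
    src <- "confocal_stack"
  } else {
    x <- stack
    vox <- attr(stack, "voxel_size")
    if (is.null(vox)) vox <- c(1, 1, 1)
    src <- "array"
  }
  stopifnot(length(dim(x)) == 3L)
  if (invert) x <- max(x) + min(x) - x
  thr <- otsu_threshold(x, levels = levels)
  structure(list(mask = x >= thr, voxel_size = vox,
                 threshold_used = thr, source = src),
            class = "binary_volume")
}

#' Concatenate two consecutive section stacks along the axial dimension
#'
#' Two consecutive brain-slice stacks are merged to form a thickness
#' comparable to one power-Doppler imaging plane. In-plane shapes and
#' voxel sizes must match; total volume is additive.
#'
#' @param a,b two `confocal_stack`s, two `binary_volume`s, or two numeric
#'   3D arrays.
#' @return the merged object of the same kind.
#' @export
merge_consecutive_slices <- function(a, b) {
  get3 <- function(o) {
    if (inherits(o, "confocal_stack")) o$intensity
    else if (inherits(o, "binary_volume")) o$mask
    else o
  }
  xa <- get3(a); xb <- get3(b)
  stopifnot(length(dim(xa)) == 3L, length(dim(xb)) == 3L)
  if (!identical(dim(xa)[2:3], dim(xb)[2:3]))
    stop("in-plane shapes differ; cannot merge slices")
  vsa <- if (is.list(a)) a$voxel_size else NULL
  vsb <- if (is.list(b)) b$voxel_size else NULL
  if (!is.null(vsa) && !is.null(vsb) && !isTRUE(all.equal(vsa, vsb)))
    stop("voxel sizes differ; cannot merge slices")
  da <- dim(xa); db <- dim(xb)
  merged <- array(vector(typeof(xa), 1L), c(da[1] + db[1], da[2], da[3]))
  merged[seq_len(da[1]), , ] <- xa
  merged[da[1] + seq_len(db[1]), , ] <- xb
  if (inherits(a, "confocal_stack")) {
    out <- a
    out$intensity <- merged
    out$truth <- NULL    # truths of individual slices no longer apply
    out
  } else if (inherits(a, "binary_volume")) {
    out <- a
    out$mask <- merged
    out
  } else {
    merged
  }
}

#' Label connected vessel components in a 3D binary volume
#'
#' Foreground voxels are grouped into connected components
#' (26-connectivity by default, 6 selectable) and summarized per object:
#' voxel count, physical volume, bounding box. The total voxel count of
#' the analyzed section (the ROI if given, the whole volume otherwise) is
#' stored for normalization.
#'
#' @param volume a `binary_volume` (or logical 3D array).
#' @param connectivity 26 (default) or 6.
#' @param min_size drop objects with fewer voxels (default 0, keep all).
#' @param roi optional logical 3D array restricting the analyzed section;
#'   the mask is intersected with it and the section volume is its voxel
#'   count.
#' @return a data.frame of class `vessel_object_table`: columns `id`,
#'   `voxel_count`, `volume_um3` and bounding-box columns; attributes
#'   `total_volume_voxels`, `voxel_size`, `connectivity`.
#' @export
label_components_3d <- function(volume, connectivity = 26L, min_size = 0L,
                                roi = NULL) {
  if (inherits(volume, "binary_volume")) {
    mask <- volume$mask
    vox <- volume$voxel_size
  } else {
    mask <- volume
    vox <- attr(volume, "voxel_size")
    if (is.null(vox)) vox <- c(1, 1, 1)
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  total <- length(mask)
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(mask)))
    mask <- mask & roi
    total <- sum(roi)
  }
  dims <- dim(mask)
  labels <- label_components3d_cpp(as.logical(mask), as.integer(dims),
                                   as.integer(connectivity))
  counts <- tabulate(labels)
  keep <- which(counts >= max(min_size, 1L))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  sel <- lab %in% keep
  idx <- idx[sel]; lab <- lab[sel]
  new_id <- match(lab, keep)
  if (length(keep)) {
    co <- arrayInd(idx, dims)
    agg <- function(f, col) vapply(seq_along(keep), function(k)
      f(co[new_id == k, col]), numeric(1))
    tab <- data.frame(
      id = seq_along(keep),
      voxel_count = counts[keep],
      volume_um3 = counts[keep] * prod(vox),
      z_min = agg(min, 1), z_max = agg(max, 1),
      y_min = agg(min, 2), y_max = agg(max, 2),
      x_min = agg(min, 3), x_max = agg(max, 3))
  } else {
    tab <- data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0),
                      z_min = numeric(0), z_max = numeric(0),
                      y_min = numeric(0), y_max = numeric(0),
                      x_min = numeric(0), x_max = numeric(0))
  }
  attr(tab, "total_volume_voxels") <- total
  attr(tab, "voxel_size") <- vox
  attr(tab, "connectivity") <- as.integer(connectivity)
  attr(tab, "label_array") <- array(match(labels, keep), dims)
  class(tab) <- c("vessel_object_table", "data.frame")
  tab
}

#' Vessel volume fraction (percent)
#'
#' `VVF = 100 * vessel volume / total section volume`, computed on voxel
#' counts.
#'
#' @param table a [label_components_3d()] result.
#' @return percent in `[0, 100]`.
#' @export
compute_vvf <- function(table) {
  total <- attr(table, "total_volume_voxels")
  if (is.null(total) || total <= 0) stop("total section volume must be positive")
  100 * sum(table$voxel_count) / total
}

#' Partition vessel objects into volume quartiles
#'
#' Objects are sorted by decreasing volume (ties by ascending id) and
#' assigned greedily: each object joins the current quartile until that
#' quartile's cumulative volume first reaches 25% of the total vessel
#' volume, after which assignment advances; Q4 takes the remainder. With
#' discrete objects the 25% rule cannot be exact in general -- each
#' quartile's share is within one object's volume of 25% -- but with many
#' equal-volume objects it is exact. Q1 therefore collects the largest
#' vessels (large arteries and veins) down to Q4, the capillary-scale
#' objects.
#'
#' @param table a non-empty [label_components_3d()] result.
#' @return object of class `vvf_result`: list with `assignment`
#'   (data.frame `id`, `quartile`), `vvf_total`, `vvf_per_quartile`
#'   (percent of section volume, sums to `vvf_total`), `volume_share`
#'   (percent of total vessel volume per quartile), `n_objects` per
#'   quartile.
#' @export
volume_quartile_partition <- function(table) {
  if (nrow(table) == 0L) stop("empty object table: nothing to partition")
  ord <- order(-table$voxel_count, table$id)
  vc <- as.numeric(table$voxel_count[ord])
  total_v <- sum(vc)
  cum <- cumsum(vc)
  q <- integer(length(vc))
  cur <- 1L
  eps <- 1e-9 * total_v
  for (i in seq_along(vc)) {
    q[i] <- cur
    if (cur < 4L && cum[i] >= cur * total_v / 4 - eps) cur <- cur + 1L
  }
  assignment <- data.frame(id = table$id[ord], quartile = paste0("Q", q))
  assignment <- assignment[order(assignment$id), ]
  rownames(assignment) <- NULL
  total_section <- attr(table, "total_volume_voxels")
  qvol <- vapply(1:4, function(k) sum(vc[q == k]), numeric(1))
  structure(
    list(assignment = assignment,
         vvf_total = 100 * total_v / total_section,
         vvf_per_quartile = stats::setNames(100 * qvol / total_section,
                                            paste0("Q", 1:4)),
         volume_share = stats::setNames(100 * qvol / total_v,
                                        paste0("Q", 1:4)),
         n_objects = stats::setNames(vapply(1:4, function(k) sum(q == k),
                                            integer(1)),
                                     paste0("Q", 1:4))),
    class = "vvf_result")
}

#' @export
print.vvf_result <- function(x, ...) {
  cat(sprintf("<vvf_result> total VVF = %.3f%%\n", x$vvf_total))
  print(data.frame(quartile = paste0("Q", 1:4),
                   vvf_percent = unname(x$vvf_per_quartile),
                   volume_share = unname(x$volume_share),
                   n_objects = unname(x$n_objects)), row.names = FALSE)
  invisible(x)
}

#' Normalized vessel count (objects per cubic millimeter)
#'
#' The number of labeled vessel objects divided by the physical volume of
#' the analyzed section.
#'
#' @param table a [label_components_3d()] result.
#' @return objects per mm^3.
#' @export
normalized_vessel_count <- function(table) {
  total <- attr(table, "total_volume_voxels")
  vox <- attr(table, "voxel_size")
  if (is.null(total) || total <= 0) stop("total section volume must be positive")
  mm3 <- total * prod(vox) / 1e9
  nrow(table) / mm3
}
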