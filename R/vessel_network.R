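# Synthetic 3D vascular networks with known ground truth.

#' Caliber classes, largest to smallest
#'
#' The four vessel caliber classes used throughout the package, ordered by
#' decreasing size: large arteries and veins, smaller arteries and veins,
#' arterioles (and venules), capillaries and venules. They correspond to
#' the quartiles Q1-Q4 of the volume- and intensity-based partitions.
#' @export
caliber_classes <- function() {
  c("large_artery_vein", "small_artery_vein", "arteriole", "capillary_venule")
}

#' Default vessel radius band per caliber class (micrometers)
#'
#' The literature this package serves does not fix numeric diameter ranges
#' for the four caliber classes; these bands are package defaults chosen to
#' give four well-separated volume scales in murine cortex/hippocampus
#' (large vessels 15-30 um radius down to capillaries 1.5-4 um). Override
#' them freely in [generate_vessel_network()].
#' @return named list of `c(min, max)` radii in micrometers.
#' @export
default_radius_bands <- function() {
  list(
    large_artery_vein = c(15, 30),
    small_artery_vein = c(8, 15),
    arteriole         = c(4, 8),
    capillary_venule  = c(1.5, 4)
  )
}

#' Default segment counts per caliber class
#'
#' Counts scale roughly with the inverse squared radius so each class
#' contributes a comparable total vessel volume.
#' @return named integer vector.
#' @export
default_segment_counts <- function() {
  c(large_artery_vein = 1L, small_artery_vein = 4L,
    arteriole = 14L, capillary_venule = 64L)
}

#' Generate a synthetic 3D vascular network with ground truth
#'
#' Vessels are straight tubular segments (with optional single branches)
#' of four caliber classes, randomly placed and oriented inside a voxel
#' volume, then rasterized: a voxel is foreground iff its center lies
#' within the segment radius of a centerline. The result carries both the
#' geometric segments and the rasterized binary mask, so downstream
#' volumetry can be checked by parameter recovery.
#'
#' @param segment_counts named integer vector, segments per caliber class
#'   (see [default_segment_counts()]). Classes with count 0 may be omitted.
#' @param radius_bands named list of `c(min, max)` radii in micrometers per
#'   class; bands must be positive and non-overlapping in decreasing class
#'   order (see [default_radius_bands()]).
#' @param volume_shape integer vector `c(nz, ny, nx)`, volume size in voxels.
#' @param voxel_size numeric length 1 or 3, micrometers per voxel (z, y, x).
#' @param length_range segment length range in micrometers.
#' @param branch_prob probability that a segment sprouts one branch of the
#'   same caliber class.
#' @param seed integer seed; identical seed and configuration give an
#'   identical network.
#' @return an object of class `vessel_network`: list with `segments`
#'   (list of centerline matrix in um, radius, caliber_class), `mask`
#'   (logical 3D array), `n_vessel_voxels`, `volume_shape`, `voxel_size`.
#' @export
generate_vessel_network <- function(segment_counts = default_segment_counts(),
                                    radius_bands = default_radius_bands(),
                                    volume_shape = c(64L, 128L, 128L),
                                    voxel_size = c(2, 2, 2),
                                    length_range = c(40, 160),
                                    branch_prob = 0.2,
                                    seed = NULL) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(length_range) == 2L, all(length_range > 0),
            branch_prob >= 0, branch_prob <= 1)
  classes <- names(segment_counts)
  if (is.null(classes) || !all(classes %in% caliber_classes()))
    stop("segment_counts must be named by caliber class")
  bands <- radius_bands[classes]
  if (any(vapply(bands, is.null, logical(1))))
    stop("radius_bands must cover every class in segment_counts")
  for (b in bands) {
    if (length(b) != 2L || any(b <= 0) || b[1] > b[2])
      stop("each radius band must be positive c(min, max)")
  }
  ord <- match(classes, caliber_classes())
  bo <- bands[order(ord)]
  if (length(bo) > 1L) {
    for (i in seq_len(length(bo) - 1L)) {
      if (bo[[i]][1] < bo[[i + 1]][2])
        stop("radius bands must be non-overlapping in decreasing class order")
    }
  }
  extent <- volume_shape * voxel_size
  rmax <- max(vapply(bands, max, numeric(1)))
  if (any(extent < 2 * rmax))
    stop("volume too small to contain the largest vessel radius (",
         rmax, " um); enlarge volume_shape or shrink the bands")

  segments <- with_seed(seed, {
    segs <- list()
    for (cl in classes) {
      n <- segment_counts[[cl]]
      if (n == 0) next
      band <- bands[[cl]]
      for (i in seq_len(n)) {
        r <- runif(1, band[1], band[2])
        p0 <- vapply(1:3, function(a)
          runif(1, min(r, extent[a] / 2), extent[a] - min(r, extent[a] / 2)),
          numeric(1))
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        len <- runif(1, length_range[1], length_range[2])
        p1 <- clip_to_box(p0, p0 + len * dir, extent)
        segs[[length(segs) + 1L]] <-
          list(centerline = rbind(p0, p1), radius = r, caliber_class = cl)
        if (runif(1) < branch_prob) {
          u <- runif(1, 0.3, 0.7)
          b0 <- p0 + u * (p1 - p0)
          bd <- dir + 0.8 * rnorm(3)
          bd <- bd / sqrt(sum(bd^2))
          br <- max(band[1], min(band[2], r * runif(1, 0.7, 1)))
          b1 <- clip_to_box(b0, b0 + 0.6 * len * bd, extent)
          segs[[length(segs) + 1L]] <-
            list(centerline = rbind(b0, b1), radius = br, caliber_class = cl)
        }
      }
    }
    segs
  })

  mask <- rasterize_segments(segments, volume_shape, voxel_size)
  structure(
    list(segments = segments, mask = mask,
         n_vessel_voxels = sum(mask),
         volume_shape = as.integer(volume_shape), voxel_size = voxel_size),
    class = "vessel_network")
}

# Shrink the segment p0 -> p1 so the endpoint stays inside [0, extent].
clip_to_box <- function(p0, p1, extent) {
  d <- p1 - p0
  tmax <- 1
  for (a in 1:3) {
    if (d[a] > 0) tmax <- min(tmax, (extent[a] - p0[a]) / d[a])
    else if (d[a] < 0) tmax <- min(tmax, -p0[a] / d[a])
  }
  p0 + max(tmax, 0) * d
}

# Rasterize a list of segments (centerline polylines in um) into a logical
# 3D array; foreground iff the voxel center is within `radius` of any
# centerline piece.
rasterize_segments <- function(segments, volume_shape, voxel_size) {
  dims <- as.integer(volume_shape)
  if (length(segments) == 0L) {
    return(array(FALSE, dims))
  }
  p0 <- list(); p1 <- list(); rr <- numeric(0)
  for (s in segments) {
    cl <- s$centerline
    stopifnot(is.matrix(cl), nrow(cl) >= 2L, ncol(cl) == 3L, s$radius > 0)
    for (i in seq_len(nrow(cl) - 1L)) {
      p0[[length(p0) + 1L]] <- cl[i, ]
      p1[[length(p1) + 1L]] <- cl[i + 1L, ]
      rr <- c(rr, s$radius)
    }
  }
  v <- raster_segments_cpp(do.call(rbind, p0), do.call(rbind, p1),
                           rr, dims, as.numeric(voxel_size))
  array(v, dims)
}

#' @export
print.vessel_network <- function(x, ...) {
  cls <- vapply(x$segments, `[[`, character(1), "caliber_class")
  cat("<vessel_network> ", paste(x$volume_shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size, collapse = "/"), " um\n", sep = "")
  cat("  segments:", length(x$segments),
      "| vessel voxels:", x$n_vessel_voxels,
      sprintf("(%.2f%%)", 100 * x$n_vessel_voxels / prod(x$volume_shape)), "\n")
  if (length(cls)) print(table(factor(cls, levels = caliber_classes())))
  invisible(x)
}
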