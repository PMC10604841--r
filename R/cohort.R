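# Simulated two-genotype cohorts: per-animal Doppler planes and confocal
# sections, quantified through the full analysis path.

#' Default ROI masks for a simulated coronal Doppler plane
#'
#' A deep elliptical "hippocampus", a shallow "cortex" band, and their
#' union (`section`), used as the dB reference for quantification.
#'
#' @param plane_shape `c(nz, nx)` plane size in pixels.
#' @return named list of logical matrices.
#' @export
default_plane_rois <- function(plane_shape) {
  nz <- plane_shape[1]; nx <- plane_shape[2]
  z <- row(matrix(0, nz, nx)); x <- col(matrix(0, nz, nx))
  hip <- ((z - 0.62 * nz) / (0.18 * nz))^2 +
    ((x - 0.5 * nx) / (0.32 * nx))^2 <= 1
  ctx <- z >= 0.08 * nz & z <= 0.30 * nz
  list(hippocampus = hip, cortex = ctx, section = hip | ctx)
}

# CBV template for one plane: smooth background plus a few bright
# vessel-like spots. The brightest spots sit in the cortex (superficial
# pial vessels), so the section-wide dB reference lies outside the
# hippocampus and regional CBV changes are not self-normalized away.
cbv_template <- function(plane_shape, rois, seed) {
  with_seed(seed, {
    base <- 0.12 + 0.1 * smooth_field2(plane_shape, blur = 2)
    ctx_idx <- which(rois$cortex)
    hip_idx <- which(rois$hippocampus)
    spots_ctx <- ctx_idx[round(seq(1, length(ctx_idx), length.out = 5))]
    spots_hip <- hip_idx[round(seq(2, length(hip_idx), length.out = 4))]
    base[spots_ctx] <- 0.70
    base[spots_hip] <- 0.45
    pmin(pmax(base, 0.02), 0.75)
  })
}

#' Simulate and quantify a two-genotype Doppler cohort
#'
#' For each animal a coronal plane is simulated (shared CBV template with
#' per-animal regional gain variability), the genotype effect multiplies
#' the hippocampal and/or cortical CBV of the mutant group, and the full
#' quantification path runs: SVD clutter filter, power image, dB against
#' the whole-section maximum, intensity quartiles per ROI.
#'
#' @param n_per_group animals per genotype (default 12, the imaging
#'   cohort size).
#' @param plane_shape `c(nz, nx)` pixels.
#' @param cbv_effect named multipliers of mutant CBV per ROI, e.g.
#'   `c(hippocampus = 1.3, cortex = 1)`.
#' @param n_frames,clutter_rank,clutter_amplitude,noise_amplitude passed
#'   to [doppler_truth()].
#' @param cutoff [svd_cutoff()] used for clutter filtering.
#' @param animal_cv lognormal coefficient of variation of each animal's
#'   regional vascular gain.
#' @param seed root seed; every animal draws from a named substream.
#' @return list with `quartiles` (tidy data.frame: `animal_id`,
#'   `genotype`, `modality`, `roi`, `quartile`, `value` = mean dB),
#'   `rois`, and `example` (the last animal's `power_doppler` image, for
#'   display).
#' @export
simulate_doppler_cohort <- function(n_per_group = 12L,
                                    plane_shape = c(24L, 24L),
                                    cbv_effect = c(hippocampus = 1.3,
                                                   cortex = 1),
                                    n_frames = 350L,
                                    clutter_rank = 2L,
                                    clutter_amplitude = 30,
                                    noise_amplitude = 0.1,
                                    cutoff = svd_cutoff(clutter_rank),
                                    animal_cv = 0.1,
                                    seed = NULL) {
  rois <- default_plane_rois(plane_shape)
  template <- cbv_template(plane_shape, rois,
                           substream_seed(seed %||% 0, "cbv_template"))
  rows <- list()
  example <- NULL
  for (g in c("wt", "trj")) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      aseed <- substream_seed(seed %||% 0, paste0("doppler_", id))
      map <- with_seed(aseed, {
        m <- template
        for (r in c("hippocampus", "cortex")) {
          gain <- exp(rnorm(1, 0, animal_cv))
          m[rois[[r]]] <- m[rois[[r]]] * gain
        }
        m
      })
      if (g == "trj") {
        for (r in names(cbv_effect)) {
          m <- rois[[r]]
          if (!is.null(m)) map[m] <- map[m] * cbv_effect[[r]]
        }
      }
      map <- pmin(map, 0.97)
      truth <- doppler_truth(map, clutter_rank = clutter_rank,
                             clutter_amplitude = clutter_amplitude,
                             noise_amplitude = noise_amplitude,
                             n_frames = n_frames)
      ens <- simulate_doppler_ensemble(truth, seed = aseed + 1L)
      filt <- svd_clutter_filter(ens, cutoff)
      pd <- to_db(power_doppler(filt, roi_masks = rois), "section")
      for (r in c("hippocampus", "cortex")) {
        qs <- intensity_quartiles(pd, r)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, genotype = g, modality = "doppler", roi = r,
          quartile = qs$table$quartile, value = qs$table$mean_db,
          stringsAsFactors = FALSE)
      }
      example <- pd
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(quartiles = out, rois = rois, example = example)
}

#' Simulate and quantify a two-genotype confocal cohort
#'
#' For each animal and region, two consecutive synthetic section stacks
#' are rendered and merged (to match the Doppler plane thickness),
#' binarized with the automatic threshold, labeled in 3D, and summarized
#' as per-quartile vessel volume fractions. The mutant effect is a
#' radius multiplier (vessel dilation, not proliferation) applied per
#' region.
#'
#' @param n_per_group animals per genotype (default 4, the confocal
#'   cohort size).
#' @param radius_effect named per-ROI radius multipliers for the mutant
#'   group.
#' @param volume_shape per-slice volume in voxels `c(nz, ny, nx)`.
#' @param segment_counts,voxel_size passed to
#'   [generate_vessel_network()].
#' @param psf_sigma,noise_sd passed to [render_confocal()].
#' @param connectivity,min_size passed to [label_components_3d()].
#' @param seed root seed.
#' @return list with `quartiles` (tidy data.frame with `value` = VVF
#'   percent per quartile), `totals` (per animal/ROI total VVF and
#'   normalized vessel count).
#' @export
simulate_confocal_cohort <- function(n_per_group = 4L,
                                     radius_effect = c(hippocampus = 1.15,
                                                       cortex = 1),
                                     volume_shape = c(12L, 120L, 120L),
                                     segment_counts = c(large_artery_vein = 1L,
                                                        small_artery_vein = 2L,
                                                        arteriole = 8L,
                                                        capillary_venule = 36L),
                                     voxel_size = c(6, 2, 2),
                                     psf_sigma = 1, noise_sd = 5,
                                     connectivity = 26L, min_size = 0L,
                                     seed = NULL) {
  rows <- list(); totals <- list()
  for (g in c("wt", "trj")) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      for (r in names(radius_effect)) {
        bands <- default_radius_bands()
        if (g == "trj") {
          bands <- lapply(bands, function(b) b * radius_effect[[r]])
        }
        slices <- lapply(1:2, function(s) {
          net <- generate_vessel_network(
            segment_counts = segment_counts, radius_bands = bands,
            volume_shape = volume_shape, voxel_size = voxel_size,
            seed = substream_seed(seed %||% 0,
                                  paste("confocal", id, r, s, sep = "_")))
          render_confocal(net, psf_sigma = psf_sigma, noise_sd = noise_sd,
                          seed = substream_seed(seed %||% 0,
                                                paste("render", id, r, s,
                                                      sep = "_")))
        })
        merged <- merge_consecutive_slices(slices[[1]], slices[[2]])
        bv <- binarize(merged)
        tab <- label_components_3d(bv, connectivity = connectivity,
                                   min_size = min_size)
        part <- volume_quartile_partition(tab)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, genotype = g, modality = "confocal", roi = r,
          quartile = paste0("Q", 1:4),
          value = unname(part$vvf_per_quartile), stringsAsFactors = FALSE)
        totals[[length(totals) + 1L]] <- data.frame(
          animal_id = id, genotype = g, roi = r,
          vvf_total = part$vvf_total,
          normalized_count = normalized_vessel_count(tab),
          n_objects = nrow(tab), threshold = bv$threshold_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  q <- do.call(rbind, rows); rownames(q) <- NULL
  tt <- do.call(rbind, totals); rownames(tt) <- NULL
  list(quartiles = q, totals = tt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
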