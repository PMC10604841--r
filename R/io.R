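# File interchange: multi-page TIFF stacks with JSON sidecars, a raw
# binary container for complex frame ensembles, ROI masks, CSV tables.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a confocal stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages scaled to `[0, 1]`;
#' the scale factor, voxel size and generation parameters go to a JSON
#' sidecar (`<path>.json`) so the stack round-trips.
#'
#' @param stack a `confocal_stack`.
#' @param path output TIFF file path.
#' @return `path`, invisibly.
#' @export
write_confocal_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  x <- stack$intensity
  scale <- max(x, 1e-12)
  pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    kind = "synthetic_confocal_stack",
    shape = dim(x), scale = scale, voxel_size_um = stack$voxel_size,
    psf_sigma_um = stack$psf_sigma, noise_sd = stack$noise_sd,
    truth = if (!is.null(stack$truth)) list(
      n_vessel_voxels = stack$truth$n_vessel_voxels,
      n_segments = length(stack$truth$segments)))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_confocal_tiff
#' @export
read_confocal_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- array(0, meta$shape)
  for (i in seq_along(pages)) x[i, , ] <- pages[[i]] * meta$scale
  structure(list(intensity = x, voxel_size = meta$voxel_size_um,
                 psf_sigma = meta$psf_sigma_um, noise_sd = meta$noise_sd,
                 truth = NULL),
            class = "confocal_stack")
}

#' Write / read a complex frame ensemble as a raw array container
#'
#' Real and imaginary parts are written as consecutive little-endian
#' float64 blocks; dimensions, frame rate and (for simulated data) the
#' ground-truth CBV map go to a JSON sidecar.
#'
#' @param ensemble a `doppler_ensemble`.
#' @param path output `.bin` file path.
#' @return `path`, invisibly.
#' @export
write_doppler_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "doppler_ensemble"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(Re(ensemble$frames)), con, size = 8,
           endian = "little")
  writeBin(as.numeric(Im(ensemble$frames)), con, size = 8,
           endian = "little")
  tr <- ensemble$truth
  meta <- list(
    kind = "doppler_ensemble", layout = "re_block_then_im_block_float64_le",
    shape = dim(ensemble$frames), frame_rate_hz = ensemble$frame_rate,
    provenance = ensemble$provenance,
    truth = if (!is.null(tr)) list(
      cbv_map = tr$cbv_map, clutter_rank = tr$clutter_rank,
      clutter_amplitude = tr$clutter_amplitude,
      noise_amplitude = tr$noise_amplitude, n_frames = tr$n_frames,
      flow_power = tr$flow_power, seed = tr$seed))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_doppler_ensemble
#' @export
read_doppler_ensemble <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  re <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  im <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- doppler_truth(
      cbv_map = matrix(unlist(meta$truth$cbv_map),
                       nrow = meta$shape[1], ncol = meta$shape[2]),
      clutter_rank = meta$truth$clutter_rank,
      clutter_amplitude = meta$truth$clutter_amplitude,
      noise_amplitude = meta$truth$noise_amplitude,
      n_frames = meta$truth$n_frames,
      flow_power = meta$truth$flow_power,
      seed = meta$truth$seed)
  }
  doppler_ensemble(array(complex(real = re, imaginary = im), meta$shape),
                   frame_rate = meta$frame_rate_hz,
                   provenance = meta$provenance, truth = truth)
}

#' Write / read a named set of 2D ROI masks as single-page TIFFs
#'
#' Each mask goes to `<dir>/<name>.tif` as a 0/1 image.
#'
#' @param masks named list of logical matrices.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_roi_masks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    tiff::writeTIFF(matrix(as.numeric(m), nrow(m), ncol(m)),
                    file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 8L)
  }
  invisible(dir)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(dir) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  masks <- lapply(files, function(f) tiff::readTIFF(f) > 0.5)
  names(masks) <- sub("\\.tif$", "", basename(files))
  masks
}

#' Write a quartile-summary table collection as tidy CSV
#'
#' @param summaries named list (animal id -> named list of ROI ->
#'   `quartile_summary`).
#' @param path output CSV path.
#' @return the tidy data.frame, invisibly.
#' @export
write_quartile_csv <- function(summaries, path) {
  rows <- list()
  for (animal in names(summaries)) {
    for (roi in names(summaries[[animal]])) {
      s <- summaries[[animal]][[roi]]
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animal, roi = roi, quartile = s$table$quartile,
        mean_db = s$table$mean_db, n_pixels = s$table$n_pixels,
        norm_constant = s$norm_constant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
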