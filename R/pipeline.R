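# End-to-end reproducible study run: simulate -> quantify -> compare ->
# report, every intermediate written to disk.

#' Default pipeline configuration
#'
#' One nested list holding every tunable of a study run; serializable to
#' YAML ([write_run_config()]) so a run is fully described by one file.
#' Defaults reproduce the study conditions the package emulates: 12
#' animals per genotype for Doppler and behavior, 4 for confocal, 350
#' frames per Doppler plane, a +30% hippocampal CBV effect and a 15%
#' hippocampal vessel-radius effect in the mutant group, behavioral shifts
#' toward an anxious-like, motor-impaired phenotype.
#'
#' @param seed root seed for the whole run.
#' @param out_dir output directory for every stage.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("vasoquant_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    doppler = list(
      n_per_group = 12L, plane_shape = c(24L, 24L),
      cbv_effect = list(hippocampus = 1.3, cortex = 1),
      n_frames = 350L, clutter_rank = 2L, clutter_amplitude = 30,
      noise_amplitude = 0.1, cut_low = 2L, cut_high = 0L,
      animal_cv = 0.1),
    confocal = list(
      n_per_group = 4L,
      radius_effect = list(hippocampus = 1.15, cortex = 1),
      volume_shape = c(12L, 120L, 120L), voxel_size = c(6, 2, 2),
      segment_counts = list(large_artery_vein = 1L, small_artery_vein = 2L,
                            arteriole = 8L, capillary_venule = 36L),
      psf_sigma = 1, noise_sd = 5, connectivity = 26L, min_size = 0L),
    behavior = list(n_per_group = 12L, zero_shift = FALSE),
    stats = list(alpha = 0.05, alpha_norm = 0.05, welch = FALSE,
                 repeated = TRUE)),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the full pipeline: simulate, quantify, compare, report
#'
#' Executes the whole study on synthetic data: behavioral tables, a
#' Doppler cohort, a confocal cohort, then the gated statistical
#' comparison, writing every intermediate (CSV/JSON) plus a quartile
#' overlay figure to `config$out_dir`. Bit-reproducible for a fixed
#' config: all randomness flows from `config$seed` through named
#' substreams.
#'
#' @param config a [default_run_config()]-style list.
#' @param force overwrite outputs from a previous run in the same
#'   directory.
#' @return object of class `study_report`: list with the tidy tables, the
#'   `study_comparison`, output file paths, and a provenance block
#'   (config hash, seed).
#' @export
run_pipeline <- function(config = default_run_config(), force = FALSE) {
  out <- config$out_dir
  marker <- file.path(out, "comparison_quartiles.csv")
  if (file.exists(marker) && !force)
    stop("output directory already holds a previous run; use force = TRUE")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "run_config.yaml")
  write_run_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  # --- behavior ---------------------------------------------------------
  beh_cfg <- behavior_effect_defaults(zero_shift = isTRUE(config$behavior$zero_shift))
  behavior <- generate_behavior_table(
    beh_cfg, n_per_group = config$behavior$n_per_group,
    seed = substream_seed(config$seed, "behavior"))
  write.csv(behavior, file.path(out, "behavior.csv"), row.names = FALSE)

  # --- doppler ----------------------------------------------------------
  dc <- config$doppler
  dop <- simulate_doppler_cohort(
    n_per_group = dc$n_per_group, plane_shape = unlist(dc$plane_shape),
    cbv_effect = unlist(dc$cbv_effect), n_frames = dc$n_frames,
    clutter_rank = dc$clutter_rank,
    clutter_amplitude = dc$clutter_amplitude,
    noise_amplitude = dc$noise_amplitude,
    cutoff = svd_cutoff(dc$cut_low, dc$cut_high),
    animal_cv = dc$animal_cv,
    seed = substream_seed(config$seed, "doppler"))
  write.csv(dop$quartiles, file.path(out, "doppler_quartiles.csv"),
            row.names = FALSE)

  # --- confocal ---------------------------------------------------------
  cc <- config$confocal
  conf <- simulate_confocal_cohort(
    n_per_group = cc$n_per_group, radius_effect = unlist(cc$radius_effect),
    volume_shape = unlist(cc$volume_shape),
    segment_counts = unlist(cc$segment_counts),
    voxel_size = unlist(cc$voxel_size),
    psf_sigma = cc$psf_sigma, noise_sd = cc$noise_sd,
    connectivity = cc$connectivity, min_size = cc$min_size,
    seed = substream_seed(config$seed, "confocal"))
  write.csv(conf$quartiles, file.path(out, "confocal_quartiles.csv"),
            row.names = FALSE)
  write.csv(conf$totals, file.path(out, "confocal_totals.csv"),
            row.names = FALSE)

  # --- compare ----------------------------------------------------------
  st <- config$stats
  quart <- rbind(dop$quartiles, conf$quartiles)
  comparison <- run_full_comparison(
    endpoints = behavior, quartile_values = quart,
    alpha = st$alpha, welch = isTRUE(st$welch),
    repeated = !isFALSE(st$repeated), alpha_norm = st$alpha_norm)
  write.csv(comparison$endpoint_report,
            file.path(out, "comparison_endpoints.csv"), row.names = FALSE)
  write.csv(comparison$quartile_report, marker, row.names = FALSE)
  write.csv(comparison$block_report,
            file.path(out, "comparison_blocks.csv"), row.names = FALSE)

  # --- report -----------------------------------------------------------
  overlay_path <- file.path(out, "quartile_overlay.png")
  ex <- dop$example
  qs <- intensity_quartiles(ex, "hippocampus")
  render_quartile_overlay(qs$assignment, file = overlay_path,
                          background = ex$db)
  provenance <- list(config_hash = config_hash, seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("vasoquant")))
  jsonlite::write_json(
    list(provenance = provenance,
         decisions = list(
           doppler_cutoff = list(low = dc$cut_low, high = dc$cut_high),
           confocal_threshold = "otsu",
           connectivity = cc$connectivity)),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  structure(list(behavior = behavior, doppler = dop$quartiles,
                 confocal = conf$quartiles, comparison = comparison,
                 out_dir = out, provenance = provenance),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed =", x$provenance$seed,
      "| hash =", substr(x$provenance$config_hash, 1, 8), "\n")
  cat("outputs in:", x$out_dir, "\n\n")
  print(x$comparison)
  invisible(x)
}
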