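# Synthetic behavioral score tables for two genotypes (wild type vs
# Trembler-J-like), with configurable per-endpoint effects.

#' Default behavioral endpoint catalogue and genotype effects
#'
#' One row per endpoint of the open-field, elevated-plus-maze and rotarod
#' assays: counts (entries, rearing, defecation, freezing/grooming
#' frequency, head shakes) and durations (freezing/grooming time, rotarod
#' permanence). `wt_mean` is the wild-type mean; `trj_shift` is the
#' additive shift of the mutant mean, signed in the direction of an
#' anxious-like, motor-impaired phenotype (fewer entries and rearing, more
#' freezing/grooming/defecation, shorter rotarod permanence). Counts are
#' drawn from a negative binomial (overdispersion typical of behavioral
#' counts), durations from a gamma.
#'
#' @param zero_shift if `TRUE`, all genotype shifts are set to 0 (null
#'   configuration for calibration experiments).
#' @return data.frame with columns `endpoint`, `family` (`"count"` or
#'   `"time"`), `wt_mean`, `trj_shift`, `dispersion`.
#' @export
behavior_effect_defaults <- function(zero_shift = FALSE) {
  cfg <- data.frame(
    endpoint = c("closed_arm_entries", "total_entries", "rearing",
                 "defecation", "freezing_freq", "freezing_time",
                 "grooming_freq", "grooming_time", "head_shakes",
                 "rotarod_time"),
    family = c("count", "count", "count", "count", "count", "time",
               "count", "time", "count", "time"),
    wt_mean = c(12, 18, 20, 2, 4, 30, 5, 25, 3, 120),
    trj_shift = c(-4, -6, -8, 3, 6, 40, 3, 15, 3, -50),
    dispersion = 5,
    stringsAsFactors = FALSE)
  if (zero_shift) cfg$trj_shift <- 0
  cfg
}

#' Generate a synthetic per-animal behavioral score table
#'
#' @param effect_config endpoint catalogue as returned by
#'   [behavior_effect_defaults()]; `dispersion` is the negative-binomial
#'   size for counts and the gamma shape for durations.
#' @param n_per_group animals per genotype (default 12, the behavioral
#'   cohort size).
#' @param seed integer seed; same seed and configuration give the same
#'   table.
#' @return data.frame with columns `animal_id`, `genotype` (`"wt"` /
#'   `"trj"`), `endpoint`, `value` in long format.
#' @export
generate_behavior_table <- function(effect_config = behavior_effect_defaults(),
                                    n_per_group = 12L, seed = NULL) {
  stopifnot(is.data.frame(effect_config),
            all(c("endpoint", "family", "wt_mean", "trj_shift",
                  "dispersion") %in% names(effect_config)))
  if (n_per_group < 3L) stop("n_per_group must be at least 3")
  if (any(effect_config$dispersion <= 0))
    stop("dispersion must be positive")
  if (any(effect_config$wt_mean <= 0))
    stop("wild-type means must be positive")
  if (anyDuplicated(effect_config$endpoint))
    stop("duplicated endpoint in effect_config")

  with_seed(seed, {
    rows <- list()
    for (g in c("wt", "trj")) {
      ids <- sprintf("%s_%02d", g, seq_len(n_per_group))
      for (i in seq_len(nrow(effect_config))) {
        e <- effect_config[i, ]
        mu <- e$wt_mean + if (g == "trj") e$trj_shift else 0
        mu <- max(mu, 0.2)   # keep a valid positive mean
        v <- switch(e$family,
          count = rnbinom(n_per_group, size = e$dispersion, mu = mu),
          time  = rgamma(n_per_group, shape = e$dispersion,
                         rate = e$dispersion / mu),
          stop("unknown endpoint family: ", e$family))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = ids, genotype = g, endpoint = e$endpoint,
          value = as.numeric(v), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
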