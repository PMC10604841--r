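# Power-Doppler image formation (SVD clutter filtering, power averaging,
# dB referencing) and ROI intensity-quartile quantification.

#' SVD clutter-filter cutoff
#'
#' @param low number of largest singular components removed (tissue
#'   clutter).
#' @param high number of smallest singular components removed (noise
#'   side); 0 by default since only clutter removal is required.
#' @export
svd_cutoff <- function(low, high = 0L) {
  low <- as.integer(low); high <- as.integer(high)
  if (low < 0L || high < 0L) stop("cutoffs must be non-negative")
  structure(list(low = low, high = high), class = "svd_cutoff")
}

#' Remove tissue clutter from a frame ensemble by SVD
#'
#' The ensemble is reshaped to its space-by-time Casorati matrix, a
#' singular value decomposition is computed, the `low` largest (and
#' optionally `high` smallest) singular components are zeroed, and the
#' ensemble is reconstructed. Slow, high-amplitude tissue motion
#' concentrates in the first singular components, so removing them leaves
#' the fast-decorrelating blood signal.
#'
#' @param ensemble a `doppler_ensemble`.
#' @param cutoff an [svd_cutoff()]; `cutoff$low + cutoff$high` must be
#'   below the number of frames.
#' @return the filtered `doppler_ensemble`; the singular values of the
#'   Casorati matrix are attached as attribute `"singular_values"`.
#' @export
svd_clutter_filter <- function(ensemble, cutoff) {
  stopifnot(inherits(ensemble, "doppler_ensemble"),
            inherits(cutoff, "svd_cutoff"))
  d <- dim(ensemble$frames)
  nt <- d[3]
  if (cutoff$low + cutoff$high >= nt)
    stop("cutoff.low + cutoff.high must be below the number of frames (",
         nt, ")")
  X <- matrix(ensemble$frames, prod(d[1:2]), nt)
  sv <- svd(X)
  rm_idx <- integer(0)
  if (cutoff$low > 0) rm_idx <- c(rm_idx, seq_len(cutoff$low))
  if (cutoff$high > 0) {
    r <- length(sv$d)
    rm_idx <- c(rm_idx, seq(r - cutoff$high + 1L, r))
  }
  if (length(rm_idx) > 0) {
    U <- sv$u[, rm_idx, drop = FALSE]
    V <- sv$v[, rm_idx, drop = FALSE]
    X <- X - U %*% (sv$d[rm_idx] * t(Conj(V)))
  }
  out <- ensemble
  out$frames <- array(X, d)
  attr(out, "singular_values") <- sv$d
  attr(out, "cutoff") <- cutoff
  out
}

#' Select an SVD cutoff among candidates
#'
#' With ground truth available (a simulated ensemble carrying its CBV
#' map), candidates are scored by the Pearson correlation between the
#' post-filter power image and the true CBV map; once the clutter
#' subspace is removed the score plateaus, so among candidates within a
#' small tolerance of the best score the one removing fewest components
#' is returned (parsimony: do not discard blood signal needlessly).
#' Without truth, a singular-value elbow heuristic is used: the candidate
#' whose `low` sits at the largest drop of the log singular-value
#' spectrum.
#'
#' @param ensemble a `doppler_ensemble`.
#' @param candidates list of [svd_cutoff()] objects (at least one).
#' @param truth optional [doppler_truth()]; defaults to the truth carried
#'   by the ensemble, if any.
#' @return the selected [svd_cutoff()].
#' @export
select_cutoff <- function(ensemble, candidates, truth = ensemble$truth) {
  stopifnot(inherits(ensemble, "doppler_ensemble"))
  if (length(candidates) == 0) stop("need at least one candidate cutoff")
  for (c in candidates) stopifnot(inherits(c, "svd_cutoff"))
  if (length(candidates) == 1L) return(candidates[[1L]])

  if (!is.null(truth)) {
    score <- vapply(candidates, function(co) {
      p <- power_doppler(svd_clutter_filter(ensemble, co))$power
      s <- suppressWarnings(cor(as.vector(p), as.vector(truth$cbv_map)))
      if (is.na(s)) -Inf else s
    }, numeric(1))
    near_best <- which(score >= max(score) - 0.005)
    sizes <- vapply(candidates, function(co) co$low + co$high, numeric(1))
    return(candidates[[near_best[which.min(sizes[near_best])]]])
  }

  d <- dim(ensemble$frames)
  X <- matrix(ensemble$frames, prod(d[1:2]), d[3])
  s <- svd(X, nu = 0, nv = 0)$d
  s <- pmax(s, .Machine$double.eps)
  drop <- diff(-log(s))           # drop between consecutive components
  score <- vapply(candidates, function(co) {
    if (co$low < 1 || co$low >= length(s)) return(-Inf)
    drop[co$low]
  }, numeric(1))
  if (all(!is.finite(score))) return(candidates[[1L]])
  candidates[[which.max(score)]]
}

#' Form a power-Doppler image from a (filtered) ensemble
#'
#' The per-pixel power is the temporal mean of the squared modulus of the
#' complex signal; it is proportional to the local cerebral blood volume
#' once clutter has been removed.
#'
#' @param ensemble a `doppler_ensemble` (typically after
#'   [svd_clutter_filter()]).
#' @param roi_masks named list of logical 2D masks (e.g. `hippocampus`,
#'   `cortex`) carried along for referencing and quartile analysis.
#' @return object of class `power_doppler`: list with `power` (linear,
#'   non-negative 2D matrix), `db` (filled by [to_db()]),
#'   `reference_power`, `roi_masks`.
#' @export
power_doppler <- function(ensemble, roi_masks = list()) {
  stopifnot(inherits(ensemble, "doppler_ensemble"))
  d <- dim(ensemble$frames)
  p <- rowMeans(matrix(Mod(ensemble$frames)^2, prod(d[1:2]), d[3]))
  structure(
    list(power = matrix(p, d[1], d[2]), db = NULL,
         reference_power = NULL, roi_masks = roi_masks),
    class = "power_doppler")
}

#' Convert a power image to decibels against an ROI reference
#'
#' The reference (0 dB) power is the maximum power within the designated
#' reference ROI, so `db = 10 log10(power / reference_power)` and the
#' brightest reference pixel maps to 0 dB. The dB map is invariant under
#' global rescaling of the power image.
#'
#' @param image a `power_doppler` object with `roi_masks` set.
#' @param reference_roi name of the reference ROI in `image$roi_masks`.
#' @return the `power_doppler` with `db` and `reference_power` filled.
#' @export
to_db <- function(image, reference_roi) {
  stopifnot(inherits(image, "power_doppler"))
  m <- image$roi_masks[[reference_roi]]
  if (is.null(m)) stop("unknown reference ROI: ", reference_roi)
  if (!any(m)) stop("reference ROI is empty")
  ref <- max(image$power[m])
  if (ref <= 0) stop("degenerate reference: no positive power in ROI '",
                     reference_roi, "'")
  image$reference_power <- ref
  image$db <- 10 * log10(image$power / ref)
  image
}

#' Partition ROI pixels into intensity quartiles
#'
#' ROI pixels are sorted by decreasing dB value and split into four
#' equal-count groups (`"count"` method, the default): Q1 holds the
#' brightest quarter of pixels (largest vessels) down to Q4, the dimmest
#' (capillary-scale signal). Remainder pixels go to the earliest
#' quartiles; ties at boundaries are broken by raster-scan order. The ROI
#' pixel count is stored as the normalization constant, making summaries
#' comparable across animals with different section sizes. An
#' equal-dB-width binning (`"range"`) is available as an alternative.
#'
#' @param image a `power_doppler` with `db` filled (see [to_db()]).
#' @param roi name of the ROI mask to quantify (at least 4 pixels).
#' @param method `"count"` (equal pixel counts, default) or `"range"`
#'   (equal dB width bins).
#' @return object of class `quartile_summary`: list with `table`
#'   (data.frame `quartile`, `mean_db`, `n_pixels`, `boundary_db`),
#'   `assignment` (integer 2D matrix, 1-4 inside the ROI, `NA` outside),
#'   `norm_constant`, `roi`, `method`.
#' @export
intensity_quartiles <- function(image, roi, method = c("count", "range")) {
  stopifnot(inherits(image, "power_doppler"))
  method <- match.arg(method)
  if (is.null(image$db)) stop("dB image not computed; call to_db() first")
  m <- image$roi_masks[[roi]]
  if (is.null(m)) stop("unknown ROI: ", roi)
  idx <- which(m)
  n <- length(idx)
  if (n < 4L) stop("ROI must contain at least 4 pixels")
  v <- image$db[idx]

  q <- integer(n)
  if (method == "count") {
    ord <- order(v, decreasing = TRUE)      # stable: ties by scan order
    base <- n %/% 4L
    sizes <- base + (seq_len(4L) <= n %% 4L)
    q[ord] <- rep.int(1:4, sizes)
  } else {
    rng <- range(v[is.finite(v)])
    if (diff(rng) == 0) {
      q[] <- 1L
    } else {
      br <- seq(rng[2], rng[1], length.out = 5L)
      q <- 5L - as.integer(cut(v, breaks = rev(br), include.lowest = TRUE))
    }
  }

  tab <- data.frame(
    quartile = paste0("Q", 1:4),
    mean_db = vapply(1:4, function(k)
      if (any(q == k)) mean(v[q == k]) else NA_real_, numeric(1)),
    n_pixels = vapply(1:4, function(k) sum(q == k), integer(1)),
    boundary_db = vapply(1:4, function(k)
      if (any(q == k)) min(v[q == k]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)

  assignment <- matrix(NA_integer_, nrow(image$db), ncol(image$db))
  assignment[idx] <- q
  structure(list(table = tab, assignment = assignment,
                 norm_constant = n, roi = roi, method = method),
            class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat("<quartile_summary> roi = ", x$roi, ", n = ", x$norm_constant,
      " pixels (", x$method, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare per-quartile means between two groups of subjects
#'
#' For each quartile Q1-Q4 the across-subject mean values of group A and
#' group B are compared with the gated two-group test of
#' [compare_groups()] (Shapiro-Wilk gate, then Student's t or
#' Mann-Whitney U).
#'
#' @param group_a,group_b lists of `quartile_summary` objects (one per
#'   subject, at least 3 per group) with identical quartile labels.
#' @param value column of the quartile table to compare (default
#'   `"mean_db"`).
#' @param ... passed to [compare_groups()].
#' @return data.frame with one row per quartile: `quartile`, `test_used`,
#'   `statistic`, `p_value`, `effect` (mean B - mean A), `n_a`, `n_b`.
#' @export
mean_quartile_comparison <- function(group_a, group_b, value = "mean_db",
                                     ...) {
  pull <- function(g) {
    t(vapply(g, function(s) {
      stopifnot(inherits(s, "quartile_summary"))
      stats::setNames(s$table[[value]], s$table$quartile)
    }, numeric(4)))
  }
  A <- pull(group_a); B <- pull(group_b)
  if (!identical(colnames(A), colnames(B)))
    stop("mismatched quartile labels between groups")
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop("need at least 3 subjects per group")
  out <- lapply(colnames(A), function(qq) {
    r <- compare_groups(A[, qq], B[, qq], ...)
    data.frame(quartile = qq, test_used = r$test_used,
               statistic = r$statistic, p_value = r$p_value,
               effect = r$effect, n_a = nrow(A), n_b = nrow(B),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
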