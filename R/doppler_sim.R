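# Synthetic ultrafast-Doppler frame ensembles with known per-pixel blood
# volume, for verifying the clutter filter and quartile quantification.

#' Ground truth for a simulated Doppler ensemble
#'
#' Describes one coronal imaging plane: a fractional cerebral-blood-volume
#' (CBV) map in `[0, 1]`, a low-rank tissue clutter model, and white noise.
#' Amplitudes are expressed relative to the blood signal RMS so the
#' clutter-to-blood ratio is explicit (in vivo tissue clutter is orders of
#' magnitude above blood).
#'
#' @param cbv_map numeric 2D matrix in `[0, 1]`, fractional blood volume
#'   per pixel.
#' @param clutter_rank number of low-rank tissue clutter components
#'   (0 disables clutter); must be below `n_frames`.
#' @param clutter_amplitude clutter RMS as a multiple of blood signal RMS.
#' @param noise_amplitude white-noise RMS as a multiple of blood signal RMS.
#' @param n_frames ensemble length; default 350 frames, the ensemble
#'   length over which one power-Doppler image is averaged.
#' @param flow_power linear power of a pixel with `cbv = 1`; per-pixel
#'   flow power is `flow_power * cbv_map`.
#' @param seed optional integer seed stored with the truth and used by
#'   [simulate_doppler_ensemble()] when no explicit seed is given.
#' @return object of class `doppler_truth`.
#' @export
doppler_truth <- function(cbv_map, clutter_rank = 2L, clutter_amplitude = 30,
                          noise_amplitude = 0.1, n_frames = 350L,
                          flow_power = 1, seed = NULL) {
  cbv_map <- as.matrix(cbv_map)
  if (any(!is.finite(cbv_map)) || any(cbv_map < 0) || any(cbv_map > 1))
    stop("cbv_map values must be finite and in [0, 1]")
  n_frames <- as.integer(n_frames)
  clutter_rank <- as.integer(clutter_rank)
  if (n_frames < 2L) stop("n_frames must be at least 2")
  if (clutter_rank < 0L || clutter_rank >= n_frames)
    stop("clutter_rank must be in [0, n_frames)")
  if (clutter_amplitude < 0 || noise_amplitude < 0 || flow_power <= 0)
    stop("amplitudes must be non-negative and flow_power positive")
  structure(
    list(cbv_map = cbv_map, clutter_rank = clutter_rank,
         clutter_amplitude = clutter_amplitude,
         noise_amplitude = noise_amplitude, n_frames = n_frames,
         flow_power = flow_power, seed = seed),
    class = "doppler_truth")
}

#' Simulate a complex ultrafast-Doppler frame ensemble
#'
#' Per-pixel time series are the sum of three components:
#' \itemize{
#'   \item tissue clutter: `clutter_rank` separable modes (smooth complex
#'     spatial fields times orthonormal low-frequency cosine temporal
#'     modes), scaled so the clutter RMS is `clutter_amplitude` times the
#'     blood RMS;
#'   \item blood flow: circular complex Gaussian, frame-to-frame
#'     independent (fast decorrelation), with per-pixel power
#'     `flow_power * cbv_map`;
#'   \item white noise: circular complex Gaussian at `noise_amplitude`
#'     times the blood RMS.
#' }
#' The blood RMS reference is `sqrt(flow_power * mean(cbv_map))`; when the
#' CBV map is all-zero the nominal reference `sqrt(flow_power / 2)` is
#' used so clutter and noise keep a finite scale.
#'
#' @param truth a [doppler_truth()] object.
#' @param seed integer seed; defaults to the seed stored in `truth`.
#' @param return_components also attach the three raw components (used for
#'   energy bookkeeping in tests).
#' @return object of class `doppler_ensemble`: list with `frames` (complex
#'   3D array, z-x-t), `frame_rate` (metadata, Hz), `provenance`
#'   (`"simulated"`), and `truth`.
#' @export
simulate_doppler_ensemble <- function(truth, seed = truth$seed,
                                      return_components = FALSE) {
  stopifnot(inherits(truth, "doppler_truth"))
  d <- dim(truth$cbv_map)
  npix <- prod(d)
  nt <- truth$n_frames
  flow_pow <- truth$flow_power * as.numeric(truth$cbv_map)
  blood_rms <- sqrt(mean(flow_pow))
  if (blood_rms == 0) blood_rms <- sqrt(truth$flow_power / 2)

  out <- with_seed(seed, {
    flow_sd <- sqrt(flow_pow / 2)
    flow <- matrix(complex(
      real = rnorm(npix * nt, sd = flow_sd),
      imaginary = rnorm(npix * nt, sd = flow_sd)), npix, nt)
    clutter <- matrix(0 + 0i, npix, nt)
    if (truth$clutter_rank > 0 && truth$clutter_amplitude > 0) {
      tt <- seq_len(nt) - 0.5
      U <- sapply(seq_len(truth$clutter_rank),
                  function(k) cos(pi * k * tt / nt))
      U <- qr.Q(qr(U))                       # orthonormal temporal modes
      S <- sapply(seq_len(truth$clutter_rank), function(k) {
        f <- smooth_field2(d, blur = 2) - 0.5 +
          1i * (smooth_field2(d, blur = 2) - 0.5)
        f <- as.vector(f)
        f / sqrt(mean(Mod(f)^2))             # unit-RMS spatial mode
      })
      amp <- truth$clutter_amplitude * blood_rms *
        sqrt(nt / truth$clutter_rank)
      clutter <- amp * (S %*% t(U))
    }
    noise <- matrix(0 + 0i, npix, nt)
    if (truth$noise_amplitude > 0) {
      nsd <- truth$noise_amplitude * blood_rms / sqrt(2)
      noise <- matrix(complex(real = rnorm(npix * nt, sd = nsd),
                              imaginary = rnorm(npix * nt, sd = nsd)),
                      npix, nt)
    }
    list(frames = array(clutter + flow + noise, c(d, nt)),
         clutter = clutter, flow = flow, noise = noise)
  })

  ens <- structure(
    list(frames = out$frames, frame_rate = 500,
         provenance = "simulated", truth = truth),
    class = "doppler_ensemble")
  if (return_components) {
    ens$components <- list(clutter = array(out$clutter, c(d, nt)),
                           flow = array(out$flow, c(d, nt)),
                           noise = array(out$noise, c(d, nt)))
  }
  ens
}

#' Construct a Doppler ensemble from an existing complex frame array
#'
#' @param frames complex 3D array (z, x, t) with at least 2 frames.
#' @param frame_rate acquisition frame rate in Hz (metadata only).
#' @param provenance `"simulated"` or `"file"`.
#' @param truth optional [doppler_truth()] carried alongside.
#' @export
doppler_ensemble <- function(frames, frame_rate = NA_real_,
                             provenance = "file", truth = NULL) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2L)
  if (any(!is.finite(Re(frames))) || any(!is.finite(Im(frames))))
    stop("frames must be finite")
  structure(list(frames = frames, frame_rate = frame_rate,
                 provenance = provenance, truth = truth),
            class = "doppler_ensemble")
}

#' @export
print.doppler_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat("<doppler_ensemble> ", d[1], " x ", d[2], " pixels, ", d[3],
      " frames (", x$provenance, ")\n", sep = "")
  invisible(x)
}
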