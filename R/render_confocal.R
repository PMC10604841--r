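# Synthetic fluorescence rendering of a vascular network, emulating a
# lectin-stained (IB4-like) confocal z-stack.

#' Render a vessel network as a synthetic confocal stack
#'
#' The ground-truth binary mask is blurred by an isotropic Gaussian point
#' spread function, scaled by a fluorescence contrast, offset by a tissue
#' background, and corrupted by additive Gaussian detector noise (clipped
#' at zero). With `psf_sigma = 0` and `noise_sd = 0` the rendering is
#' two-valued and any threshold strictly between `background` and
#' `background + contrast` recovers the truth mask exactly.
#'
#' @param network a [generate_vessel_network()] result.
#' @param psf_sigma point-spread-function sigma in micrometers. At the
#'   default 2 um voxel sampling the confocal PSF is subvoxel, so the
#'   default blur is mild.
#' @param noise_sd detector noise standard deviation (intensity units).
#' @param contrast fluorescence intensity of vessel voxels above background.
#' @param background tissue background intensity.
#' @param seed integer seed for the noise draw.
#' @return object of class `confocal_stack`: list with `intensity` (3D
#'   array, z-y-x), `voxel_size`, `psf_sigma`, `noise_sd`, and `truth`
#'   (the parent network).
#' @export
render_confocal <- function(network, psf_sigma = 1, noise_sd = 5,
                            contrast = 100, background = 10, seed = NULL) {
  stopifnot(inherits(network, "vessel_network"))
  if (contrast < 0) stop("contrast must be non-negative")
  if (psf_sigma < 0 || noise_sd < 0)
    stop("psf_sigma and noise_sd must be non-negative")
  x <- array(as.numeric(network$mask), dim(network$mask))
  if (psf_sigma > 0) {
    x <- gaussian_blur3(x, psf_sigma / network$voxel_size)
  }
  x <- contrast * x + background
  if (noise_sd > 0) {
    x <- with_seed(seed, x + rnorm(length(x), sd = noise_sd))
    x <- pmax(x, 0)
    dim(x) <- dim(network$mask)
  }
  structure(
    list(intensity = x, voxel_size = network$voxel_size,
         psf_sigma = psf_sigma, noise_sd = noise_sd, truth = network),
    class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  cat("<confocal_stack> ", paste(dim(x$intensity), collapse = " x "),
      " voxels; psf_sigma = ", x$psf_sigma, " um, noise_sd = ", x$noise_sd,
      "\n", sep = "")
  invisible(x)
}
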