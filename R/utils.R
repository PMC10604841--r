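# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible per-stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' (and each simulated animal) draws from its own named substream so stages
#' can be re-run independently without disturbing one another.
#'
#' @param seed integer root seed.
#' @param label character label naming the substream.
#' @return an integer seed (always below 2^31).
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  code <- utf8ToInt(label)
  h <- sum(code * (seq_along(code) %% 7L + 1L))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array; `sigma` is in voxels, one value
# per axis (z, y, x). Borders are zero-padded.
gaussian_blur3 <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3L, length(sigma) == 3L, all(sigma >= 0))
  for (ax in 1:3) {
    if (sigma[ax] <= 1e-8) next
    x <- convolve_axis3(x, gaussian_kernel(sigma[ax]), ax)
  }
  x
}

convolve_axis3 <- function(x, k, ax) {
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, dp[1], dp[2] * dp[3])
  r <- (length(k) - 1L) / 2L
  pad <- matrix(0, r, ncol(m))
  mf <- stats::filter(rbind(pad, m, pad), k, sides = 2)
  m <- matrix(mf[(r + 1L):(r + dp[1]), , drop = FALSE], dp[1], ncol(m))
  aperm(array(m, dp), order(perm))
}

# Smooth 2D random field in [0, 1]: blurred white noise, rescaled.
smooth_field2 <- function(shape, blur = 2) {
  x <- matrix(runif(prod(shape)), shape[1], shape[2])
  x3 <- array(x, c(shape, 1L))
  x <- gaussian_blur3(x3, c(blur, blur, 0))[, , 1]
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, shape[1], shape[2]))
  (x - rng[1]) / diff(rng)
}
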