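# Quartile overlay figures: Q1 blue, Q2 fuchsia, Q3 green, Q4 yellow.

#' Quartile overlay palette
#'
#' The fixed four-color convention used in every overlay: Q1 blue, Q2
#' fuchsia, Q3 green, Q4 yellow (largest to smallest vessels).
#' @export
quartile_palette <- function() {
  c(Q1 = "#0000FF", Q2 = "#FF00FF", Q3 = "#00FF00", Q4 = "#FFFF00")
}

#' Render a color-coded quartile overlay to a PNG file
#'
#' Pixels of each quartile are painted with the fixed palette
#' ([quartile_palette()]); pixels outside the assignment are shown as the
#' grayscale background (when given) or black. Empty quartiles are marked
#' as such in the legend.
#'
#' @param assignment integer matrix with values 1-4 inside the ROI and
#'   `NA` outside (e.g. `intensity_quartiles(...)$assignment`).
#' @param file output PNG path.
#' @param background optional numeric matrix (e.g. the dB image) of the
#'   same shape, displayed in grayscale outside the ROI.
#' @param scale pixel magnification of the written image.
#' @return `file`, invisibly.
#' @export
render_quartile_overlay <- function(assignment, file, background = NULL,
                                    scale = 8L) {
  stopifnot(is.matrix(assignment))
  if (!is.null(background) &&
      !identical(dim(background), dim(assignment)))
    stop("assignment and background shapes differ")
  pal <- quartile_palette()
  nz <- nrow(assignment); nx <- ncol(assignment)

  rgb_img <- array(0, c(nz, nx, 3))
  if (!is.null(background)) {
    b <- background
    b[!is.finite(b)] <- min(b[is.finite(b)])
    rng <- range(b)
    g <- if (diff(rng) > 0) (b - rng[1]) / diff(rng) else b * 0
    for (k in 1:3) rgb_img[, , k] <- 0.6 * g
  }
  for (q in 1:4) {
    idx <- which(assignment == q)
    if (!length(idx)) next
    cv <- grDevices::col2rgb(pal[q]) / 255
    for (k in 1:3) {
      plane <- rgb_img[, , k]
      plane[idx] <- cv[k]
      rgb_img[, , k] <- plane
    }
  }

  counts <- vapply(1:4, function(q) sum(assignment == q, na.rm = TRUE),
                   integer(1))
  labels <- sprintf("Q%d%s", 1:4, ifelse(counts == 0, " (empty)", ""))

  grDevices::png(file, width = nx * scale, height = nz * scale + 40)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(NA, xlim = c(0, nx), ylim = c(-40 / scale, nz),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(rgb_img), 0, 0, nx, nz,
                        interpolate = FALSE)
  graphics::legend("bottomleft", legend = labels, fill = pal, horiz = TRUE,
                   bty = "n", text.col = "white")
  invisible(file)
}
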