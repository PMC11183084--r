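# Image representation: numeric matrix [row = y (downward), col = x],
# intensities in [0, 1], origin top-left, 0-based pixel centres when
# converting to physical coordinates. RGB input is reduced by Rec.709
# luminance. This is the single place the coordinate convention lives.

#' Read a grayscale image (PNG or TIFF)
#'
#' @param path image file; 8/16-bit grayscale or RGB (reduced by
#'   luminance).
#' @return A numeric matrix `[y, x]` with values in `[0, 1]`, origin
#'   top-left, y increasing downward.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

#' Write a grayscale image as PNG
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (.png).
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# sampled Gaussian kernel over integer offsets, unit sum
gauss_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  o <- (-r):r
  g <- exp(-o^2 / (2 * sigma^2))
  g / sum(g)
}

# sampled derivative-of-Gaussian kernel, normalised so that correlation
# with a linear ramp of unit slope returns 1; filter2() flips the kernel
# (convolution), so the sign is flipped here to yield a correlation-style
# derivative along increasing index
dgauss_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  o <- (-r):r
  dg <- o * exp(-o^2 / (2 * sigma^2))
  -dg / sum(o * dg)
}

smooth_image <- function(img, sigma) {
  g <- gauss_kernel(sigma)
  EBImage::filter2(img, outer(g, g), boundary = "replicate")
}

# gradients: d/dy is along dim 1 (rows), d/dx along dim 2 (cols)
grad_xy <- function(img, sigma = 2) {
  g <- gauss_kernel(sigma)
  dg <- dgauss_kernel(sigma)
  list(gy = EBImage::filter2(img, outer(dg, g), boundary = "replicate"),
       gx = EBImage::filter2(img, outer(g, dg), boundary = "replicate"))
}

# bilinear interpolation at fractional pixel positions (x, y in 1-based
# matrix coordinates); clamps to the image border
sample_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# sub-pixel refinement of an extremum: parabola through (i-1, i, i+1)
parabolic_vertex <- function(v_m, v_0, v_p) {
  den <- v_m - 2 * v_0 + v_p
  if (abs(den) < .Machine$double.eps) return(0)
  max(-1, min(1, 0.5 * (v_m - v_p) / den))
}
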