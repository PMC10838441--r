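# Foreground extraction and spectral preprocessing. Segmentation follows
# the usual plant-imaging recipe: synthesize an RGB preview from three
# bands, score greenness, Otsu-threshold, clean up with morphological
# opening/closing and keep the largest connected component.

#' Synthesize an 8-bit RGB preview from a reflectance cube
#'
#' Picks the bands nearest to the configured red, green and blue
#' wavelengths and stretches each channel independently to 0-255.
#'
#' @param cube a reflectance [hypercube()].
#' @param rgb_nm target wavelengths (nm) for the R, G, B channels.
#' @return Integer array `height x width x 3` with values in 0..255.
#' @export
synthesize_rgb <- function(cube, rgb_nm = c(660, 550, 470)) {
  if (!inherits(cube, "hypercube")) stop("'cube' must be a hypercube")
  wl <- cube$wavelengths
  if (min(rgb_nm) < min(wl) - 25 || max(rgb_nm) > max(wl) + 25)
    stop("wavelength grid does not cover the requested visible R/G/B bands")
  d <- dim(cube$values)
  out <- array(0L, c(d[1L], d[2L], 3L))
  for (ch in 1:3) {
    band <- which.min(abs(wl - rgb_nm[ch]))
    plane <- cube$values[, , band]
    rng <- range(plane)
    if (rng[2] > rng[1]) {
      plane <- (plane - rng[1]) / (rng[2] - rng[1])
    } else {
      plane <- matrix(0, d[1L], d[2L])
    }
    out[, , ch] <- as.integer(round(plane * 255))
  }
  out
}

#' Otsu threshold of a value sample
#'
#' Classical histogram thresholding: the values are binned into `levels`
#' equal-width bins spanning their observed range, and the bin boundary
#' maximizing the between-class variance
#' \eqn{\sigma_b^2(t) = w_0(t) w_1(t) (\mu_0(t) - \mu_1(t))^2}
#' is returned. The search is evaluated with cumulative histogram moments;
#' ties go to the lowest maximizing cut. Because the bins track the value
#' range, the threshold is equivariant under shifts and positive scalings
#' of the data.
#'
#' @param values numeric vector or matrix with at least two distinct values.
#' @param levels number of histogram bins (default 256).
#' @return The threshold, on the scale of `values`; pixels strictly above it
#'   are foreground.
#' @export
otsu_threshold <- function(values, levels = 256) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || rng[1] == rng[2])
    stop("Otsu threshold needs at least two distinct values")
  levels <- as.integer(levels)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bins <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), levels)
  counts <- tabulate(bins, levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  total <- w0[levels]
  msum <- m0[levels]
  t_idx <- seq_len(levels - 1L)
  w1 <- total - w0[t_idx]
  between <- ifelse(
    w0[t_idx] == 0 | w1 == 0, -Inf,
    w0[t_idx] * w1 * (m0[t_idx] / w0[t_idx] - (msum - m0[t_idx]) / w1)^2)
  breaks[which.max(between) + 1L]
}

#' Segment the plant foreground of a calibrated cube
#'
#' Scores greenness with the excess-green index (2G - R - B) computed from
#' the reflectance planes nearest to the configured R/G/B wavelengths,
#' binarizes the score with [otsu_threshold()], applies morphological
#' opening then closing with a disc structuring element and keeps the
#' largest connected component. Greenness is scored on reflectance rather
#' than on the 8-bit preview of [synthesize_rgb()] because the preview's
#' independent per-channel contrast stretch equalizes the channels on
#' dark-background scenes and erases exactly the green excess being
#' measured.
#'
#' @param cube a reflectance [hypercube()].
#' @param radius structuring-element radius in pixels (default 2).
#' @param rgb_nm R/G/B wavelengths used for the greenness score.
#' @return An object of class `"foreground_mask"`: list with `mask` (logical
#'   matrix) and `radius`.
#' @export
segment_foreground <- function(cube, radius = 2, rgb_nm = c(660, 550, 470)) {
  if (!inherits(cube, "hypercube")) stop("'cube' must be a hypercube")
  wl <- cube$wavelengths
  if (min(rgb_nm) < min(wl) - 25 || max(rgb_nm) > max(wl) + 25)
    stop("wavelength grid does not cover the visible R/G/B bands")
  plane <- function(nm) cube$values[, , which.min(abs(wl - nm))]
  greenness <- 2 * plane(rgb_nm[2]) - plane(rgb_nm[1]) - plane(rgb_nm[3])
  thr <- otsu_threshold(greenness)
  bin <- (greenness > thr) * 1
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  cleaned <- EBImage::closing(EBImage::opening(bin, kern), kern)
  if (sum(cleaned) == 0)
    stop("segmentation produced an empty foreground mask")
  labels <- EBImage::bwlabel(cleaned)
  counts <- tabulate(labels[labels > 0])
  mask <- labels == which.max(counts)
  structure(list(mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
                 radius = radius),
            class = "foreground_mask")
}

#' Mean spectrum over the segmented region of interest
#'
#' Arithmetic per-band mean of the reflectance of foreground pixels only
#' (mask-multiplication semantics: background pixels have no influence).
#'
#' @param cube a reflectance [hypercube()].
#' @param mask a [segment_foreground()] result or a logical matrix matching
#'   the cube's spatial dimensions.
#' @return Numeric vector of per-band means, named by wavelength.
#' @export
mean_roi_spectrum <- function(cube, mask) {
  if (!inherits(cube, "hypercube")) stop("'cube' must be a hypercube")
  if (inherits(mask, "foreground_mask")) mask <- mask$mask
  d <- dim(cube$values)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("'mask' must be a logical matrix matching the cube's spatial shape")
  if (!any(mask)) stop("'mask' selects no foreground pixels")
  flat <- matrix(cube$values, d[1L] * d[2L], d[3L])
  out <- colMeans(flat[as.vector(mask), , drop = FALSE])
  names(out) <- cube$wavelengths
  out
}

#' Min-max scale spectra to the unit interval
#'
#' Per-sample scaling `(x - min) / (max - min)` so that each spectrum spans
#' exactly \[0, 1\]. For a spectra matrix the default scales every row
#' independently; `scope = "band"` instead scales each column over the whole
#' dataset (rarely wanted, as it couples samples).
#'
#' @param x numeric spectrum vector or `samples x bands` matrix.
#' @param scope `"sample"` (default, per row) or `"band"` (per column),
#'   matrices only.
#' @return Scaled vector or matrix of the same shape.
#' @export
minmax_scale <- function(x, scope = c("sample", "band")) {
  scope <- match.arg(scope)
  scale_vec <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2])
      stop("cannot min-max scale a constant spectrum")
    (v - rng[1]) / (rng[2] - rng[1])
  }
  if (is.matrix(x)) {
    if (scope == "sample") t(apply(x, 1L, scale_vec)) else apply(x, 2L, scale_vec)
  } else {
    scale_vec(x)
  }
}

#' First derivative of reflectance with respect to wavelength
#'
#' Central differences at interior bands and one-sided differences at the
#' two ends, so the output has the same length as the input. Exact for
#' spectra linear in wavelength.
#'
#' @param x numeric spectrum vector or `samples x bands` matrix.
#' @param wavelengths band centres (nm) matching `x`.
#' @return Derivative spectrum (same shape as `x`), units 1/nm.
#' @export
first_derivative <- function(x, wavelengths) {
  check_grid(wavelengths)
  if (length(wavelengths) < 3L)
    stop("first derivative needs at least 3 bands")
  deriv_vec <- function(v) {
    n <- length(v)
    if (n != length(wavelengths))
      stop("spectrum length must equal the number of wavelengths")
    d <- numeric(n)
    d[1] <- (v[2] - v[1]) / (wavelengths[2] - wavelengths[1])
    d[n] <- (v[n] - v[n - 1]) / (wavelengths[n] - wavelengths[n - 1])
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (wavelengths[i + 1] - wavelengths[i - 1])
    d
  }
  if (is.matrix(x)) t(apply(x, 1L, deriv_vec)) else deriv_vec(x)
}

#' Augmentation configuration for spectral jitter
#'
#' @param offset_factor additive offset range as a multiple of the
#'   spectrum's standard deviation (default 0.10).
#' @param slope_low,slope_high bounds of the uniform multiplicative factor
#'   (defaults 0.95 and 1.05).
#' @return An object of class `"augmentation_config"`.
#' @export
augmentation_config <- function(offset_factor = 0.10, slope_low = 0.95,
                                slope_high = 1.05) {
  if (offset_factor < 0) stop("'offset_factor' must be non-negative")
  if (!(slope_low > 0 && slope_low <= slope_high))
    stop("need 0 < slope_low <= slope_high")
  structure(list(offset_factor = offset_factor, slope_low = slope_low,
                 slope_high = slope_high),
            class = "augmentation_config")
}

#' Randomly jitter the offset and slope of a spectrum
#'
#' Draws a multiplicative factor `a ~ U(slope_low, slope_high)` and an
#' additive offset `b ~ U(-f sigma, +f sigma)` (with `sigma` the standard
#' deviation of the input spectrum and `f` the offset factor) and returns
#' `a * x + b`. The standard chemometric offset/gain jitter used to augment
#' small spectral training sets.
#'
#' @param x numeric spectrum vector (non-constant).
#' @param cfg an [augmentation_config()].
#' @param seed optional integer seed (global RNG state is preserved).
#' @return Jittered spectrum of the same length.
#' @export
augment_spectrum <- function(x, cfg = augmentation_config(), seed = NULL) {
  if (stats::sd(x) == 0) stop("cannot augment a constant spectrum")
  draw <- with_seed(seed, {
    a <- stats::runif(1, cfg$slope_low, cfg$slope_high)
    s <- cfg$offset_factor * stats::sd(x)
    b <- stats::runif(1, -s, s)
    c(a, b)
  })
  draw[1] * x + draw[2]
}
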