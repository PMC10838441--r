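# Synthetic Vis-NIR leaf scenes and spectra. The forward model is a smooth
# baseline with a logistic red-edge ramp to an NIR plateau, minus Gaussian
# absorption dips (blue and red chlorophyll bands) whose depth grows
# linearly with the SPAD value. It is deliberately simple: monotone in
# SPAD, reflectance bounded in [0, 1], and with a known informative window
# for attention/wavelength-selection checks.

# internal: evaluate expr under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Leaf reflectance forward model
#'
#' Parameterizes the synthetic mapping from a SPAD chlorophyll reading to a
#' Vis-NIR reflectance spectrum: a flat visible baseline rising through a
#' logistic red edge to an NIR plateau, with Gaussian absorption dips at the
#' blue and red chlorophyll bands whose depth increases linearly with SPAD.
#'
#' @param visible_reflectance baseline reflectance in the visible range.
#' @param nir_reflectance plateau reflectance beyond the red edge.
#' @param red_edge_nm centre of the logistic red-edge transition (nm).
#' @param red_edge_width_nm scale of the logistic transition (nm).
#' @param absorption_centers_nm chlorophyll absorption band centres (nm).
#' @param absorption_widths_nm Gaussian standard deviations per centre (nm).
#' @param depth_per_spad absorption depth added per SPAD unit.
#' @param noise_sd standard deviation of additive per-band reflectance noise.
#' @return An object of class `"leaf_spectrum_model"`.
#' @export
leaf_spectrum_model <- function(visible_reflectance = 0.55,
                                nir_reflectance = 0.85,
                                red_edge_nm = 715,
                                red_edge_width_nm = 16,
                                absorption_centers_nm = c(450, 662),
                                absorption_widths_nm = c(22, 28),
                                depth_per_spad = 0.009,
                                noise_sd = 0.01) {
  if (length(absorption_centers_nm) != length(absorption_widths_nm))
    stop("one Gaussian width per absorption centre is required")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(visible_reflectance = visible_reflectance,
                 nir_reflectance = nir_reflectance,
                 red_edge_nm = red_edge_nm,
                 red_edge_width_nm = red_edge_width_nm,
                 absorption_centers_nm = absorption_centers_nm,
                 absorption_widths_nm = absorption_widths_nm,
                 depth_per_spad = depth_per_spad,
                 noise_sd = noise_sd),
            class = "leaf_spectrum_model")
}

# internal: noise-free baseline (SPAD = 0) reflectance on a grid
baseline_reflectance <- function(model, wavelengths) {
  model$visible_reflectance +
    (model$nir_reflectance - model$visible_reflectance) *
    stats::plogis((wavelengths - model$red_edge_nm) / model$red_edge_width_nm)
}

# internal: summed unit-height Gaussian absorption profile
absorption_profile <- function(model, wavelengths) {
  prof <- numeric(length(wavelengths))
  for (j in seq_along(model$absorption_centers_nm)) {
    prof <- prof + exp(-(wavelengths - model$absorption_centers_nm[j])^2 /
                         (2 * model$absorption_widths_nm[j]^2))
  }
  prof
}

#' Default Vis-NIR band grid
#'
#' The working wavelength grid of the pipeline: 231 equally spaced bands
#' spanning 387-1003 nm (the sensor range), optionally trimmed to the
#' low-noise 437-919 nm window, which retains 180 bands.
#'
#' @param trimmed if `TRUE` (default) return the 180-band trimmed grid,
#'   otherwise the full 231-band sensor grid.
#' @return Numeric vector of band centres (nm).
#' @export
vnir_grid <- function(trimmed = TRUE) {
  full <- make_wavelength_grid(387, 1003, 231)
  if (!trimmed) return(full)
  trim_to_range(full, full, 437, 919)$wavelengths
}

#' Generate one synthetic mean reflectance spectrum
#'
#' @param spad ground-truth chlorophyll value (SPAD units, >= 0).
#' @param wavelengths band grid (nm).
#' @param model a [leaf_spectrum_model()].
#' @param seed optional integer; when given, noise is drawn under this seed
#'   without disturbing the global RNG state.
#' @return Numeric reflectance vector in \[0, 1\], named by wavelength.
#' @examples
#' s <- generate_spectrum(35, vnir_grid(), seed = 1)
#' @export
generate_spectrum <- function(spad, wavelengths, model = leaf_spectrum_model(),
                              seed = NULL) {
  if (!is.numeric(spad) || length(spad) != 1L || spad < 0)
    stop("'spad' must be a single non-negative number")
  check_grid(wavelengths)
  r <- baseline_reflectance(model, wavelengths) -
    model$depth_per_spad * spad * absorption_profile(model, wavelengths)
  if (model$noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(wavelengths), 0, model$noise_sd))
    r <- r + noise
  }
  r <- pmin(pmax(r, 0), 1)
  names(r) <- wavelengths
  r
}

# internal: logical ellipse-union "lettuce blob" mask
blob_mask <- function(height, width, seed) {
  with_seed(seed, {
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    cy <- height / 2 + stats::runif(1, -0.05, 0.05) * height
    cx <- width / 2 + stats::runif(1, -0.05, 0.05) * width
    a1 <- 0.32 * height * stats::runif(1, 0.9, 1.1)
    b1 <- 0.30 * width * stats::runif(1, 0.9, 1.1)
    m <- ((rr - cy) / a1)^2 + ((cc - cx) / b1)^2 <= 1
    # a second, offset lobe makes the outline less regular
    th <- stats::runif(1, 0, 2 * pi)
    cy2 <- cy + 0.18 * height * sin(th)
    cx2 <- cx + 0.18 * width * cos(th)
    a2 <- 0.2 * height
    b2 <- 0.2 * width
    m | (((rr - cy2) / a2)^2 + ((cc - cx2) / b2)^2 <= 1)
  })
}

#' Generate a synthetic hyperspectral scene
#'
#' Produces a raw-DN cube of a single leafy "blob" on a dark background,
#' together with matching white/dark reference frames and the ground-truth
#' foreground mask. Foreground pixels carry the model spectrum for the given
#' SPAD value plus independent per-pixel noise; background pixels sit at the
#' dark level (plus noise proportional to `model$noise_sd`), so that
#' calibrated background reflectance is approximately zero.
#'
#' @param spad ground-truth chlorophyll value (SPAD units).
#' @param height,width spatial dimensions in pixels (each >= 8).
#' @param wavelengths band grid (nm).
#' @param model a [leaf_spectrum_model()].
#' @param seed integer seed controlling blob shape and noise.
#' @return An object of class `"synthetic_scene"`: list with `cube` (raw
#'   [hypercube()]), `refs` ([reference_frames()]), `truth_mask` (logical
#'   matrix) and `spad`.
#' @export
generate_cube <- function(spad, height = 64, width = 64,
                          wavelengths = vnir_grid(trimmed = FALSE),
                          model = leaf_spectrum_model(), seed = 1) {
  if (height < 8 || width < 8)
    stop("'height' and 'width' must both be at least 8 pixels")
  check_grid(wavelengths)
  n_bands <- length(wavelengths)
  # deterministic references: spatially flat, smooth spectral illumination
  illum <- 3000 * (0.7 + 0.3 * exp(-((wavelengths - 700) / 250)^2))
  dark_level <- 120
  white <- array(rep(illum + dark_level, each = height * width),
                 c(height, width, n_bands))
  dark <- array(dark_level, c(height, width, n_bands))
  gain <- white - dark
  mask <- blob_mask(height, width, seed)
  clean <- generate_spectrum(spad,  wavelengths,
                             model = within_noiseless(model))
  refl <- with_seed(seed + 1L, {
    n_fg <- sum(mask)
    r <- array(0, c(height, width, n_bands))
    for (b in seq_len(n_bands)) {
      plane <- matrix(stats::rnorm(height * width, 0, 0.5 * model$noise_sd),
                      height, width)
      plane[mask] <- clean[b] + stats::rnorm(n_fg, 0, model$noise_sd)
      r[, , b] <- plane
    }
    r
  })
  raw <- hypercube(dark + gain * refl, wavelengths, kind = "raw")
  structure(list(cube = raw,
                 refs = reference_frames(white, dark),
                 truth_mask = mask,
                 spad = spad),
            class = "synthetic_scene")
}

# internal: copy of a model with noise switched off
within_noiseless <- function(model) {
  model$noise_sd <- 0
  model
}

#' Generate a labelled benchmark dataset
#'
#' Draws `n` SPAD values uniformly from `spad_range` and the matching noisy
#' mean spectra, emulating the per-plant measurement protocol of a
#' greenhouse chlorophyll study (one ROI-averaged spectrum and one SPAD
#' meter reading per plant). The default size of 478 samples matches a
#' typical single-variety greenhouse campaign.
#'
#' @param n number of samples (default 478); must be at least `min_folds`.
#' @param seed integer seed; two calls with the same arguments are identical.
#' @param spad_range length-2 positive interval for the SPAD labels.
#' @param wavelengths band grid (nm); default: trimmed 180-band grid.
#' @param model a [leaf_spectrum_model()].
#' @param min_folds smallest fold count the dataset must support (default 5).
#' @return An object of class `"labeled_dataset"`: list with `spectra`
#'   (`n x bands` matrix, columns named by wavelength), `spad`, `wavelengths`
#'   and `model`.
#' @export
generate_dataset <- function(n = 478, seed = 1, spad_range = c(15, 50),
                             wavelengths = vnir_grid(),
                             model = leaf_spectrum_model(),
                             min_folds = 5) {
  if (n < min_folds)
    stop(sprintf("'n' (%d) must be at least the fold count (%d)", n, min_folds))
  if (length(spad_range) != 2L || any(spad_range < 0) ||
      spad_range[1] >= spad_range[2])
    stop("'spad_range' must be a positive increasing interval")
  check_grid(wavelengths)
  out <- with_seed(seed, {
    spad <- stats::runif(n, spad_range[1], spad_range[2])
    spectra <- matrix(0, n, length(wavelengths),
                      dimnames = list(NULL, wavelengths))
    for (i in seq_len(n))
      spectra[i, ] <- generate_spectrum(spad[i], wavelengths, model)
    list(spectra = spectra, spad = spad)
  })
  structure(list(spectra = out$spectra, spad = out$spad,
                 wavelengths = wavelengths, model = model),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d bands, SPAD %.1f-%.1f\n",
              nrow(x$spectra), ncol(x$spectra), min(x$spad), max(x$spad)))
  invisible(x)
}
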