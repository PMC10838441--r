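#' Build an equally spaced wavelength grid
#'
#' Constructs the vector of band-centre wavelengths for a line-scan
#' spectrograph: `n_bands` centres equally spaced from `start_nm` to
#' `stop_nm`, both endpoints included.
#'
#' @param start_nm first band centre (nm).
#' @param stop_nm last band centre (nm); must exceed `start_nm`.
#' @param n_bands number of bands (>= 2).
#' @return Numeric vector of strictly increasing band centres (nm).
#' @examples
#' wl <- make_wavelength_grid(387, 1003, 231)
#' length(wl)   # 231
#' diff(wl)[1]  # 616/230 nm
#' @export
make_wavelength_grid <- function(start_nm, stop_nm, n_bands) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), length(start_nm) == 1L,
            length(stop_nm) == 1L)
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 2)
    stop("'n_bands' must be a single number >= 2")
  if (stop_nm <= start_nm)
    stop("'stop_nm' must be strictly greater than 'start_nm'")
  seq(start_nm, stop_nm, length.out = as.integer(n_bands))
}

# internal: validate a wavelength vector
check_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L)
    stop("wavelength grid must be numeric with at least 2 bands")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  invisible(wavelengths)
}

#' Restrict a cube or spectrum to a wavelength window
#'
#' Keeps exactly the bands whose centre lies in the closed interval
#' `[lo_nm, hi_nm]`. Band order is preserved. High noise at the extremes of
#' a Vis-NIR sensor's range is the usual reason to trim; on the default
#' 231-band grid over 387-1003 nm the window 437-919 nm retains 180 bands.
#'
#' @param x a [hypercube()], a spectra matrix (samples x bands), or a numeric
#'   spectrum vector.
#' @param ... passed to methods.
#' @param lo_nm,hi_nm closed wavelength window (nm), `lo_nm < hi_nm`.
#' @param wavelengths band centres of `x` (not needed for hypercubes).
#' @return For a hypercube, a trimmed hypercube. Otherwise a list with
#'   elements `values` and `wavelengths`.
#' @export
trim_to_range <- function(x, ...) UseMethod("trim_to_range")

# internal: indices of bands kept by the closed window
trim_index <- function(wavelengths, lo_nm, hi_nm) {
  check_grid(wavelengths)
  if (!(lo_nm <= hi_nm)) stop("'lo_nm' must not exceed 'hi_nm'")
  keep <- which(wavelengths >= lo_nm & wavelengths <= hi_nm)
  if (length(keep) == 0L)
    stop(sprintf("no bands inside [%g, %g] nm", lo_nm, hi_nm))
  keep
}

#' @rdname trim_to_range
#' @export
trim_to_range.hypercube <- function(x, lo_nm, hi_nm, ...) {
  keep <- trim_index(x$wavelengths, lo_nm, hi_nm)
  hypercube(x$values[, , keep, drop = FALSE], x$wavelengths[keep], kind = x$kind)
}

#' @rdname trim_to_range
#' @export
trim_to_range.default <- function(x, wavelengths, lo_nm, hi_nm, ...) {
  keep <- trim_index(wavelengths, lo_nm, hi_nm)
  if (is.matrix(x)) {
    if (ncol(x) != length(wavelengths))
      stop("ncol(x) must equal length(wavelengths)")
    list(values = x[, keep, drop = FALSE], wavelengths = wavelengths[keep])
  } else {
    if (length(x) != length(wavelengths))
      stop("length(x) must equal length(wavelengths)")
    list(values = x[keep], wavelengths = wavelengths[keep])
  }
}
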