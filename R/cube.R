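#' Hyperspectral cube container
#'
#' A hypercube is a `height x width x bands` array of either raw detector
#' counts (digital numbers, `kind = "raw"`) or calibrated reflectance
#' (`kind = "reflectance"`), together with the band-centre wavelengths.
#'
#' @param values numeric array of dimension `height x width x bands`.
#' @param wavelengths strictly increasing band centres (nm); length must
#'   equal the third dimension of `values`.
#' @param kind `"raw"` for uncalibrated digital numbers, `"reflectance"`
#'   for calibrated data.
#' @return An object of class `"hypercube"`: a list with elements `values`,
#'   `wavelengths` and `kind`.
#' @examples
#' wl <- make_wavelength_grid(400, 700, 4)
#' cube <- hypercube(array(runif(5 * 6 * 4), c(5, 6, 4)), wl, "reflectance")
#' dim(cube$values)
#' @export
hypercube <- function(values, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array (height x width x bands)")
  check_grid(wavelengths)
  if (dim(values)[3L] != length(wavelengths))
    stop(sprintf("cube has %d bands but grid has %d wavelengths",
                 dim(values)[3L], length(wavelengths)))
  if (kind == "reflectance" && any(!is.finite(values)))
    stop("reflectance cube must contain only finite values")
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind = %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' White and dark reference frames
#'
#' Bundles the white-panel and closed-shutter (dark-current) reference
#' recordings used for reflectance calibration. Each frame is either a full
#' `height x width x bands` array matching the cube, or a `1 x width x bands`
#' line reference (one calibration line per cross-track pixel, as produced
#' by line-scan hardware) that is broadcast down the scan direction.
#'
#' @param white white reference frame (array).
#' @param dark dark reference frame (array, same shape as `white`).
#' @return An object of class `"reference_frames"`.
#' @export
reference_frames <- function(white, dark) {
  for (nm in c("white", "dark")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      stop(sprintf("'%s' must be a 3-D array", nm))
  }
  if (!identical(dim(white), dim(dark)))
    stop("white and dark frames must have identical dimensions")
  structure(list(white = white, dark = dark), class = "reference_frames")
}

# internal: broadcast a 1 x w x b line reference to h x w x b
broadcast_ref <- function(ref, d) {
  dr <- dim(ref)
  if (identical(dr, d)) return(ref)
  if (dr[1L] == 1L && dr[2L] == d[2L] && dr[3L] == d[3L]) {
    out <- array(0, d)
    for (b in seq_len(d[3L]))
      out[, , b] <- matrix(ref[1L, , b], d[1L], d[2L], byrow = TRUE)
    return(out)
  }
  stop(sprintf(
    "reference frame of dimension %s cannot be broadcast to cube dimension %s",
    paste(dr, collapse = "x"), paste(d, collapse = "x")))
}

#' Calibrate raw digital numbers to reflectance
#'
#' Converts raw detector counts to reflectance with the standard two-point
#' radiometric correction
#' \deqn{R = (I_{raw} - I_d) / (I_w - I_d)}
#' where \eqn{I_w} and \eqn{I_d} are the white-panel and dark-current
#' reference frames. The result is deliberately not clipped to \[0, 1\]:
#' sensor noise can push individual pixels slightly past the white level,
#' and clipping is a preprocessing decision, not part of the correction.
#'
#' @param raw a raw-DN [hypercube()].
#' @param refs a [reference_frames()] object; full-frame or line references.
#' @return A reflectance hypercube of the same shape.
#' @examples
#' wl <- make_wavelength_grid(400, 700, 3)
#' raw <- hypercube(array(5, c(2, 2, 3)), wl, "raw")
#' refs <- reference_frames(array(9, c(2, 2, 3)), array(1, c(2, 2, 3)))
#' calibrate_reflectance(raw, refs)$values[1, 1, 1]  # 0.5
#' @export
calibrate_reflectance <- function(raw, refs) {
  if (!inherits(raw, "hypercube")) stop("'raw' must be a hypercube")
  if (raw$kind != "raw") stop("'raw' must be of kind \"raw\"")
  if (!inherits(refs, "reference_frames"))
    stop("'refs' must be a reference_frames object")
  d <- dim(raw$values)
  white <- broadcast_ref(refs$white, d)
  dark <- broadcast_ref(refs$dark, d)
  denom <- white - dark
  bad <- which(denom == 0)
  if (length(bad) > 0L) {
    ijk <- arrayInd(bad[1L], d)
    stop(sprintf(
      "white - dark is zero at pixel (%d, %d), band %d (%.1f nm): cannot calibrate",
      ijk[1], ijk[2], ijk[3], raw$wavelengths[ijk[3]]))
  }
  hypercube((raw$values - dark) / denom, raw$wavelengths, kind = "reflectance")
}
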