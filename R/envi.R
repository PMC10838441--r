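# ENVI header + flat-binary cube I/O. No installed package reads this
# layout, so the (small) format is handled here directly. Only the fields
# needed to reconstruct a cube are interpreted; unknown header keys are
# ignored on read and omitted on write.

# ENVI data type codes handled: 1 byte, 2 int16, 4 float32, 5 float64,
# 12 uint16
.envi_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# internal: parse an ENVI header file into a named list of strings
parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1L]))
    stop(sprintf("'%s' is not an ENVI header (missing ENVI magic line)", hdr_path))
  fields <- list()
  lines <- txt[-1L]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
    }
    fields[[key]] <- trimws(val)
    i <- i + 1L
  }
  fields
}

#' Read a hyperspectral cube in ENVI format
#'
#' Reads an ENVI header (`.hdr`) plus companion flat-binary file. BIL, BIP
#' and BSQ interleaves and data types 1 (byte), 2 (int16), 4 (float32),
#' 5 (float64) and 12 (uint16) are supported. The header must carry the
#' `samples`, `lines`, `bands`, `data type`, `interleave` and `wavelength`
#' fields.
#'
#' @param path path to the `.hdr` file, or to the binary file if a sibling
#'   `<path>.hdr` exists.
#' @param kind cube kind passed to [hypercube()]; default `"reflectance"`.
#' @return A [hypercube()].
#' @export
read_cube <- function(path, kind = c("reflectance", "raw")) {
  kind <- match.arg(kind)
  if (grepl("\\.hdr$", path)) {
    hdr_path <- path
    bin_path <- sub("\\.hdr$", "", path)
  } else {
    hdr_path <- paste0(path, ".hdr")
    bin_path <- path
  }
  if (!file.exists(hdr_path)) stop(sprintf("header file '%s' not found", hdr_path))
  if (!file.exists(bin_path)) stop(sprintf("binary file '%s' not found", bin_path))
  h <- parse_envi_header(hdr_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave", "wavelength"))
    if (is.null(h[[key]]))
      stop(sprintf("ENVI header '%s' is missing required field '%s'", hdr_path, key))
  samples <- as.integer(h[["samples"]])
  lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  interleave <- tolower(h[["interleave"]])
  dtype <- .envi_types[[h[["data type"]]]]
  if (is.null(dtype))
    stop(sprintf("unsupported ENVI data type %s", h[["data type"]]))
  wl <- as.numeric(strsplit(h[["wavelength"]], ",", fixed = TRUE)[[1L]])
  if (length(wl) != bands)
    stop(sprintf("header lists %d wavelengths for %d bands", length(wl), bands))
  n <- samples * lines * bands
  raw <- readBin(bin_path, what = dtype$what, n = n, size = dtype$size,
                 signed = dtype$signed, endian = "little")
  if (length(raw) != n)
    stop(sprintf("binary file '%s' holds %d values, expected %d",
                 bin_path, length(raw), n))
  # reshape to lines x samples x bands; fastest-varying index first
  vals <- switch(interleave,
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop(sprintf("unsupported interleave '%s'", interleave))
  )
  hypercube(vals, wl, kind = kind)
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path>` (flat binary, little-endian) and `<path>.hdr`. Values are
#' stored as float64 (`data type = 5`) so that a write/read round trip is
#' bit-exact.
#'
#' @param cube a [hypercube()].
#' @param path output path for the binary file; the header gains `.hdr`.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  interleave <- match.arg(interleave)
  if (!inherits(cube, "hypercube")) stop("'cube' must be a hypercube")
  d <- dim(cube$values)  # lines, samples, bands
  ord <- switch(interleave,
    bsq = c(2L, 1L, 3L),
    bil = c(2L, 3L, 1L),
    bip = c(3L, 2L, 1L)
  )
  flat <- as.vector(aperm(cube$values, ord))
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 15), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 8L, endian = "little")
  invisible(path)
}
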