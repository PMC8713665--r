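#' Multispectral datacube
#'
#' An H x W x B stack of grayscale band images in detector counts, plus
#' acquisition metadata. Band order matches the filter bank.
#'
#' @param bands Numeric H x W x B array (a matrix is promoted to B = 1),
#'   intensities >= 0.
#' @param meta List of metadata: typically `band_centres_nm`, `fwhm_nm`,
#'   `exposure_ms`, `gain_db`, `timestamp`, optionally `sensor_max`
#'   (saturation level in counts).
#' @return An object of class `datacube`.
#' @export
datacube <- function(bands, meta = list()) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  if (any(bands < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(list(bands = bands, meta = meta), class = "datacube")
}

#' @export
print.datacube <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<datacube> %d x %d px, %d bands\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.datacube <- function(x) dim(x$bands)

n_bands <- function(cube) dim(cube$bands)[3]

check_same_geometry <- function(a, b, what) {
  if (!identical(dim(a$bands), dim(b$bands)))
    stop(sprintf("%s: shape/band mismatch (%s vs %s)", what,
                 paste(dim(a$bands), collapse = "x"),
                 paste(dim(b$bands), collapse = "x")))
}

#' Subtract a dark frame from a raw stack
#'
#' Per-pixel, per-band subtraction of the dark stack recorded with the
#' illumination off; negative differences are clipped to zero.
#'
#' @param raw,dark [datacube()]s of identical shape and band order.
#' @return A [datacube()] of corrected counts; `raw`'s metadata is kept.
#' @export
dark_correct <- function(raw, dark) {
  stopifnot(inherits(raw, "datacube"), inherits(dark, "datacube"))
  check_same_geometry(raw, dark, "dark_correct")
  datacube(pmax(raw$bands - dark$bands, 0), raw$meta)
}

#' Reflectance cube
#'
#' Dimensionless reflectance per pixel per band; values above 1 are
#' possible under noise. `invalid` flags pixels where calibration was
#' degenerate (white-minus-dark at or below `eps_denom` in any band, or
#' saturated counts when the sensor maximum is known).
#'
#' @param bands Numeric H x W x B array, finite.
#' @param invalid Logical H x W matrix.
#' @param meta Metadata list.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(bands, invalid = NULL, meta = list()) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  if (any(!is.finite(bands))) stop("reflectance must be finite everywhere")
  if (is.null(invalid))
    invalid <- matrix(FALSE, dim(bands)[1], dim(bands)[2])
  stopifnot(identical(dim(invalid), dim(bands)[1:2]))
  structure(list(bands = bands, invalid = invalid, meta = meta),
            class = "reflectance_cube")
}

#' Convert calibrated counts to reflectance
#'
#' `R = (I_raw - I_dark) / (I_white - I_dark)` per pixel per band, the
#' white stack being an image of a diffuse reflectance standard. Pixels
#' whose denominator is <= `eps_denom` counts in any band are flagged
#' invalid (reflectance set to 0 there); pixels saturated in the raw stack
#' (counts >= `meta$sensor_max`) are flagged too.
#'
#' @param raw Raw [datacube()] (not yet dark-corrected).
#' @param white White-reference [datacube()].
#' @param dark Dark [datacube()].
#' @param eps_denom Minimum usable white-minus-dark signal, in counts.
#' @return A [reflectance_cube()].
#' @export
to_reflectance <- function(raw, white, dark, eps_denom = 1) {
  stopifnot(inherits(raw, "datacube"), inherits(white, "datacube"),
            inherits(dark, "datacube"))
  check_same_geometry(raw, white, "to_reflectance")
  check_same_geometry(raw, dark, "to_reflectance")
  denom <- white$bands - dark$bands
  if (all(white$bands == 0)) stop("fully-zero white reference frame")
  bad <- apply(denom <= eps_denom, c(1, 2), any)
  if (!is.null(raw$meta$sensor_max))
    bad <- bad | apply(raw$bands >= raw$meta$sensor_max, c(1, 2), any)
  denom[denom <= eps_denom] <- 1  # placeholder; flagged invalid anyway
  r <- pmax(raw$bands - dark$bands, 0) / denom
  r[array(bad, dim(r))] <- 0
  reflectance_cube(r, bad, raw$meta)
}

#' Absorbance cube
#'
#' Base-10 absorbance per pixel per band, finite everywhere (reflectance
#' floored before the log). Carries forward the calibration invalid mask.
#'
#' @param bands Numeric H x W x B array.
#' @param invalid Logical H x W matrix.
#' @param meta Metadata list.
#' @return An object of class `absorbance_cube`.
#' @export
absorbance_cube <- function(bands, invalid = NULL, meta = list()) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  if (any(!is.finite(bands))) stop("absorbance must be finite everywhere")
  if (is.null(invalid))
    invalid <- matrix(FALSE, dim(bands)[1], dim(bands)[2])
  structure(list(bands = bands, invalid = invalid, meta = meta),
            class = "absorbance_cube")
}

#' Convert reflectance to absorbance
#'
#' `A = -log10(max(R, r_floor))`; the floor keeps absorbance finite at
#' zero-reflectance pixels without distorting the usable dynamic range of
#' a 12-bit sensor.
#'
#' @param r A [reflectance_cube()].
#' @param r_floor Reflectance floor, default `1e-4` (absorbance cap 4).
#' @return An [absorbance_cube()].
#' @export
to_absorbance <- function(r, r_floor = 1e-4) {
  stopifnot(inherits(r, "reflectance_cube"), r_floor > 0)
  absorbance_cube(-log10(pmax(r$bands, r_floor)), r$invalid, r$meta)
}

#' Write a datacube as a multi-page TIFF with a YAML sidecar
#'
#' One 32-bit float grayscale page per band, band order preserved;
#' metadata goes to `<path>.yaml`. Counts are stored divided by `scale`
#' since TIFF float samples are conventionally kept in `[0, 1]`.
#'
#' @param cube A [datacube()].
#' @param path Output TIFF path.
#' @param scale Count value mapped to 1.0 in the file (default 4096,
#'   one above a 12-bit sensor's maximum).
#' @return `path`, invisibly.
#' @export
write_datacube <- function(cube, path, scale = 4096) {
  stopifnot(inherits(cube, "datacube"))
  pages <- lapply(seq_len(n_bands(cube)),
                  function(b) cube$bands[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- cube$meta
  meta$count_scale <- scale
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a datacube written by [write_datacube()]
#'
#' @param path TIFF path; the `<path>.yaml` sidecar is read if present.
#' @return A [datacube()] in detector counts.
#' @export
read_datacube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  scale <- if (is.null(meta$count_scale)) 4096 else meta$count_scale
  meta$count_scale <- NULL
  bands <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) bands[, , b] <- pages[[b]] * scale
  datacube(bands, meta)
}
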