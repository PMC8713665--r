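#' Project a ground-truth reflectance curve onto the camera bands
#'
#' Convolves a wavelength-resolved reflectance curve (e.g. a spectrometer
#' measurement of a colour-checker panel) with each filter passband,
#' making it directly comparable with per-band imaging reflectance. Uses
#' the same transmission-weighted mean as [band_convolve()].
#'
#' @param curve List with `wavelengths` (nm) and `reflectance` values
#'   covering every passband.
#' @param bank A [filter_bank()].
#' @return Numeric vector of B band reflectances.
#' @export
truth_to_bands <- function(curve, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  s <- list(wavelengths = curve$wavelengths, epsilon = curve$reflectance)
  vapply(bank$filters, function(f) band_convolve(s, f), numeric(1))
}

#' Mean per-band reflectance over a panel
#'
#' @param r A [reflectance_cube()].
#' @param panel_mask Logical H x W mask of one colour-checker panel,
#'   nonempty.
#' @return Numeric vector of B per-band means over the mask.
#' @export
panel_mean_reflectance <- function(r, panel_mask) {
  stopifnot(inherits(r, "reflectance_cube"))
  if (!any(panel_mask)) stop("empty panel mask")
  apply(r$bands, 3, function(b) mean(b[panel_mask]))
}

#' Bland-Altman agreement between paired measurements
#'
#' Differences `d = x - y`, their mean (bias) and the 95% limits of
#' agreement `mean(d) +/- 1.96 * sd(d)` (sample standard deviation).
#' The per-pair table carries `(x + y)/2` against `d` for the classic
#' plot, plus the optional grouping (e.g. band wavelength) for a
#' per-wavelength difference view.
#'
#' @param x,y Paired numeric vectors of equal length >= 2 (e.g. imaging
#'   vs spectrometer band reflectances).
#' @param group Optional grouping labels per pair.
#' @return List of class `agreement_summary`: `mean_difference`,
#'   `limits_of_agreement` (the half-width, >= 0), `table` (data frame
#'   `mean`, `difference`, `group`).
#' @export
bland_altman <- function(x, y, group = NULL) {
  if (length(x) != length(y)) stop("paired vectors must match in length")
  stopifnot(length(x) >= 2L)
  d <- x - y
  structure(list(
    mean_difference = mean(d),
    limits_of_agreement = 1.96 * stats::sd(d),
    table = data.frame(mean = (x + y) / 2, difference = d,
                       group = if (is.null(group)) NA else group)),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> bias %.4g, 95%% limits +/- %.4g (n = %d)\n",
    x$mean_difference, x$limits_of_agreement, nrow(x$table)))
  invisible(x)
}

#' Run the colour-card spectral validation
#'
#' Compares per-panel mean imaging reflectance against band-convolved
#' ground-truth curves and summarises the agreement Bland-Altman style,
#' grouped by band centre wavelength.
#'
#' @param r A [reflectance_cube()] of the imaged card.
#' @param panel_labels Integer H x W label image (0 = background,
#'   k = panel k).
#' @param truth_curves List of curves (each with `wavelengths`,
#'   `reflectance`), one per panel, in label order.
#' @param bank The [filter_bank()].
#' @return List: `summary` (an `agreement_summary`), `per_panel` (data
#'   frame of panel, band, wavelength, MSI and truth reflectance).
#' @export
validate_card <- function(r, panel_labels, truth_curves, bank) {
  ids <- sort(unique(panel_labels[panel_labels > 0]))
  stopifnot(length(truth_curves) >= length(ids))
  ctr <- band_centres(bank)
  rows <- do.call(rbind, lapply(ids, function(k) {
    data.frame(panel = k, band = seq_along(ctr), wavelength_nm = ctr,
               msi = panel_mean_reflectance(r, panel_labels == k),
               truth = truth_to_bands(truth_curves[[k]], bank))
  }))
  list(summary = bland_altman(rows$msi, rows$truth,
                              group = rows$wavelength_nm),
       per_panel = rows)
}
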