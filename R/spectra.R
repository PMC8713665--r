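#' Chromophore extinction spectrum
#'
#' Container for the wavelength-resolved extinction coefficient of one
#' chromophore on a strictly increasing, uniform wavelength grid. Units are
#' relative: concentrations estimated against these spectra are relative
#' concentrations, consistent across chromophores sharing one scale.
#'
#' @param name Chromophore label, e.g. `"HbO2"`.
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing and uniformly spaced.
#' @param epsilon Numeric vector of extinction coefficients, finite and
#'   non-negative, one per wavelength.
#' @return An object of class `extinction_spectrum`.
#' @export
extinction_spectrum <- function(name, wavelengths, epsilon) {
  stopifnot(is.character(name), length(name) == 1L,
            length(wavelengths) == length(epsilon),
            length(wavelengths) >= 2L)
  dw <- diff(wavelengths)
  if (any(dw <= 0)) stop("wavelength grid must be strictly increasing")
  if (max(dw) - min(dw) > 1e-9 * mean(dw))
    stop("wavelength grid must be uniform")
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stop("epsilon must be finite and >= 0")
  structure(list(name = name, wavelengths = as.numeric(wavelengths),
                 epsilon = as.numeric(epsilon)),
            class = "extinction_spectrum")
}

#' @export
print.extinction_spectrum <- function(x, ...) {
  cat(sprintf("<extinction_spectrum> %s: %d points, %.0f-%.0f nm\n",
              x$name, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Gaussian spectral filter
#'
#' One narrow-band interference filter of the filter wheel, with a Gaussian
#' transmission profile parameterised by its centre wavelength and full
#' width at half maximum.
#'
#' @param centre_nm Centre wavelength in nm.
#' @param fwhm_nm Full width at half maximum in nm, > 0.
#' @param peak Peak transmission as a fraction in (0, 1].
#' @return An object of class `spectral_filter`.
#' @export
spectral_filter <- function(centre_nm, fwhm_nm, peak = 0.9) {
  stopifnot(is.finite(centre_nm), is.finite(fwhm_nm), fwhm_nm > 0,
            is.finite(peak), peak > 0, peak <= 1)
  structure(list(centre_nm = centre_nm, fwhm_nm = fwhm_nm, peak = peak),
            class = "spectral_filter")
}

#' Ordered bank of spectral filters
#'
#' The filters defining the camera's spectral sampling, in datacube band
#' order. Centre wavelengths must be strictly increasing.
#'
#' @param filters List of [spectral_filter()] objects.
#' @return An object of class `filter_bank`.
#' @export
filter_bank <- function(filters) {
  stopifnot(length(filters) >= 1L,
            all(vapply(filters, inherits, logical(1), "spectral_filter")))
  ctr <- vapply(filters, `[[`, numeric(1), "centre_nm")
  if (any(diff(ctr) <= 0))
    stop("filter centre wavelengths must be strictly increasing")
  structure(list(filters = filters), class = "filter_bank")
}

#' @export
length.filter_bank <- function(x) length(x$filters)

#' @export
print.filter_bank <- function(x, ...) {
  ctr <- band_centres(x)
  cat(sprintf("<filter_bank> %d bands: %s nm\n", length(x),
              paste(ctr, collapse = ", ")))
  invisible(x)
}

#' Band centre wavelengths of a filter bank
#' @param bank A [filter_bank()].
#' @return Numeric vector of centre wavelengths in nm, in band order.
#' @export
band_centres <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  vapply(bank$filters, `[[`, numeric(1), "centre_nm")
}

#' Default eight-filter bank
#'
#' Eight Gaussian passbands at 470, 500, 520, 546, 560, 577, 600 and 645 nm
#' (FWHM 20 nm, peak transmission 0.9), straddling the HbO2/Hb difference
#' features in the visible range. Override per instrument with
#' [read_filter_bank()].
#'
#' @param fwhm_nm FWHM applied to every filter (nm).
#' @param peak Peak transmission applied to every filter.
#' @return A [filter_bank()] of length 8.
#' @export
default_filter_bank <- function(fwhm_nm = 20, peak = 0.9) {
  centres <- c(470, 500, 520, 546, 560, 577, 600, 645)
  filter_bank(lapply(centres, spectral_filter, fwhm_nm = fwhm_nm,
                     peak = peak))
}

#' Read a filter bank from a YAML config
#'
#' The config holds a `filters:` list with `centre_nm`, `fwhm_nm` and
#' optional `peak` per entry; list order is datacube band order.
#'
#' @param path Path to the YAML file.
#' @return A [filter_bank()].
#' @export
read_filter_bank <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$filters)) stop("config has no 'filters' block")
  filter_bank(lapply(cfg$filters, function(f)
    spectral_filter(f$centre_nm, f$fwhm_nm,
                    if (is.null(f$peak)) 0.9 else f$peak)))
}

#' Gaussian transmission curve of a filter
#'
#' Evaluates `peak * exp(-4*log(2) * (lambda - centre)^2 / fwhm^2)` on a
#' wavelength grid. By construction the value is `peak` at the centre and
#' `peak/2` at `centre +/- fwhm/2`.
#'
#' The grid must capture at least `min_coverage` of the filter's total
#' transmission weight (analytic Gaussian integral); a grid missing the
#' passband raises a domain-coverage error. Edge filters of a bank may
#' have one tail truncated by the grid — only the captured shape enters
#' the band convolution, identically in the forward model and the fit.
#'
#' @param filter A [spectral_filter()].
#' @param wavelengths Uniform wavelength grid (nm).
#' @param min_coverage Minimum captured fraction of the passband weight
#'   (default 0.5).
#' @return Numeric vector of transmissions, same length as `wavelengths`.
#' @export
gaussian_transmission <- function(filter, wavelengths, min_coverage = 0.5) {
  stopifnot(inherits(filter, "spectral_filter"))
  tr <- filter$peak *
    exp(-4 * log(2) * (wavelengths - filter$centre_nm)^2 / filter$fwhm_nm^2)
  dl <- if (length(wavelengths) > 1) wavelengths[2] - wavelengths[1] else 1
  total <- filter$peak * filter$fwhm_nm * sqrt(pi / (4 * log(2)))
  if (sum(tr) * dl < min_coverage * total)
    stop(sprintf(
      "wavelength grid does not cover the %g nm passband", filter$centre_nm))
  tr
}

#' Band-convolve a spectrum with one filter passband
#'
#' Transmission-weighted mean of the spectrum over the passband,
#' `sum(eps * T) / sum(T)`. Coarsely tabulated spectra (grid step above
#' `resolution_nm`) are first refined by linear interpolation so the
#' quadrature error of the tabulation step is negligible against the
#' passband shape. White-reference normalisation cancels illuminant and
#' throughput scale, so only the passband shape matters: the result is
#' independent of peak transmission.
#'
#' @param spectrum An [extinction_spectrum()] (or any object with
#'   `wavelengths` and `epsilon` fields) covering the passband.
#' @param filter A [spectral_filter()].
#' @param resolution_nm Internal quadrature step (default 0.1 nm).
#' @return Scalar band coefficient.
#' @export
band_convolve <- function(spectrum, filter, resolution_nm = 0.1) {
  wl <- spectrum$wavelengths
  eps <- spectrum$epsilon
  if (length(wl) > 1 && wl[2] - wl[1] > resolution_nm) {
    fine <- seq(wl[1], wl[length(wl)], by = resolution_nm)
    eps <- stats::approx(wl, eps, fine)$y
    wl <- fine
  }
  tr <- gaussian_transmission(filter, wl)
  w <- sum(tr)
  if (w <= 0) stop("degenerate filter: zero total transmission weight")
  sum(eps * tr) / w
}

#' Build the band-convolved design matrix
#'
#' For each filter of the bank, convolves the HbO2, Hb and fat extinction
#' spectra with the passband and appends a constant column of ones for the
#' wavelength-independent scattering offset G. This is the design matrix of
#' the per-pixel modified Beer-Lambert regression
#' `A_b = [HbO2] e1_b + [Hb] e2_b + [Fat] e3_b + G`.
#'
#' @param bank A [filter_bank()].
#' @param spectra List of three [extinction_spectrum()] objects on a common
#'   grid, in order HbO2, Hb, Fat.
#' @return A B x 4 numeric matrix with columns `hbo2`, `hb`, `fat`, `g`,
#'   an attribute `condition_number`, and class `design_matrix`. A
#'   rank-deficient result triggers a warning.
#' @export
build_design_matrix <- function(bank, spectra) {
  stopifnot(inherits(bank, "filter_bank"), length(spectra) == 3L)
  for (s in spectra[-1])
    if (!isTRUE(all.equal(s$wavelengths, spectra[[1]]$wavelengths)))
      stop("all spectra must share one wavelength grid")
  X <- cbind(
    vapply(bank$filters, function(f) band_convolve(spectra[[1]], f),
           numeric(1)),
    vapply(bank$filters, function(f) band_convolve(spectra[[2]], f),
           numeric(1)),
    vapply(bank$filters, function(f) band_convolve(spectra[[3]], f),
           numeric(1)),
    1)
  colnames(X) <- c("hbo2", "hb", "fat", "g")
  rk <- qr(X)$rank
  if (rk < min(dim(X)))
    warning(sprintf("ill-conditioned filter bank: design rank %d < %d",
                    rk, min(dim(X))))
  attr(X, "condition_number") <- kappa(X, exact = TRUE)
  class(X) <- c("design_matrix", class(X))
  X
}

#' Packaged chromophore extinction spectra
#'
#' Loads the three delimited-text extinction tables shipped with the
#' package (450-650 nm, 1 nm grid). These are smooth synthetic stand-ins
#' that reproduce the qualitative features of the tabulated haemoglobin and
#' lipid compilations (HbO2 beta/alpha peaks near 542/577 nm, the broad Hb
#' peak near 555 nm, Hb exceeding HbO2 beyond 600 nm, lipid absorption
#' confined to the blue end), normalised to a common relative scale.
#'
#' @return Named list of [extinction_spectrum()]: `hbo2`, `hb`, `fat`.
#' @export
packaged_spectra <- function() {
  rd <- function(file, name) {
    tab <- utils::read.delim(system.file("extdata", file,
                                         package = "oximsi",
                                         mustWork = TRUE))
    extinction_spectrum(name, tab$wavelength_nm, tab$epsilon)
  }
  list(hbo2 = rd("extinction_hbo2_synthetic.tsv", "HbO2"),
       hb   = rd("extinction_hb_synthetic.tsv", "Hb"),
       fat  = rd("extinction_fat_synthetic.tsv", "Fat"))
}

#' Read an extinction table from delimited text
#'
#' Expects columns `wavelength_nm` and `epsilon` (tab- or
#' whitespace-delimited, header row).
#'
#' @param path Path to the table.
#' @param name Chromophore label; defaults to the file name.
#' @return An [extinction_spectrum()].
#' @export
read_extinction <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = TRUE)
  extinction_spectrum(name, tab$wavelength_nm, tab$epsilon)
}
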