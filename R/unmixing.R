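#' Per-pixel tissue property maps
#'
#' Result of unmixing an absorbance cube against the modified Beer-Lambert
#' design matrix: relative concentration maps for HbO2, Hb and fat, the
#' scattering offset G, the coefficient of determination of each fit, and
#' (after [derive_so2_thb()]) SO2 in percent and total haemoglobin.
#' Excluded pixels carry the sentinel 0 in every derived map plus
#' `valid = FALSE`; quantitative analyses use the mask, never the sentinel.
#'
#' @param hbo2,hb,fat,g_offset,cod Numeric H x W matrices.
#' @param valid Logical H x W matrix.
#' @param so2,thb Optional numeric H x W matrices (filled by
#'   [derive_so2_thb()]).
#' @param filtered Logical, whether [apply_validity_filter()] has run.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(hbo2, hb, fat, g_offset, cod, valid,
                        so2 = NULL, thb = NULL, filtered = FALSE) {
  d <- dim(hbo2)
  for (m in list(hb, fat, g_offset, cod, valid))
    stopifnot(identical(dim(m), d))
  structure(list(hbo2 = hbo2, hb = hb, fat = fat, g_offset = g_offset,
                 cod = cod, so2 = so2, thb = thb, valid = valid,
                 filtered = filtered),
            class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat(sprintf("<tissue_maps> %d x %d px, %.1f%% valid%s\n",
              nrow(x$hbo2), ncol(x$hbo2), 100 * mean(x$valid),
              if (is.null(x$so2)) "" else ", SO2/THb derived"))
  invisible(x)
}

# shared vectorised least-squares core: A is B x N, X is B x 4
fit_ls <- function(Amat, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  coef <- qr.coef(qx, Amat)                      # 4 x N
  res <- Amat - X %*% coef
  ss_res <- colSums(res^2)
  mu <- colMeans(Amat)
  ss_tot <- colSums(Amat^2) - nrow(Amat) * mu^2
  tol <- 1e-15 * pmax(1, colSums(Amat^2))
  cod <- ifelse(ss_tot <= tol,
                ifelse(ss_res <= tol, 1, 0),
                pmin(pmax(1 - ss_res / ss_tot, 0), 1))
  list(coef = coef, cod = cod)
}

#' Fit the modified Beer-Lambert model at one pixel
#'
#' Unconstrained ordinary least squares of a B-band absorbance vector on
#' the four design columns (band-convolved HbO2, Hb and fat extinctions
#' plus the constant scattering offset). The coefficient of determination
#' is `1 - SS_res/SS_tot` with `SS_tot` taken about the band mean; a
#' zero-variance vector gets CoD 1 if the residual is also zero, else 0.
#'
#' @param absorbance Numeric vector of length B (B >= 4).
#' @param design A [build_design_matrix()] result (B x 4, full rank).
#' @return Named list: `hbo2`, `hb`, `fat`, `g`, `cod`.
#' @export
fit_pixel <- function(absorbance, design) {
  stopifnot(length(absorbance) == nrow(design), nrow(design) >= 4L)
  if (any(!is.finite(absorbance)))
    stop("non-finite absorbance vector")
  f <- fit_ls(matrix(absorbance, ncol = 1), unclass(design))
  cf <- unname(f$coef[, 1])
  list(hbo2 = cf[1], hb = cf[2], fat = cf[3], g = cf[4],
       cod = unname(f$cod[1]))
}

#' Unmix every pixel of an absorbance cube
#'
#' Applies [fit_pixel()]'s regression at every spatial location in one
#' vectorised pass. Pixels with non-finite absorbance, or flagged invalid
#' by calibration, are marked invalid with zero coefficients.
#'
#' @param a An [absorbance_cube()] with B bands matching the design rows.
#' @param design A [build_design_matrix()] result.
#' @return A [tissue_maps()] (validity filter not yet applied; `valid`
#'   reflects only fit feasibility).
#' @export
fit_cube <- function(a, design) {
  stopifnot(inherits(a, "absorbance_cube"))
  d <- dim(a$bands)
  if (d[3] != nrow(design))
    stop("cube band count does not match design rows")
  npix <- d[1] * d[2]
  Amat <- t(matrix(a$bands, nrow = npix, ncol = d[3]))  # B x N
  ok <- colSums(!is.finite(Amat)) == 0 & !as.vector(a$invalid)
  coef <- matrix(0, 4, npix)
  cod <- numeric(npix)
  if (any(ok)) {
    f <- fit_ls(Amat[, ok, drop = FALSE], unclass(design))
    coef[, ok] <- f$coef
    cod[ok] <- f$cod
  }
  shape <- function(v) matrix(v, d[1], d[2])
  tissue_maps(shape(coef[1, ]), shape(coef[2, ]), shape(coef[3, ]),
              shape(coef[4, ]), shape(cod), shape(ok))
}

#' Exclude poorly-fitted and non-physical pixels
#'
#' A pixel is kept only if its coefficient of determination is at least
#' `cod_threshold` and all three concentration estimates are
#' non-negative. Excluded pixels are assigned the sentinel 0 in the
#' concentration (and any derived) maps and `valid = FALSE`; the
#' scattering offset is left untouched.
#'
#' @param maps A [tissue_maps()].
#' @param cod_threshold CoD cut-off in `[0, 1]`, default 0.9.
#' @return The filtered [tissue_maps()].
#' @export
apply_validity_filter <- function(maps, cod_threshold = 0.9) {
  stopifnot(inherits(maps, "tissue_maps"),
            cod_threshold >= 0, cod_threshold <= 1)
  keep <- maps$valid & maps$cod >= cod_threshold &
    maps$hbo2 >= 0 & maps$hb >= 0 & maps$fat >= 0
  z <- function(m) { m[!keep] <- 0; m }
  maps$hbo2 <- z(maps$hbo2); maps$hb <- z(maps$hb); maps$fat <- z(maps$fat)
  if (!is.null(maps$so2)) maps$so2 <- z(maps$so2)
  if (!is.null(maps$thb)) maps$thb <- z(maps$thb)
  maps$valid <- keep
  maps$filtered <- TRUE
  maps
}

#' Derive SO2 and total haemoglobin maps
#'
#' `THb = HbO2 + Hb`; `SO2 = 100 * HbO2 / THb` (percent) where the pixel
#' is valid and THb is positive. Pixels with zero THb become invalid
#' (oxygen saturation is undefined without haemoglobin).
#'
#' @param maps A [tissue_maps()], normally after [apply_validity_filter()].
#' @return The [tissue_maps()] with `so2` and `thb` filled in.
#' @export
derive_so2_thb <- function(maps) {
  stopifnot(inherits(maps, "tissue_maps"))
  thb <- maps$hbo2 + maps$hb
  keep <- maps$valid & thb > 0
  so2 <- matrix(0, nrow(thb), ncol(thb))
  so2[keep] <- 100 * maps$hbo2[keep] / thb[keep]
  thb[!keep] <- 0
  maps$so2 <- so2
  maps$thb <- thb
  maps$valid <- keep
  maps
}

#' Calibrate-and-unmix convenience pipeline
#'
#' Runs reflectance calibration, absorbance conversion, per-pixel
#' unmixing, the validity filter and SO2/THb derivation in order.
#'
#' @param raw,white,dark [datacube()]s.
#' @param design A [build_design_matrix()] result.
#' @param cod_threshold CoD cut-off, default 0.9.
#' @param r_floor Reflectance floor for the log, default `1e-4`.
#' @return A [tissue_maps()] with SO2/THb derived.
#' @export
unmix_stack <- function(raw, white, dark, design, cod_threshold = 0.9,
                        r_floor = 1e-4) {
  r <- to_reflectance(raw, white, dark)
  a <- to_absorbance(r, r_floor)
  m <- fit_cube(a, design)
  m <- apply_validity_filter(m, cod_threshold)
  derive_so2_thb(m)
}

#' Smooth colour-camera response at given wavelengths
#'
#' Packaged Gaussian approximation of a typical Bayer-pattern camera's
#' red/green/blue spectral response (centres 610/540/465 nm). Exact curves
#' vary by sensor; substitute your own weight matrix in [rgb_from_cube()]
#' if known.
#'
#' @param wavelengths Numeric vector in nm.
#' @return 3 x length(wavelengths) matrix, rows R, G, B.
#' @export
rgb_camera_response <- function(wavelengths) {
  rbind(r = exp(-((wavelengths - 610) / 45)^2),
        g = exp(-((wavelengths - 540) / 40)^2),
        b = exp(-((wavelengths - 465) / 30)^2))
}

#' Reconstruct an RGB image from a reflectance cube
#'
#' Each colour plane is a weighted sum of the bands, the weights being a
#' colour-camera response evaluated at the band centres and normalised so
#' that a unit-reflectance cube maps to white. Output clipped to `[0, 1]`.
#'
#' @param r A [reflectance_cube()].
#' @param bank The [filter_bank()] giving band centres.
#' @param response Function of wavelengths returning a 3 x B weight
#'   matrix; default [rgb_camera_response()].
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
rgb_from_cube <- function(r, bank, response = rgb_camera_response) {
  stopifnot(inherits(r, "reflectance_cube"))
  d <- dim(r$bands)
  if (length(bank) != d[3]) stop("band count does not match bank")
  w <- response(band_centres(bank))
  w <- w / rowSums(w)                 # unit reflectance -> white
  flat <- matrix(r$bands, d[1] * d[2], d[3])
  out <- pmin(pmax(flat %*% t(w), 0), 1)
  array(out, c(d[1], d[2], 3))
}

#' SO2 pseudocolour map
#'
#' Piecewise-linear dark-blue -> green -> yellow ramp over 0-100% SO2,
#' matching the convention of perfusion maps in the surgical-imaging
#' literature (low saturation dark/blue, high saturation bright yellow).
#'
#' @param so2 Numeric vector/matrix of SO2 percentages in `[0, 100]`.
#' @return N x 3 matrix of RGB values in `[0, 1]` (N = length(so2)).
#' @export
so2_colormap <- function(so2) {
  ramp <- grDevices::colorRamp(
    c("#00007F", "#0055CC", "#00AA66", "#AAEE22", "#FFFF00"))
  ramp(pmin(pmax(as.vector(so2), 0), 100) / 100) / 255
}

#' Overlay the SO2 map on an RGB reconstruction
#'
#' Alpha blend `out = alpha * colormap(SO2) + (1 - alpha) * rgb` with the
#' transparency weighted by total haemoglobin:
#' `alpha = clip(THb / THb_ref, 0, 1)`, `THb_ref` the 99th percentile of
#' valid THb. Invalid pixels show the plain RGB image.
#'
#' @param rgb H x W x 3 array from [rgb_from_cube()].
#' @param maps A [tissue_maps()] with SO2/THb derived.
#' @param colormap Function mapping SO2 percent to N x 3 RGB; default
#'   [so2_colormap()].
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
overlay_so2 <- function(rgb, maps, colormap = so2_colormap) {
  stopifnot(inherits(maps, "tissue_maps"), !is.null(maps$thb))
  d <- dim(rgb)
  stopifnot(identical(d[1:2], dim(maps$thb)), d[3] == 3L)
  thb_ref <- if (any(maps$valid))
    stats::quantile(maps$thb[maps$valid], 0.99, names = FALSE) else Inf
  alpha <- as.vector(pmin(pmax(maps$thb / thb_ref, 0), 1))
  alpha[!as.vector(maps$valid)] <- 0
  cm <- colormap(maps$so2)
  flat <- matrix(rgb, d[1] * d[2], 3)
  array(alpha * cm + (1 - alpha) * flat, d)
}

#' Export tissue maps as grayscale images plus summary text
#'
#' Writes one grayscale TIFF per map (SO2 scaled so 100% maps to 1.0, CoD
#' as-is, concentrations normalised by their valid maximum), the validity
#' mask, and a delimited-text summary of valid-pixel statistics.
#'
#' @param maps A [tissue_maps()] with SO2/THb derived.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tissue_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "tissue_maps"), !is.null(maps$so2))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) {
    mx <- if (any(maps$valid)) max(m[maps$valid], 1e-12) else 1
    pmin(pmax(m / mx, 0), 1)
  }
  tiff::writeTIFF(maps$so2 / 100, file.path(dir, "so2.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(pmin(pmax(maps$cod, 0), 1), file.path(dir, "cod.tif"),
                  bits.per.sample = 32L)
  for (nm in c("hbo2", "hb", "fat", "thb"))
    tiff::writeTIFF(norm01(maps[[nm]]),
                    file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L)
  tiff::writeTIFF(maps$valid * 1, file.path(dir, "valid.tif"),
                  bits.per.sample = 32L)
  v <- maps$valid
  summ <- data.frame(
    map = c("so2_percent", "thb_rel", "cod"),
    mean = c(mean(maps$so2[v]), mean(maps$thb[v]), mean(maps$cod[v])),
    median = c(stats::median(maps$so2[v]), stats::median(maps$thb[v]),
               stats::median(maps$cod[v])),
    n_valid = sum(v))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
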