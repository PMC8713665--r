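#' Phantom tissue scene
#'
#' Ground-truth concentration maps and geometry for a synthetic scene
#' that the forward model turns into raw acquisition stacks. All
#' concentrations are relative units (meaningful within one scene).
#'
#' @param hbo2,hb,fat,g_map Numeric H x W maps, non-negative (g_map may
#'   be any finite offset).
#' @param tissue_mask Logical H x W mask of analysable tissue.
#' @param labels Integer H x W region labels (0 background, 1 serosa,
#'   2 fat border).
#' @param axis Optional list with `start`, `end` (`c(x, y)` pixels) of
#'   the segment axis.
#' @param truth Optional list of extra ground-truth records (per-division
#'   SO2, etc.).
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(hbo2, hb, fat, g_map, tissue_mask,
                          labels = NULL, axis = NULL, truth = list()) {
  d <- dim(hbo2)
  for (m in list(hb, fat, g_map)) stopifnot(identical(dim(m), d))
  stopifnot(all(is.finite(hbo2)), all(hbo2 >= 0), all(hb >= 0),
            all(fat >= 0), all(is.finite(g_map)))
  if (is.null(labels)) labels <- matrix(as.integer(tissue_mask), d[1], d[2])
  structure(list(hbo2 = hbo2, hb = hb, fat = fat, g_map = g_map,
                 tissue_mask = tissue_mask, labels = labels, axis = axis,
                 truth = truth, shape = d),
            class = "phantom_scene")
}

#' Acquisition model for synthetic sequences
#'
#' Sensor and motion parameters used when rendering a phantom into noisy,
#' jittered acquisition bursts.
#'
#' @param bank [filter_bank()] (default [default_filter_bank()]).
#' @param white_level White-reference signal level in counts (default
#'   3500, comfortably inside a 12-bit range).
#' @param dark_level Dark offset in counts (default 64).
#' @param noise_sigma_rel Multiplicative noise sigma as a fraction of
#'   signal (default 0.01, approximating shot noise at high counts).
#' @param jitter_sigma_px Standard deviation of the per-stack translation
#'   jitter in pixels (default 2, emulating respiratory drift).
#' @param n_stacks Stacks per burst (default 6).
#' @param seed Integer seed; mandatory for any stochastic output.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(bank = default_filter_bank(),
                              white_level = 3500, dark_level = 64,
                              noise_sigma_rel = 0.01,
                              jitter_sigma_px = 2, n_stacks = 6,
                              seed = 1L) {
  stopifnot(noise_sigma_rel >= 0, jitter_sigma_px >= 0, n_stacks >= 1,
            is.finite(seed))
  structure(list(bank = bank, white_level = white_level,
                 dark_level = dark_level,
                 noise_sigma_rel = noise_sigma_rel,
                 jitter_sigma_px = jitter_sigma_px,
                 n_stacks = as.integer(n_stacks),
                 seed = as.integer(seed)),
            class = "acquisition_model")
}

# per-band transmission-weighted means of each extinction curve,
# computed by direct fine-grid summation at 0.1 nm (deliberately not via
# build_design_matrix: the forward model and the unmixing fit must reach
# the band coefficients through separate code paths so round-trip tests
# exercise both).
band_weights_finegrid <- function(bank, spectra) {
  wl0 <- spectra[[1]]$wavelengths
  wl <- seq(wl0[1], wl0[length(wl0)], by = min(0.1, wl0[2] - wl0[1]))
  eps <- lapply(spectra, function(s)
    stats::approx(s$wavelengths, s$epsilon, wl)$y)
  t(vapply(bank$filters, function(f) {
    tr <- gaussian_transmission(f, wl)
    vapply(eps, function(e) sum(e * tr) / sum(tr), numeric(1))
  }, numeric(3)))                                      # B x 3
}

#' Render a phantom scene into raw/dark/white stacks
#'
#' Runs the modified Beer-Lambert model forwards: per-band absorbance
#' from the wavelength-resolved chromophore spectra convolved with each
#' passband, reflectance `R = 10^(-A)`, and detector counts
#' `dark + R * (white - dark)`. Noise-free; the output is exactly
#' consistent with the calibration + unmixing inverse.
#'
#' @param scene A [phantom_scene()].
#' @param bank A [filter_bank()].
#' @param white_level,dark_level Counts for the uniform white and dark
#'   stacks.
#' @param spectra Chromophore spectra (default [packaged_spectra()]).
#' @return List: `raw`, `dark`, `white` ([datacube()]s), `reflectance`
#'   (the noise-free H x W x B reflectance array).
#' @export
forward_cube <- function(scene, bank = default_filter_bank(),
                         white_level = 3500, dark_level = 64,
                         spectra = packaged_spectra()) {
  stopifnot(inherits(scene, "phantom_scene"))
  w <- band_weights_finegrid(bank, spectra)
  d <- c(scene$shape, length(bank))
  refl <- array(0, d)
  for (b in seq_len(length(bank))) {
    A <- scene$hbo2 * w[b, 1] + scene$hb * w[b, 2] +
      scene$fat * w[b, 3] + scene$g_map
    refl[, , b] <- 10^(-A)
  }
  meta <- list(band_centres_nm = band_centres(bank),
               exposure_ms = 33, gain_db = 0)
  mk <- function(a) datacube(a, meta)
  list(raw = mk(dark_level + refl * (white_level - dark_level)),
       dark = mk(array(dark_level, d)),
       white = mk(array(white_level, d)),
       reflectance = refl)
}

#' Bowel-segment phantom with a longitudinal SO2 profile
#'
#' A horizontal tube of serosal tissue whose axial SO2 follows the given
#' per-division profile (half-open binning `[k*L/n, (k+1)*L/n)` along the
#' axis, matching [build_rois()]), optionally flanked by fat-rich border
#' strips emulating mesenteric adipose tissue (high SO2, as observed for
#' mesenteric fat), over a zero-haemoglobin background. The axis length
#' is chosen as a multiple of the division count so division boundaries
#' fall exactly between pixel columns.
#'
#' @param so2_profile Numeric vector of per-division SO2 percentages in
#'   `[0, 100]`, proximal to distal.
#' @param thb_level Total haemoglobin in the serosa (relative units,
#'   default 1).
#' @param fat_border Add flanking adipose strips (default TRUE).
#' @param shape `c(H, W)` in pixels (default `c(256, 512)`).
#' @param serosa_fat Fat concentration within the serosa (default 0.1).
#' @param g_level Scattering offset within tissue (default 0.1).
#' @return A [phantom_scene()]; `truth$so2_per_division` holds the
#'   profile and `truth$division_map` the per-pixel division index
#'   (0 = outside).
#' @export
bowel_phantom <- function(so2_profile, thb_level = 1.0,
                          fat_border = TRUE, shape = c(256, 512),
                          serosa_fat = 0.1, g_level = 0.1) {
  stopifnot(all(so2_profile >= 0), all(so2_profile <= 100))
  n <- length(so2_profile)
  H <- shape[1]; W <- shape[2]
  L <- n * max(floor(0.85 * W / n), 1)
  x0 <- floor((W - L) / 2)
  yc <- floor(H / 2)
  half_h <- floor(H / 5)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  t_ax <- X - x0
  in_x <- t_ax >= 0 & t_ax <= L
  serosa <- in_x & abs(Y - yc) <= half_h
  division <- matrix(0L, H, W)
  division[serosa] <- pmin(floor(t_ax[serosa] / (L / n)), n - 1) + 1L
  zero <- matrix(0, H, W)
  hbo2 <- zero; hb <- zero; fat <- zero; g <- zero
  so2 <- so2_profile[ifelse(division > 0, division, 1)] / 100
  hbo2[serosa] <- (thb_level * so2)[serosa]
  hb[serosa] <- (thb_level * (1 - so2))[serosa]
  fat[serosa] <- serosa_fat
  g[serosa] <- g_level
  labels <- matrix(0L, H, W)
  labels[serosa] <- 1L
  if (fat_border) {
    strip <- floor(H / 10)
    border <- in_x & abs(Y - yc) > half_h & abs(Y - yc) <= half_h + strip
    fat[border] <- 0.8
    hbo2[border] <- 0.3 * thb_level * 0.9
    hb[border] <- 0.3 * thb_level * 0.1
    g[border] <- g_level
    labels[border] <- 2L
  }
  phantom_scene(hbo2, hb, fat, g, serosa, labels,
                axis = list(start = c(x0, yc), end = c(x0 + L, yc)),
                truth = list(so2_per_division = so2_profile,
                             division_map = division,
                             axis_length_px = L))
}

#' Noisy, jittered acquisition burst from a phantom
#'
#' Renders the scene noise-free, then produces `n_stacks` raw cubes each
#' translated by an i.i.d. Gaussian per-stack jitter (band-limited
#' Fourier resampling, identical across the bands of a stack) and
#' corrupted by multiplicative Gaussian noise
#' `counts * (1 + sigma * N(0,1))`, clipped at zero. The first stack is
#' the unshifted reference. Fully reproducible from the model's seed.
#'
#' @param scene A [phantom_scene()].
#' @param model An [acquisition_model()].
#' @param spectra Chromophore spectra (default [packaged_spectra()]).
#' @return List: `sequence` ([cube_sequence()] of raw stacks), `shifts`
#'   (n x 2 matrix of applied `(dy, dx)`), `dark`, `white`
#'   ([datacube()]s), `forward` (the noise-free [forward_cube()] output).
#' @export
noisy_sequence <- function(scene, model, spectra = packaged_spectra()) {
  stopifnot(inherits(model, "acquisition_model"))
  fw <- forward_cube(scene, model$bank, model$white_level,
                     model$dark_level, spectra)
  set.seed(model$seed)
  n <- model$n_stacks
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  if (n > 1 && model$jitter_sigma_px > 0)
    shifts[-1, ] <- stats::rnorm(2 * (n - 1), 0, model$jitter_sigma_px)
  d <- dim(fw$raw$bands)
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    b <- fw$raw$bands
    if (any(shifts[i, ] != 0))
      for (k in seq_len(d[3]))
        b[, , k] <- fourier_shift(b[, , k], shifts[i, 1], shifts[i, 2])
    if (model$noise_sigma_rel > 0)
      b <- b * (1 + model$noise_sigma_rel *
                  array(stats::rnorm(prod(d)), d))
    stacks[[i]] <- datacube(pmax(b, 0), fw$raw$meta)
  }
  list(sequence = cube_sequence(stacks), shifts = shifts,
       dark = fw$dark, white = fw$white, forward = fw)
}

#' Synthetic colour-checker card
#'
#' A grid of uniform panels with smooth random reflectance curves
#' (bounded to `[0.05, 0.95]`), rendered into raw/dark/white stacks
#' through the same passband convolution as the forward model, with the
#' ground-truth curves exported alongside. Stand-in fixture for a
#' physical colour checker plus spectrometer.
#'
#' @param n_panels Number of panels (>= 1, default 12).
#' @param seed Integer seed for the random curves.
#' @param bank [filter_bank()] (default [default_filter_bank()]).
#' @param panel_px Side length of one square panel in pixels.
#' @param white_level,dark_level Counts for the reference stacks.
#' @return List: `raw`, `dark`, `white` ([datacube()]s), `labels`
#'   (integer panel label image), `truth_curves` (list of
#'   `wavelengths`/`reflectance` curves per panel), `bank`.
#' @export
synthetic_colour_card <- function(n_panels = 12, seed = 1L,
                                  bank = default_filter_bank(),
                                  panel_px = 24, white_level = 3500,
                                  dark_level = 64) {
  stopifnot(n_panels >= 1)
  set.seed(seed)
  wl <- 450:650
  curves <- lapply(seq_len(n_panels), function(i) {
    r <- stats::runif(1, 0.25, 0.75) +
      colSums((stats::runif(3, 0, 0.15) / (1:3)) *
                cos(outer(1:3, 2 * pi * (wl - 450) / 200) +
                      stats::runif(3, 0, 2 * pi)))
    list(wavelengths = wl,
         reflectance = pmin(pmax(r, 0.05), 0.95))
  })
  ncol_p <- ceiling(sqrt(n_panels))
  nrow_p <- ceiling(n_panels / ncol_p)
  H <- nrow_p * panel_px; W <- ncol_p * panel_px
  labels <- matrix(0L, H, W)
  refl <- array(0, c(H, W, length(bank)))
  for (i in seq_len(n_panels)) {
    rr <- (i - 1) %/% ncol_p
    cc <- (i - 1) %% ncol_p
    ys <- rr * panel_px + seq_len(panel_px)
    xs <- cc * panel_px + seq_len(panel_px)
    labels[ys, xs] <- i
    rb <- truth_to_bands(curves[[i]], bank)
    for (b in seq_along(rb)) refl[ys, xs, b] <- rb[b]
  }
  meta <- list(band_centres_nm = band_centres(bank))
  list(raw = datacube(dark_level + refl * (white_level - dark_level),
                      meta),
       dark = datacube(array(dark_level, dim(refl)), meta),
       white = datacube(array(white_level, dim(refl)), meta),
       labels = labels, truth_curves = curves, bank = bank)
}
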