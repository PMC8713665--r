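# shared fixtures, built once per run
oxi_spectra <- packaged_spectra()
oxi_bank <- default_filter_bank()
oxi_design <- build_design_matrix(
  oxi_bank, list(oxi_spectra$hbo2, oxi_spectra$hb, oxi_spectra$fat))

# uniform-tissue scene covering the whole frame (no geometry, no border)
uniform_scene <- function(hbo2, hb, fat = 0.1, g = 0.1,
                          shape = c(16, 16)) {
  m <- function(v) matrix(v, shape[1], shape[2])
  phantom_scene(m(hbo2), m(hb), m(fat), m(g),
                tissue_mask = m(TRUE) > 0)
}

# full pipeline on a noise-free rendering of a scene
unmix_scene <- function(scene, design = oxi_design, bank = oxi_bank) {
  fw <- forward_cube(scene, bank)
  unmix_stack(fw$raw, fw$white, fw$dark, design)
}

# ROI spec matching a bowel phantom's axis, 1 cm per division
phantom_profile_spec <- function(scene, n = 10, roi_width = 80) {
  profile_spec(scene$axis$start, scene$axis$end, n_divisions = n,
               roi_width = roi_width,
               mm_per_pixel = 10 * n / scene$truth$axis_length_px)
}
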