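test_that("an exact linear mixture is recovered with CoD 1", {
  X <- unclass(oxi_design)
  truth <- c(0.7, 0.3, 0.1, 0.2)
  f <- fit_pixel(as.vector(X %*% truth), oxi_design)
  expect_equal(c(f$hbo2, f$hb, f$fat, f$g), truth, tolerance = 1e-10)
  expect_equal(f$cod, 1)
})

test_that("a constant absorbance vector loads only the offset", {
  f <- fit_pixel(rep(0.42, 8), oxi_design)
  expect_equal(c(f$hbo2, f$hb, f$fat), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(f$g, 0.42, tolerance = 1e-10)
  expect_equal(f$cod, 1)                       # zero variance, zero residual
})

test_that("random fits agree with a normal-equations oracle", {
  set.seed(11)
  X <- unclass(oxi_design)
  for (i in 1:25) {
    a <- stats::rnorm(8)
    f <- fit_pixel(a, oxi_design)
    beta <- solve(t(X) %*% X, t(X) %*% a)      # independent solver
    expect_equal(c(f$hbo2, f$hb, f$fat, f$g), as.vector(beta),
                 tolerance = 1e-8)
    res <- a - X %*% beta
    expect_equal(f$cod, 1 - sum(res^2) / sum((a - mean(a))^2),
                 tolerance = 1e-8)
  }
})

test_that("fit_cube matches fit_pixel on uniform and 1 x 1 cubes", {
  a_vec <- as.vector(unclass(oxi_design) %*% c(0.5, 0.5, 0.2, 0.1)) +
    c(0.01, -0.02, 0, 0.01, 0, -0.01, 0.02, 0)
  single <- fit_pixel(a_vec, oxi_design)
  cube <- absorbance_cube(aperm(array(a_vec, c(8, 6, 7)), c(2, 3, 1)))
  m <- fit_cube(cube, oxi_design)
  expect_equal(unique(as.vector(m$hbo2)), single$hbo2, tolerance = 1e-12)
  expect_equal(unique(as.vector(m$cod)), single$cod, tolerance = 1e-12)
  tiny <- fit_cube(absorbance_cube(array(a_vec, c(1, 1, 8))), oxi_design)
  expect_equal(tiny$hb[1, 1], single$hb, tolerance = 1e-12)
})

test_that("calibration-invalid pixels come out invalid with zeroed maps", {
  sc <- uniform_scene(0.6, 0.2, shape = c(4, 4))
  fw <- forward_cube(sc)
  r <- to_reflectance(fw$raw, fw$white, fw$dark)
  r$invalid[2, 2] <- TRUE
  m <- fit_cube(to_absorbance(r), oxi_design)
  expect_false(m$valid[2, 2])
  expect_equal(m$hbo2[2, 2], 0)
  expect_true(all(m$valid[-6]))
})

test_that("validity filter excludes low CoD and negative concentrations", {
  mk <- function() {
    o <- matrix(1, 2, 3)
    tissue_maps(hbo2 = o * 0.5, hb = o * 0.3, fat = o * 0.1,
                g_offset = o * 0.2, cod = o, valid = o > 0)
  }
  m <- mk()
  m$cod[1, 1] <- 0.89        # below threshold -> excluded
  m$cod[1, 2] <- 0.9         # exactly at threshold -> kept
  m$hb[2, 1] <- -0.01        # negative concentration -> excluded
  f <- apply_validity_filter(m, 0.9)
  expect_false(f$valid[1, 1])
  expect_true(f$valid[1, 2])
  expect_false(f$valid[2, 1])
  expect_equal(f$hbo2[1, 1], 0)
  expect_equal(f$hb[2, 1], 0)
  expect_equal(f$g_offset[1, 1], 0.2)          # offset untouched
  # all-clean maps pass through unchanged
  clean <- apply_validity_filter(mk(), 0.9)
  expect_true(all(clean$valid))
  expect_equal(clean$hbo2, mk()$hbo2)
})

test_that("SO2 and THb derivation", {
  o <- matrix(1, 1, 4)
  m <- tissue_maps(hbo2 = matrix(c(0.3, 0.4, 3, 0), 1, 4),
                   hb = matrix(c(0.3, 0, 1, 0), 1, 4),
                   fat = o * 0, g_offset = o * 0, cod = o, valid = o > 0)
  d <- derive_so2_thb(m)
  expect_equal(d$so2[1, 1:3], c(50, 100, 75))
  expect_equal(d$thb[1, 3], 4)
  expect_false(d$valid[1, 4])                  # zero THb -> invalid
  expect_equal(d$so2[1, 4], 0)
})

test_that("SO2 is invariant to illumination scale, absorbed by G", {
  sc <- uniform_scene(0.6, 0.3, fat = 0.2, g = 0.1, shape = c(5, 5))
  fw <- forward_cube(sc)
  base <- unmix_stack(fw$raw, fw$white, fw$dark, oxi_design)
  for (k in c(0.5, 2)) {
    r <- to_reflectance(fw$raw, fw$white, fw$dark)
    rk <- reflectance_cube(r$bands * k, r$invalid, r$meta)
    mk <- derive_so2_thb(apply_validity_filter(
      fit_cube(to_absorbance(rk), oxi_design)))
    expect_equal(mk$so2, base$so2, tolerance = 1e-8)
    expect_equal(mk$hbo2, base$hbo2, tolerance = 1e-8)
    expect_equal(mk$g_offset, base$g_offset - log10(k), tolerance = 1e-8)
  }
})

test_that("RGB reconstruction maps unit reflectance to white", {
  d <- c(3, 4, 8)
  unit <- reflectance_cube(array(1, d))
  expect_equal(rgb_from_cube(unit, oxi_bank), array(1, c(3, 4, 3)))
  expect_equal(rgb_from_cube(reflectance_cube(array(0, d)), oxi_bank),
               array(0, c(3, 4, 3)))
  red_only <- array(0, d); red_only[, , 8] <- 1     # 645 nm band
  rgb <- rgb_from_cube(reflectance_cube(red_only), oxi_bank)
  expect_gt(rgb[1, 1, 1], rgb[1, 1, 2])
  expect_gt(rgb[1, 1, 1], rgb[1, 1, 3])
})

test_that("SO2 overlay blends by THb-weighted transparency", {
  H <- 4; W <- 4
  rgb <- array(0.5, c(H, W, 3))
  o <- matrix(1, H, W)
  mk_maps <- function(thb) {
    m <- tissue_maps(hbo2 = thb, hb = thb * 0, fat = o * 0,
                     g_offset = o * 0, cod = o, valid = o > 0,
                     so2 = o * 100, thb = thb)
    m$valid <- thb > 0
    m
  }
  # zero THb everywhere -> pure RGB
  expect_equal(overlay_so2(rgb, mk_maps(o * 0)), rgb)
  # saturated alpha at so2 = 100 -> pure colormap endpoint
  full <- overlay_so2(rgb, mk_maps(o))
  expect_equal(full[1, 1, ], as.vector(so2_colormap(100)))
  # alpha = 0.5 -> exact channel-wise midpoint
  thb <- o; thb[1, 1] <- 0.5
  half <- overlay_so2(rgb, mk_maps(thb), colormap = so2_colormap)
  expect_equal(half[1, 1, ],
               0.5 * as.vector(so2_colormap(100)) + 0.5 * rgb[1, 1, ],
               tolerance = 1e-12)
})

test_that("tissue maps export to grayscale images plus a summary table", {
  sc <- bowel_phantom(rep(75, 5), shape = c(24, 60))
  m <- unmix_scene(sc)
  dir <- withr::local_tempdir()
  write_tissue_maps(m, dir)
  expect_true(all(file.exists(file.path(
    dir, c("so2.tif", "cod.tif", "valid.tif", "summary.tsv")))))
  back <- tiff::readTIFF(file.path(dir, "so2.tif")) * 100
  expect_equal(back[sc$tissue_mask][1], 75, tolerance = 1e-4)
  summ <- read.delim(file.path(dir, "summary.tsv"))
  expect_equal(summ$mean[summ$map == "so2_percent"],
               mean(m$so2[m$valid]), tolerance = 1e-6)
})
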