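test_that("horizontal-axis ROIs are disjoint equal rectangles", {
  sp <- profile_spec(c(11, 50), c(91, 50), n_divisions = 10,
                     roi_width = 20)
  rois <- build_rois(sp, c(100, 100))
  expect_length(rois, 10)
  counts <- vapply(rois, sum, numeric(1))
  expect_true(all(counts == counts[1]))
  overlap <- Reduce(`+`, rois)
  expect_true(all(overlap <= 1))                    # disjoint
  # ROI 1 sits at the proximal end
  expect_true(any(rois[[1]][, 12]))
  expect_false(any(rois[[1]][, 30]))
})

test_that("ROIs are equivariant under a 90-degree scene rotation", {
  sp <- profile_spec(c(15, 20), c(75, 60), n_divisions = 5,
                     roi_width = 12)
  rois <- build_rois(sp, c(80, 90))
  sp_t <- profile_spec(rev(sp$start_point), rev(sp$end_point),
                       n_divisions = 5, roi_width = 12)
  rois_t <- build_rois(sp_t, c(90, 80))
  for (k in 1:5) expect_equal(rois_t[[k]], t(rois[[k]]))
})

test_that("oblique-axis membership matches a point-in-rectangle oracle", {
  sp <- profile_spec(c(10.3, 12.7), c(50.3, 52.7), n_divisions = 4,
                     roi_width = 9)
  rois <- build_rois(sp, c(64, 64))
  d <- sp$end_point - sp$start_point
  L <- sqrt(sum(d^2)); u <- d / L
  for (k in c(1, 3)) {
    lo <- (k - 1) * L / 4; hi <- k * L / 4
    oracle <- matrix(FALSE, 64, 64)
    for (y in 1:64) for (x in 1:64) {
      p <- c(x, y) - sp$start_point
      tt <- sum(p * u)
      ss <- p[1] * (-u[2]) + p[2] * u[1]
      oracle[y, x] <- tt >= lo && tt < hi && abs(ss) <= 4.5
    }
    expect_equal(rois[[k]], oracle)
  }
})

test_that("degenerate or out-of-image axes are rejected", {
  expect_error(profile_spec(c(5, 5), c(5, 5)), "degenerate")
  sp <- profile_spec(c(-3, 5), c(50, 5))
  expect_error(build_rois(sp, c(20, 60)), "inside")
})

test_that("threshold masking recovers the phantom tube", {
  sc <- bowel_phantom(rep(75, 10), fat_border = FALSE, shape = c(64, 128))
  fw <- forward_cube(sc)
  a <- to_absorbance(to_reflectance(fw$raw, fw$white, fw$dark))
  m <- tissue_mask(a$bands[, , 4], method = "threshold")
  dice <- 2 * sum(m & sc$tissue_mask) / (sum(m) + sum(sc$tissue_mask))
  expect_gte(dice, 0.95)
})

test_that("provided masks pass through; empty images warn", {
  given <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(tissue_mask(given, method = "provided"), given)
  expect_warning(tissue_mask(matrix(0, 8, 8), method = "threshold"),
                 "empty")
})

test_that("watershed masking keeps the seeded region", {
  img <- matrix(0, 40, 80)
  img[8:32, 5:35] <- 1          # two separated blobs
  img[8:32, 45:75] <- 1
  m <- tissue_mask(img, method = "watershed", seeds = list(c(10, 20)))
  expect_true(m[20, 10])
  expect_false(any(m[, 45:75]))
})

test_that("uniform phantom gives flat ROI statistics", {
  sc <- bowel_phantom(rep(75, 10), shape = c(64, 128))
  m <- unmix_scene(sc)
  pr <- profile_statistics(m, build_rois(phantom_profile_spec(sc),
                                         sc$shape), sc$tissue_mask)
  expect_equal(pr$mean_so2, rep(75, 10), tolerance = 1e-9)
  expect_equal(pr$median_so2, rep(75, 10), tolerance = 1e-9)
  expect_equal(pr$q75 - pr$q25, rep(0, 10), tolerance = 1e-9)
  expect_true(all(pr$n > 0))
  expect_lte(sum(pr$n), sum(sc$tissue_mask))
})

test_that("ROI statistics use only valid in-mask pixels", {
  sc <- bowel_phantom(seq(82, 70, length.out = 10), shape = c(64, 128))
  m <- unmix_scene(sc)
  rois <- build_rois(phantom_profile_spec(sc), sc$shape)
  pr <- profile_statistics(m, rois, sc$tissue_mask)
  # flipping the sentinel at an invalid pixel never changes statistics
  out <- which(!m$valid)[1]
  m2 <- m; m2$so2[out] <- 999
  expect_equal(profile_statistics(m2, rois, sc$tissue_mask), pr)
  # two-pixel ROI arithmetic
  tiny <- list(matrix(FALSE, nrow(m$so2), ncol(m$so2)))
  pick <- which(m$valid & sc$tissue_mask)[1:2]
  m3 <- m; m3$so2[pick] <- c(60, 80)
  tiny[[1]][pick] <- TRUE
  pt <- profile_statistics(m3, tiny, sc$tissue_mask)
  expect_equal(pt$mean_so2, 70)
  expect_equal(pt$median_so2, 70)
  expect_equal(pt$n, 2L)
  # empty ROI -> NA statistics, n = 0
  pe <- profile_statistics(m, list(matrix(FALSE, 64, 128)))
  expect_true(is.na(pe$mean_so2))
  expect_equal(pe$n, 0L)
})

test_that("monotone axial profiles give monotone ROI means", {
  sc <- bowel_phantom(seq(85, 65, length.out = 10), shape = c(64, 128))
  m <- unmix_scene(sc)
  pr <- profile_statistics(m, build_rois(phantom_profile_spec(sc),
                                         sc$shape), sc$tissue_mask)
  expect_true(all(diff(pr$mean_so2) < 0))
})

test_that("temporal stability summarises repeated acquisitions", {
  sc <- bowel_phantom(rep(75, 5), shape = c(32, 64))
  m <- unmix_scene(sc)
  roi <- sc$tissue_mask
  ts <- temporal_stability(list(m, m, m), roi)
  expect_equal(ts$means, rep(75, 3), tolerance = 1e-9)
  expect_equal(ts$sd, 0)
  # single valid pixel reduces to a per-pixel trace
  one <- matrix(FALSE, 32, 64)
  one[which(m$valid & roi)[1]] <- TRUE
  m2 <- m; m2$so2[one] <- 60
  expect_equal(temporal_stability(list(m, m2), one)$means, c(75, 60))
})

test_that("clinical decisions bin onto the correct ROI", {
  sc <- bowel_phantom(seq(82, 70, length.out = 10), shape = c(64, 128))
  m <- unmix_scene(sc)
  sp <- phantom_profile_spec(sc)           # 1 cm per division
  pr <- profile_statistics(m, build_rois(sp, sc$shape), sc$tissue_mask)
  expect_equal(decision_alignment(pr, 3.5, sp)$roi_index, 4L)
  expect_equal(decision_alignment(pr, 0, sp)$roi_index, 1L)  # half-open
  expect_equal(decision_alignment(pr, 10, sp)$roi_index, 10L)
  expect_error(decision_alignment(pr, 11, sp), "outside")
  # decreasing profile, decision in ROI 1 -> above the segment median
  al <- decision_alignment(pr, 0.5, sp)
  expect_true(al$above_median)
  expect_gt(al$margin_percent, 0)
})

test_that("profile specs round-trip through YAML and results through TSV", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(start_point = c(10, 20), end_point = c(90, 20),
                        n_divisions = 8, roi_width = 30,
                        mm_per_pixel = 1.25, decision_cm = 3.5), path)
  sp <- read_profile_spec(path)
  expect_equal(sp$n_divisions, 8L)
  expect_equal(attr(sp, "decision_cm"), 3.5)
  sc <- bowel_phantom(rep(75, 5), shape = c(32, 64))
  pr <- profile_statistics(unmix_scene(sc),
                           build_rois(phantom_profile_spec(sc, n = 5),
                                      sc$shape), sc$tissue_mask)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_profile_result(pr, out)
  expect_equal(read.delim(out)$mean_so2, pr$mean_so2, tolerance = 1e-9)
})
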