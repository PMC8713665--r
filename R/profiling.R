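#' Longitudinal profile specification
#'
#' Defines the bowel-segment axis and its subdivision into
#' regions-of-interest: a line from the proximal to the distal end,
#' split into `n_divisions` equal half-open bins, with one rectangular
#' ROI per bin aligned perpendicular to the axis.
#'
#' @param start_point,end_point Numeric `c(x, y)` pixel coordinates of
#'   the axis endpoints (x = column, y = row), proximal first.
#' @param n_divisions Number of divisions along the axis (default 10).
#' @param roi_width ROI extent perpendicular to the axis, in pixels.
#' @param roi_length ROI extent along the axis, in pixels; default the
#'   full division length (ROIs tile the axis without gaps).
#' @param mm_per_pixel Physical scale, for mapping clinical-decision
#'   positions in cm onto the axis.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(start_point, end_point, n_divisions = 10,
                         roi_width = 40, roi_length = NULL,
                         mm_per_pixel = NULL) {
  stopifnot(length(start_point) == 2L, length(end_point) == 2L,
            n_divisions >= 1, roi_width > 0)
  if (all(start_point == end_point)) stop("degenerate zero-length axis")
  structure(list(start_point = as.numeric(start_point),
                 end_point = as.numeric(end_point),
                 n_divisions = as.integer(n_divisions),
                 roi_width = roi_width, roi_length = roi_length,
                 mm_per_pixel = mm_per_pixel),
            class = "profile_spec")
}

#' Read a profile spec from a YAML config
#'
#' Expects keys `start_point`, `end_point` (each `[x, y]`), and
#' optionally `n_divisions`, `roi_width`, `roi_length`, `mm_per_pixel`,
#' `decision_cm`.
#'
#' @param path Path to the YAML file.
#' @return A [profile_spec()]; any `decision_cm` is attached as an
#'   attribute of the same name.
#' @export
read_profile_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  sp <- profile_spec(unlist(cfg$start_point), unlist(cfg$end_point),
                     n_divisions = cfg$n_divisions %||% 10,
                     roi_width = cfg$roi_width %||% 40,
                     roi_length = cfg$roi_length,
                     mm_per_pixel = cfg$mm_per_pixel)
  attr(sp, "decision_cm") <- cfg$decision_cm
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

axis_geometry <- function(spec) {
  d <- spec$end_point - spec$start_point
  len <- sqrt(sum(d^2))
  u <- d / len
  list(len = len, u = u, v = c(-u[2], u[1]))
}

#' Build the perpendicular ROI masks along the axis
#'
#' Splits the axis into `n_divisions` equal half-open bins
#' `[k*L/n, (k+1)*L/n)` and returns one boolean mask per bin: a rectangle
#' centred on the bin midpoint, `roi_length` pixels along the axis and
#' `roi_width` across it, clipped to the image bounds. With the default
#' `roi_length` the masks tile the axis and are disjoint.
#'
#' @param spec A [profile_spec()] with endpoints inside the image.
#' @param image_shape `c(H, W)` of the maps the ROIs will index.
#' @return List of `n_divisions` logical H x W matrices, proximal first.
#' @export
build_rois <- function(spec, image_shape) {
  stopifnot(inherits(spec, "profile_spec"), length(image_shape) >= 2L)
  H <- image_shape[1]; W <- image_shape[2]
  inside <- function(p) p[1] >= 1 && p[1] <= W && p[2] >= 1 && p[2] <= H
  if (!inside(spec$start_point) || !inside(spec$end_point))
    stop("axis endpoints must lie inside the image")
  g <- axis_geometry(spec)
  n <- spec$n_divisions
  len_along <- spec$roi_length %||% (g$len / n)
  X <- matrix(rep(seq_len(W), each = H), H, W)   # column = x
  Y <- matrix(rep(seq_len(H), W), H, W)          # row = y
  t_ax <- (X - spec$start_point[1]) * g$u[1] +
          (Y - spec$start_point[2]) * g$u[2]
  s_ax <- (X - spec$start_point[1]) * g$v[1] +
          (Y - spec$start_point[2]) * g$v[2]
  across <- abs(s_ax) <= spec$roi_width / 2
  lapply(seq_len(n) - 1L, function(k) {
    mid <- (k + 0.5) * g$len / n
    t_ax >= mid - len_along / 2 & t_ax < mid + len_along / 2 & across
  })
}

#' Segment the analysable tissue surface
#'
#' Produces the binary mask restricting quantitative analysis to exposed
#' serosal tissue. Three methods: `"provided"` passes a caller-supplied
#' mask through; `"threshold"` applies a global threshold (Otsu if not
#' given) and keeps the largest connected component; `"watershed"`
#' splits the thresholded foreground by watershed on the distance map and
#' keeps the regions containing the seed points (or the largest region
#' when no seeds are given).
#'
#' @param img Numeric matrix (an RGB-luminance or single-band image), or
#'   for `"provided"` the mask itself / a TIFF path.
#' @param method `"provided"`, `"threshold"` or `"watershed"`.
#' @param threshold Optional global threshold for the foreground, on the
#'   scale of `img`.
#' @param seeds Optional list of `c(x, y)` seed points for `"watershed"`.
#' @return Logical H x W mask; an empty result triggers a warning.
#' @export
tissue_mask <- function(img, method = c("threshold", "watershed",
                                        "provided"),
                        threshold = NULL, seeds = NULL) {
  method <- match.arg(method)
  if (method == "provided") {
    m <- if (is.character(img)) tiff::readTIFF(img) > 0.5 else img > 0.5
    if (is.logical(img)) m <- img
    if (!any(m)) warning("provided tissue mask is empty")
    return(m)
  }
  rng <- range(img)
  norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(norm))
         else (threshold - rng[1]) / max(diff(rng), 1e-12)
  fg <- norm > thr
  if (!any(fg)) { warning("tissue mask is empty"); return(fg) }
  lab <- if (method == "threshold") EBImage::bwlabel(fg)
         else EBImage::watershed(EBImage::distmap(fg))
  lab <- as.matrix(EBImage::imageData(lab))
  keep <- if (method == "watershed" && !is.null(seeds)) {
    unique(vapply(seeds, function(p) lab[p[2], p[1]], numeric(1)))
  } else {
    tb <- table(lab[lab > 0])
    as.numeric(names(tb)[which.max(tb)])
  }
  m <- matrix(lab %in% keep[keep > 0], nrow(img), ncol(img))
  if (!any(m)) warning("tissue mask is empty")
  m
}

#' Per-ROI SO2 statistics along the segment
#'
#' For each ROI, statistics of the SO2 map over the pixels in
#' `ROI & mask & valid`. Quartiles use linear interpolation between
#' order statistics. ROIs with no contributing pixels report `NA`
#' statistics and `n = 0`.
#'
#' @param maps A [tissue_maps()] with SO2 derived.
#' @param rois List of logical masks from [build_rois()].
#' @param mask Optional logical tissue mask (default: all pixels).
#' @return A `profile_result` data frame with columns `roi` (1 =
#'   proximal), `mean_so2`, `median_so2`, `q25`, `q75`, `n`.
#' @export
profile_statistics <- function(maps, rois, mask = NULL) {
  stopifnot(inherits(maps, "tissue_maps"), !is.null(maps$so2))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(maps$so2), ncol(maps$so2))
  rows <- lapply(seq_along(rois), function(k) {
    sel <- rois[[k]] & mask & maps$valid
    v <- maps$so2[sel]
    if (length(v) == 0)
      return(data.frame(roi = k, mean_so2 = NA_real_,
                        median_so2 = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, n = 0L))
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    data.frame(roi = k, mean_so2 = mean(v), median_so2 = stats::median(v),
               q25 = q[1], q75 = q[2], n = length(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("profile_result", class(out))
  out
}

#' Acquisition-to-acquisition stability of ROI-mean SO2
#'
#' For a burst of repeated acquisitions of the same organ, the mean SO2
#' over one ROI is computed per acquisition (valid pixels only) and the
#' standard deviation across acquisitions summarises measurement
#' stability.
#'
#' @param maps_list List (>= 2) of [tissue_maps()] with SO2 derived, one
#'   per acquisition, same geometry.
#' @param roi Logical mask of the ROI.
#' @return List: `means` (per-acquisition ROI-mean SO2, in acquisition
#'   order), `sd` (their standard deviation, percentage points).
#' @export
temporal_stability <- function(maps_list, roi) {
  stopifnot(length(maps_list) >= 2L)
  means <- vapply(maps_list, function(m) {
    sel <- roi & m$valid
    if (!any(sel)) return(NA_real_)
    mean(m$so2[sel])
  }, numeric(1))
  list(means = means, sd = stats::sd(means))
}

#' Locate the clinical transection decision on the profile
#'
#' Maps a decision position (cm from the proximal end) onto its ROI via
#' the same half-open binning as [build_rois()], and reports whether that
#' ROI's median SO2 lies above the segment-wide median (the median of the
#' per-ROI medians), with the margin in percentage points.
#'
#' @param result A `profile_result` from [profile_statistics()].
#' @param decision_cm Decision position along the axis, in cm from the
#'   proximal end.
#' @param spec The [profile_spec()] used (must carry `mm_per_pixel`).
#' @return List: `roi_index`, `above_median` (logical), `margin_percent`
#'   (ROI median minus segment median).
#' @export
decision_alignment <- function(result, decision_cm, spec) {
  stopifnot(inherits(spec, "profile_spec"), !is.null(spec$mm_per_pixel))
  g <- axis_geometry(spec)
  len_cm <- g$len * spec$mm_per_pixel / 10
  if (decision_cm < 0 || decision_cm > len_cm)
    stop(sprintf("decision %.2f cm outside the 0-%.2f cm axis",
                 decision_cm, len_cm))
  div_cm <- len_cm / spec$n_divisions
  idx <- min(floor(decision_cm / div_cm) + 1, spec$n_divisions)
  seg_median <- stats::median(result$median_so2, na.rm = TRUE)
  margin <- result$median_so2[result$roi == idx] - seg_median
  list(roi_index = as.integer(idx),
       above_median = isTRUE(margin > 0),
       margin_percent = margin)
}

#' Packaged longitudinal SO2 profile table
#'
#' Ten-position SO2 profiles (percent, proximal to distal at 1 cm
#' spacing) for seven colorectal-surgery patients, with the surgeon's
#' transection-decision position for each. Used as ground-truth input for
#' bowel phantoms and round-trip tests.
#'
#' @return List: `profiles` (10 x 7 numeric matrix, columns P1..P7),
#'   `decisions_cm` (named numeric vector of decision positions).
#' @export
so2_profile_table <- function() {
  tab <- utils::read.delim(system.file("extdata",
                                       "bowel_so2_profiles.tsv",
                                       package = "oximsi",
                                       mustWork = TRUE),
                           stringsAsFactors = FALSE)
  dec <- tab[tab$position_cm == "decision", -1]
  prof <- tab[tab$position_cm != "decision", ]
  m <- as.matrix(prof[, -1])
  rownames(m) <- prof$position_cm
  list(profiles = m, decisions_cm = unlist(dec))
}

#' Export a profile result as delimited text
#'
#' Writes the per-ROI summary table, and optionally a long-format
#' (boxplot-ready) table of the underlying valid SO2 values.
#'
#' @param result A `profile_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
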