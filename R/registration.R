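#' Sequence of sequentially-acquired cubes
#'
#' Ordered list of [datacube()] (or [reflectance_cube()]) stacks sharing
#' shape and band order, e.g. a 3-5 s burst acquired for temporal
#' averaging.
#'
#' @param stacks List of cubes with identical dimensions.
#' @param timestamps Optional numeric acquisition times (seconds).
#' @return An object of class `cube_sequence`.
#' @export
cube_sequence <- function(stacks, timestamps = seq_along(stacks)) {
  stopifnot(length(stacks) >= 1L, length(timestamps) == length(stacks))
  d <- dim(stacks[[1]]$bands)
  for (s in stacks[-1])
    if (!identical(dim(s$bands), d)) stop("stacks must share one shape")
  structure(list(stacks = stacks, timestamps = timestamps),
            class = "cube_sequence")
}

#' @export
length.cube_sequence <- function(x) length(x$stacks)

# signed DFT frequency indices 0,1,...,-1 for length n
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Exact periodic (Fourier) translation of an image
#'
#' Band-limited resampling: multiplies the spectrum by a linear phase so
#' the content moves by `(dy, dx)` pixels (rows down, columns right) with
#' wrap-around at the borders. Subpixel shifts are exact for band-limited
#' content, which makes this the reference warp for registration tests
#' and the phantom generator's jitter model.
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in pixels along rows / columns (may be fractional).
#' @return Shifted matrix of the same size.
#' @export
fourier_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ph <- exp(-2i * pi * (outer(fft_freq(nr) * dy / nr,
                              fft_freq(nc) * dx / nc, "+")))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

#' Estimate the translation between two images
#'
#' Phase correlation in the frequency domain gives the integer shift; the
#' cross-power spectrum is then evaluated on an upsampled grid around the
#' peak (matrix-multiply DFT) for subpixel precision of about 1/`usf`
#' pixel. Returns `c(dy, dx)` such that `moving` matches `reference`
#' translated by `(dy, dx)`; applying the negated shift to `moving`
#' aligns it with `reference`.
#'
#' @param reference,moving Numeric matrices of identical size,
#'   non-constant.
#' @param usf Upsampling factor for the subpixel refinement (default 50,
#'   i.e. 0.02 px grid).
#' @return Numeric `c(dy, dx)` in pixels.
#' @export
estimate_shift <- function(reference, moving, usf = 50) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("cannot register a constant image")
  nr <- nrow(reference); nc <- ncol(reference)
  cp <- stats::fft(reference) * Conj(stats::fft(moving))
  cp <- cp / pmax(Mod(cp), 1e-12)
  r <- Mod(stats::fft(cp, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  # peak at index p corresponds to argument -shift (mod n)
  wrap <- function(p, n) { s <- p - 1; if (s > n / 2) s - n else s }
  s0 <- c(-wrap(pk[1], nr), -wrap(pk[2], nc))
  # upsampled cross-power around the integer estimate
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  sy <- -s0[1] + seq(-1, 1, by = 1 / usf)
  sx <- -s0[2] + seq(-1, 1, by = 1 / usf)
  ky <- exp(2i * pi * outer(sy, fy) / nr)
  kx <- exp(2i * pi * outer(fx, sx) / nc)
  rr <- Mod(ky %*% cp %*% kx)
  pk2 <- which(rr == max(rr), arr.ind = TRUE)[1, ]
  c(dy = -sy[pk2[1]], dx = -sx[pk2[2]])
}

#' Bilinear translation with coverage tracking
#'
#' Shifts an image by `(dy, dx)` pixels using bilinear interpolation;
#' pixels sampling outside the source are set to `NA` so downstream
#' averaging can build a coverage mask.
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in pixels (rows down, columns right).
#' @return Shifted matrix with `NA` at uncovered borders.
#' @export
apply_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ys <- seq_len(nr) - dy
  xs <- seq_len(nc) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0; wx <- xs - x0
  at <- function(yi, xi) {
    ok <- yi >= 1 & yi <= nr
    yi2 <- pmin(pmax(yi, 1), nr)
    m <- img[yi2, pmin(pmax(xi, 1), nc), drop = FALSE]
    m[!ok, ] <- NA
    m[, !(xi >= 1 & xi <= nc)] <- NA
    m
  }
  (1 - wy) * ((at(y0, x0) * rep(1 - wx, each = nr)) +
              (at(y0, x0 + 1) * rep(wx, each = nr))) +
    wy * ((at(y0 + 1, x0) * rep(1 - wx, each = nr)) +
          (at(y0 + 1, x0 + 1) * rep(wx, each = nr)))
}

#' Register a cube sequence by rigid 2-D translation
#'
#' Estimates one translation per stack on a single alignment band against
#' the reference stack and applies the negated shift identically to every
#' band of that stack (intra-stack motion is neglected: a full stack is
#' acquired in ~0.3 s, fast relative to respiration). Motion is modelled
#' as pure translation, the dominant component of respiratory drift.
#'
#' @param seq A [cube_sequence()].
#' @param reference_index Stack to align to (default 1).
#' @param band_for_alignment Band used for shift estimation; default the
#'   band with the highest mean intensity in the reference stack (best
#'   SNR).
#' @return List: `sequence` (registered [cube_sequence()], uncovered
#'   border pixels `NA`), `shifts` (n x 2 matrix of estimated `(dy, dx)`
#'   per stack).
#' @export
register_sequence <- function(seq, reference_index = 1,
                              band_for_alignment = NULL) {
  stopifnot(inherits(seq, "cube_sequence"))
  n <- length(seq)
  stopifnot(reference_index >= 1, reference_index <= n)
  ref <- seq$stacks[[reference_index]]
  if (is.null(band_for_alignment))
    band_for_alignment <- which.max(apply(ref$bands, 3, mean))
  refband <- ref$bands[, , band_for_alignment]
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- seq$stacks
  for (i in seq_len(n)) {
    if (i == reference_index) next
    s <- estimate_shift(refband, out[[i]]$bands[, , band_for_alignment])
    shifts[i, ] <- s
    bb <- out[[i]]$bands
    for (b in seq_len(dim(bb)[3]))
      bb[, , b] <- apply_shift(bb[, , b], -s[1], -s[2])
    out[[i]]$bands <- bb
  }
  list(sequence = cube_sequence(out, seq$timestamps), shifts = shifts)
}

#' Temporally average a (registered) cube sequence
#'
#' Per-pixel, per-band mean across stacks. Positions not covered by every
#' frame (NA after registration warping) are excluded: they are zero in
#' the output and `FALSE` in the coverage mask.
#'
#' @param seq A [cube_sequence()], normally after [register_sequence()].
#' @return List: `cube` (averaged stack, same class of content as the
#'   inputs' band array wrapped in [datacube()]), `coverage` (logical
#'   H x W matrix, TRUE where every frame contributed every band).
#' @export
temporal_average <- function(seq) {
  stopifnot(inherits(seq, "cube_sequence"), length(seq) >= 1L)
  d <- dim(seq$stacks[[1]]$bands)
  acc <- array(0, d)
  ok <- array(TRUE, d)
  for (s in seq$stacks) {
    b <- s$bands
    ok <- ok & is.finite(b)
    b[!is.finite(b)] <- 0
    acc <- acc + b
  }
  acc <- acc / length(seq)
  coverage <- apply(ok, c(1, 2), all)
  acc[!ok] <- 0
  acc[array(!coverage, d)] <- 0
  list(cube = datacube(acc, seq$stacks[[1]]$meta), coverage = coverage)
}
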