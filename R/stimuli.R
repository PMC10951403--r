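#' Construct a stimulus image
#'
#' A labelled square grayscale image. Pixel values are dimensionless luminance
#' with nominal range \[0, 1\]; `pixels_per_degree` ties the pixel grid to
#' visual angle so that spatial frequencies can be expressed in cycles per
#' degree (cpd).
#'
#' @param pixels Square numeric matrix of finite luminance values.
#' @param family Character label for the texture family.
#' @param stim_class `"texture"` or `"scramble"`.
#' @param exemplar_id Integer exemplar index.
#' @param rotation_deg Rotation, 0 or 90 degrees.
#' @param pixels_per_degree Pixels per degree of visual angle.
#' @return An object of class `stim_image`.
#' @export
stim_image <- function(pixels, family = "none", stim_class = c("texture", "scramble"),
                       exemplar_id = 1L, rotation_deg = 0,
                       pixels_per_degree = 2.56) {
  stim_class <- match.arg(stim_class)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels))
    stop("stimulus images must be square")
  if (!all(is.finite(pixels)))
    stop("stimulus images must contain only finite values")
  if (!rotation_deg %in% c(0, 90))
    stop("rotation_deg must be 0 or 90")
  structure(
    list(pixels = pixels, family = family, stim_class = stim_class,
         exemplar_id = as.integer(exemplar_id), rotation_deg = rotation_deg,
         pixels_per_degree = pixels_per_degree),
    class = "stim_image")
}

#' @export
print.stim_image <- function(x, ...) {
  cat(sprintf("<stim_image> %dx%d px, family=%s, class=%s, exemplar=%d, rot=%d deg, %.3g px/deg\n",
              nrow(x$pixels), ncol(x$pixels), x$family, x$stim_class,
              x$exemplar_id, x$rotation_deg, x$pixels_per_degree))
  invisible(x)
}

as_pixels <- function(img) if (inherits(img, "stim_image")) img$pixels else as.matrix(img)

replace_pixels <- function(img, px) {
  if (inherits(img, "stim_image")) { img$pixels <- px; img } else px
}

#' Construct an image set
#'
#' @param images List of [stim_image] objects sharing shape and pixel scale.
#' @param provenance List of generation parameters and seeds.
#' @return An object of class `image_set` with a `manifest` data frame.
#' @export
image_set <- function(images, provenance = list()) {
  stopifnot(length(images) > 0)
  man <- do.call(rbind, lapply(images, function(im)
    data.frame(family = im$family, stim_class = im$stim_class,
               exemplar_id = im$exemplar_id, rotation_deg = im$rotation_deg,
               stringsAsFactors = FALSE)))
  key <- with(man, paste(family, stim_class, exemplar_id, rotation_deg))
  if (anyDuplicated(key))
    stop("duplicate (family, stim_class, exemplar_id, rotation_deg) keys in image set")
  sides <- vapply(images, function(im) nrow(im$pixels), integer(1))
  if (length(unique(sides)) != 1)
    stop("all images in a set must share the same shape")
  structure(list(images = images, manifest = man, provenance = provenance),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images, %dx%d px\n", length(x$images),
              nrow(x$images[[1]]$pixels), ncol(x$images[[1]]$pixels)))
  print(table(x$manifest$family, x$manifest$stim_class))
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Normalize mean luminance and RMS contrast
#'
#' Z-scores the pixel values (population standard deviation), multiplies by a
#' fixed contrast `sigma`, and adds a fixed mean luminance `mu`, so every
#' normalized image has sample mean `mu` and standard deviation `sigma`.
#' The map is affine and strictly increasing, hence pixel-rank preserving.
#'
#' @param img A [stim_image] or plain matrix.
#' @param sigma Target RMS contrast (SD of pixel values); default 0.15.
#' @param mu Target mean luminance; default 0.5.
#' @return Object of the same type as `img`.
#' @export
normalize_luminance_contrast <- function(img, sigma = 0.15, mu = 0.5) {
  stopifnot(sigma > 0)
  px <- as_pixels(img)
  s <- sqrt(pop_var(px))
  if (s == 0)
    stop("degenerate input: constant image, z-score undefined")
  replace_pixels(img, (px - mean(px)) / s * sigma + mu)
}

#' Phase-scramble an image
#'
#' Produces a spectrally matched noise image: the Fourier amplitude spectrum of
#' the input is retained while phases are replaced by the phases of the Fourier
#' transform of a seeded Gaussian-noise image. Because the noise image is real,
#' its phase field is Hermitian-odd, so the output is real by construction.
#' The DC term is kept from the input, preserving the mean exactly.
#'
#' @param img A [stim_image] or matrix (square).
#' @param rng_seed Integer seed for the Gaussian phase-donor image.
#' @return Scrambled image; for `stim_image` input, `stim_class` is set to
#'   `"scramble"`.
#' @export
phase_scramble <- function(img, rng_seed = 1L) {
  px <- as_pixels(img)
  n <- nrow(px)
  if (n != ncol(px)) stop("phase_scramble requires a square image")
  F <- fft2(px)
  noise <- with_seed(rng_seed, matrix(rnorm(n * n), n, n))
  ph <- Arg(fft2(noise))
  S <- Mod(F) * exp(1i * ph)
  S[1, 1] <- F[1, 1]                      # DC preserved exactly
  out <- Re(ifft2(S))
  out <- out - mean(out) + mean(px)   # pin the mean exactly (DC unchanged)
  if (inherits(img, "stim_image")) {
    img$pixels <- out
    img$stim_class <- "scramble"
    img
  } else out
}

#' Radial frequency map in cycles per degree
#'
#' @param n Image side in pixels.
#' @param pixels_per_degree Pixels per degree of visual angle.
#' @return `n` x `n` matrix of spatial frequency (cpd), origin at the corner.
#' @export
cpd_grid <- function(n, pixels_per_degree) {
  f <- fft_freqs(n)                       # cycles / pixel
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  sqrt(fx^2 + fy^2) * pixels_per_degree
}

# Fraction of non-DC Fourier amplitude at spatial frequencies <= hi_cpd.
# The image is Hann-windowed first: stimuli are aperiodic crops, and without
# tapering the boundary discontinuity leaks amplitude across all frequencies.
hann2 <- function(n) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  outer(w, w)
}

band_coverage <- function(px, ppd, hi_cpd = 0.5) {
  px <- (px - mean(px)) * hann2(nrow(px))
  amp <- Mod(fft2(px)); amp[1, 1] <- 0
  cpd <- cpd_grid(nrow(px), ppd)
  sum(amp[cpd <= hi_cpd]) / sum(amp)
}

# Magnify image content by factor z > 1 (zoom into the central 1/z portion)
# using exact trigonometric (Fourier) interpolation, so spatial frequencies
# scale down by z without introducing interpolation harmonics.
zoom_image <- function(px, z) {
  n <- nrow(px)
  ctr <- (n + 1) / 2
  coord <- ctr + (seq_len(n) - ctr) / z - 1   # 0-based sample positions
  k <- fft_freqs(n) * n                       # signed integer frequencies
  E <- exp(2i * pi * outer(coord, k) / n) / n
  Re(E %*% fft2(px) %*% t(E))
}

#' Rescale an image set into a perceptual spatial-frequency band
#'
#' Iteratively magnifies each image until at least `coverage` of its total
#' (non-DC) Fourier amplitude lies at spatial frequencies of `band_cpd[2]` cpd
#' or below; images already satisfying the criterion are returned unchanged
#' (scale factor 1). After rescaling, family-mean amplitude spectra are
#' compared over `[band_cpd[1], band_cpd[2]]` cpd and the maximum pairwise
#' normalized spectral distance is reported.
#'
#' @param imgs An [image_set].
#' @param band_cpd Frequency interval in cpd; default `c(0.01, 0.5)`.
#' @param coverage Required amplitude fraction below the band's upper edge;
#'   default 0.95.
#' @param step Multiplicative zoom per iteration; default 1.1.
#' @param max_iter Iteration cap per image; default 60.
#' @param overlap_tol Tolerance on the max pairwise normalized spectral
#'   distance between family means; exceeding it raises a warning. Default 0.5.
#' @return An [image_set]; attributes `scale_factors`, `iterations`, and
#'   `spectral_overlap` record the rescaling diagnostics.
#' @export
rescale_to_band <- function(imgs, band_cpd = c(0.01, 0.5), coverage = 0.95,
                            step = 1.1, max_iter = 60, overlap_tol = 0.5) {
  stopifnot(inherits(imgs, "image_set"))
  ppd <- imgs$images[[1]]$pixels_per_degree
  n <- nrow(imgs$images[[1]]$pixels)
  nyq_cpd <- 0.5 * ppd
  if (band_cpd[2] > nyq_cpd)
    stop("band upper edge exceeds the Nyquist frequency in cpd")
  scales <- numeric(length(imgs$images))
  iters <- integer(length(imgs$images))
  for (i in seq_along(imgs$images)) {
    px <- imgs$images[[i]]$pixels
    z <- 1
    it <- 0L
    cov <- band_coverage(px, ppd, band_cpd[2])
    while (cov < coverage && it < max_iter) {
      px <- zoom_image(px, step)
      z <- z * step
      it <- it + 1L
      cov <- band_coverage(px, ppd, band_cpd[2])
    }
    if (cov < coverage)
      stop(sprintf("rescale_to_band did not converge for image %d: coverage %.4f after %d iterations",
                   i, cov, it))
    imgs$images[[i]]$pixels <- px
    scales[i] <- z
    iters[i] <- it
  }
  # family-mean spectra in the band, normalized; max pairwise RMS distance
  cpd <- cpd_grid(n, ppd)
  sel <- cpd >= band_cpd[1] & cpd <= band_cpd[2]
  fams <- unique(imgs$manifest$family)
  w2 <- hann2(n)
  prof <- sapply(fams, function(f) {
    idx <- which(imgs$manifest$family == f)
    m <- Reduce(`+`, lapply(imgs$images[idx], function(im)
      Mod(fft2((im$pixels - mean(im$pixels)) * w2)))) / length(idx)
    v <- m[sel]
    v / sqrt(sum(v^2))
  })
  d <- 0
  if (length(fams) > 1) {
    for (a in seq_along(fams)) for (b in seq_len(a - 1))
      d <- max(d, sqrt(sum((prof[, a] - prof[, b])^2)))
    if (d > overlap_tol)
      warning(sprintf("family-mean spectra overlap poorly: max normalized distance %.3f", d))
  }
  attr(imgs, "scale_factors") <- scales
  attr(imgs, "iterations") <- iters
  attr(imgs, "spectral_overlap") <- d
  imgs
}

#' Raised-cosine circular window
#'
#' Vignettes an image toward the background level `mu`: gain 1 inside the
#' central plateau, half-cosine ramp across the transition band, and 0 (pixels
#' equal to `mu`) outside the window.
#'
#' @param img A [stim_image] or matrix.
#' @param diameter_deg Window diameter in degrees of visual angle.
#' @param mu Background luminance; default 0.5.
#' @param transition Fraction of the radius used for the cosine ramp;
#'   default 0.2.
#' @param pixels_per_degree Pixel scale; taken from `img` when it is a
#'   `stim_image`.
#' @return Windowed image of the same type as `img`.
#' @export
apply_raised_cosine <- function(img, diameter_deg, mu = 0.5, transition = 0.2,
                                pixels_per_degree = NULL) {
  px <- as_pixels(img)
  ppd <- if (inherits(img, "stim_image")) img$pixels_per_degree else pixels_per_degree
  if (is.null(ppd)) stop("pixels_per_degree required for matrix input")
  n <- nrow(px)
  if (diameter_deg * ppd > n * sqrt(2))
    stop("window diameter exceeds the image extent")
  ctr <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)) / ppd  # deg
  r2 <- diameter_deg / 2
  r1 <- r2 * (1 - transition)
  gain <- raised_cosine_gain(r, r1, r2)
  replace_pixels(img, mu + gain * (px - mu))
}

#' @rdname apply_raised_cosine
#' @param r Radial distance (same units as `r1`, `r2`).
#' @param r1 Plateau radius (gain 1 inside).
#' @param r2 Outer radius (gain 0 outside).
#' @export
raised_cosine_gain <- function(r, r1, r2) {
  g <- 0.5 * (1 + cos(pi * (r - r1) / (r2 - r1)))
  g[r <= r1] <- 1
  g[r >= r2] <- 0
  g
}

#' Histogram-match an image set to a common reference
#'
#' Maps every image's luminance histogram onto a shared reference (the mean
#' order statistics across the set) through a monotone rank mapping, so
#' histogram shape -- in particular skewness and kurtosis -- carries no
#' information about family or texture/scramble class. Apply before
#' [normalize_luminance_contrast()].
#'
#' @param imgs An [image_set].
#' @param rng_seed Seed used only to break rank ties reproducibly.
#' @return An [image_set] with matched histograms.
#' @export
match_histograms_control <- function(imgs, rng_seed = 1L) {
  stopifnot(inherits(imgs, "image_set"), length(imgs$images) > 0)
  sorted <- lapply(imgs$images, function(im) sort(as.vector(im$pixels)))
  ref <- Reduce(`+`, sorted) / length(sorted)
  with_seed(rng_seed, {
    for (i in seq_along(imgs$images)) {
      px <- imgs$images[[i]]$pixels
      rk <- rank(px, ties.method = "random")
      imgs$images[[i]]$pixels <- matrix(ref[rk], nrow(px), ncol(px))
    }
  })
  imgs
}

#' Rotate a stimulus image by 90 degrees
#'
#' Exact (lossless) array rotation: transpose then reverse rows.
#'
#' @param img A [stim_image] or matrix.
#' @return Rotated image; for `stim_image` input `rotation_deg` is set to 90.
#' @export
rotate90 <- function(img) {
  px <- as_pixels(img)
  out <- t(px)[rev(seq_len(ncol(px))), , drop = FALSE]
  if (inherits(img, "stim_image")) {
    img$pixels <- out
    img$rotation_deg <- 90
    img
  } else out
}
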