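# Complex steerable pyramid, constructed in the frequency domain as a tight
# frame at full resolution (no downsampling). Oriented bands are analytic
# (single-lobed in frequency), so band magnitudes are local energy envelopes.
# Circular (wrap-around) boundary handling is inherited from the DFT, making
# periodic shift-invariance of downstream statistics exact.

# Raised-cosine radial lowpass with cutoff c: 1 below c/2, 0 above c,
# log-frequency half-cosine in between. Highpass is the quadrature complement.
radial_lowpass <- function(r, cutoff) {
  out <- numeric(length(r))
  out[r <= cutoff / 2] <- 1
  mid <- r > cutoff / 2 & r < cutoff
  out[mid] <- cos(pi / 2 * log2(2 * r[mid] / cutoff))
  matrix(out, nrow = nrow(r))
}

radial_highpass <- function(r, cutoff) sqrt(pmax(0, 1 - radial_lowpass(r, cutoff)^2))

# Single-lobe angular masks g_k(theta) = cos(theta - theta_k)^(K-1) on the
# half-plane |theta - theta_k| < pi/2, normalized so that
# sum_k (g_k(theta) + g_k(theta + pi))^2 = 1 for all theta.
angular_masks <- function(theta, n_orientations) {
  K <- n_orientations
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  # normalization constant: sum over k of cos^(2(K-1)) spaced pi/K is constant
  tg <- seq(0, pi, length.out = 721)
  Cs <- rowSums(sapply(seq_len(K) - 1, function(k) cos(tg - k * pi / K)^(2 * (K - 1))))
  Cn <- sqrt(max(Cs))
  lapply(seq_len(K) - 1, function(k) {
    d <- wrap(theta - k * pi / K)
    g <- ifelse(abs(d) < pi / 2, cos(d)^(K - 1), 0)
    matrix(g / Cn, nrow = nrow(theta))
  })
}

# All frequency-domain masks for an n x n image.
pyramid_masks <- function(n, n_scales, n_orientations) {
  g <- freq_grids(n)
  H0 <- radial_highpass(g$r, pi)
  ang <- angular_masks(g$theta, n_orientations)
  low_cum <- radial_lowpass(g$r, pi)
  band_rad <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    band_rad[[s]] <- low_cum * radial_highpass(g$r, pi / 2^s)
    low_cum <- low_cum * radial_lowpass(g$r, pi / 2^s)
  }
  # symmetric (two-lobe) angular masks used for reconstruction
  Cn <- ang_norm_const(n_orientations)
  ang_sym <- lapply(seq_len(n_orientations) - 1, function(k) {
    wrap <- function(a) (a + pi) %% (2 * pi) - pi
    d1 <- wrap(g$theta - k * pi / n_orientations)
    d2 <- wrap(g$theta - k * pi / n_orientations - pi)
    a1 <- ifelse(abs(d1) < pi / 2, cos(d1)^(n_orientations - 1), 0)
    a2 <- ifelse(abs(d2) < pi / 2, cos(d2)^(n_orientations - 1), 0)
    matrix((a1 + a2) / Cn, nrow = nrow(g$theta))
  })
  list(H0 = H0, band_rad = band_rad, low = low_cum, ang = ang, ang_sym = ang_sym)
}

ang_norm_const <- function(K) {
  tg <- seq(0, pi, length.out = 721)
  Cs <- rowSums(sapply(seq_len(K) - 1, function(k) cos(tg - k * pi / K)^(2 * (K - 1))))
  sqrt(max(Cs))
}

#' Build a complex steerable pyramid
#'
#' Decomposes a square image into `n_scales` x `n_orientations` oriented
#' complex subbands plus real highpass and lowpass residuals, using
#' raised-cosine radial filters (one-octave transitions) and
#' `cos^(K-1)` angular filters restricted to a half-plane (analytic bands).
#' The filter set is a tight frame: analysis followed by
#' [reconstruct_pyramid()] returns the input to machine precision, and image
#' energy equals the energy of the residuals plus twice the energy of the
#' complex bands.
#'
#' All subbands are kept at full resolution; the scale of a band is encoded in
#' its passband, and statistics on coarse scales use proportionally strided
#' neighborhoods (equivalent to critical downsampling for these band-limited
#' signals).
#'
#' @param img A [stim_image] or square numeric matrix; side divisible by
#'   `2^n_scales`.
#' @param n_scales Number of scales (octaves); default 4.
#' @param n_orientations Number of orientations; default 4.
#' @return An object of class `steerable_pyramid`: `bands[[s]][[k]]` complex
#'   matrices, `highpass`, `lowpass` real matrices, and `meta`.
#' @export
build_pyramid <- function(img, n_scales = 4, n_orientations = 4) {
  px <- as_pixels(img)
  n <- nrow(px)
  if (n != ncol(px)) stop("image must be square")
  if (n %% 2^n_scales != 0)
    stop(sprintf("image side (%d) must be divisible by 2^n_scales (%d)", n, 2^n_scales))
  m <- pyramid_masks(n, n_scales, n_orientations)
  F <- fft2(px)
  bands <- lapply(seq_len(n_scales), function(s)
    lapply(seq_len(n_orientations), function(k)
      ifft2(m$band_rad[[s]] * m$ang[[k]] * F)))
  structure(
    list(bands = bands,
         highpass = Re(ifft2(m$H0 * F)),
         lowpass = Re(ifft2(m$low * F)),
         meta = list(n = n, n_scales = n_scales, n_orientations = n_orientations)),
    class = "steerable_pyramid")
}

#' @export
print.steerable_pyramid <- function(x, ...) {
  cat(sprintf("<steerable_pyramid> %dx%d px, %d scales x %d orientations (complex bands)\n",
              x$meta$n, x$meta$n, x$meta$n_scales, x$meta$n_orientations))
  invisible(x)
}

#' Reconstruct an image from its steerable pyramid
#'
#' Applies the synthesis half of the tight frame: residuals are re-filtered
#' with their own masks and each oriented band contributes `2 Re(band)`
#' filtered with the symmetric (two-lobed) version of its analysis mask.
#'
#' @param pyr A `steerable_pyramid`.
#' @return Real matrix of the same size as the analysed image.
#' @export
reconstruct_pyramid <- function(pyr) {
  n <- pyr$meta$n
  m <- pyramid_masks(n, pyr$meta$n_scales, pyr$meta$n_orientations)
  acc <- m$H0 * fft2(pyr$highpass) + m$low * fft2(pyr$lowpass)
  for (s in seq_len(pyr$meta$n_scales))
    for (k in seq_len(pyr$meta$n_orientations))
      acc <- acc + m$band_rad[[s]] * m$ang_sym[[k]] *
        fft2(2 * Re(pyr$bands[[s]][[k]]))
  Re(ifft2(acc))
}

#' Energy accounting for a steerable pyramid
#'
#' For the analytic tight frame, image energy satisfies
#' `sum(img^2) = sum(hp^2) + sum(lp^2) + 2 * sum(|bands|^2)`.
#'
#' @param pyr A `steerable_pyramid`.
#' @return Named numeric vector with `highpass`, `lowpass`, `bands`, `total`.
#' @export
pyramid_energy <- function(pyr) {
  eb <- sum(vapply(unlist(pyr$bands, recursive = FALSE),
                   function(b) sum(Mod(b)^2), numeric(1)))
  c(highpass = sum(pyr$highpass^2), lowpass = sum(pyr$lowpass^2),
    bands = 2 * eb, total = sum(pyr$highpass^2) + sum(pyr$lowpass^2) + 2 * eb)
}
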