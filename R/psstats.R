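# Portilla-Simoncelli texture statistics on the complex steerable pyramid.
#
# Coefficient inventory (default parameters: 4 scales, 4 orientations,
# 7-pixel neighborhood) -- 740 coefficients in four named groups:
#
#   marginal   (2):   skewness and kurtosis of the pixel histogram
#                     (mean and SD are equalized upstream and excluded).
#   spectral   (18):  RMS magnitude (root band energy) of the 16 oriented
#                     subbands (16); variances of the highpass and lowpass
#                     residuals (2). All are exact functionals of the
#                     amplitude spectrum, so spectrum-matched scrambles match
#                     their textures here by construction.
#   linear_cc  (240): normalized central autocorrelation of the 5 partial
#                     lowpass reconstructions, 7x7 neighborhood, 24 unique
#                     off-centre offsets under point symmetry (120);
#                     within-scale cross-orientation correlations of the real
#                     band outputs, C(4,2) x 4 (24); cross-scale correlations
#                     of real child bands against the real and imaginary parts
#                     of the phase-doubled parent, 4x4x2x3 (96).
#   energy_cc  (480): variance of each centred band magnitude (16); normalized
#                     magnitude autocorrelations, 24 x 16 (384); within-scale
#                     magnitude cross-correlations, 6 x 4 (24); cross-scale
#                     magnitude correlations, 4x4x3 (48); same-orientation
#                     grandparent (two-octave) magnitude correlations,
#                     4 x 2 (8).
#
# All autocorrelations are correlation coefficients (the centre, identically
# 1, is dropped; variances are carried as separate coefficients). Lags at
# scale s are strided by 2^(s-1) pixels, which for these band-limited maps
# equals the autocorrelation of the critically downsampled band.

# Unique off-centre offsets of a (2h+1)^2 neighborhood under point symmetry:
# (a, b) with a > 0, or a == 0 and b > 0.
neigh_offsets <- function(neighborhood) {
  h <- (neighborhood - 1) %/% 2
  out <- list()
  for (a in 0:h) for (b in (-h):h) {
    if (a == 0 && b <= 0) next
    out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

# Named normalized autocorrelation values at strided offsets, via the FFT
# autocovariance surface.
strided_autocorr <- function(m, offsets, stride, prefix) {
  ac <- circ_autocov(m)
  n1 <- nrow(ac); n2 <- ncol(ac)
  v0 <- ac[1, 1]
  vals <- vapply(offsets, function(ab) {
    i <- (ab[1] * stride) %% n1 + 1
    j <- (ab[2] * stride) %% n2 + 1
    if (v0 <= 0) 0 else ac[i, j] / v0
  }, numeric(1))
  names(vals) <- vapply(offsets, function(ab)
    sprintf("%s_ac_%d_%d", prefix, ab[1], ab[2]), character(1))
  vals
}

# Partial lowpass reconstructions PR_0..PR_S: image content below the
# highpass, then below each successive scale band; PR_S is the lowpass
# residual content. Returned with the lag stride appropriate to each level.
partial_recons <- function(px, n_scales) {
  n <- nrow(px)
  g <- freq_grids(n)
  F <- fft2(px)
  cl <- radial_lowpass(g$r, pi)
  out <- vector("list", n_scales + 1)
  out[[1]] <- list(map = Re(ifft2(cl * F)), stride = 1L, level = 0L)
  for (s in seq_len(n_scales)) {
    cl <- cl * radial_lowpass(g$r, pi / 2^s)
    out[[s + 1]] <- list(map = Re(ifft2(cl * F)), stride = 2L^s, level = s)
  }
  out
}

#' Compute Portilla-Simoncelli statistics of an image
#'
#' Decomposes the image with [build_pyramid()] and measures the four canonical
#' groups of texture statistics: marginal moments of the pixel histogram,
#' spectral (band-energy) statistics, linear cross-correlations of the real
#' filter outputs over a spatial neighborhood, and energy cross-correlations
#' of the band magnitudes across positions, orientations, and scales. With the
#' default parameters (4 scales, 4 orientations, 7-pixel neighborhood) the
#' concatenated vector has exactly 740 coefficients; the full inventory is
#' documented in the package source and the methods vignette.
#'
#' Statistics are spatial averages over the whole image with circular boundary
#' handling, so they are invariant to periodic translations of the input.
#'
#' @param img A [stim_image] or square matrix, side divisible by 16.
#' @param neighborhood Odd neighborhood size in pixels; default 7.
#' @param n_scales,n_orientations Pyramid parameters; defaults 4 and 4.
#' @return Object of class `ps_statistics`: named numeric vectors `marginal`,
#'   `spectral`, `linear_cc`, `energy_cc`, plus `group_index` and `meta`.
#' @export
compute_ps_statistics <- function(img, neighborhood = 7, n_scales = 4,
                                  n_orientations = 4) {
  if (neighborhood %% 2 != 1) stop("neighborhood must be odd")
  px <- as_pixels(img)
  pyr <- build_pyramid(px, n_scales, n_orientations)
  S <- n_scales; K <- n_orientations
  offs <- neigh_offsets(neighborhood)

  marginal <- c(skewness = pop_skewness(px), kurtosis = pop_kurtosis(px))

  # band magnitudes; RMS magnitude is the (root) band energy, an exact
  # functional of the amplitude spectrum
  mags <- lapply(pyr$bands, function(sc) lapply(sc, Mod))
  band_rms <- unlist(lapply(seq_len(S), function(s) {
    v <- vapply(seq_len(K), function(k) sqrt(mean(mags[[s]][[k]]^2)), numeric(1))
    names(v) <- sprintf("bandrms_s%d_o%d", s, seq_len(K)); v
  }))

  recons <- partial_recons(px, S)
  spectral <- c(band_rms,
                hp_var = pop_var(pyr$highpass),
                lp_var = pop_var(recons[[S + 1]]$map))

  # linear cross-correlations ------------------------------------------------
  lin_ac <- unlist(lapply(recons, function(rc)
    strided_autocorr(rc$map, offs, rc$stride, sprintf("recon%d", rc$level))))

  reals <- lapply(pyr$bands, function(sc) lapply(sc, Re))
  lin_cousin <- unlist(lapply(seq_len(S), function(s) {
    v <- c(); nm <- c()
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      v <- c(v, flat_cor(reals[[s]][[i]], reals[[s]][[j]]))
      nm <- c(nm, sprintf("realcc_s%d_o%d_o%d", s, i, j))
    }
    names(v) <- nm; v
  }))

  # phase-doubled parents
  pdbl <- function(b) {
    m <- Mod(b)
    out <- b * 0
    nz <- m > 0
    out[nz] <- b[nz]^2 / m[nz]
    out
  }
  lin_parent <- unlist(lapply(seq_len(S - 1), function(s) {
    v <- c(); nm <- c()
    for (i in seq_len(K)) for (j in seq_len(K)) {
      pd <- pdbl(pyr$bands[[s + 1]][[j]])
      v <- c(v, flat_cor(reals[[s]][[i]], Re(pd)),
             flat_cor(reals[[s]][[i]], Im(pd)))
      nm <- c(nm, sprintf("realpar_s%d_o%d_s%d_o%d_re", s, i, s + 1, j),
              sprintf("realpar_s%d_o%d_s%d_o%d_im", s, i, s + 1, j))
    }
    names(v) <- nm; v
  }))
  linear_cc <- c(lin_ac, lin_cousin, lin_parent)

  # energy cross-correlations ------------------------------------------------
  magc <- lapply(mags, function(sc) lapply(sc, function(m) m - mean(m)))
  mag_var <- unlist(lapply(seq_len(S), function(s) {
    v <- vapply(seq_len(K), function(k) pop_var(mags[[s]][[k]]), numeric(1))
    names(v) <- sprintf("magvar_s%d_o%d", s, seq_len(K)); v
  }))
  mag_ac <- unlist(lapply(seq_len(S), function(s)
    unlist(lapply(seq_len(K), function(k)
      strided_autocorr(magc[[s]][[k]], offs, 2L^(s - 1L),
                       sprintf("mag_s%d_o%d", s, k))))))
  mag_cousin <- unlist(lapply(seq_len(S), function(s) {
    v <- c(); nm <- c()
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      v <- c(v, flat_cor(magc[[s]][[i]], magc[[s]][[j]]))
      nm <- c(nm, sprintf("magcc_s%d_o%d_o%d", s, i, j))
    }
    names(v) <- nm; v
  }))
  mag_parent <- unlist(lapply(seq_len(S - 1), function(s) {
    v <- c(); nm <- c()
    for (i in seq_len(K)) for (j in seq_len(K)) {
      v <- c(v, flat_cor(magc[[s]][[i]], magc[[s + 1]][[j]]))
      nm <- c(nm, sprintf("magpar_s%d_o%d_s%d_o%d", s, i, s + 1, j))
    }
    names(v) <- nm; v
  }))
  mag_grandparent <- unlist(lapply(seq_len(S - 2), function(s) {
    v <- vapply(seq_len(K), function(k)
      flat_cor(magc[[s]][[k]], magc[[s + 2]][[k]]), numeric(1))
    names(v) <- sprintf("maggp_s%d_s%d_o%d", s, s + 2, seq_len(K)); v
  }))
  energy_cc <- c(mag_var, mag_ac, mag_cousin, mag_parent, mag_grandparent)

  groups <- list(marginal = marginal, spectral = spectral,
                 linear_cc = linear_cc, energy_cc = energy_cc)
  lens <- vapply(groups, length, integer(1))
  idx <- split(seq_len(sum(lens)), rep(names(groups), lens))[names(groups)]
  structure(
    c(groups,
      list(group_index = idx,
           meta = list(n = nrow(px), n_scales = S, n_orientations = K,
                       neighborhood = neighborhood))),
    class = "ps_statistics")
}

#' @export
print.ps_statistics <- function(x, ...) {
  lens <- vapply(x[c("marginal", "spectral", "linear_cc", "energy_cc")],
                 length, integer(1))
  cat(sprintf("<ps_statistics> %d coefficients (%s)\n", sum(lens),
              paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")))
  invisible(x)
}

#' Concatenate a `ps_statistics` object into one named vector
#'
#' @param x A `ps_statistics` object.
#' @param ... Unused.
#' @return Named numeric vector (740 values at the default parameters).
#' @export
as.vector.ps_statistics <- function(x, ...) {
  unlist(x[c("marginal", "spectral", "linear_cc", "energy_cc")],
         use.names = TRUE)
}

#' Spatial-frequency and orientation amplitude profiles
#'
#' Averages the 2-D Fourier amplitude spectrum in radial spatial-frequency
#' bins (cpd) and orientation bins (degrees, modulo 180). The DC term is
#' excluded.
#'
#' @param img A [stim_image] or matrix.
#' @param sf_bins Spatial-frequency bin edges in cpd; default
#'   `seq(0.01, 0.5, by = 0.02)`.
#' @param ori_bins Orientation bin edges in degrees; default
#'   `seq(0, 180, by = 15)`.
#' @param pixels_per_degree Pixel scale; taken from a `stim_image`.
#' @param normalize If `TRUE`, scale each profile to maximum 1.
#' @return List with `sf` and `ori` data frames (bin centres and mean
#'   amplitudes; empty bins are `NA`).
#' @export
spectral_profile <- function(img, sf_bins = seq(0.01, 0.5, by = 0.02),
                             ori_bins = seq(0, 180, by = 15),
                             pixels_per_degree = NULL, normalize = FALSE) {
  px <- as_pixels(img)
  ppd <- if (inherits(img, "stim_image")) img$pixels_per_degree else pixels_per_degree
  if (is.null(ppd)) stop("pixels_per_degree required for matrix input")
  n <- nrow(px)
  amp <- Mod(fft2(px)); amp[1, 1] <- NA
  cpd <- cpd_grid(n, ppd)
  f <- fft_freqs(n)
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  ang <- (atan2(fy, fx) * 180 / pi) %% 180
  ok <- !is.na(amp)
  sf_cut <- cut(cpd[ok], sf_bins, include.lowest = TRUE)
  sf_amp <- tapply(amp[ok], sf_cut, mean)
  ori_ok <- ok & cpd >= min(sf_bins) & cpd <= max(sf_bins)
  ori_cut <- cut(ang[ori_ok], ori_bins, include.lowest = TRUE)
  ori_amp <- tapply(amp[ori_ok], ori_cut, mean)
  if (normalize) {
    sf_amp <- sf_amp / max(sf_amp, na.rm = TRUE)
    ori_amp <- ori_amp / max(ori_amp, na.rm = TRUE)
  }
  list(sf = data.frame(cpd = (head(sf_bins, -1) + tail(sf_bins, -1)) / 2,
                       amplitude = as.numeric(sf_amp)),
       ori = data.frame(deg = (head(ori_bins, -1) + tail(ori_bins, -1)) / 2,
                        amplitude = as.numeric(ori_amp)))
}
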