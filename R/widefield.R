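# Mesoscale (widefield) preprocessing and texture-selectivity analysis:
# per-channel ΔF/F, hemodynamic correction, trial tensors, peak and p-value
# maps, retinotopic ROIs, and area-level d' with a pre-stimulus null.

# Flatten [frames, ny, nx] to [frames, npix]; inverse handled by callers.
flat_movie <- function(movie) {
  d <- dim(movie)
  list(mat = matrix(movie, d[1]), ny = d[2], nx = d[3])
}

#' Per-pixel relative fluorescence (ΔF/F)
#'
#' Fits a linear trend `F(t) ~ a t + b` to each pixel's time series and
#' returns `ΔF/F = (F - (a t + b)) / b`: the series is detrended and
#' normalized by the fitted baseline. Pixels whose fitted intercept magnitude
#' falls below `min_intercept` (relative to the series scale) are masked
#' with `NA`.
#'
#' @param movie Array `[frames, ny, nx]` or matrix `[frames, npix]` of raw
#'   fluorescence.
#' @param frame_rate Frames per second (defines `t` in seconds).
#' @param min_intercept Minimum |intercept| as a fraction of the mean
#'   absolute signal; default 1e-3.
#' @return ΔF/F with the same shape as the input; attribute `trend` holds the
#'   per-pixel `(a, b)` coefficients.
#' @export
channel_dff <- function(movie, frame_rate = 1, min_intercept = 1e-3) {
  was_arr <- length(dim(movie)) == 3
  fm <- if (was_arr) flat_movie(movie) else list(mat = movie)
  F <- fm$mat
  nf <- nrow(F)
  if (nf < 2) stop("time series must have length >= 2")
  t <- (seq_len(nf) - 1) / frame_rate
  tc <- t - mean(t)
  a <- colSums(tc * F) / sum(tc^2)
  b <- colMeans(F) - a * mean(t)
  bad <- abs(b) < min_intercept * mean(abs(F))
  trend <- outer(t, a) + rep(b, each = nf)
  dff <- (F - trend) / rep(b, each = nf)
  if (any(bad)) dff[, bad] <- NA_real_
  out <- if (was_arr) array(dff, dim(movie)) else dff
  attr(out, "trend") <- cbind(a = a, b = b)
  attr(out, "masked") <- which(bad)
  out
}

#' Hemodynamic correction of the calcium channel
#'
#' Low-pass filters the calcium-independent (violet) ΔF/F with a Butterworth
#' filter applied forward-backward (zero phase), fits it linearly to the blue
#' ΔF/F per pixel (`blue ~ c violet_lp + d`), and subtracts the fitted
#' component.
#'
#' @param blue,violet ΔF/F arrays `[frames, ny, nx]` or matrices
#'   `[frames, npix]` of equal shape.
#' @param frame_rate Sampling rate in Hz.
#' @param cutoff_hz Low-pass cutoff; default 5.
#' @param order Filter order; default 6.
#' @return List: `corrected` (same shape as `blue`) and `fit` (per-pixel
#'   `c`, `d`).
#' @export
hemodynamic_correct <- function(blue, violet, frame_rate, cutoff_hz = 5,
                                order = 6) {
  stopifnot(identical(dim(blue), dim(violet)))
  if (cutoff_hz >= frame_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  was_arr <- length(dim(blue)) == 3
  B <- if (was_arr) flat_movie(blue)$mat else blue
  V <- if (was_arr) flat_movie(violet)$mat else violet
  bf <- signal::butter(order, cutoff_hz / (frame_rate / 2), type = "low")
  Vlp <- apply(V, 2, function(x) {
    if (anyNA(x)) return(x)
    signal::filtfilt(bf, x)
  })
  if (any(!is.finite(Vlp[, colSums(is.na(V)) == 0])))
    stop(sprintf("low-pass filter unstable for %d pixels",
                 sum(apply(Vlp, 2, function(x) any(!is.finite(x))))))
  vc <- sweep(Vlp, 2, colMeans(Vlp))
  cc <- colSums(vc * B) / colSums(vc^2)
  dd <- colMeans(B) - cc * colMeans(Vlp)
  corr <- B - (rep(cc, each = nrow(B)) * Vlp + rep(dd, each = nrow(B)))
  out <- if (was_arr) array(corr, dim(blue)) else corr
  list(corrected = out, fit = cbind(c = cc, d = dd))
}

#' Split a continuous movie into a trial tensor
#'
#' Extracts, for every schedule trial, the frames in `window_ms` relative to
#' stimulus onset. Stimulus and blank trials are returned separately; trials
#' whose window falls outside the movie are dropped with a warning.
#'
#' @param movie ΔF/F array `[frames, ny, nx]`.
#' @param schedule A `trial_schedule`.
#' @param window_ms Window relative to onset; default `c(-500, 1000)`.
#' @param frame_rate Hz; default from the schedule.
#' @return Object of class `trial_tensor`: `values`
#'   `[trial, frame, ny, nx]`, `trials` (schedule rows kept), `time_ms`
#'   (frame times), and `blank` (same structure for blank trials).
#' @export
split_trials <- function(movie, schedule, window_ms = c(-500, 1000),
                         frame_rate = attr(schedule, "frame_rate")) {
  d <- dim(movie)
  rel <- seq(round(window_ms[1] / 1000 * frame_rate),
             round(window_ms[2] / 1000 * frame_rate))
  time_ms <- rel / frame_rate * 1000
  ok <- schedule$onset_frame + min(rel) >= 1 &
    schedule$onset_frame + max(rel) <= d[1]
  if (any(!ok))
    warning(sprintf("dropping %d trials with windows outside the movie", sum(!ok)))
  sched <- schedule[ok, , drop = FALSE]
  grab <- function(rows) {
    vals <- array(NA_real_, c(nrow(rows), length(rel), d[2], d[3]))
    for (i in seq_len(nrow(rows)))
      vals[i, , , ] <- movie[rows$onset_frame[i] + rel, , , drop = FALSE]
    vals
  }
  st <- sched[!sched$blank, , drop = FALSE]
  bl <- sched[sched$blank, , drop = FALSE]
  structure(list(values = grab(st), trials = st, time_ms = time_ms,
                 blank = list(values = grab(bl), trials = bl),
                 frame_rate = frame_rate),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d stimulus trials x %d frames x %dx%d px; %d blanks\n",
              d[1], d[2], d[3], d[4], nrow(x$blank$trials)))
  invisible(x)
}

window_frames <- function(tensor, window_ms) {
  which(tensor$time_ms >= window_ms[1] & tensor$time_ms <= window_ms[2])
}

# Repeat-averaged per-exemplar pixel responses in a time window:
# array [exemplar-condition, ny, nx] plus the condition table.
exemplar_responses <- function(tensor, window_ms = c(200, 400)) {
  wf <- window_frames(tensor, window_ms)
  tr <- tensor$trials
  key <- paste(tr$family, tr$stim_class, tr$exemplar, tr$rotation)
  ukey <- unique(key)
  d <- dim(tensor$values)
  out <- array(NA_real_, c(length(ukey), d[3], d[4]))
  for (i in seq_along(ukey)) {
    idx <- which(key == ukey[i])
    out[i, , ] <- apply(tensor$values[idx, wf, , , drop = FALSE], c(3, 4), mean)
  }
  info <- tr[match(ukey, key), c("family", "stim_class", "exemplar", "rotation")]
  rownames(info) <- NULL
  list(values = out, info = info)
}

#' Peak-response map
#'
#' Mean ΔF/F over repeats, exemplars, families, and the frames in
#' `window_ms` (default 200-400 ms after onset).
#'
#' @param tensor A `trial_tensor`.
#' @param window_ms Averaging window; default `c(200, 400)`.
#' @return Matrix `[ny, nx]`.
#' @export
peak_response_map <- function(tensor, window_ms = c(200, 400)) {
  wf <- window_frames(tensor, window_ms)
  apply(tensor$values[, wf, , , drop = FALSE], c(3, 4), mean)
}

#' Pixelwise texture-vs-scramble significance map
#'
#' Repeat-averaged texture exemplar responses are paired with randomly chosen
#' scramble exemplars of the same family (seeded permutation). Per pixel, the
#' texture-minus-scramble difference distribution in the post-stimulus window
#' (200-400 ms) is tested against the same construction in a pre-stimulus
#' window (-350 to -100 ms) with a paired two-sided t-test.
#'
#' @param tensor A `trial_tensor`.
#' @param post_ms,pre_ms Post and pre windows; defaults `c(200, 400)` and
#'   `c(-350, -100)`.
#' @param rng_seed Seed for the texture-scramble exemplar pairing.
#' @return List: `p` (matrix of p-values), `t` (t statistics), `pairing`.
#' @export
pixel_significance_map <- function(tensor, post_ms = c(200, 400),
                                   pre_ms = c(-350, -100), rng_seed = 1L) {
  post <- exemplar_responses(tensor, post_ms)
  pre <- exemplar_responses(tensor, pre_ms)
  info <- post$info
  pairing <- with_seed(rng_seed, {
    do.call(rbind, lapply(split(seq_len(nrow(info)), info$family), function(ix) {
      texi <- ix[info$stim_class[ix] == "texture"]
      scri <- ix[info$stim_class[ix] == "scramble"]
      data.frame(tex = texi, scr = sample(scri, length(texi), replace = length(scri) < length(texi)))
    }))
  })
  d <- dim(post$values)
  npix <- d[2] * d[3]
  flat <- function(a) matrix(a, dim(a)[1], npix)
  dpost <- flat(post$values)[pairing$tex, , drop = FALSE] -
    flat(post$values)[pairing$scr, , drop = FALSE]
  dpre <- flat(pre$values)[pairing$tex, , drop = FALSE] -
    flat(pre$values)[pairing$scr, , drop = FALSE]
  dd <- dpost - dpre
  n <- nrow(dd)
  m <- colMeans(dd)
  se <- sqrt(apply(dd, 2, var) / n)
  tstat <- ifelse(se > 0, m / se, 0)
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p[se == 0] <- 1
  list(p = matrix(p, d[2], d[3]), t = matrix(tstat, d[2], d[3]),
       pairing = pairing)
}

#' Region of interest from retinotopic maps
#'
#' @param azimuth,elevation Matrices of visual-field coordinates (degrees).
#' @param az_bounds,el_bounds Inclusive bounds; defaults `c(-10, 30)` and
#'   `c(-30, 30)`.
#' @param area_mask Optional logical matrix restricting the ROI to one area.
#' @param label Area label carried in the result; default `"area"`.
#' @return Object of class `area_roi`: logical `mask` plus the bounds used.
#' @export
roi_from_retinotopy <- function(azimuth, elevation, az_bounds = c(-10, 30),
                                el_bounds = c(-30, 30), area_mask = NULL,
                                label = "area") {
  mask <- azimuth >= az_bounds[1] & azimuth <= az_bounds[2] &
    elevation >= el_bounds[1] & elevation <= el_bounds[2]
  if (!is.null(area_mask)) mask <- mask & area_mask
  if (!any(mask)) stop("empty ROI: no pixels fall inside the given bounds")
  structure(list(mask = mask, label = label, az_bounds = az_bounds,
                 el_bounds = el_bounds), class = "area_roi")
}

#' Fraction of significantly modulated pixels in an ROI
#'
#' @param p_map Matrix of p-values.
#' @param roi An `area_roi` or logical mask.
#' @param alpha Significance level; default 0.01.
#' @return Proportion of ROI pixels with `p < alpha`.
#' @export
area_modulated_fraction <- function(p_map, roi, alpha = 0.01) {
  mask <- if (inherits(roi, "area_roi")) roi$mask else roi
  mean(p_map[mask] < alpha)
}

# Texture-scramble discriminability: standardized mean difference with the
# pooled-variance denominator.
dprime_pooled <- function(x, y) {
  pv <- 0.5 * (var(x) + var(y))
  if (pv == 0) stop("undefined d': zero pooled variance")
  (mean(x) - mean(y)) / sqrt(pv)
}

#' Area-level texture-scramble d'
#'
#' Responses are averaged over repeats, ROI pixels, and the response window;
#' d' contrasts the per-exemplar texture and scramble distributions using the
#' pooled-variance standardized mean difference. A null interval is obtained
#' by applying the same computation to a pre-stimulus window under seeded
#' random assignments of exemplars to the two classes, reporting the 5th and
#' 95th percentiles.
#'
#' @param tensor A `trial_tensor`.
#' @param roi An `area_roi` or logical mask.
#' @param resp_ms Response window; default `c(200, 400)`.
#' @param null_ms Pre-stimulus window; default `c(-300, 0)`.
#' @param n_null Null resamples; default 200.
#' @param rng_seed Seed.
#' @return List: `dprime`, `null_interval` (5th/95th percentiles), `n_tex`,
#'   `n_scr`.
#' @export
area_dprime <- function(tensor, roi, resp_ms = c(200, 400),
                        null_ms = c(-300, 0), n_null = 200, rng_seed = 1L) {
  mask <- if (inherits(roi, "area_roi")) roi$mask else roi
  roi_means <- function(window_ms) {
    er <- exemplar_responses(tensor, window_ms)
    v <- apply(er$values, 1, function(m) mean(m[mask]))
    split(v, er$info$stim_class)
  }
  resp <- roi_means(resp_ms)
  if (length(resp$texture) < 2 || length(resp$scramble) < 2)
    stop("need at least 2 exemplars per class")
  dp <- dprime_pooled(resp$texture, resp$scramble)
  nullv <- roi_means(null_ms)
  pool <- c(nullv$texture, nullv$scramble)
  nt <- length(nullv$texture)
  nulld <- with_seed(rng_seed, replicate(n_null, {
    idx <- sample(length(pool), nt)
    dprime_pooled(pool[idx], pool[-idx])
  }))
  list(dprime = dp, null_interval = unname(quantile(nulld, c(0.05, 0.95))),
       n_tex = length(resp$texture), n_scr = length(resp$scramble))
}

#' Per-pixel texture-scramble d' map
#'
#' @param tensor A `trial_tensor`.
#' @param window_ms Response window; default `c(200, 400)`.
#' @return Matrix `[ny, nx]` of d' values.
#' @export
pixel_dprime_map <- function(tensor, window_ms = c(200, 400)) {
  er <- exemplar_responses(tensor, window_ms)
  d <- dim(er$values)
  flat <- matrix(er$values, d[1], d[2] * d[3])
  tex <- flat[er$info$stim_class == "texture", , drop = FALSE]
  scr <- flat[er$info$stim_class == "scramble", , drop = FALSE]
  pv <- 0.5 * (apply(tex, 2, var) + apply(scr, 2, var))
  dp <- (colMeans(tex) - colMeans(scr)) / sqrt(pv)
  dp[pv == 0] <- NA_real_
  matrix(dp, d[2], d[3])
}

#' Visual-field gradient of discriminability
#'
#' Compares mean pixel d' between the upper (`[0, 40]` deg elevation) and
#' lower (`[-40, 0]`) visual fields within `[-20, 20]` deg azimuth, and
#' between the left and right fields within `[-20, 20]` deg elevation,
#' using two-sided t-tests.
#'
#' @param dprime_map Matrix of pixel d' values.
#' @param azimuth,elevation Retinotopic maps (degrees).
#' @return Data frame with one row per comparison: means, difference,
#'   p-value.
#' @export
field_gradient_dprime <- function(dprime_map, azimuth, elevation) {
  sel <- function(az_rng, el_rng)
    dprime_map[azimuth >= az_rng[1] & azimuth <= az_rng[2] &
                 elevation >= el_rng[1] & elevation <= el_rng[2] &
                 !is.na(dprime_map)]
  cmp <- function(name, g1, g2) {
    pt <- if (length(g1) > 1 && length(g2) > 1) t.test(g1, g2)$p.value else NA_real_
    data.frame(comparison = name, mean1 = mean(g1), mean2 = mean(g2),
               difference = mean(g1) - mean(g2), p_value = pt,
               stringsAsFactors = FALSE)
  }
  rbind(
    cmp("upper_vs_lower", sel(c(-20, 20), c(0, 40)), sel(c(-20, 20), c(-40, 0))),
    cmp("left_vs_right", sel(c(-40, 0), c(-20, 20)), sel(c(0, 40), c(-20, 20))))
}
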