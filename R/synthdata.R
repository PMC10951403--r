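# Synthetic ground-truth generators for every input the pipeline consumes:
# texture image families, trial schedules, dual-channel widefield movies,
# two-photon soma/neuropil traces, and go/no-go behavioral sessions.
# Every generator is a pure function of (parameters, seed).

#' Default texture-family parameters
#'
#' Four families with distinct envelope-correlation strengths (kappa) and
#' orientation biases. Kappa controls the strength of the shared multiplicative
#' envelope, i.e. the family's higher-order (energy) correlations; at kappa = 0
#' the images are Gaussian and statistically identical to their own phase
#' scrambles. "rocks" is given the weakest higher-order structure, so its
#' texture-scramble distance in energy statistics is the smallest of the four.
#'
#' @return Data frame with one row per family.
#' @export
default_family_params <- function() {
  data.frame(
    family = c("scales", "rocks", "honeycomb", "plants"),
    kappa = c(0.70, 0.10, 0.90, 0.55),
    ori_deg = c(45, NA, 0, 90),          # NA = isotropic
    ori_bw_deg = c(30, NA, 25, 35),
    sf_peak = c(0.10, 0.08, 0.12, 0.09), # cycles / pixel
    sf_bw_oct = c(0.8, 1.0, 0.6, 0.9),
    stringsAsFactors = FALSE)
}

# Oriented band-pass filter (log-Gaussian radial x wrapped-Gaussian angular)
# applied to white noise in the frequency domain.
filtered_noise <- function(n, sf_peak, sf_bw_oct, ori_deg = NA, ori_bw_deg = NA) {
  g <- freq_grids(n)
  fr <- g$r / (2 * pi)                   # cycles / pixel
  rad <- exp(-(log2(pmax(fr, 1e-9) / sf_peak))^2 / (2 * sf_bw_oct^2))
  rad[1, 1] <- 0
  if (!is.na(ori_deg)) {
    d <- g$theta - ori_deg * pi / 180
    d <- atan2(sin(2 * d), cos(2 * d)) / 2   # wrap to (-pi/2, pi/2]
    rad <- rad * exp(-d^2 / (2 * (ori_bw_deg * pi / 180)^2))
  }
  noise <- matrix(rnorm(n * n), n)
  Re(ifft2(fft2(noise) * rad))
}

# Smooth positive random envelope (low-pass field, exponentiated). The
# cutoff is specified in cycles per image so that every exemplar contains a
# comparable number of envelope patches at any image size (ergodicity of the
# energy statistics is then size-independent); 5 cycles/image equals
# 0.02 cycles/pixel at the default 256-px size.
random_envelope <- function(n, cycles_per_image = 5, strength = 1) {
  g <- freq_grids(n)
  fr <- g$r / (2 * pi)
  lp <- exp(-(fr * n / cycles_per_image)^2)
  z <- Re(ifft2(fft2(matrix(rnorm(n * n), n)) * lp))
  z <- (z - mean(z)) / sqrt(pop_var(z))
  exp(strength * z)
}

#' Generate one synthetic texture family
#'
#' Exemplars are oriented filtered-noise carriers multiplied by a smooth
#' random envelope raised to the power `kappa`, followed by a mild pointwise
#' nonlinearity whose strength also scales with `kappa`
#' (`g(x) = sign(x) |x|^(1 - 0.3 kappa)`). The multiplicative envelope creates
#' family-specific energy cross-correlations across positions, scales, and
#' orientations; `kappa = 0` yields Gaussian images whose energy statistics
#' match their own phase scrambles up to sampling error.
#'
#' @param params One-row data frame as in [default_family_params()], or a list
#'   with the same fields.
#' @param n_exemplars Number of exemplars; default 20.
#' @param size Image side in pixels; default 256.
#' @param pixels_per_degree Pixel scale; default `size / 100` (a 100-degree
#'   stimulus spans the image).
#' @param rng_seed Integer seed.
#' @param normalize Apply [normalize_luminance_contrast()] (sigma 0.15,
#'   mu 0.5); default TRUE.
#' @return An [image_set] of textures.
#' @export
make_texture_family <- function(params, n_exemplars = 20, size = 256,
                                pixels_per_degree = size / 100, rng_seed = 1L,
                                normalize = TRUE) {
  params <- as.list(params)
  stopifnot(params$kappa >= 0, params$kappa <= 1)
  imgs <- with_seed(rng_seed, {
    lapply(seq_len(n_exemplars), function(e) {
      carrier <- filtered_noise(size, params$sf_peak, params$sf_bw_oct,
                                params$ori_deg, params$ori_bw_deg)
      env <- random_envelope(size)
      x <- carrier * env^params$kappa
      x <- sign(x) * abs(x)^(1 - 0.3 * params$kappa)
      im <- stim_image(x, family = params$family, stim_class = "texture",
                       exemplar_id = e, rotation_deg = 0,
                       pixels_per_degree = pixels_per_degree)
      if (normalize) normalize_luminance_contrast(im) else im
    })
  })
  image_set(imgs, provenance = c(params, list(n_exemplars = n_exemplars,
                                              size = size, rng_seed = rng_seed)))
}

#' Generate the full default stimulus set
#'
#' Four texture families with `n_exemplars` exemplars each; every texture is
#' phase-scrambled (seeded) to give the four matched scramble families; every
#' image appears at rotations 0 and 90 degrees. All images are normalized to
#' mean 0.5 and SD 0.15. With the defaults (20 exemplars) the set holds
#' exactly 8 x 20 x 2 = 320 images.
#'
#' @param family_params Data frame as [default_family_params()].
#' @param n_exemplars Exemplars per family; default 20.
#' @param size Image side in pixels; default 256.
#' @param pixels_per_degree Pixel scale; default `size / 100`.
#' @param rng_seed Integer seed.
#' @return An [image_set].
#' @export
make_full_image_set <- function(family_params = default_family_params(),
                                n_exemplars = 20, size = 256,
                                pixels_per_degree = size / 100, rng_seed = 1L) {
  images <- list()
  for (fi in seq_len(nrow(family_params))) {
    fam <- make_texture_family(family_params[fi, ], n_exemplars, size,
                               pixels_per_degree,
                               rng_seed = rng_seed + 1000L * fi)
    for (im in fam$images) {
      scr <- phase_scramble(im, rng_seed = rng_seed + 1000L * fi + im$exemplar_id)
      scr <- normalize_luminance_contrast(scr)
      images <- c(images, list(im, rotate90(im), scr, rotate90(scr)))
    }
  }
  image_set(images, provenance = list(rng_seed = rng_seed, size = size,
                                      n_exemplars = n_exemplars))
}

#' Build a randomized trial schedule
#'
#' Widefield mode: 8 categories x 20 exemplars x 10 repeats = 1600 stimulus
#' trials plus 200 blanks. Two-photon mode: 8 x 20 x 2 rotations x 8 repeats
#' = 2560 stimulus trials plus 160 blanks. Stimuli last 250 ms followed by a
#' 750 ms inter-trial interval; presentation order is fully randomized given
#' the seed.
#'
#' @param mode `"widefield"` or `"twophoton"`.
#' @param rng_seed Integer seed.
#' @param families Family labels; default the four default families.
#' @param n_exemplars Exemplars per family; default 20.
#' @param n_repeats Repeats per image; default 10 (widefield) or 8
#'   (two-photon).
#' @param n_blanks Blank trials; default 200 (widefield) or 160 (two-photon).
#' @param frame_rate Acquisition rate in Hz used to assign onset frames;
#'   default 20 (widefield) or 15 (two-photon).
#' @param stim_ms,iti_ms Stimulus and inter-trial durations; defaults 250
#'   and 750 ms.
#' @return Object of class `trial_schedule`: a data frame with one row per
#'   trial (family, stim_class, exemplar, rotation, blank, onset_s,
#'   onset_frame) and attributes for the timing parameters.
#' @export
make_trial_schedule <- function(mode = c("widefield", "twophoton"),
                                rng_seed = 1L,
                                families = default_family_params()$family,
                                n_exemplars = 20,
                                n_repeats = NULL, n_blanks = NULL,
                                frame_rate = NULL,
                                stim_ms = 250, iti_ms = 750) {
  mode <- match.arg(mode)
  if (is.null(n_repeats)) n_repeats <- if (mode == "widefield") 10L else 8L
  if (is.null(n_blanks)) n_blanks <- if (mode == "widefield") 200L else 160L
  if (is.null(frame_rate)) frame_rate <- if (mode == "widefield") 20 else 15
  rotations <- if (mode == "widefield") 0 else c(0, 90)
  base <- expand.grid(family = families, stim_class = c("texture", "scramble"),
                      exemplar = seq_len(n_exemplars), rotation = rotations,
                      repeat_id = seq_len(n_repeats),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$blank <- FALSE
  if (n_blanks > 0) {
    blanks <- data.frame(family = NA_character_, stim_class = NA_character_,
                         exemplar = NA_integer_, rotation = NA_real_,
                         repeat_id = NA_integer_, blank = TRUE)
    base <- rbind(base, blanks[rep(1, n_blanks), ])
  }
  ord <- with_seed(rng_seed, sample.int(nrow(base)))
  sched <- base[ord, , drop = FALSE]
  rownames(sched) <- NULL
  period_s <- (stim_ms + iti_ms) / 1000
  sched$trial <- seq_len(nrow(sched))
  sched$onset_s <- 1 + (sched$trial - 1) * period_s
  sched$onset_frame <- round(sched$onset_s * frame_rate) + 1L
  structure(sched, class = c("trial_schedule", "data.frame"),
            mode = mode, frame_rate = frame_rate, stim_ms = stim_ms,
            iti_ms = iti_ms, rng_seed = rng_seed)
}

# Double-exponential calcium impulse response (GCaMP surrogate), unit peak.
calcium_kernel <- function(frame_rate, rise_s = 0.05, decay_s = 0.5,
                           dur_s = 2.5) {
  t <- seq(0, dur_s, by = 1 / frame_rate)
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  k / max(k)
}

# Band-limited (< cutoff_hz) noise time series.
bandlimited_noise <- function(n, frame_rate, cutoff_hz = 4) {
  bf <- signal::butter(2, min(0.95, cutoff_hz / (frame_rate / 2)), type = "low")
  x <- signal::filtfilt(bf, rnorm(n))
  as.numeric((x - mean(x)) / sd(x))
}

#' Ground-truth parameters for a widefield simulation
#'
#' Two Gaussian cortical "areas" (V1 and LM) on a square pixel grid, with
#' linear azimuth/elevation retinotopy, an LM:V1 texture-gain ratio (default
#' 2), an upper-visual-field texture-modulation bias inside V1, and a shared
#' hemodynamic artifact with coupling `c_true` and offset `d_true`. The
#' offset is 0 by construction: after per-channel detrending a constant
#' offset is not identifiable, so the generator programs none.
#'
#' @param npx Grid side in pixels; default 64.
#' @param tex_gain_v1 Fractional texture-vs-scramble response gain in V1;
#'   default 0.15.
#' @param tex_gain_ratio LM:V1 texture-gain ratio; default 2.
#' @param upper_bias Elevation slope of V1 texture gain; default 0.5.
#' @param c_true,d_true Hemodynamic coupling and offset; defaults 0.8 and 0.
#' @param artifact_sd ΔF/F SD of the artifact; default 0.015.
#' @param noise_sd Per-frame pixel noise SD (ΔF/F); default 0.002
#'   (shot-noise-limited widefield imaging, small against the 1-2%
#'   hemodynamic fluctuations).
#' @param amp Peak stimulus-evoked ΔF/F in area centres; default 0.02.
#' @return List of ground-truth fields (gain maps, retinotopy, coefficients).
#' @export
widefield_ground_truth <- function(npx = 64, tex_gain_v1 = 0.15,
                                   tex_gain_ratio = 2, upper_bias = 0.5,
                                   c_true = 0.8, d_true = 0,
                                   artifact_sd = 0.015, noise_sd = 0.002,
                                   amp = 0.02) {
  x <- matrix(seq(0, 1, length.out = npx), npx, npx, byrow = TRUE)
  y <- matrix(seq(0, 1, length.out = npx), npx, npx)
  blob <- function(cx, cy, w) exp(-(((x - cx)^2 + (y - cy)^2)) / (2 * w^2))
  v1 <- blob(0.30, 0.5, 0.13)
  lm <- blob(0.72, 0.5, 0.10)
  v1_mask <- v1 > exp(-2)
  lm_mask <- lm > exp(-2)
  # retinotopy: azimuth along x, elevation along y within each area
  azimuth <- (x - 0.3) / 0.26 * 40
  azimuth[lm_mask] <- (x[lm_mask] - 0.72) / 0.2 * 40
  elevation <- (0.5 - y) / 0.26 * 40
  list(npx = npx, gain_v1 = v1, gain_lm = lm,
       v1_mask = v1_mask, lm_mask = lm_mask,
       azimuth = azimuth, elevation = elevation,
       tex_gain_v1 = tex_gain_v1,
       tex_gain_lm = tex_gain_v1 * tex_gain_ratio,
       upper_bias = upper_bias,
       c_true = c_true, d_true = d_true,
       artifact_sd = artifact_sd, noise_sd = noise_sd, amp = amp)
}

#' Simulate a dual-channel widefield session
#'
#' The blue channel carries the calcium signal (per-pixel gain maps times a
#' trial drive convolved with a double-exponential calcium kernel) plus a
#' shared band-limited (< 5 Hz) hemodynamic artifact scaled by `c_true`; the
#' violet channel carries the artifact alone (calcium-independent) plus
#' noise. Fluorescence is returned in raw units (`F = F0 (1 + dff)` with a
#' slow linear drift) so the full preprocessing chain can be exercised.
#' Texture trials drive LM with `tex_gain_lm > tex_gain_v1`, and within V1
#' the texture modulation grows with elevation (upper-field bias).
#'
#' @param schedule A `trial_schedule` (widefield mode; may be desk-scaled).
#' @param truth Output of [widefield_ground_truth()].
#' @param rng_seed Integer seed.
#' @param f0_blue,f0_violet Baseline fluorescence; defaults 1000 and 600.
#' @param drift_per_s Linear drift in F units per second; default -0.02.
#' @return List: `blue`, `violet` (arrays `[frames, npx, npx]`), `frame_rate`,
#'   `schedule`, `truth`, plus the noiseless `dff_calcium` and `artifact`
#'   ΔF/F components for validation.
#' @export
simulate_widefield_session <- function(schedule, truth, rng_seed = 1L,
                                       f0_blue = 1000, f0_violet = 600,
                                       drift_per_s = -0.02) {
  fr <- attr(schedule, "frame_rate")
  npx <- truth$npx
  kern <- calcium_kernel(fr)
  n_frames <- max(schedule$onset_frame) + length(kern) + fr
  el_norm <- truth$elevation / 40
  gain_tex_map <- truth$gain_v1 * truth$tex_gain_v1 * (1 + truth$upper_bias * el_norm) +
    truth$gain_lm * truth$tex_gain_lm
  gain_all_map <- truth$gain_v1 + truth$gain_lm

  # trial impulse trains for "any stimulus" and "texture extra" drives
  imp_all <- numeric(n_frames)
  imp_tex <- numeric(n_frames)
  st <- schedule[!schedule$blank, ]
  imp_all[st$onset_frame] <- imp_all[st$onset_frame] + 1
  tx <- st[st$stim_class == "texture", ]
  imp_tex[tx$onset_frame] <- imp_tex[tx$onset_frame] + 1
  conv_k <- function(x) {
    out <- stats::convolve(x, rev(kern), type = "open")[seq_along(x)]
    out
  }
  drive_all <- conv_k(imp_all) * truth$amp
  drive_tex <- conv_k(imp_tex) * truth$amp

  with_seed(rng_seed, {
    art_t <- bandlimited_noise(n_frames, fr, 4) * truth$artifact_sd
    art_gain <- 0.5 + matrix(runif(npx * npx), npx)      # vascular heterogeneity
    dff_cal <- outer(drive_all, as.vector(gain_all_map)) +
      outer(drive_tex, as.vector(gain_tex_map))
    art <- outer(art_t, as.vector(art_gain))
    dff_blue <- dff_cal + truth$c_true * art + truth$d_true +
      matrix(rnorm(length(dff_cal), sd = truth$noise_sd), nrow = n_frames)
    dff_violet <- art +
      matrix(rnorm(length(art), sd = truth$noise_sd), nrow = n_frames)
    tsec <- (seq_len(n_frames) - 1) / fr
    blue <- f0_blue * (1 + dff_blue) + drift_per_s * tsec
    violet <- f0_violet * (1 + dff_violet) + drift_per_s * tsec
    list(blue = array(blue, c(n_frames, npx, npx)),
         violet = array(violet, c(n_frames, npx, npx)),
         frame_rate = fr, schedule = schedule, truth = truth,
         dff_calcium = array(dff_cal, c(n_frames, npx, npx)),
         artifact = art_t)
  })
}

#' Ground truth for a two-photon simulation
#'
#' Per-cell linear weights on the 8 reduced PS features (2 PCs x 4 groups).
#' Responsive cells draw weights concentrated on the energy-group features by
#' default; a configurable fraction of cells is silent (zero weights and
#' baseline response).
#'
#' @param n_cells Number of cells; default 60.
#' @param silent_frac Fraction of silent cells; default 0.3.
#' @param energy_weight_sd SD of energy-feature weights; default 8 (ΔF/F %
#'   per z-scored feature unit).
#' @param other_weight_sd SD of the remaining feature weights; default 1.5.
#' @param baseline Mean evoked response offset (ΔF/F %); default 12.
#' @param noise_sd Trial-to-trial response noise (ΔF/F %); default 2.
#' @param neuropil_r Neuropil mixing coefficient; fixed at 0.7.
#' @param drift_per_s Linear drift (F units/s); default -0.01.
#' @param rng_seed Seed for weight draws.
#' @return List with `w_true` (cells x 8), `baseline`, `silent`, and the
#'   nuisance parameters.
#' @export
twophoton_ground_truth <- function(n_cells = 60, silent_frac = 0.3,
                                   energy_weight_sd = 8, other_weight_sd = 1.5,
                                   baseline = 12, noise_sd = 2,
                                   neuropil_r = 0.7, drift_per_s = -0.01,
                                   rng_seed = 1L) {
  with_seed(rng_seed, {
    silent <- runif(n_cells) < silent_frac
    w <- cbind(matrix(rnorm(n_cells * 6, sd = other_weight_sd), n_cells),
               matrix(rnorm(n_cells * 2, sd = energy_weight_sd), n_cells))
    colnames(w) <- c(sprintf("marginal_pc%d", 1:2), sprintf("spectral_pc%d", 1:2),
                     sprintf("linear_cc_pc%d", 1:2), sprintf("energy_cc_pc%d", 1:2))
    w[silent, ] <- 0
    list(w_true = w, baseline = ifelse(silent, 0, baseline), silent = silent,
         noise_sd = noise_sd, neuropil_r = neuropil_r,
         drift_per_s = drift_per_s)
  })
}

#' Simulate a two-photon session
#'
#' Per-cell trial amplitudes are `max(0, w_true . x + baseline)` (ΔF/F %),
#' scaling a double-exponential calcium kernel. The neuropil trace is shared
#' across cells (band-limited noise plus a small stimulus-locked component);
#' observed soma fluorescence is `Fs = Fs_true + r Fn`, so neuropil
#' correction with the same `r` recovers the true soma trace exactly in the
#' noiseless case. A linear drift is added to the true soma signal.
#'
#' @param features Matrix (stimuli x 8) of reduced PS features with rownames
#'   `"family|stim_class|exemplar|rotation"`, or any feature matrix whose rows
#'   can be matched to schedule trials via `feature_key()`.
#' @param schedule A `trial_schedule` (twophoton mode; may be desk-scaled).
#' @param truth Output of [twophoton_ground_truth()].
#' @param rng_seed Integer seed.
#' @param f0 Baseline soma fluorescence; default 200.
#' @param fn0 Baseline neuropil fluorescence; default 150.
#' @param pre_s Stimulus-free seconds prepended for baseline estimation;
#'   default 6.
#' @return List: `soma`, `neuropil` (cells x frames), `frame_rate`,
#'   `schedule`, `truth`, `soma_true`, and `amplitudes` (cells x trials,
#'   ΔF/F %).
#' @export
simulate_twophoton_session <- function(features, schedule, truth,
                                       rng_seed = 1L, f0 = 200, fn0 = 150,
                                       pre_s = 6) {
  fr <- attr(schedule, "frame_rate")
  pre_f <- round(pre_s * fr)
  sched <- schedule
  sched$onset_frame <- sched$onset_frame + pre_f
  n_cells <- nrow(truth$w_true)
  kern <- calcium_kernel(fr)
  n_frames <- max(sched$onset_frame) + length(kern) + fr
  keys <- feature_key(sched)
  fidx <- match(keys, rownames(features))
  if (any(is.na(fidx) & !sched$blank))
    stop("schedule contains stimuli with no matching feature row")
  with_seed(rng_seed, {
    amp <- matrix(0, n_cells, nrow(sched))
    stim <- which(!sched$blank)
    x <- features[fidx[stim], , drop = FALSE]
    amp[, stim] <- pmax(0, truth$w_true %*% t(x) + truth$baseline +
                          matrix(rnorm(n_cells * length(stim), sd = truth$noise_sd),
                                 n_cells))
    dff_true <- matrix(0, n_cells, n_frames)
    for (tr in seq_len(nrow(sched))) {
      on <- sched$onset_frame[tr]
      idx <- on:min(n_frames, on + length(kern) - 1)
      if (any(amp[, tr] > 0))
        dff_true[, idx] <- dff_true[, idx] + amp[, tr] %o% kern[seq_along(idx)]
    }
    tsec <- (seq_len(n_frames) - 1) / fr
    soma_true <- f0 * (1 + dff_true / 100) +
      matrix(rep(truth$drift_per_s * tsec, each = n_cells), n_cells)
    fn_t <- fn0 * (1 + 0.03 * bandlimited_noise(n_frames, fr, 2) +
                     0.01 * stats::convolve(
                       {v <- numeric(n_frames); v[sched$onset_frame[stim]] <- 1; v},
                       rev(kern), type = "open")[seq_len(n_frames)])
    neuropil <- matrix(rep(fn_t, each = n_cells), n_cells)
    soma <- soma_true + truth$neuropil_r * neuropil
    list(soma = soma, neuropil = neuropil, frame_rate = fr, schedule = sched,
         truth = truth, soma_true = soma_true, amplitudes = amp,
         pre_frames = pre_f)
  })
}

#' Stimulus key used to match schedule rows to feature/response rows
#'
#' @param x A schedule or manifest data frame with family, stim_class,
#'   exemplar (or exemplar_id), and rotation (or rotation_deg) columns.
#' @return Character vector `"family|stim_class|exemplar|rotation"`; `NA`
#'   for blank trials.
#' @export
feature_key <- function(x) {
  ex <- if ("exemplar" %in% names(x)) x$exemplar else x$exemplar_id
  rot <- if ("rotation" %in% names(x)) x$rotation else x$rotation_deg
  blank <- if (is.null(x$blank)) rep(FALSE, nrow(x)) else x$blank %in% TRUE
  ifelse(blank, NA_character_,
         paste(x$family, x$stim_class, ex, rot, sep = "|"))
}

#' Simulate go/no-go behavioral sessions
#'
#' An equal-variance signal-detection observer: on each trial the decision
#' variable is `sensitivity x I(go stimulus) + N(0, 1)` and the observer
#' responds when it exceeds the unbiased criterion `sensitivity / 2`. Hit and
#' false-alarm rates therefore follow the standard model with
#' `d' = sensitivity`.
#'
#' @param sensitivities Named numeric vector of programmed d' per family (or
#'   family pair).
#' @param n_sessions Sessions per family; default 5.
#' @param trials_per_session Trials per session; default 400.
#' @param rng_seed Integer seed.
#' @return Data frame of trials: session, family, go, response.
#' @export
simulate_behavior_sessions <- function(sensitivities, n_sessions = 5,
                                       trials_per_session = 400, rng_seed = 1L) {
  with_seed(rng_seed, {
    out <- list()
    for (f in names(sensitivities)) {
      s <- sensitivities[[f]]
      for (ses in seq_len(n_sessions)) {
        go <- runif(trials_per_session) < 0.5
        dv <- s * go + rnorm(trials_per_session)
        out[[length(out) + 1L]] <- data.frame(
          family = f, session = ses, go = go, response = dv > s / 2,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
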