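test_that("channel ΔF/F removes trends and recovers embedded signals", {
  fr <- 20
  t <- (0:399) / fr
  # pure linear ramp -> zero output
  ramp <- matrix(5 + 2 * t, ncol = 1)
  expect_lt(max(abs(channel_dff(ramp, fr))), 1e-12)
  # constant F = b -> zero output
  expect_lt(max(abs(channel_dff(matrix(7, 400, 1), fr))), 1e-12)
  # ramp + known sinusoid -> sinusoid / intercept (least-squares oracle)
  b <- 10; a <- 0.5
  s <- sin(2 * pi * 1.3 * t)
  F <- matrix(b + a * t + s, ncol = 1)
  out <- channel_dff(F, fr)
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% F)     # independent LS oracle
  oracle <- (F - X %*% beta) / beta[1]
  expect_lt(max(abs(out - oracle)), 1e-10)
  # near-zero intercept is masked
  Fz <- matrix(0.000001 + 0 * t, ncol = 1)
  expect_true(all(is.na(channel_dff(cbind(Fz, F), fr)[, 1])))
})

test_that("hemodynamic correction recovers programmed coupling coefficients", {
  set.seed(30)
  fr <- 20; nf <- 1200
  t <- (0:(nf - 1)) / fr
  art <- as.numeric(signal::filtfilt(signal::butter(2, 0.3), rnorm(nf)))
  sig <- sin(2 * pi * 0.7 * t)
  # violet carries the artifact; blue = signal + 0.8 * artifact_lp + 0.1
  bf <- signal::butter(6, 5 / (fr / 2), type = "low")
  art_lp <- as.numeric(signal::filtfilt(bf, art))
  blue <- matrix(sig + 0.8 * art_lp + 0.1, ncol = 1)
  violet <- matrix(art, ncol = 1)
  hc <- hemodynamic_correct(blue, violet, frame_rate = fr)
  expect_lt(abs(hc$fit[1, "c"] - 0.8), 0.8 * 0.05)
  expect_lt(abs(hc$fit[1, "d"] - 0.1), 0.02)
  expect_gt(cor(hc$corrected[, 1], sig), 0.99)
  # violet uncorrelated with blue: c ~ 0, output ~ blue
  v2 <- matrix(rnorm(nf), ncol = 1)
  hc2 <- hemodynamic_correct(matrix(sig, ncol = 1), v2, frame_rate = fr)
  expect_lt(abs(hc2$fit[1, "c"]), 0.05)
  expect_gt(cor(hc2$corrected[, 1], sig), 0.99)
})

test_that("full synthetic session: corrected signal decorrelates from the artifact", {
  # full-length schedule: the residual artifact correlation scales with
  # 1/sqrt(session length), so the full-length trial count is used on a
  # small pixel grid
  sched <- make_trial_schedule("widefield", rng_seed = 4)
  truth <- widefield_ground_truth(npx = 8)
  sess <- simulate_widefield_session(sched, truth, rng_seed = 5)
  fr <- sess$frame_rate
  bd <- channel_dff(sess$blue, fr)
  vd <- channel_dff(sess$violet, fr)
  hc <- hemodynamic_correct(bd, vd, fr)
  # recovered c within 5% of truth (averaged over pixels)
  expect_lt(abs(mean(hc$fit[, "c"]) - truth$c_true) / truth$c_true, 0.05)
  # corrected traces within the visual areas no longer track the artifact
  # (background pixels carry no calcium signal, so their ratio of residual
  # artifact to noise is not the quantity the correction targets)
  mask <- as.vector(truth$v1_mask | truth$lm_mask)
  flatten <- matrix(hc$corrected, dim(bd)[1])
  cors <- vapply(which(mask),
                 function(j) abs(cor(flatten[, j], sess$artifact)), numeric(1))
  expect_lt(median(cors), 0.05)
  # uncorrected blue did track it
  braw <- matrix(bd, dim(bd)[1])
  cors_raw <- vapply(which(mask),
                     function(j) abs(cor(braw[, j], sess$artifact)), numeric(1))
  expect_gt(median(cors_raw), 0.5)
})

test_that("trial splitting aligns onsets and separates blanks", {
  sched <- make_trial_schedule("widefield", rng_seed = 6, n_exemplars = 3,
                               n_repeats = 2, n_blanks = 8)
  fr <- attr(sched, "frame_rate")
  nf <- max(sched$onset_frame) + 2 * fr
  movie <- array(rnorm(nf * 4 * 4), c(nf, 4, 4))
  tt <- split_trials(movie, sched, window_ms = c(-500, 1000))
  expect_identical(dim(tt$values)[1], sum(!sched$blank))
  expect_identical(nrow(tt$blank$trials), sum(sched$blank))
  # the frame at t = 0 is the movie frame at the scheduled onset index
  i0 <- which(tt$time_ms == 0)
  for (k in c(1, 5, 11))
    expect_identical(tt$values[k, i0, , ],
                     movie[tt$trials$onset_frame[k], , ])
  # trials whose window leaves the movie are dropped with a warning
  short <- array(rnorm(30 * 4 * 4), c(30, 4, 4))
  expect_warning(split_trials(short, sched), "dropping")
})

test_that("widefield default schedule yields the seven-dimensional tensor structure", {
  sched <- make_trial_schedule("widefield", rng_seed = 1)
  tab <- table(sched$stim_class, sched$family)
  expect_true(all(tab == 200))   # 20 exemplars x 10 repeats per class/family
  expect_identical(dim(tab), c(2L, 4L))
})

test_that("peak-response maps recover the programmed gain field", {
  sched <- make_trial_schedule("widefield", rng_seed = 7, n_exemplars = 4,
                               n_repeats = 4, n_blanks = 12)
  truth <- widefield_ground_truth(npx = 12, noise_sd = 0.002)
  sess <- simulate_widefield_session(sched, truth, rng_seed = 8)
  fr <- sess$frame_rate
  hc <- hemodynamic_correct(channel_dff(sess$blue, fr),
                            channel_dff(sess$violet, fr), fr)
  tt <- split_trials(array(hc$corrected, dim(sess$blue)), sched)
  pm <- peak_response_map(tt)
  prog <- truth$gain_v1 + truth$gain_lm   # dominant programmed spatial pattern
  expect_gt(cor(as.vector(pm), as.vector(prog)), 0.95)
  # all-zero tensor gives a zero map
  tz <- tt; tz$values[] <- 0
  expect_true(all(peak_response_map(tz) == 0))
  # a pre-stimulus window is much weaker than the peak; it is not zero
  # because at 1 s pacing the calcium kernel of the previous trial has not
  # fully decayed
  pre <- peak_response_map(tt, window_ms = c(-400, -200))
  expect_lt(max(abs(pre)), 0.75 * max(abs(pm)))
})

test_that("significance maps are calibrated on null data and detect programmed effects", {
  # null: no texture modulation anywhere
  sched <- make_trial_schedule("widefield", rng_seed = 9, n_exemplars = 8,
                               n_repeats = 4, n_blanks = 8)
  truth0 <- widefield_ground_truth(npx = 14, tex_gain_v1 = 0, upper_bias = 0,
                                   artifact_sd = 0, noise_sd = 0.01)
  sess <- simulate_widefield_session(sched, truth0, rng_seed = 10)
  tt <- split_trials(channel_dff(sess$blue, sess$frame_rate), sched)
  pm <- pixel_significance_map(tt, rng_seed = 1)
  frac <- mean(pm$p < 0.05)
  n <- length(pm$p)
  expect_lt(abs(frac - 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  # programmed LM modulation lights up LM pixels
  truth1 <- widefield_ground_truth(npx = 14, noise_sd = 0.002)
  sess1 <- simulate_widefield_session(sched, truth1, rng_seed = 11)
  hc <- hemodynamic_correct(channel_dff(sess1$blue, sess1$frame_rate),
                            channel_dff(sess1$violet, sess1$frame_rate),
                            sess1$frame_rate)
  tt1 <- split_trials(array(hc$corrected, dim(sess1$blue)), sched)
  pm1 <- pixel_significance_map(tt1, rng_seed = 1)
  expect_gt(mean(pm1$p[truth1$lm_mask] < 0.01), 0.8)
  # identical pre/post values give p = 1
  tz <- tt; tz$values[] <- 1
  pmz <- pixel_significance_map(tz, rng_seed = 1)
  expect_true(all(pmz$p == 1))
})

test_that("retinotopic ROIs equal the analytic rectangle", {
  az <- matrix(seq(-40, 40, length.out = 20), 20, 20, byrow = TRUE)
  el <- matrix(seq(40, -40, length.out = 20), 20, 20)
  roi <- roi_from_retinotopy(az, el, az_bounds = c(-10, 30),
                             el_bounds = c(-30, 30))
  expect_identical(roi$mask, az >= -10 & az <= 30 & el >= -30 & el <= 30)
  # bounds covering everything reproduce the area mask
  am <- matrix(rep(c(TRUE, FALSE), 200), 20)
  roi2 <- roi_from_retinotopy(az, el, c(-90, 90), c(-90, 90), area_mask = am)
  expect_identical(roi2$mask, am)
  expect_error(roi_from_retinotopy(az, el, c(100, 120), c(-30, 30)), "empty")
})

test_that("modulated fraction counts exactly", {
  p <- matrix(1, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  expect_identical(area_modulated_fraction(p, roi), 0)
  p[roi] <- 0.001
  expect_identical(area_modulated_fraction(p, roi), 1)
  p[1:5, 1:5] <- 0.5   # half the ROI significant
  expect_identical(area_modulated_fraction(p, roi, alpha = 0.01), 0.5)
})

test_that("area d' follows the pooled-variance formula and its null calibration", {
  # oracle equivalence on random instances
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(80, 2); y <- rnorm(80, 1)
    expect_equal(texgeom:::dprime_pooled(x, y), oracle_dprime_pooled(x, y),
                 tolerance = 1e-12)
  }
  # mu 2 vs 1 with unit variances -> d' = 1 exactly
  x <- c(1, 3); y <- c(0, 2)   # means 2,1; var 2,2 -> pooled sqrt(2)
  expect_equal(texgeom:::dprime_pooled(x, y), 1 / sqrt(2))
  expect_error(texgeom:::dprime_pooled(c(1, 1), c(1, 1)), "zero pooled")
  # affine invariance: common rescaling leaves d' unchanged
  a <- rnorm(40); b <- rnorm(40, 0.5)
  expect_equal(texgeom:::dprime_pooled(3 * a + 2, 3 * b + 2),
               texgeom:::dprime_pooled(a, b), tolerance = 1e-12)
})

test_that("area d' detects the programmed LM > V1 ordering", {
  sched <- make_trial_schedule("widefield", rng_seed = 12, n_exemplars = 6,
                               n_repeats = 4, n_blanks = 12)
  truth <- widefield_ground_truth(npx = 14, noise_sd = 0.003)
  sess <- simulate_widefield_session(sched, truth, rng_seed = 13)
  hc <- hemodynamic_correct(channel_dff(sess$blue, sess$frame_rate),
                            channel_dff(sess$violet, sess$frame_rate),
                            sess$frame_rate)
  tt <- split_trials(array(hc$corrected, dim(sess$blue)), sched)
  d_v1 <- area_dprime(tt, truth$v1_mask, rng_seed = 3)
  d_lm <- area_dprime(tt, truth$lm_mask, rng_seed = 3)
  expect_gt(d_lm$dprime, d_v1$dprime)
  expect_gt(d_lm$dprime, d_lm$null_interval[2])
  expect_lt(d_v1$null_interval[1], d_v1$null_interval[2])
})

test_that("field gradients report the programmed upper-field bias and flip with elevation", {
  set.seed(32)
  npx <- 30
  az <- matrix(seq(-40, 40, length.out = npx), npx, npx, byrow = TRUE)
  el <- matrix(seq(40, -40, length.out = npx), npx, npx)
  dmap <- 0.5 + 0.01 * el + matrix(rnorm(npx * npx, sd = 0.05), npx)
  g <- field_gradient_dprime(dmap, az, el)
  up <- g[g$comparison == "upper_vs_lower", ]
  expect_gt(up$difference, 0)
  expect_lt(up$p_value, 0.01)
  # flipping the elevation map flips the comparison
  g2 <- field_gradient_dprime(dmap, az, -el)
  expect_lt(g2$difference[g2$comparison == "upper_vs_lower"], 0)
  # symmetric map: difference near zero
  g3 <- field_gradient_dprime(matrix(0.5, npx, npx) +
                                matrix(rnorm(npx^2, sd = 0.05), npx), az, el)
  expect_lt(abs(g3$difference[1]), 0.05)
})
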