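# Single-cell (two-photon) preprocessing, responsiveness screening, d'
# metrics, and the ridge encoding model on reduced PS features with
# permutation thresholds and variance partitioning.

#' Preprocess two-photon traces
#'
#' Neuropil correction `Fc = Fs - r Fn`, baseline `Fu` from the first
#' `baseline_s` seconds (stimulus-free), linear detrending of `Fc` to a
#' zero-mean residual `Fd`, and `ΔF/F = 100 Fd / Fu` (%). Cells with a
#' non-positive baseline are masked.
#'
#' @param soma,neuropil Matrices (cells x frames) of raw fluorescence.
#' @param r Neuropil mixing coefficient; default 0.7.
#' @param baseline_s Seconds used for the baseline; default 5.
#' @param frame_rate Hz.
#' @return Object of class `cell_traces`: `dff` (%), `corrected`, `baseline`,
#'   `masked`, `r`, `frame_rate`.
#' @export
preprocess_traces <- function(soma, neuropil, r = 0.7, baseline_s = 5,
                              frame_rate) {
  stopifnot(identical(dim(soma), dim(neuropil)))
  fc <- soma - r * neuropil
  nb <- max(2, round(baseline_s * frame_rate))
  fu <- rowMeans(fc[, seq_len(min(nb, ncol(fc))), drop = FALSE])
  masked <- which(fu <= 0)
  t <- seq_len(ncol(fc))
  tc <- t - mean(t)
  a <- (fc %*% tc) / sum(tc^2)
  fd <- fc - a %*% t(tc)
  fd <- fd - rowMeans(fd)
  dff <- 100 * fd / fu
  if (length(masked)) dff[masked, ] <- NA_real_
  structure(list(dff = dff, corrected = fc, baseline = fu, masked = masked,
                 r = r, frame_rate = frame_rate),
            class = "cell_traces")
}

#' @export
print.cell_traces <- function(x, ...) {
  cat(sprintf("<cell_traces> %d cells x %d frames (%.3g Hz), %d masked\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate, length(x$masked)))
  invisible(x)
}

#' Frame-zero corrected trial tensor for cell traces
#'
#' Extracts per-trial windows of ΔF/F and subtracts each trial's mean
#' activity in the pre-stimulus window. Stimulus and blank trials are
#' separated.
#'
#' @param traces A `cell_traces` object (or ΔF/F matrix with `frame_rate`).
#' @param schedule A `trial_schedule` with onset frames valid for the traces.
#' @param window_ms Trial window; default `c(-500, 1000)`.
#' @param pre_ms Baseline window subtracted per trial; default `c(-500, 0)`.
#' @return Object of class `cell_tensor`: `values` `[cell, trial, frame]`,
#'   `trials`, `time_ms`, `blank`.
#' @export
frame_zero_tensor <- function(traces, schedule, window_ms = c(-500, 1000),
                              pre_ms = c(-500, 0)) {
  dff <- if (inherits(traces, "cell_traces")) traces$dff else traces
  fr <- if (inherits(traces, "cell_traces")) traces$frame_rate else attr(traces, "frame_rate")
  rel <- seq(round(window_ms[1] / 1000 * fr), round(window_ms[2] / 1000 * fr))
  time_ms <- rel / fr * 1000
  ok <- schedule$onset_frame + min(rel) >= 1 &
    schedule$onset_frame + max(rel) <= ncol(dff)
  if (any(!ok))
    warning(sprintf("dropping %d trials outside the recording", sum(!ok)))
  sched <- schedule[ok, , drop = FALSE]
  # half-open window: the onset frame itself belongs to the response
  prei <- which(time_ms >= pre_ms[1] & time_ms < pre_ms[2])
  grab <- function(rows) {
    vals <- array(NA_real_, c(nrow(dff), nrow(rows), length(rel)))
    for (i in seq_len(nrow(rows))) {
      w <- dff[, rows$onset_frame[i] + rel, drop = FALSE]
      vals[, i, ] <- w - rowMeans(w[, prei, drop = FALSE])
    }
    vals
  }
  st <- sched[!sched$blank, , drop = FALSE]
  bl <- sched[sched$blank, , drop = FALSE]
  structure(list(values = grab(st), trials = st, time_ms = time_ms,
                 blank = list(values = grab(bl), trials = bl),
                 frame_rate = fr),
            class = "cell_tensor")
}

cell_window_means <- function(tensor, window_ms = c(250, 500), blank = FALSE) {
  wf <- which(tensor$time_ms >= window_ms[1] & tensor$time_ms <= window_ms[2])
  src <- if (blank) tensor$blank$values else tensor$values
  apply(src[, , wf, drop = FALSE], c(1, 2), mean)
}

#' Screen for stimulus-responsive cells
#'
#' Per cell and stimulus exemplar, computes
#' `d'_stim = (mu_stim - mu_blank) / (sd_stim + sd_blank)` from window-mean
#' responses across repeats versus blank trials. A cell is responsive when
#' its maximum `d'_stim` is at least `d_min` and its maximum repeat-averaged
#' response is at least `dff_min_pct` (ΔF/F %).
#'
#' @param tensor A `cell_tensor` (with blank trials).
#' @param window_ms Response window; default `c(250, 500)`.
#' @param d_min Minimum d'; default 1.
#' @param dff_min_pct Minimum response; default 6.
#' @return List: `responsive` (logical per cell), `dprime_stim`
#'   (cells x exemplar-conditions), `max_response`.
#' @export
select_responsive <- function(tensor, window_ms = c(250, 500), d_min = 1,
                              dff_min_pct = 6) {
  wm <- cell_window_means(tensor, window_ms)
  bm <- cell_window_means(tensor, window_ms, blank = TRUE)
  if (ncol(bm) < 2) stop("need at least 2 blank trials")
  tr <- tensor$trials
  key <- feature_key(tr)
  ukey <- unique(key)
  mu_b <- rowMeans(bm)
  sd_b <- apply(bm, 1, sd)
  dstim <- sapply(ukey, function(k) {
    idx <- which(key == k)
    if (length(idx) < 2) return(rep(NA_real_, nrow(wm)))
    mu_s <- rowMeans(wm[, idx, drop = FALSE])
    sd_s <- apply(wm[, idx, drop = FALSE], 1, sd)
    den <- sd_s + sd_b
    ifelse(den > 0, (mu_s - mu_b) / den, NA_real_)
  })
  mean_resp <- sapply(ukey, function(k)
    rowMeans(wm[, key == k, drop = FALSE]))
  max_d <- apply(dstim, 1, max, na.rm = TRUE)
  max_r <- apply(mean_resp, 1, max, na.rm = TRUE)
  list(responsive = max_d >= d_min & max_r >= dff_min_pct,
       dprime_stim = dstim, max_response = max_r)
}

#' Per-exemplar response table
#'
#' Cells x stimuli matrix of frame-zero corrected ΔF/F averaged over repeats
#' and the response window; column names are [feature_key()] strings.
#'
#' @param tensor A `cell_tensor`.
#' @param window_ms Response window; default `c(250, 500)`.
#' @return Matrix cells x stimuli with a `stimuli` attribute (data frame).
#' @export
cell_response_table <- function(tensor, window_ms = c(250, 500)) {
  wm <- cell_window_means(tensor, window_ms)
  key <- feature_key(tensor$trials)
  ukey <- unique(key)
  out <- sapply(ukey, function(k) rowMeans(wm[, key == k, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, ukey))
  info <- tensor$trials[match(ukey, key),
                        c("family", "stim_class", "exemplar", "rotation")]
  rownames(info) <- NULL
  attr(out, "stimuli") <- info
  out
}

#' Per-cell texture-scramble d'
#'
#' Pooled-variance standardized mean difference between each cell's responses
#' to texture and scramble exemplars (exemplars and rotations pooled by
#' default; set `by_family` to get one value per family).
#'
#' @param table Response table from [cell_response_table()].
#' @param by_family Compute per family; default FALSE (pooled).
#' @return Numeric vector (cells) or matrix (cells x families).
#' @export
cell_texscr_dprime <- function(table, by_family = FALSE) {
  info <- attr(table, "stimuli")
  one <- function(cols_t, cols_s, x)
    (mean(x[cols_t]) - mean(x[cols_s])) /
      sqrt(0.5 * (var(x[cols_t]) + var(x[cols_s])))
  if (!by_family) {
    ct <- which(info$stim_class == "texture")
    cs <- which(info$stim_class == "scramble")
    apply(table, 1, function(x) one(ct, cs, x))
  } else {
    fams <- unique(info$family)
    out <- sapply(fams, function(f) {
      ct <- which(info$stim_class == "texture" & info$family == f)
      cs <- which(info$stim_class == "scramble" & info$family == f)
      apply(table, 1, function(x) one(ct, cs, x))
    })
    colnames(out) <- fams
    out
  }
}

# Closed-form ridge solution for centred X, y: (X'X + lambda I)^-1 X'y.
ridge_solve <- function(X, y, lambda) {
  p <- ncol(X)
  solve(crossprod(X) + diag(lambda, p), crossprod(X, y))
}

#' Fit ridge encoding models on reduced PS features
#'
#' For each cell, predicts window-mean responses to all stimuli as a linear
#' function of the reduced PS features (default: first two PCs of each of the
#' four groups), minimizing `||y - Xw||^2 + lambda ||w||^2` with an
#' unpenalized intercept (responses are centred per fold). `lambda` is chosen
#' per cell by grid search on cross-validated explained variance
#' (`EV = 1 - SSE/SST` on held-out folds, in %; negative values are reported
#' as-is). Folds are stratified over stimulus categories and seeded.
#'
#' @param table Response table (cells x stimuli) from
#'   [cell_response_table()].
#' @param features Matrix (stimuli x features) with rownames matching the
#'   table's column keys; typically 8 columns (2 PCs x 4 groups).
#' @param folds Number of CV folds; default 5.
#' @param lambda_grid Ridge grid; default 13 points log-spaced 1e-3..1e3.
#' @param rng_seed Seed for fold assignment.
#' @return Object of class `encoding_fit`: `weights` (cells x features),
#'   `intercept`, `lambda`, `cv_ev` (%), `folds`, `feature_names`.
#' @export
fit_encoding_model <- function(table, features, folds = 5,
                               lambda_grid = 10^seq(-3, 3, by = 0.5),
                               rng_seed = 1L) {
  X <- as.matrix(features)[colnames(table), , drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("degenerate (rank-deficient) feature matrix")
  info <- attr(table, "stimuli")
  strat <- paste(info$family, info$stim_class)
  fold <- stratified_folds(strat, folds, rng_seed)
  n_cells <- nrow(table)
  W <- matrix(NA_real_, n_cells, ncol(X),
              dimnames = list(rownames(table), colnames(X)))
  b0 <- lam <- ev <- numeric(n_cells)
  for (ci in seq_len(n_cells)) {
    y <- table[ci, ]
    cvev <- sapply(lambda_grid, function(l) {
      se <- st <- 0
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xm <- colMeans(X[tr, , drop = FALSE]); ym <- mean(y[tr])
        w <- ridge_solve(sweep(X[tr, , drop = FALSE], 2, Xm), y[tr] - ym, l)
        pred <- sweep(X[!tr, , drop = FALSE], 2, Xm) %*% w + ym
        se <- se + sum((y[!tr] - pred)^2)
        st <- st + sum((y[!tr] - mean(y[tr]))^2)
      }
      100 * (1 - se / st)
    })
    best <- which.max(cvev)
    lam[ci] <- lambda_grid[best]
    ev[ci] <- cvev[best]
    Xm <- colMeans(X); ym <- mean(y)
    W[ci, ] <- ridge_solve(sweep(X, 2, Xm), y - ym, lam[ci])
    b0[ci] <- ym - sum(W[ci, ] * Xm)
  }
  structure(list(weights = W, intercept = b0, lambda = lam, cv_ev = ev,
                 folds = fold, feature_names = colnames(X),
                 lambda_grid = lambda_grid, rng_seed = rng_seed),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d cells x %d features; median CV EV %.1f%%\n",
              nrow(x$weights), ncol(x$weights), median(x$cv_ev)))
  invisible(x)
}

#' @export
coef.encoding_fit <- function(object, ...) object$weights

#' Predict responses from a fitted encoding model
#'
#' @param object An `encoding_fit`.
#' @param features Matrix (stimuli x features).
#' @param ... Unused.
#' @return Matrix cells x stimuli of predicted responses.
#' @export
predict.encoding_fit <- function(object, features, ...) {
  object$weights %*% t(as.matrix(features)) + object$intercept
}

#' Permutation threshold for encoding-model explained variance
#'
#' Refits every cell after permuting the assignment of feature rows to
#' stimuli (seeded; `n_shuffles` independent permutations, pooled across
#' cells) and returns the `1 - alpha` quantile of the shuffled
#' cross-validated EV distribution.
#'
#' @param table Response table (cells x stimuli).
#' @param features Feature matrix (stimuli x features).
#' @param n_shuffles Permutations; default 20 (EVs pool across cells).
#' @param alpha Significance level; default 0.05.
#' @param folds,lambda_grid,rng_seed As in [fit_encoding_model()].
#' @return List: `threshold` (EV %, the `1-alpha` shuffled quantile),
#'   `shuffled_ev` (all shuffled EVs).
#' @export
permutation_ev_threshold <- function(table, features, n_shuffles = 20,
                                     alpha = 0.05, folds = 5,
                                     lambda_grid = 10^seq(-3, 3, by = 0.5),
                                     rng_seed = 1L) {
  X <- as.matrix(features)[colnames(table), , drop = FALSE]
  evs <- unlist(lapply(seq_len(n_shuffles), function(s) {
    perm <- with_seed(rng_seed + s, sample(nrow(X)))
    Xp <- X[perm, , drop = FALSE]
    rownames(Xp) <- rownames(X)
    fit <- fit_encoding_model(table, Xp, folds = folds,
                              lambda_grid = lambda_grid,
                              rng_seed = rng_seed + s)
    fit$cv_ev
  }))
  list(threshold = unname(quantile(evs, 1 - alpha)), shuffled_ev = evs)
}

#' Per-group summed absolute weights
#'
#' `W_i = sum_j |w_ij|` over the features of each PS group, per cell.
#'
#' @param fit An `encoding_fit` whose feature names carry group prefixes
#'   (`"<group>_pc<j>"`).
#' @return Matrix cells x groups.
#' @export
group_weight_sums <- function(fit) {
  grp <- sub("_pc[0-9]+$", "", fit$feature_names)
  out <- sapply(unique(grp), function(g)
    rowSums(abs(fit$weights[, grp == g, drop = FALSE])))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, unique(grp)))
  out
}

#' Unique explained variance per PS group
#'
#' For cells whose full-model cross-validated EV is at least `min_full_ev`,
#' refits reduced models omitting one group at a time and reports
#' `ΔEV_u = 100 (EV_full - EV_reduced) / EV_full` per group.
#'
#' @param table Response table (cells x stimuli).
#' @param features Feature matrix (stimuli x features, grouped names).
#' @param min_full_ev Inclusion threshold (EV %); default 10.
#' @param folds,lambda_grid,rng_seed As in [fit_encoding_model()].
#' @return List: `delta_ev_u` (included cells x groups, %), `full_ev`,
#'   `included` (logical per cell).
#' @export
unique_ev <- function(table, features, min_full_ev = 10, folds = 5,
                      lambda_grid = 10^seq(-3, 3, by = 0.5), rng_seed = 1L) {
  full <- fit_encoding_model(table, features, folds, lambda_grid, rng_seed)
  keep <- full$cv_ev >= min_full_ev
  grp <- sub("_pc[0-9]+$", "", colnames(features))
  groups <- unique(grp)
  sub_tab <- table[keep, , drop = FALSE]
  attr(sub_tab, "stimuli") <- attr(table, "stimuli")
  dev <- sapply(groups, function(g) {
    red <- fit_encoding_model(sub_tab, features[, grp != g, drop = FALSE],
                              folds, lambda_grid, rng_seed)
    100 * (full$cv_ev[keep] - red$cv_ev) / full$cv_ev[keep]
  })
  if (is.null(dim(dev))) dev <- matrix(dev, nrow = sum(keep), dimnames = list(NULL, groups))
  list(delta_ev_u = dev, full_ev = full$cv_ev, included = keep)
}
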