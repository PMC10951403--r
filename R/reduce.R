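# Per-group dimensionality reduction of PS statistics and cluster geometry in
# the reduced stimulus-statistics space.

#' Reduce a collection of PS statistics by per-group PCA
#'
#' For each statistical group: z-score every coefficient across images
#' (population SD; zero-variance coefficients are dropped with a warning),
#' apply PCA, retain at most `max_components` components, then z-score the
#' retained scores across images again so the groups are commensurate. The
#' marginal group (two raw dimensions) bypasses PCA and is only z-scored.
#' PCA component signs are fixed by making the largest-magnitude loading of
#' each component positive, so embeddings are reproducible.
#'
#' @param stats List of `ps_statistics` objects (>= 2 images).
#' @param max_components Maximum retained PCs per group; default 8.
#' @param min_ev Flagging threshold for the per-group retained explained
#'   variance; default 0.70.
#' @return Object of class `reduced_stats`: `matrix` (images x features),
#'   `group_blocks` (column spans per group), `pca_models` (per-group centres,
#'   scales, loadings, explained-variance fractions), `ev_retained`, and
#'   `low_ev_flag`.
#' @export
reduce_statistics <- function(stats, max_components = 8, min_ev = 0.70) {
  stopifnot(length(stats) >= 2)
  groups <- c("marginal", "spectral", "linear_cc", "energy_cc")
  models <- list()
  blocks <- list()
  out <- NULL
  ev_ret <- c()
  for (g in groups) {
    X <- do.call(rbind, lapply(stats, function(s) s[[g]]))
    sds <- apply(X, 2, function(x) sqrt(pop_var(x)))
    # columns that are constant to numerical precision carry no information
    # and would amplify rounding noise under z-scoring
    drop <- sds <= 1e-10 * pmax(apply(abs(X), 2, max), .Machine$double.xmin)
    if (any(drop)) {
      warning(sprintf("dropping %d zero-variance %s coefficients", sum(drop), g))
      X <- X[, !drop, drop = FALSE]
      sds <- sds[!drop]
    }
    ctr <- colMeans(X)
    Z <- sweep(sweep(X, 2, ctr), 2, sds, `/`)
    if (g == "marginal") {
      scores <- Z
      rot <- diag(ncol(Z))
      ev <- 1
    } else {
      pc <- prcomp(Z, center = FALSE, scale. = FALSE)
      ncomp <- min(max_components, ncol(pc$rotation), nrow(Z) - 1)
      rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
      # deterministic sign: largest-|loading| entry positive
      for (j in seq_len(ncol(rot))) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) rot[, j] <- -rot[, j]
      }
      scores <- Z %*% rot
      tot <- sum(pc$sdev^2)
      ev <- sum(pc$sdev[seq_len(ncomp)]^2) / tot
    }
    sc_ctr <- colMeans(scores)
    sc_sd <- apply(scores, 2, function(x) sqrt(pop_var(x)))
    sc_sd[sc_sd == 0] <- 1
    scores <- sweep(sweep(scores, 2, sc_ctr), 2, sc_sd, `/`)
    colnames(scores) <- sprintf("%s_pc%d", g, seq_len(ncol(scores)))
    models[[g]] <- list(dropped = which(drop), center = ctr, scale = sds,
                        rotation = rot, score_center = sc_ctr,
                        score_scale = sc_sd, ev_retained = ev)
    blocks[[g]] <- seq.int(ifelse(is.null(out), 0, ncol(out)) + 1,
                           length.out = ncol(scores))
    out <- cbind(out, scores)
    ev_ret[g] <- ev
  }
  structure(list(matrix = out, group_blocks = blocks, pca_models = models,
                 ev_retained = ev_ret,
                 low_ev_flag = ev_ret < min_ev),
            class = "reduced_stats")
}

#' @export
print.reduced_stats <- function(x, ...) {
  cat(sprintf("<reduced_stats> %d images x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  for (g in names(x$group_blocks))
    cat(sprintf("  %-10s %d cols, retained EV %.1f%%\n", g,
                length(x$group_blocks[[g]]), 100 * x$ev_retained[g]))
  invisible(x)
}

#' Project new PS statistics into a fitted reduced space
#'
#' Applies the stored per-group z-scoring, loadings, and score normalization
#' of a [reduce_statistics()] fit. Projecting an image that was part of the
#' fit set reproduces its stored row.
#'
#' @param reduced A `reduced_stats` object.
#' @param stats A `ps_statistics` object or list of them.
#' @return Matrix (images x features) in the reduced space.
#' @export
project_reduced <- function(reduced, stats) {
  if (inherits(stats, "ps_statistics")) stats <- list(stats)
  out <- NULL
  for (g in names(reduced$group_blocks)) {
    m <- reduced$pca_models[[g]]
    X <- do.call(rbind, lapply(stats, function(s) s[[g]]))
    if (length(m$dropped)) X <- X[, -m$dropped, drop = FALSE]
    Z <- sweep(sweep(X, 2, m$center), 2, m$scale, `/`)
    sc <- Z %*% m$rotation
    sc <- sweep(sweep(sc, 2, m$score_center), 2, m$score_scale, `/`)
    out <- cbind(out, sc)
  }
  colnames(out) <- colnames(reduced$matrix)
  out
}

#' Cluster geometry in a 2-D statistics subspace
#'
#' For each labelled cluster of points computes the centroid and the radius
#' `r = (sd_x + sd_y) / 2`; for each pair of clusters, the Euclidean centroid
#' distance normalized by the mean of the two radii. The normalized distance
#' is invariant to a global rescaling of the space.
#'
#' @param points Numeric matrix with 2 columns.
#' @param labels Cluster labels, one per row.
#' @return Object of class `stat_cluster_geometry`: `clusters` data frame
#'   (label, centroid, radius) and `pairs` data frame (labels, raw and
#'   normalized distances).
#' @export
stat_cluster_geometry <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(labels))
  labs <- unique(labels)
  cl <- do.call(rbind, lapply(labs, function(l) {
    p <- points[labels == l, , drop = FALSE]
    if (nrow(p) < 2)
      stop(sprintf("cluster '%s' has fewer than 2 points: radius undefined", l))
    data.frame(label = l, mx = mean(p[, 1]), my = mean(p[, 2]),
               radius = (sd(p[, 1]) + sd(p[, 2])) / 2,
               stringsAsFactors = FALSE)
  }))
  prs <- NULL
  if (length(labs) > 1) {
    for (a in seq_along(labs)) for (b in seq_len(a - 1)) {
      d <- sqrt((cl$mx[a] - cl$mx[b])^2 + (cl$my[a] - cl$my[b])^2)
      rbar <- (cl$radius[a] + cl$radius[b]) / 2
      prs <- rbind(prs, data.frame(
        label1 = labs[b], label2 = labs[a], distance = d,
        norm_distance = if (rbar > 0) d / rbar else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(clusters = cl, pairs = prs), class = "stat_cluster_geometry")
}

#' @export
print.stat_cluster_geometry <- function(x, ...) {
  cat("<stat_cluster_geometry>\n")
  print(x$clusters, row.names = FALSE)
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence intervals for normalized cluster distances
#'
#' Resamples points within each cluster with replacement, recomputes the
#' normalized pairwise distances, and reports percentile confidence intervals
#' at the Sidak-adjusted per-comparison level
#' `1 - (1 - alpha)^(1/n_comparisons)` (99.15% for alpha = 0.05 and 6
#' comparisons). For each pair of pairs, a non-overlap flag marks CI pairs
#' that do not intersect.
#'
#' @param points Numeric 2-column matrix.
#' @param labels Cluster labels.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param alpha Family-wise level; default 0.05.
#' @param n_comparisons Number of comparisons for the Sidak correction;
#'   default: number of cluster pairs.
#' @param rng_seed Seed; default 1.
#' @return List with `level` (per-comparison CI level), `pairs` data frame
#'   (distance, CI bounds), and `nonoverlap` logical matrix.
#' @export
bootstrap_distance_test <- function(points, labels, n_boot = 1000,
                                    alpha = 0.05, n_comparisons = NULL,
                                    rng_seed = 1L) {
  stopifnot(n_boot >= 100)
  points <- as.matrix(points)
  base <- stat_cluster_geometry(points, labels)
  np <- nrow(base$pairs)
  if (is.null(n_comparisons)) n_comparisons <- np
  level <- (1 - alpha)^(1 / n_comparisons)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  idx_by <- split(seq_along(labels), labels)
  boots <- with_seed(rng_seed, {
    sapply(seq_len(n_boot), function(i) {
      idx <- unlist(lapply(idx_by, function(ix) sample(ix, length(ix), replace = TRUE)))
      stat_cluster_geometry(points[idx, , drop = FALSE],
                            labels[idx])$pairs$norm_distance
    })
  })
  if (np == 1) boots <- matrix(boots, nrow = 1)
  ci <- t(apply(boots, 1, quantile, probs = qs, na.rm = TRUE))
  prs <- cbind(base$pairs, ci_lo = ci[, 1], ci_hi = ci[, 2])
  nonov <- matrix(FALSE, np, np)
  if (np > 1)
    for (a in seq_len(np)) for (b in seq_len(np))
      nonov[a, b] <- prs$ci_lo[a] > prs$ci_hi[b] || prs$ci_hi[a] < prs$ci_lo[b]
  list(level = level, pairs = prs, nonoverlap = nonov)
}

#' Encoding-model feature matrix from reduced statistics
#'
#' Takes the first `n_pcs` components of each group of a [reduce_statistics()]
#' fit (default 2, i.e. 8 features) and labels rows with the stimulus key
#' `"family|stim_class|exemplar|rotation"` so they can be matched to trial
#' schedules and response tables.
#'
#' @param reduced A `reduced_stats` object.
#' @param manifest Image-set manifest (data frame with family, stim_class,
#'   exemplar_id, rotation_deg) in the same row order as the fit.
#' @param n_pcs Components per group; default 2.
#' @return Matrix (stimuli x `4 * n_pcs`) with key rownames.
#' @export
encoding_features <- function(reduced, manifest, n_pcs = 2) {
  cols <- unlist(lapply(reduced$group_blocks, function(b) b[seq_len(min(n_pcs, length(b)))]))
  X <- reduced$matrix[, cols, drop = FALSE]
  rownames(X) <- feature_key(manifest)
  X
}
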