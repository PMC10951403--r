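# Population embeddings, texture/scramble and family decoding, and
# representational-geometry metrics including the shared V1-LM space.

#' PCA embedding of population responses
#'
#' Z-scores each cell's responses across stimuli (population SD) and applies
#' PCA to the stimuli x cells matrix. Component signs are fixed by making the
#' largest-magnitude loading positive.
#'
#' @param table Response table (cells x stimuli) from
#'   [cell_response_table()], or any cells x stimuli matrix with a `stimuli`
#'   attribute.
#' @param n_components Number of PCs; default 20 (capped by the data).
#' @return Object of class `embedding`: `points` (stimuli x components),
#'   `loadings` (cells x components), `ev_fraction`, `zscore` parameters,
#'   `stimuli`.
#' @export
embed_population <- function(table, n_components = 20) {
  Y <- t(as.matrix(table))                     # stimuli x cells
  ctr <- colMeans(Y)
  sds <- apply(Y, 2, function(x) sqrt(pop_var(x)))
  keep <- sds > 0
  Z <- sweep(sweep(Y[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], `/`)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$rotation), nrow(Z) - 1)
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(points = Z %*% rot, loadings = rot,
                 ev_fraction = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)],
                 zscore = list(center = ctr, sd = sds, keep = keep),
                 stimuli = attr(table, "stimuli")),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d stimuli x %d components (EV %.1f%%)\n",
              nrow(x$points), ncol(x$points), 100 * sum(x$ev_fraction)))
  invisible(x)
}

# Cross-validated logistic decoding; binary via glmnet ridge with a small
# fixed penalty for numerical stability on separable data.
cv_binary_logistic <- function(X, y, folds = 5, lambda = 1e-3, rng_seed = 1L) {
  fold <- stratified_folds(as.character(y), folds, rng_seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- suppressWarnings(
      glmnet::glmnet(X[tr, , drop = FALSE], factor(y[tr]),
                     family = "binomial", alpha = 0, lambda = lambda,
                     standardize = FALSE))
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
    mean(pred == as.character(factor(y[!tr], levels = levels(factor(y[tr])))))
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc)
}

#' Decode textures versus scrambles
#'
#' Binary logistic classifier (5-fold CV) separating texture from scramble
#' stimuli of one family in an embedding space.
#'
#' @param emb An `embedding` (or points matrix with a `stimuli` attribute).
#' @param family Family label; `NULL` pools all families.
#' @param n_components Components used; default all available.
#' @param folds CV folds; default 5.
#' @param rng_seed Seed for fold assignment.
#' @return Object of class `decoder_result`: task, per-fold and mean
#'   accuracy, chance level.
#' @export
decode_texture_vs_scramble <- function(emb, family = NULL, n_components = NULL,
                                       folds = 5, rng_seed = 1L) {
  pts <- emb$points
  info <- emb$stimuli
  sel <- if (is.null(family)) rep(TRUE, nrow(info)) else info$family == family
  X <- pts[sel, seq_len(min(ncol(pts), n_components %||% ncol(pts))), drop = FALSE]
  y <- info$stim_class[sel]
  res <- cv_binary_logistic(X, y, folds, rng_seed = rng_seed)
  structure(list(task = "texture_vs_scramble", family = family,
                 accuracy = res$accuracy, fold_accuracy = res$fold_accuracy,
                 chance = 0.5, n_components = ncol(X)),
            class = "decoder_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> %s%s: accuracy %.3f (chance %.2f, %d components)\n",
              x$task, if (!is.null(x$family)) paste0(" [", x$family, "]") else "",
              x$accuracy, x$chance, x$n_components))
  invisible(x)
}

#' Decode texture families
#'
#' Multinomial logistic classifier with an L1 penalty on the texture stimuli
#' (scrambles excluded), 5-fold cross-validated; the penalty is chosen by an
#' inner grid search on the training folds. Optionally sweeps the number of
#' embedding components.
#'
#' @param emb An `embedding`.
#' @param n_components Components used; default all.
#' @param folds CV folds; default 5.
#' @param lambda_grid L1 penalty grid; default `10^seq(-3, 0, by = 0.5)`.
#' @param sweep_components Optional vector of component counts for an
#'   accuracy-vs-dimensionality curve.
#' @param rng_seed Seed.
#' @return A `decoder_result` with `chance = 1/n_families`; when sweeping, a
#'   `sweep` data frame is attached.
#' @export
decode_families <- function(emb, n_components = NULL, folds = 5,
                            lambda_grid = 10^seq(-3, 0, by = 0.5),
                            sweep_components = NULL, rng_seed = 1L) {
  info <- emb$stimuli
  sel <- info$stim_class == "texture"
  y <- factor(info$family[sel])
  run <- function(ncomp) {
    X <- emb$points[sel, seq_len(ncomp), drop = FALSE]
    fold <- stratified_folds(as.character(y), folds, rng_seed)
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      # inner selection of lambda on the training folds
      inner <- stratified_folds(as.character(y[tr]), min(3, folds), rng_seed + f)
      inner_acc <- vapply(lambda_grid, function(l) {
        mean(vapply(unique(inner), function(g) {
          it <- inner != g
          fit <- suppressWarnings(
            glmnet::glmnet(X[tr, , drop = FALSE][it, , drop = FALSE],
                           y[tr][it], family = "multinomial", alpha = 1,
                           lambda = l, standardize = FALSE))
          mean(predict(fit, X[tr, , drop = FALSE][!it, , drop = FALSE],
                       type = "class") == as.character(y[tr][!it]))
        }, numeric(1)))
      }, numeric(1))
      l_best <- lambda_grid[which.max(inner_acc)]
      fit <- suppressWarnings(
        glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                       family = "multinomial", alpha = 1,
                       lambda = l_best, standardize = FALSE))
      mean(predict(fit, X[!tr, , drop = FALSE], type = "class") ==
             as.character(y[!tr]))
    }, numeric(1))
    list(accuracy = mean(acc), fold_accuracy = acc)
  }
  ncomp <- min(ncol(emb$points), n_components %||% ncol(emb$points))
  res <- run(ncomp)
  out <- structure(list(task = "family_multinomial", family = NULL,
                        accuracy = res$accuracy,
                        fold_accuracy = res$fold_accuracy,
                        chance = 1 / nlevels(y), n_components = ncomp),
                   class = "decoder_result")
  if (!is.null(sweep_components)) {
    out$sweep <- data.frame(
      n_components = sweep_components,
      accuracy = vapply(sweep_components, function(k) run(k)$accuracy,
                        numeric(1)))
  }
  out
}

#' Shared PCA space for two populations
#'
#' Concatenates the z-scored cells of two areas recorded with identical
#' stimuli, fits a single PCA, and projects each area separately by zeroing
#' the other area's cells before applying the shared loadings. Because the
#' projection is linear and applied without re-centring, the two per-area
#' projections sum to the full projection.
#'
#' @param tableA,tableB Response tables (cells x stimuli) over the same
#'   stimuli.
#' @param n_components Shared components; default 16.
#' @return List: `full`, `projA`, `projB` (stimuli x components),
#'   `loadings`, `stimuli`, `cellsA` (column count of area A).
#' @export
shared_embedding <- function(tableA, tableB, n_components = 16) {
  if (!identical(colnames(tableA), colnames(tableB)))
    stop("the two areas must share an identical stimulus set")
  zsc <- function(tab) {
    Y <- t(as.matrix(tab))
    sds <- apply(Y, 2, function(x) sqrt(pop_var(x)))
    keep <- sds > 0
    sweep(sweep(Y[, keep, drop = FALSE], 2, colMeans(Y)[keep]), 2, sds[keep], `/`)
  }
  ZA <- zsc(tableA); ZB <- zsc(tableB)
  Z <- cbind(ZA, ZB)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$rotation), nrow(Z) - 1)
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  nA <- ncol(ZA)
  ZA0 <- cbind(ZA, ZB * 0)
  ZB0 <- cbind(ZA * 0, ZB)
  list(full = Z %*% rot, projA = ZA0 %*% rot, projB = ZB0 %*% rot,
       loadings = rot, stimuli = attr(tableA, "stimuli"), cellsA = nA)
}

# Ledoit-Wolf-style shrinkage of a covariance matrix toward the scaled
# identity; returns the shrunk matrix and the intensity used.
shrink_cov <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  gamma <- if (d2 > 0) b2 / d2 else 1
  list(sigma = (1 - gamma) * S + gamma * diag(mu, p), intensity = gamma)
}

#' Cluster geometry of population embeddings
#'
#' Per family: centroid, radius (mean of the per-component SDs, reducing to
#' `(sd_x + sd_y)/2` in 2-D), pairwise Euclidean centroid distances, and
#' Mahalanobis distances using the pooled within-pair covariance with
#' Ledoit-Wolf shrinkage toward the scaled identity.
#'
#' @param points Matrix (stimuli x components) -- e.g. `emb$points` or a
#'   per-area projection from [shared_embedding()].
#' @param labels Family label per row.
#' @return Object of class `neural_cluster_geometry`: `clusters` (label,
#'   radius, centroid), `pairs` (Euclidean and Mahalanobis distances,
#'   shrinkage intensity).
#' @export
neural_cluster_geometry <- function(points, labels) {
  points <- as.matrix(points)
  labs <- unique(labels)
  cl <- lapply(labs, function(l) points[labels == l, , drop = FALSE])
  radii <- vapply(cl, function(p) {
    if (nrow(p) < 2) stop("cluster with fewer than 2 points: radius undefined")
    mean(apply(p, 2, sd))
  }, numeric(1))
  cents <- t(vapply(cl, colMeans, numeric(ncol(points))))
  prs <- NULL
  for (a in seq_along(labs)) for (b in seq_len(a - 1)) {
    delta <- cents[a, ] - cents[b, ]
    sh <- shrink_cov(rbind(sweep(cl[[a]], 2, cents[a, ]),
                           sweep(cl[[b]], 2, cents[b, ])))
    maha <- sqrt(drop(t(delta) %*% solve(sh$sigma, delta)))
    prs <- rbind(prs, data.frame(
      label1 = labs[b], label2 = labs[a],
      euclidean = sqrt(sum(delta^2)), mahalanobis = maha,
      shrinkage = sh$intensity, stringsAsFactors = FALSE))
  }
  structure(list(clusters = data.frame(label = labs, radius = radii,
                                       stringsAsFactors = FALSE),
                 centroids = cents, pairs = prs),
            class = "neural_cluster_geometry")
}

#' @export
print.neural_cluster_geometry <- function(x, ...) {
  cat("<neural_cluster_geometry>\n")
  print(x$clusters, row.names = FALSE)
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}
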