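# Internal numeric helpers shared across modules.

# Population (ddof = 0) central moments; kurtosis is the raw fourth
# standardized moment (3 for a Gaussian), not excess.
pop_var <- function(x) mean((x - mean(x))^2)

pop_skewness <- function(x) {
  m2 <- pop_var(x)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

pop_kurtosis <- function(x) {
  m2 <- pop_var(x)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# Signed FFT frequencies (cycles/sample) for an n-point axis.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# n x n matrices of radial frequency (radians/sample) and angle for a 2-D FFT
# with the origin at the corner (unshifted convention).
freq_grids <- function(n) {
  f <- fft_freqs(n) * 2 * pi
  fx <- matrix(f, n, n, byrow = TRUE)   # column index -> x
  fy <- matrix(f, n, n)                 # row index -> y
  list(r = sqrt(fx^2 + fy^2), theta = atan2(fy, fx))
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circularly shift a matrix by (dy, dx) rows/columns.
circ_shift <- function(m, dy, dx) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 - dy) %% n1) + 1
  j <- ((seq_len(n2) - 1 - dx) %% n2) + 1
  m[i, j, drop = FALSE]
}

# Full circular autocovariance surface of a (mean-centred) matrix, via FFT.
# Entry [1 + dy, 1 + dx] (0-based lags, wrapped) is mean(m * shift(m, dy, dx)).
circ_autocov <- function(m) {
  m <- m - mean(m)
  Re(ifft2(Mod(fft2(m))^2)) / length(m)
}

# Pearson correlation of two matrices treated as flat vectors, population
# normalization; returns 0 when either argument is constant.
flat_cor <- function(a, b) {
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Seeded RNG scoping: run expr with a local RNG seeded by `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified k-fold assignment: within each stratum, trials are dealt to folds
# in a seeded random order.
stratified_folds <- function(strata, k, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}
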