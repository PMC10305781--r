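# Independent reference implementations used as oracles. These deliberately
# avoid the code paths of the package: Procrustes by grid search over the
# rotation angle, SPARC by a dense explicit DFT, segment distance by brute
# force sampling, alpha by the covariance-matrix closed form.

# Procrustes distance by exhaustive alignment: grid over rotation angle
# (with and without reflection), closed-form optimal scale per angle, local
# refinement with optimize(). No SVD anywhere.
oracle_procrustes <- function(A, B, n_grid = 20000L) {
  A <- sweep(A, 2L, colMeans(A)); B <- sweep(B, 2L, colMeans(B))
  A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
  best <- -Inf
  for (refl in c(1, -1)) {
    Br <- B %*% diag(c(1, refl))
    M <- crossprod(Br, A)
    corr_at <- function(th)
      sum(diag(M %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)))
    ths <- seq(0, 2 * pi, length.out = n_grid)
    cv <- vapply(ths, corr_at, numeric(1))
    i <- which.max(abs(cv))
    o <- stats::optimize(function(th) -abs(corr_at(th)),
                         interval = ths[i] + c(-1, 1) * 2 * pi / n_grid)
    best <- max(best, -o$objective)
  }
  1 - best^2
}

# SPARC by explicit dense DFT: the adaptive band edge follows the metric's
# definitional FFT-grid rule; the spectrum, normalization and trapezoidal
# arc length are recomputed on a 10x-oversampled frequency grid.
oracle_sparc <- function(v, fs, fc = 10, amp_threshold = 0.05, pad_level = 4) {
  v <- v / max(abs(v))
  n <- length(v)
  nfft <- 2^(ceiling(log2(n)) + pad_level)
  f_grid <- (0:(nfft - 1)) * fs / nfft
  j <- 0:(n - 1)
  dft_mag <- function(f) Mod(sum(v * exp(-2i * pi * f * j / fs)))
  coarse <- vapply(f_grid[f_grid <= fc], dft_mag, numeric(1))
  coarse <- coarse / coarse[1L]
  edge <- f_grid[max(which(coarse >= amp_threshold))]
  f_dense <- seq(0, edge, by = fs / nfft / 10)
  m_dense <- vapply(f_dense, dft_mag, numeric(1))
  m_dense <- m_dense / m_dense[1L]
  band <- f_dense[length(f_dense)] - f_dense[1L]
  -sum(sqrt((diff(f_dense) / band)^2 + diff(m_dense)^2))
}

# Minimum distance between two 3D segments by dense sampling.
oracle_segment_distance <- function(p0, p1, q0, q1, n = 1500L) {
  s <- seq(0, 1, length.out = n)
  P <- outer(1 - s, p0) + outer(s, p1)
  Q <- outer(1 - s, q0) + outer(s, q1)
  d2 <- outer(rowSums(P^2), rep(1, n)) + outer(rep(1, n), rowSums(Q^2)) -
    2 * P %*% t(Q)
  idx <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(max(0, min(d2))), s = s[idx[1L]], t = s[idx[2L]])
}

# Cronbach's alpha from the covariance matrix: k/(k-1) (1 - tr(S)/sum(S)).
oracle_alpha <- function(items) {
  S <- stats::cov(items)
  k <- ncol(items)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# Random non-degenerate 2D point set.
random_curve <- function(n = 20L) matrix(stats::rnorm(2L * n), ncol = 2L)

# Similarity transform of a 2D point set.
similarity_transform <- function(X, angle, scl, shift, reflect = FALSE) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  if (reflect) R <- R %*% diag(c(1, -1))
  sweep(scl * X %*% R, 2L, shift, "+")
}
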