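#' 2D Procrustes distance between two curves
#'
#' Full similarity-alignment Procrustes: both point sets are centred at their
#' centroids and scaled to unit Frobenius norm; the optimal orthogonal
#' alignment (rotation, and reflection when `reflection = TRUE`) is found by
#' singular value decomposition, with the optimal uniform scale applied when
#' `scale = TRUE`. The returned distance is the residual sum of squared
#' distances after alignment, which lies in \[0, 1\] and is symmetric in its
#' arguments: 0 means the two curves have identical shape.
#'
#' @param curve_a,curve_b N x 2 matrices (N >= 3) of matched points.
#' @param scale apply the optimal uniform scale (default `TRUE`).
#' @param reflection allow reflections in the alignment (default `TRUE`).
#' @return the Procrustes distance, a dimensionless scalar in \[0, 1\].
#' @export
procrustes_distance <- function(curve_a, curve_b, scale = TRUE, reflection = TRUE) {
  A <- as.matrix(curve_a); B <- as.matrix(curve_b)
  if (!is.numeric(A) || !is.numeric(B) || ncol(A) != 2L || ncol(B) != 2L)
    stop("curves must be numeric N x 2 matrices")
  if (nrow(A) != nrow(B)) stop("curves must have the same number of points")
  if (nrow(A) < 3L) stop("need at least 3 points")
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-variance curve")
  A <- A / na; B <- B / nb
  sv <- svd(crossprod(A, B))
  s <- sv$d
  if (!reflection && det(sv$u %*% t(sv$v)) < 0) s[length(s)] <- -s[length(s)]
  trace_s <- sum(s)
  pd <- if (scale) 1 - trace_s^2 else 2 - 2 * trace_s
  max(0, min(1, pd))
}

#' Spectral arc-length (SPARC) smoothness of a speed profile
#'
#' The magnitude spectrum of the speed profile is computed with a zero-padded
#' FFT (padded to `2^(ceiling(log2(N)) + pad_level)`), normalized by its value
#' at zero frequency, restricted to the band \[0, `fc`\] and adaptively
#' truncated at the last frequency where the normalized magnitude still
#' reaches `amp_threshold`. The index is the negative arc length of the
#' normalized spectrum over the retained band, with the frequency axis
#' normalized by the band edge. Values are negative; smoother movements give
#' higher (less negative) values, and the index is invariant to amplitude
#' scaling of the profile.
#'
#' @param speed numeric speed profile (length >= 8), uniformly sampled.
#' @param fs sampling rate of the profile in Hz; must exceed `2 * fc`.
#' @param fc band limit in Hz (default 10).
#' @param amp_threshold adaptive-cutoff amplitude threshold (default 0.05).
#' @param pad_level zero-padding exponent (default 4).
#' @return the SPARC index (dimensionless, <= 0).
#' @export
sparc <- function(speed, fs, fc = 10, amp_threshold = 0.05, pad_level = 4) {
  speed <- as.numeric(speed)
  n <- length(speed)
  if (n < 8L) stop("speed profile too short (need >= 8 samples)")
  if (fs <= 2 * fc) stop("fs must exceed 2 * fc")
  if (all(speed == 0)) stop("zero speed profile")
  speed <- speed / max(abs(speed))   # amplitude invariance
  nfft <- 2^(ceiling(log2(n)) + pad_level)
  spec <- Mod(stats::fft(c(speed, rep(0, nfft - n))))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- f <= fc
  fsel <- f[sel]
  msel <- spec[sel] / spec[1L]
  # adaptive band edge: last frequency in [0, fc] still above threshold
  above <- which(msel >= amp_threshold)
  hi <- above[length(above)]
  fsel <- fsel[1L:hi]
  msel <- msel[1L:hi]
  if (length(fsel) < 2L) stop("degenerate spectrum band")
  band <- fsel[length(fsel)] - fsel[1L]
  -sum(sqrt((diff(fsel) / band)^2 + diff(msel)^2))
}

#' Per-stroke imitation metrics
#'
#' Computes the Procrustes distance between the avatar and participant 2D
#' bowing curves of one paired stroke, the SPARC smoothness of each
#' performer's speed profile, and their difference
#' `dsi = si_participant - si_avatar` (positive when the participant moved
#' more smoothly than the reference).
#'
#' @param pair a `stroke_pair` from [pair_strokes()].
#' @param fs sampling rate of the resampled profiles (defaults to the rate
#'   stored in the pair).
#' @param fc,amp_threshold,pad_level SPARC parameters (see [sparc()]).
#' @param scale,reflection Procrustes options (see [procrustes_distance()]).
#' @return a one-row data frame: `pd`, `si_avatar`, `si_participant`, `dsi`,
#'   plus the stroke metadata.
#' @export
stroke_metrics <- function(pair, fs = NULL, fc = 10, amp_threshold = 0.05,
                           pad_level = 4, scale = TRUE, reflection = TRUE) {
  stopifnot(inherits(pair, "stroke_pair"))
  fs <- fs %||% pair$fs
  res <- tryCatch({
    pd <- procrustes_distance(pair$avatar_curve, pair$participant_curve,
                              scale = scale, reflection = reflection)
    si_a <- sparc(pair$avatar_speed, fs, fc, amp_threshold, pad_level)
    si_p <- sparc(pair$participant_speed, fs, fc, amp_threshold, pad_level)
    data.frame(pd = pd, si_avatar = si_a, si_participant = si_p, dsi = si_p - si_a)
  }, error = function(e) {
    stop("stroke ", pair$stroke$start_frame, "-", pair$stroke$end_frame, ": ",
         conditionMessage(e), call. = FALSE)
  })
  cbind(res, pair$stroke)
}

#' Metrics for one whole performance
#'
#' Convenience wrapper running the stroke pipeline for one avatar/participant
#' pair: derivatives, segmentation, length and loudness gates, pairing, and
#' per-stroke metrics.
#'
#' @param avatar an `avatar_performance`.
#' @param participant_trace the follower [motion_trace()].
#' @param min_length length-gate threshold in mm (default 150).
#' @param loudness_fraction loudness-gate fraction (default 0.15).
#' @param n_resample resampled points per stroke curve (default 100).
#' @param cutoff derivative low-pass cutoff in Hz (default 12).
#' @param min_duration,min_excursion segmentation hysteresis (see
#'   [segment_strokes()]).
#' @return data frame of per-stroke metrics (one row per surviving stroke).
#' @export
performance_metrics <- function(avatar, participant_trace, min_length = 150,
                                loudness_fraction = 0.15, n_resample = 100,
                                cutoff = 12, min_duration = 0.08, min_excursion = 10) {
  stopifnot(inherits(avatar, "avatar_performance"))
  akin <- derivatives(bow_contact_kinematics(avatar$trace), cutoff)
  pkin <- derivatives(bow_contact_kinematics(participant_trace), cutoff)
  env <- loudness_envelope(avatar$audio, avatar$trace)
  st <- segment_strokes(akin, min_duration = min_duration, min_excursion = min_excursion)
  st <- gate_loudness(gate_length(st, min_length), env, loudness_fraction)
  pairs <- pair_strokes(akin, pkin, st, n_resample)
  if (!length(pairs)) return(NULL)
  out <- do.call(rbind, lapply(pairs, stroke_metrics))
  out$stroke_index <- seq_len(nrow(out))
  out
}
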