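#' Bow-contact kinematics from marker trajectories
#'
#' Computes per-frame bow kinematics from the bow and violin markers: the
#' contact point is the pair of closest points between the bow-axis segment
#' (frog to tip) and the string-axis segment (bridge toward scroll, truncated
#' to `string_length`). `dist_frog` is the arclength from the frog to the
#' bow-side closest point, `dist_bridge` the arclength from the bridge to the
#' string-side closest point, and `tilt_angle` the angle between the two axes
#' in degrees. Distances are clamped to the physical segment ranges.
#'
#' @param trace a [motion_trace()] with markers `bow_frog`, `bow_tip`,
#'   `violin_bridge`, `violin_scroll`.
#' @param bow_length bow hair length in mm (default 650).
#' @param string_length playable string length in mm (default 330).
#' @return an object of class `bow_kinematics`: time, `dist_frog`,
#'   `dist_bridge`, `tilt_angle` (deg), sampling rate, and slots for
#'   derivatives (filled by [derivatives()]).
#' @export
bow_contact_kinematics <- function(trace, bow_length = BOW_LENGTH_MM,
                                   string_length = STRING_LENGTH_MM) {
  stopifnot(inherits(trace, "motion_trace"))
  require_markers(trace, c("bow_frog", "bow_tip", "violin_bridge", "violin_scroll"))
  P0 <- trace$markers$bow_frog
  u_raw <- trace$markers$bow_tip - P0
  Q0 <- trace$markers$violin_bridge
  v_raw <- trace$markers$violin_scroll - Q0
  if (!all(is.finite(P0 + u_raw + Q0 + v_raw)))
    stop("non-finite marker coordinates (gap frames?) in trace")
  lu <- sqrt(rowSums(u_raw^2))
  lv <- sqrt(rowSums(v_raw^2))
  if (any(lu < 1e-9)) stop("collinear markers: bow axis has zero length")
  if (any(lv < 1e-9)) stop("collinear markers: string axis has zero length")
  # unit axes; string truncated to string_length
  u <- u_raw / lu
  v <- v_raw / lv
  len_u <- pmin(lu, bow_length)
  len_v <- pmin(lv, string_length)

  # closest points between segments P0 + s*u (s in [0,len_u]) and
  # Q0 + t*v (t in [0,len_v]); vectorized over frames
  w0 <- P0 - Q0
  b <- rowSums(u * v)
  d_ <- rowSums(u * w0)
  e_ <- rowSums(v * w0)
  denom <- 1 - b^2
  par <- denom < 1e-12
  s <- ifelse(par, 0, (b * e_ - d_) / pmax(denom, 1e-12))
  s <- pmax(0, pmin(len_u, s))
  t_ <- pmax(0, pmin(len_v, e_ + b * s))
  s <- pmax(0, pmin(len_u, b * t_ - d_))

  tilt_signed <- acos(pmax(-1, pmin(1, b))) * 180 / pi

  structure(list(time = trace$time, dist_frog = s, dist_bridge = t_,
                 tilt_angle = tilt_signed, rate = trace$rate,
                 velocity = NULL, acceleration = NULL, jerk = NULL,
                 bow_length = bow_length, string_length = string_length),
            class = "bow_kinematics")
}

#' @export
print.bow_kinematics <- function(x, ...) {
  cat(sprintf("<bow_kinematics> %d frames @ %g Hz; dist_frog [%.1f, %.1f] mm%s\n",
              length(x$time), x$rate, min(x$dist_frog), max(x$dist_frog),
              if (is.null(x$velocity)) " (no derivatives yet)" else ""))
  invisible(x)
}

#' Smoothed derivatives of bow position
#'
#' Low-pass filters `dist_frog` with a zero-phase 4th-order Butterworth filter
#' at `cutoff`, then differentiates by central differences (one-sided at the
#' endpoints) to obtain bow velocity, acceleration and jerk.
#'
#' @param kin a `bow_kinematics` object.
#' @param cutoff low-pass cutoff in Hz (default 12, above bowing frequency
#'   content but below tremor/noise bands); must be below the Nyquist rate.
#' @return `kin` with `velocity` (mm/s), `acceleration` (mm/s^2) and `jerk`
#'   (mm/s^3) filled, and `dist_frog_smooth` holding the filtered position.
#' @export
derivatives <- function(kin, cutoff = 12) {
  stopifnot(inherits(kin, "bow_kinematics"))
  if (length(kin$time) < 9L) stop("need at least 9 frames to differentiate")
  if (cutoff >= kin$rate / 2) stop("cutoff must be below the Nyquist frequency")
  xs <- lowpass_zerophase(kin$dist_frog, kin$rate, cutoff)
  kin$dist_frog_smooth <- xs
  kin$velocity <- num_gradient(xs, kin$rate)
  kin$acceleration <- num_gradient(kin$velocity, kin$rate)
  kin$jerk <- num_gradient(kin$acceleration, kin$rate)
  kin
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Compose a rotation from Euler angles
#'
#' Intrinsic rotation sequences: `R = R1(a1) %*% R2(a2) %*% R3(a3)` with axes
#' named by the sequence string (e.g. `"ZXY"`, `"YXY"`). Angles in degrees.
#'
#' @param angles numeric length-3, degrees.
#' @param seq rotation sequence, one of `"ZXY"`, `"YXY"`, `"XYZ"`, `"ZYX"`.
#' @return 3x3 rotation matrix.
#' @export
euler_compose <- function(angles, seq = "ZXY") {
  a <- angles * pi / 180
  ax <- strsplit(seq, "")[[1]]
  R <- diag(3)
  fns <- list(X = rot_x, Y = rot_y, Z = rot_z)
  for (i in 1:3) R <- R %*% fns[[ax[i]]](a[i])
  R
}

#' Decompose a rotation into Euler angles
#'
#' Inverse of [euler_compose()] for the supported sequences. For the symmetric
#' sequence `"YXY"` the middle angle is returned in (0, 180); for asymmetric
#' sequences the middle angle is in (-90, 90). Angles in degrees, all in
#' (-180, 180].
#'
#' @param R 3x3 rotation matrix.
#' @param seq rotation sequence (see [euler_compose()]).
#' @return numeric length-3 vector of angles in degrees.
#' @export
euler_decompose <- function(R, seq = "ZXY") {
  stopifnot(is.matrix(R), all(dim(R) == 3L))
  r <- function(x) x * 180 / pi
  if (seq == "ZXY") {
    b <- asin(pmax(-1, pmin(1, R[3, 2])))
    a <- atan2(-R[1, 2], R[2, 2])
    c <- atan2(-R[3, 1], R[3, 3])
  } else if (seq == "YXY") {
    b <- acos(pmax(-1, pmin(1, R[2, 2])))
    a <- atan2(R[1, 2], R[3, 2] + 0)
    c <- atan2(R[2, 1], -R[2, 3] + 0)   # "+ 0" avoids atan2(0, -0) = pi
  } else if (seq == "XYZ") {
    b <- asin(pmax(-1, pmin(1, R[1, 3])))
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  } else if (seq == "ZYX") {
    b <- asin(pmax(-1, pmin(1, -R[3, 1])))
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  } else stop("unsupported Euler sequence: ", seq)
  r(c(a, b, c))
}

# Orthonormal segment frame from a 3-marker cluster (rows p1, p2, p3):
# x along p1->p2, z normal to the cluster plane, y completing the frame.
cluster_frame <- function(p1, p2, p3, segment = "segment") {
  x <- p2 - p1
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("degenerate marker cluster for segment '", segment, "'")
  x <- x / nx
  z <- c(x[2] * (p3 - p1)[3] - x[3] * (p3 - p1)[2],
         x[3] * (p3 - p1)[1] - x[1] * (p3 - p1)[3],
         x[1] * (p3 - p1)[2] - x[2] * (p3 - p1)[1])
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9 * nx) stop("collinear marker cluster for segment '", segment, "'")
  z <- z / nz
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

#' Right-arm joint angles from marker clusters
#'
#' Builds per-frame orthonormal segment frames from the 3-marker clusters
#' `thorax`, `upper_arm`, `forearm` and `hand` (markers `<segment>_1..3`), and
#' decomposes the distal-in-proximal relative rotations by fixed Euler
#' sequences following ISB-style recommendations: shoulder
#' (thorax -> upper arm) Y-X-Y (plane of elevation, elevation, axial
#' rotation), elbow (upper arm -> forearm) Z-X-Y (flexion-extension, carrying
#' angle, pronation-supination) and wrist (forearm -> hand) Z-X-Y
#' (flexion-extension, deviation, rotation). Angular velocities are obtained
#' by low-pass filtered differencing of the unwrapped angles.
#'
#' @param trace a [motion_trace()] carrying the four clusters.
#' @param cutoff low-pass cutoff (Hz) for angular velocities.
#' @return an object of class `joint_angles`: a list of per-joint matrices of
#'   angles (deg) and angular velocities (deg/s).
#' @export
joint_angles <- function(trace, cutoff = 12) {
  stopifnot(inherits(trace, "motion_trace"))
  segs <- c("thorax", "upper_arm", "forearm", "hand")
  require_markers(trace, as.vector(outer(segs, 1:3, paste, sep = "_")))
  n <- n_frames(trace)
  frames <- lapply(segs, function(s) {
    m1 <- trace$markers[[paste0(s, "_1")]]
    m2 <- trace$markers[[paste0(s, "_2")]]
    m3 <- trace$markers[[paste0(s, "_3")]]
    lapply(seq_len(n), function(i) cluster_frame(m1[i, ], m2[i, ], m3[i, ], s))
  })
  names(frames) <- segs
  joints <- list(
    shoulder = list(prox = "thorax", dist = "upper_arm", seq = "YXY",
                    names = c("plane_of_elevation", "elevation", "axial_rotation")),
    elbow = list(prox = "upper_arm", dist = "forearm", seq = "ZXY",
                 names = c("FE", "AA", "PS")),
    wrist = list(prox = "forearm", dist = "hand", seq = "ZXY",
                 names = c("FE", "AA", "PS"))
  )
  out <- list(time = trace$time, rate = trace$rate)
  for (j in names(joints)) {
    spec <- joints[[j]]
    ang <- t(vapply(seq_len(n), function(i) {
      R <- crossprod(frames[[spec$prox]][[i]], frames[[spec$dist]][[i]])
      euler_decompose(R, spec$seq)
    }, numeric(3)))
    colnames(ang) <- spec$names
    vel <- ang
    if (n >= 9L) {
      for (k in 1:3) {
        unwrapped <- unwrap_deg(ang[, k])
        vel[, k] <- num_gradient(lowpass_zerophase(unwrapped, trace$rate, min(cutoff, trace$rate / 2 - 1)),
                                 trace$rate)
      }
    } else vel[] <- NA_real_
    out[[j]] <- list(angles = ang, velocity = vel)
  }
  structure(out, class = "joint_angles")
}

unwrap_deg <- function(a) {
  d <- diff(a)
  steps <- cumsum(c(0, round(d / 360))) * 360
  a - steps
}

#' Frame-rate loudness envelope of an audio signal
#'
#' RMS amplitude of the audio in a centered window evaluated at every motion
#' frame, on the motion time grid (linear amplitude, not dB, so the
#' median-fraction loudness gate is scale-invariant). Optionally estimates a
#' fundamental frequency per frame by autocorrelation over voiced windows.
#'
#' @param audio an [audio_signal()] sharing `t = 0` with the trace.
#' @param trace the paired [motion_trace()].
#' @param window RMS window length in s (default 0.05).
#' @param compute_f0 also estimate f0 (Hz) per frame (default `FALSE`; carried
#'   as metadata only).
#' @param f0_range search range in Hz for the autocorrelation peak.
#' @return an object of class `loudness_envelope`: `time`, `loudness`, and
#'   optionally `f0` (NA in unvoiced frames).
#' @export
loudness_envelope <- function(audio, trace, window = 0.05, compute_f0 = FALSE,
                              f0_range = c(80, 1000)) {
  stopifnot(inherits(audio, "audio_signal"), inherits(trace, "motion_trace"), window > 0)
  fs <- audio$rate
  x <- audio$samples
  if ((length(x) - 1) / fs < trace$time[length(trace$time)] - 1e-9)
    stop("audio is shorter than the motion span")
  cs <- cumsum(c(0, x^2))
  half <- round(window * fs / 2)
  centers <- round(trace$time * fs) + 1L
  lo <- pmax(1L, centers - half)
  hi <- pmin(length(x), centers + half)
  loud <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  env <- list(time = trace$time, loudness = loud)
  if (compute_f0) {
    lag_min <- max(2L, floor(fs / f0_range[2L]))
    lag_max <- ceiling(fs / f0_range[1L])
    thresh <- stats::median(loud) * 0.15
    f0 <- rep(NA_real_, length(centers))
    for (i in seq_along(centers)) {
      if (loud[i] <= thresh) next
      seg <- x[lo[i]:hi[i]]
      if (length(seg) <= 2L * lag_max) next
      seg <- seg - mean(seg)
      ac <- stats::acf(seg, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
      pk <- which.max(ac[(lag_min + 1L):(lag_max + 1L)]) + lag_min - 1L
      f0[i] <- fs / pk
    }
    env$f0 <- f0
  }
  structure(env, class = "loudness_envelope")
}
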