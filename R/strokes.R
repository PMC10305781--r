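#' Segment bow strokes from bow kinematics
#'
#' Strokes are maximal intervals of constant bow-velocity sign within moving
#' regions, with hysteresis: candidate segments shorter than `min_duration` or
#' with excursion below `min_excursion` are merged into a neighbouring stroke,
#' which suppresses tremor-induced micro-reversals. Windows are half-open
#' `[start_frame, end_frame)` so consecutive strokes partition time without
#' overlap. Down-bow means increasing bow-frog distance.
#'
#' @param kin a `bow_kinematics` with [derivatives()] computed.
#' @param min_duration minimum stroke duration in s (default 0.08).
#' @param min_excursion minimum bow excursion in mm (default 10).
#' @param move_threshold speed below which the bow counts as stationary
#'   (mm/s, default 5).
#' @return data frame of class `stroke_table`: one row per stroke with
#'   `start_frame`, `end_frame` (1-based, half-open), `direction`, `length`
#'   (mm), `duration` (s) and `mean_loudness` (NA until [gate_loudness()]).
#' @export
segment_strokes <- function(kin, min_duration = 0.08, min_excursion = 10,
                            move_threshold = 5) {
  stopifnot(inherits(kin, "bow_kinematics"))
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      direction = character(), length = numeric(),
                      duration = numeric(), mean_loudness = numeric())
  class(empty) <- c("stroke_table", "data.frame")
  n <- length(kin$time)
  if (n == 0L) return(empty)
  if (is.null(kin$velocity)) stop("velocity not computed; call derivatives() first")
  v <- kin$velocity
  x <- kin$dist_frog_smooth %||% kin$dist_frog
  fs <- kin$rate
  moving <- abs(v) > move_threshold
  sgn <- sign(v)
  # runs of constant sign within moving regions
  grp <- cumsum(c(TRUE, diff(sgn * moving) != 0 | diff(moving) != 0))
  segs <- list()
  for (g in split(seq_len(n), grp)) {
    if (!moving[g[1L]]) next
    segs[[length(segs) + 1L]] <- c(g[1L], g[length(g)] + 1L)  # half-open
  }
  if (!length(segs)) return(empty)
  seg_df <- function(s) {
    i0 <- s[1L]; i1 <- min(s[2L], n)
    data.frame(start_frame = i0, end_frame = s[2L],
               excursion = x[i1] - x[i0],
               duration = (s[2L] - i0) / fs)
  }
  tab <- do.call(rbind, lapply(segs, seg_df))
  # hysteresis: merge too-short / too-small segments into a neighbour
  repeat {
    bad <- which(tab$duration < min_duration | abs(tab$excursion) < min_excursion)
    if (!length(bad) || nrow(tab) == 1L) break
    i <- bad[1L]
    j <- if (i > 1L && (i == nrow(tab) || tab$end_frame[i - 1L] == tab$start_frame[i])) i - 1L
         else if (i < nrow(tab)) i + 1L else i - 1L
    k <- min(i, j); l <- max(i, j)
    if (tab$end_frame[k] == tab$start_frame[l]) {
      tab$end_frame[k] <- tab$end_frame[l]
      i0 <- tab$start_frame[k]; i1 <- min(tab$end_frame[k], n)
      tab$excursion[k] <- x[i1] - x[i0]
      tab$duration[k] <- (tab$end_frame[k] - i0) / fs
      tab <- tab[-l, , drop = FALSE]
    } else {
      tab <- tab[-i, , drop = FALSE]   # isolated micro-segment: drop
    }
    rownames(tab) <- NULL
  }
  keep <- tab$duration >= min_duration & abs(tab$excursion) >= min_excursion
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(empty)
  out <- data.frame(start_frame = tab$start_frame, end_frame = tab$end_frame,
                    direction = ifelse(tab$excursion >= 0, "down", "up"),
                    length = abs(tab$excursion), duration = tab$duration,
                    mean_loudness = NA_real_)
  rownames(out) <- NULL
  class(out) <- c("stroke_table", "data.frame")
  out
}

#' Length gate for bow strokes
#'
#' Keeps strokes whose bowing length strictly exceeds `min_length`
#' ("exceeding" read as strict inequality). Order is preserved.
#'
#' @param strokes a `stroke_table`.
#' @param min_length threshold in mm (default 150).
#' @return the filtered `stroke_table`.
#' @export
gate_length <- function(strokes, min_length = 150) {
  out <- strokes[strokes$length > min_length, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stroke_table", "data.frame")
  out
}

#' Loudness gate for bow strokes
#'
#' The reference is the median per-frame loudness over the whole performance;
#' strokes whose mean in-window loudness reaches at least
#' `fraction * reference` are kept. Loudness is linear RMS amplitude, so the
#' gate is invariant to an overall gain change.
#'
#' @param strokes a `stroke_table`.
#' @param env a `loudness_envelope` on the same frame grid, covering every
#'   stroke window.
#' @param fraction fraction of the median loudness required (default 0.15).
#' @return the filtered `stroke_table` with `mean_loudness` filled.
#' @export
gate_loudness <- function(strokes, env, fraction = 0.15) {
  stopifnot(inherits(env, "loudness_envelope"))
  if (all(env$loudness == 0)) stop("silent performance: loudness envelope is all zero")
  if (nrow(strokes) && max(strokes$end_frame) - 1L > length(env$loudness))
    stop("loudness envelope does not cover all stroke windows")
  ref <- stats::median(env$loudness)
  if (nrow(strokes)) {
    strokes$mean_loudness <- vapply(seq_len(nrow(strokes)), function(i) {
      mean(env$loudness[strokes$start_frame[i]:(strokes$end_frame[i] - 1L)])
    }, numeric(1))
    strokes <- strokes[strokes$mean_loudness >= fraction * ref, , drop = FALSE]
  }
  rownames(strokes) <- NULL
  class(strokes) <- c("stroke_table", "data.frame")
  strokes
}

#' Pair avatar and participant stroke windows
#'
#' For each surviving avatar-anchored stroke, extracts the identical frame
#' window from both performers and resamples the 2D bowing curve
#' `(dist_frog, dist_bridge)` and the speed profile of each performer to
#' `n_resample` points by linear interpolation in time. Pairs whose window
#' extends past the participant trace are dropped with a warning.
#'
#' @param avatar_kin,participant_kin `bow_kinematics` on the same time base
#'   (participant must have [derivatives()] computed for speed profiles).
#' @param strokes a `stroke_table` anchored on the avatar.
#' @param n_resample number of resampled points per curve (default 100).
#' @return list of `stroke_pair` objects: each has `stroke` (the table row),
#'   `avatar_curve`/`participant_curve` (`n_resample` x 2) and
#'   `avatar_speed`/`participant_speed` (length `n_resample`).
#' @export
pair_strokes <- function(avatar_kin, participant_kin, strokes, n_resample = 100) {
  stopifnot(inherits(avatar_kin, "bow_kinematics"),
            inherits(participant_kin, "bow_kinematics"))
  if (is.null(avatar_kin$velocity) || is.null(participant_kin$velocity))
    stop("both kinematics need derivatives() computed")
  np <- length(participant_kin$time)
  pairs <- list()
  dropped <- 0L
  for (i in seq_len(nrow(strokes))) {
    i0 <- strokes$start_frame[i]; i1 <- strokes$end_frame[i] - 1L
    if (i1 > np) { dropped <- dropped + 1L; next }
    idx <- i0:i1
    t_in <- avatar_kin$time[idx]
    t_out <- seq(t_in[1L], t_in[length(t_in)], length.out = n_resample)
    rs <- function(y) stats::approx(t_in, y[idx], xout = t_out)$y
    pairs[[length(pairs) + 1L]] <- structure(list(
      stroke = strokes[i, , drop = FALSE],
      avatar_curve = cbind(rs(avatar_kin$dist_frog), rs(avatar_kin$dist_bridge)),
      participant_curve = cbind(rs(participant_kin$dist_frog), rs(participant_kin$dist_bridge)),
      avatar_speed = abs(rs(avatar_kin$velocity)),
      participant_speed = abs(rs(participant_kin$velocity)),
      fs = (n_resample - 1) / (t_out[n_resample] - t_out[1L])
    ), class = "stroke_pair")
  }
  if (dropped > 0L)
    warning(dropped, " stroke window(s) extend past the participant trace and were dropped")
  pairs
}
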