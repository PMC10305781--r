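#' Define a score for the synthetic performer
#'
#' A score is an ordered list of bow strokes. Each stroke has a direction
#' (`"down"` = away from the frog, i.e. increasing bow-frog distance, `"up"` =
#' toward it), a length in mm, a duration in seconds, a relative dynamic in
#' \[0, 1\] that scales the audio amplitude, and an optional rest after the
#' stroke. Directions must alternate unless a rest separates two strokes.
#'
#' @param strokes data frame with columns `direction` ("up"/"down"), `length`
#'   (mm), `duration` (s), `dynamic` (0-1) and `rest_after` (s). `dynamic`
#'   and `rest_after` default to 0.8 and 0 when absent.
#' @param rate_motion motion-capture sampling rate in Hz (default 120).
#' @param rate_audio audio sampling rate in Hz (default 48000).
#' @return an object of class `score_spec`.
#' @export
score_spec <- function(strokes, rate_motion = 120, rate_audio = 48000) {
  stopifnot(is.data.frame(strokes))
  if (nrow(strokes) == 0L) stop("empty score")
  if (is.null(strokes$dynamic)) strokes$dynamic <- 0.8
  if (is.null(strokes$rest_after)) strokes$rest_after <- 0
  stopifnot(all(c("direction", "length", "duration") %in% names(strokes)))
  if (!all(strokes$direction %in% c("up", "down"))) stop("direction must be 'up' or 'down'")
  if (any(strokes$length <= 0)) stop("stroke lengths must be > 0")
  if (any(strokes$duration <= 0)) stop("stroke durations must be > 0")
  if (any(strokes$dynamic < 0 | strokes$dynamic > 1)) stop("dynamic must lie in [0, 1]")
  if (any(strokes$rest_after < 0)) stop("rest_after must be >= 0")
  n <- nrow(strokes)
  if (n > 1L) {
    same <- strokes$direction[-1L] == strokes$direction[-n]
    sep <- strokes$rest_after[-n] > 0
    if (any(same & !sep))
      stop("consecutive strokes in the same direction must be separated by a rest")
  }
  structure(list(strokes = strokes, rate_motion = rate_motion, rate_audio = rate_audio),
            class = "score_spec")
}

#' A default alternating-stroke score
#'
#' Convenience constructor: `n` alternating down/up strokes of equal length
#' and duration, starting on a down-bow.
#'
#' @param n number of strokes.
#' @param length stroke length in mm.
#' @param duration stroke duration in s.
#' @param dynamic relative amplitude in \[0, 1\].
#' @param rest_after rest after each stroke in s.
#' @inheritParams score_spec
#' @return a [score_spec()].
#' @export
default_score <- function(n = 16, length = 300, duration = 0.5, dynamic = 0.8,
                          rest_after = 0, rate_motion = 120, rate_audio = 48000) {
  if (n < 1) stop("empty score")
  score_spec(data.frame(
    direction = rep(c("down", "up"), length.out = n),
    length = length, duration = duration,
    dynamic = dynamic, rest_after = rest_after
  ), rate_motion = rate_motion, rate_audio = rate_audio)
}

# Minimum-jerk normalized displacement s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5.
min_jerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
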