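tri_wave_kin <- function(cycles = 5, amp = 300, period = 1, fs = 120) {
  t <- seq(0, cycles * period, by = 1 / fs)
  x <- amp * (2 * abs(2 * (t / period - floor(t / period + 0.5))) )
  kin <- list(time = t, dist_frog = 60 + x, dist_bridge = rep(50, length(t)),
              tilt_angle = rep(90, length(t)), rate = fs, velocity = NULL)
  class(kin) <- "bow_kinematics"
  derivatives(kin)
}

fake_strokes <- function(lengths, loud = NULL, frames_per = 10L) {
  n <- length(lengths)
  st <- data.frame(start_frame = seq_len(max(n, 1L))[seq_len(n)] * frames_per - frames_per + 1L,
                   end_frame = seq_len(max(n, 1L))[seq_len(n)] * frames_per + 1L,
                   direction = rep(c("down", "up"), length.out = n),
                   length = lengths, duration = rep(frames_per / 120, n),
                   mean_loudness = rep(NA_real_, n))
  class(st) <- c("stroke_table", "data.frame")
  st
}

test_that("triangular wave segments into alternating strokes, degenerate inputs handled", {
  kin <- tri_wave_kin(cycles = 5)
  st <- segment_strokes(kin)
  expect_identical(nrow(st), 10L)
  expect_true(all(st$direction == rep(c("down", "up"), 5)))
  expect_true(all(abs(st$length - 600) < 30))  # filter edge loss only
  expect_true(all(st$end_frame[-10] <= st$start_frame[-1] + 1))

  flat <- kin; flat$dist_frog <- rep(100, length(flat$time))
  flat <- derivatives(flat)
  expect_identical(nrow(segment_strokes(flat)), 0L)

  ramp <- kin; ramp$dist_frog <- 60 + 100 * ramp$time
  ramp <- derivatives(ramp)
  sr <- segment_strokes(ramp)
  expect_identical(nrow(sr), 1L)
  expect_identical(sr$direction, "down")
  expect_error(segment_strokes(tri_wave_kin_unfiltered <- local({
    k <- tri_wave_kin(); k$velocity <- NULL; k
  })), "velocity not computed")
})

test_that("re-segmenting one detected stroke returns exactly that stroke", {
  kin <- tri_wave_kin(cycles = 3)
  st <- segment_strokes(kin)
  idx <- st$start_frame[2]:(st$end_frame[2] - 1L)
  sub <- list(time = kin$time[idx] - kin$time[idx[1]], dist_frog = kin$dist_frog[idx],
              dist_bridge = kin$dist_bridge[idx], tilt_angle = kin$tilt_angle[idx],
              rate = kin$rate, velocity = NULL)
  class(sub) <- "bow_kinematics"
  st2 <- segment_strokes(derivatives(sub))
  expect_identical(nrow(st2), 1L)
  expect_identical(st2$direction, st$direction[2])
})

test_that("length gate keeps exactly the strictly-exceeding strokes", {
  st <- fake_strokes(c(100, 149.9, 150, 200, 400))
  kept <- gate_length(st, 150)
  expect_identical(nrow(kept), 2L)
  expect_identical(kept$length, c(200, 400))
  expect_identical(nrow(gate_length(fake_strokes(numeric(0)))), 0L)
  expect_identical(nrow(gate_length(st, 0)), 5L)
})

test_that("loudness gate matches constructed-envelope arithmetic", {
  st <- fake_strokes(rep(300, 5))
  env_of <- function(per_stroke_amp, median_target) {
    loud <- rep(median_target, 200)   # enough background frames to pin the median
    for (i in 1:5) loud[st$start_frame[i]:(st$end_frame[i] - 1L)] <- per_stroke_amp[i]
    structure(list(time = (0:199) / 120, loudness = loud), class = "loudness_envelope")
  }
  # two strokes at 0.1 of a performance whose median loudness is 0.7:
  # 0.1 < 0.15 * 0.7 -> removed
  env <- env_of(c(1, 0.1, 1, 0.1, 1), 0.7)
  expect_equal(stats::median(env$loudness), 0.7)
  kept <- gate_loudness(st, env, 0.15)
  expect_identical(nrow(kept), 3L)
  expect_true(all(kept$mean_loudness == 1))

  uniform <- structure(list(time = (0:199) / 120, loudness = rep(0.4, 200)),
                       class = "loudness_envelope")
  expect_identical(nrow(gate_loudness(st, uniform, 0.15)), 5L)
  expect_identical(nrow(gate_loudness(st, env, 0)), 5L)
  silent <- structure(list(time = (0:199) / 120, loudness = rep(0, 200)),
                      class = "loudness_envelope")
  expect_error(gate_loudness(st, silent), "silent performance")
})

test_that("gates commute and agree with brute-force enumeration", {
  set.seed(21)
  st <- fake_strokes(runif(20, 50, 500))
  loud <- runif(500, 0, 1)
  env <- structure(list(time = (seq_along(loud) - 1) / 120, loudness = loud),
                   class = "loudness_envelope")
  a <- gate_loudness(gate_length(st, 150), env, 0.15)
  b <- gate_length(gate_loudness(st, env, 0.15), 150)
  expect_equal(a$start_frame, b$start_frame)
  # brute force survivors
  ref <- stats::median(loud)
  ml <- vapply(seq_len(nrow(st)), function(i)
    mean(loud[st$start_frame[i]:(st$end_frame[i] - 1L)]), numeric(1))
  brute <- which(st$length > 150 & ml >= 0.15 * ref)
  expect_identical(a$start_frame, st$start_frame[brute])
  expect_lte(nrow(a), nrow(st))
})

test_that("pair_strokes extracts identical windows, resamples to N, bounds lag error", {
  av <- generate_avatar(tiny_score(n = 6))
  akin <- derivatives(bow_contact_kinematics(av$trace))
  st <- gate_length(segment_strokes(akin), 150)
  fol <- generate_follower(av, fidelity_params())
  pkin <- derivatives(bow_contact_kinematics(fol))
  pairs <- pair_strokes(akin, pkin, st, n_resample = 100)
  expect_identical(length(pairs), nrow(st))
  for (p in pairs) {
    expect_identical(dim(p$avatar_curve), c(100L, 2L))
    expect_identical(dim(p$participant_curve), c(100L, 2L))
    expect_equal(p$avatar_curve, p$participant_curve, tolerance = 1e-9)
  }

  lagged <- generate_follower(av, fidelity_params(tracking_lag = 0.05))
  lkin <- derivatives(bow_contact_kinematics(lagged))
  lp <- pair_strokes(akin, lkin, st)
  vmax <- max(abs(akin$velocity))
  for (p in lp)
    expect_lte(max(abs(p$avatar_curve[, 1] - p$participant_curve[, 1])),
               0.05 * vmax * 1.05 + 0.5)

  # participant shorter than a stroke window -> dropped with a warning
  short <- pkin
  keep <- seq_len(st$end_frame[3] - 5L)
  for (f in c("time", "dist_frog", "dist_bridge", "tilt_angle", "velocity",
              "acceleration", "jerk", "dist_frog_smooth"))
    short[[f]] <- short[[f]][keep]
  expect_warning(ps <- pair_strokes(akin, short, st), "dropped")
  expect_lt(length(ps), nrow(st))
})
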