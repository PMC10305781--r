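test_that("avatar bow path has one monotone segment per stroke with minimum-jerk speed", {
  sc <- tiny_score(n = 10, length = 300, duration = 0.5)
  av <- generate_avatar(sc)
  d <- av$path$d
  v <- diff(d)
  runs <- rle(sign(v[v != 0]))
  expect_identical(length(runs$lengths), 10L)

  # closed-form minimum-jerk peak speed 1.875 L / T, via dense differentiation
  tt <- seq(0, 0.5, by = 1e-5)
  dd <- 300 * (10 * (tt / 0.5)^3 - 15 * (tt / 0.5)^4 + 6 * (tt / 0.5)^5)
  peak_dense <- max(abs(diff(dd))) / 1e-5
  expect_equal(peak_dense, 1.875 * 300 / 0.5, tolerance = 1e-4)
  peak_gen <- max(abs(diff(d))) * sc$rate_motion
  expect_equal(peak_gen, 1.875 * 300 / 0.5, tolerance = 0.01)
})

test_that("avatar audio envelope tracks the stroke dynamics and is reproducible", {
  sc <- score_spec(data.frame(direction = c("down", "up"), length = 300,
                              duration = 0.5, dynamic = c(0.9, 0.3),
                              rest_after = c(0.2, 0.2)), rate_audio = 8000)
  av <- generate_avatar(sc)
  x <- av$audio$samples
  rms <- function(i0, i1) sqrt(mean(x[i0:i1]^2))
  # mid-stroke RMS ~ dynamic / sqrt(2); rests near zero
  expect_equal(rms(8000 * 0.2, 8000 * 0.3), 0.9 / sqrt(2), tolerance = 0.01)
  expect_equal(rms(8000 * 0.9, 8000 * 1.0), 0.3 / sqrt(2), tolerance = 0.01)
  expect_lt(rms(8000 * 0.55, 8000 * 0.65), 1e-10)
  expect_identical(generate_avatar(sc)$trace$markers, av$trace$markers)
  expect_error(default_score(n = 0), "empty|length")
})

test_that("neutral follower reproduces the avatar exactly", {
  av <- generate_avatar(tiny_score(n = 6))
  fol <- generate_follower(av, fidelity_params())
  expect_identical(fol$markers, av$trace$markers)
  expect_error(generate_follower(av, fidelity_params(tracking_lag = 100)),
               "exceeds the performance duration")
})

test_that("spatial noise raises Procrustes distance monotonically over many strokes", {
  av <- generate_avatar(tiny_score(n = 12))
  mean_pd <- function(sd_mm) {
    pds <- unlist(lapply(1:5, function(s) {
      fol <- generate_follower(av, fidelity_params(spatial_noise_sd = sd_mm, seed = s))
      performance_metrics(av, fol)$pd
    }))
    expect_gte(length(pds), 50)
    mean(pds)
  }
  m0 <- mean_pd(0); m2 <- mean_pd(2); m5 <- mean_pd(5)
  expect_lt(m0, m2)
  expect_lt(m2, m5)
  expect_lt(m0, 1e-10)
})

test_that("tremor lowers the follower's per-stroke SPARC below the avatar's", {
  av <- generate_avatar(tiny_score(n = 8))
  fol <- generate_follower(av, fidelity_params(tremor_amp = 3, tremor_freq = 8, seed = 2))
  m <- performance_metrics(av, fol)
  expect_true(all(m$dsi < 0))
  expect_true(all(m$si_avatar <= -1))
  expect_true(all(m$si_participant < m$si_avatar))
})

test_that("cohort generation conserves the design cell count and truth ledger", {
  des <- cohort_design(seed = 3)
  coh <- generate_cohort(des, realize = FALSE)
  expect_identical(nrow(coh$cells), 11L * 2L * 4L)
  expect_identical(nrow(coh$params), 88L)
  # same seed -> identical ledger
  coh2 <- generate_cohort(cohort_design(seed = 3), realize = FALSE)
  expect_identical(coh$params, coh2$params)
  # zero condition effects -> all deltas neutral
  des0 <- cohort_design(condition_effects = list("2D" = list(), "3D" = list()), seed = 4)
  coh0 <- generate_cohort(des0, realize = FALSE)
  expect_true(all(coh0$params$delta_spatial_noise_sd == 0))
  expect_true(all(coh0$params$delta_gain_error == 1))
  # per-participant baselines are positive (log-normal draws)
  expect_true(all(coh$params$spatial_noise_sd > 0))
  expect_true(all(coh$params$tremor_amp > 0))
  # non-default shape
  des_s <- cohort_design(n_participants = 5, conditions = c("a", "b", "c"),
                         n_trials = 2, condition_effects = list(), seed = 5)
  expect_identical(nrow(generate_cohort(des_s, realize = FALSE)$cells), 5L * 3L * 2L)
})

test_that("questionnaire generator yields 8 administrations per participant and hits the reliability target", {
  des <- cohort_design(seed = 6)
  q <- generate_questionnaires(des)
  expect_identical(nrow(q), 88L)
  expect_true(all(table(q$participant) == 8L))
  expect_true(all(q$WPQ_1 %in% 1:7))
  expect_true(all(q$MPQS_1 %in% 1:5))
  expect_true(all(q$difficulty >= 0 & q$difficulty <= 100))
  expect_error(generate_questionnaires(des, reliability_target = 1.2), "between 0 and 1")
  expect_error(generate_questionnaires(des, n_items = c(WPQ = 1, MPQS = 5, MPQP = 5)),
               "at least 2 items")

  # ~500 respondents: recovered alpha within +/- 0.05 of the target
  big <- cohort_design(n_participants = 63, seed = 7)
  qb <- generate_questionnaires(big, n_items = c(WPQ = 5, MPQS = 5, MPQP = 5),
                                reliability_target = 0.85)
  for (sc in c("WPQ", "MPQS", "MPQP")) {
    a <- cronbach_alpha(qb[, grep(paste0("^", sc, "_"), names(qb))])
    expect_lt(abs(a - 0.85), 0.05)
  }

  # no condition shift -> condition means agree within Monte-Carlo error
  des0 <- cohort_design(n_participants = 40, presence_effects = c("2D" = 0, "3D" = 0),
                        seed = 8)
  q0 <- generate_questionnaires(des0)
  wpq <- rowMeans(q0[, grep("^WPQ_", names(q0))])
  expect_lt(abs(mean(wpq[q0$condition == "2D"]) - mean(wpq[q0$condition == "3D"])), 0.15)
})
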