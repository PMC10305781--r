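make_bow_trace <- function(frog, tip, bridge, scroll, n = 3L) {
  rep_m <- function(p) matrix(rep(p, each = n), n, 3L)
  motion_trace(time = (seq_len(n) - 1) / 120,
               markers = list(bow_frog = rep_m(frog), bow_tip = rep_m(tip),
                              violin_bridge = rep_m(bridge), violin_scroll = rep_m(scroll)))
}

test_that("contact point geometry: orthogonal crossing at frog and bridge", {
  tr <- make_bow_trace(frog = c(0, 0, 0), tip = c(650, 0, 0),
                       bridge = c(0, 0, 0), scroll = c(0, 330, 0))
  kin <- bow_contact_kinematics(tr)
  expect_equal(kin$dist_frog, rep(0, 3), tolerance = 1e-9)
  expect_equal(kin$dist_bridge, rep(0, 3), tolerance = 1e-9)
  expect_equal(kin$tilt_angle, rep(90, 3), tolerance = 1e-9)
})

test_that("contact point at an analytically placed 300 mm from the frog", {
  # bow along x crossing the string axis at x=300 from the frog, 50 from bridge
  tr <- make_bow_trace(frog = c(-300, 50, 0), tip = c(350, 50, 0),
                       bridge = c(0, 0, 0), scroll = c(0, 330, 0))
  kin <- bow_contact_kinematics(tr)
  expect_equal(kin$dist_frog[1], 300, tolerance = 0.1)
  expect_equal(kin$dist_bridge[1], 50, tolerance = 0.1)
  expect_error(bow_contact_kinematics(make_bow_trace(c(0, 0, 0), c(0, 0, 0),
                                                     c(0, 0, 0), c(0, 330, 0))),
               "collinear markers")
})

test_that("contact distances match a brute-force two-segment search on random skew pairs", {
  set.seed(11)
  for (i in 1:8) {
    frog <- rnorm(3, 0, 100); tip <- frog + 650 * rnorm(3) / sqrt(sum(rnorm(3)^2))
    dir_b <- rnorm(3); dir_b <- dir_b / sqrt(sum(dir_b^2))
    bridge <- rnorm(3, 0, 100); scroll <- bridge + 330 * dir_b
    tr <- make_bow_trace(frog, tip, bridge, scroll, n = 3L)
    kin <- bow_contact_kinematics(tr)
    or <- oracle_segment_distance(frog, tip, bridge, scroll)
    expect_lt(abs(kin$dist_frog[1] - or$s * sqrt(sum((tip - frog)^2))), 1)
    expect_lt(abs(kin$dist_bridge[1] - or$t * sqrt(sum((scroll - bridge)^2))), 1)
  }
})

test_that("contact kinematics are invariant under rigid-body motion of all markers", {
  av <- generate_avatar(tiny_score(n = 4))
  kin0 <- bow_contact_kinematics(av$trace)
  R <- euler_compose(c(31, 47, -12), "ZXY")
  shift <- c(123, -45, 67)
  moved <- av$trace
  moved$markers <- lapply(moved$markers, function(m) sweep(m %*% t(R), 2, shift, "+"))
  kin1 <- bow_contact_kinematics(moved)
  expect_equal(kin1$dist_frog, kin0$dist_frog, tolerance = 1e-8)
  expect_equal(kin1$dist_bridge, kin0$dist_bridge, tolerance = 1e-8)
  expect_equal(kin1$tilt_angle, kin0$tilt_angle, tolerance = 1e-8)
})

test_that("derivatives: ramp, minimum-jerk peak, constant, linearity", {
  n <- 240
  base <- list(time = (0:(n - 1)) / 120, dist_frog = numeric(n), dist_bridge = numeric(n),
               tilt_angle = numeric(n), rate = 120, velocity = NULL)
  class(base) <- "bow_kinematics"
  ramp <- base; ramp$dist_frog <- 100 * ramp$time
  kr <- derivatives(ramp)
  interior <- 20:(n - 20)
  expect_equal(kr$velocity[interior], rep(100, length(interior)), tolerance = 0.01)
  expect_lt(max(abs(kr$acceleration[interior])), 1)

  mj <- base; tau <- pmin(mj$time / 1.5, 1)
  mj$dist_frog <- 400 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  km <- derivatives(mj)
  expect_equal(max(abs(km$velocity)), 1.875 * 400 / 1.5, tolerance = 0.02)

  const <- base; const$dist_frog <- rep(42, n)
  kc <- derivatives(const)
  expect_lt(max(abs(kc$velocity)), 1e-9)
  expect_lt(max(abs(kc$jerk)), 1e-6)

  # linearity of the filtered derivative operator
  x <- sin(2 * pi * 1.3 * base$time); y <- cos(2 * pi * 0.7 * base$time)
  dv <- function(sig) { k <- base; k$dist_frog <- sig; derivatives(k)$velocity }
  expect_equal(dv(2 * x + 3 * y), 2 * dv(x) + 3 * dv(y), tolerance = 1e-8)

  expect_error(derivatives(ramp, cutoff = 60), "Nyquist")
  short <- base; short$time <- short$time[1:5]; short$dist_frog <- short$dist_frog[1:5]
  expect_error(derivatives(short), "9 frames")
})

test_that("Euler decomposition round-trips and matches constructed rotations", {
  set.seed(12)
  for (sq in c("ZXY", "YXY", "XYZ", "ZYX")) {
    for (i in 1:25) {
      a <- runif(3, -170, 170)
      a[2] <- if (sq == "YXY") runif(1, 5, 175) else runif(1, -85, 85)
      R <- euler_compose(a, sq)
      back <- euler_compose(euler_decompose(R, sq), sq)
      expect_lt(max(abs(back - R)), 1e-9)
    }
  }
  expect_equal(euler_decompose(diag(3), "ZXY"), c(0, 0, 0))
  # 90 degree rotation about the first (flexion) axis of ZXY
  expect_equal(euler_decompose(euler_compose(c(90, 0, 0), "ZXY"), "ZXY")[1], 90,
               tolerance = 0.5)
})

test_that("joint angles recover a constructed elbow flexion and reject degenerate clusters", {
  n <- 3L
  tri <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0))
  place <- function(R, origin) lapply(1:3, function(i)
    matrix(rep(origin + as.vector(R %*% tri[i, ]), each = n), n, 3L))
  mk <- list()
  for (seg in c("thorax", "upper_arm", "hand")) {
    pts <- place(diag(3), c(0, 0, 0))
    for (i in 1:3) mk[[paste0(seg, "_", i)]] <- pts[[i]]
  }
  Rfe <- euler_compose(c(90, 0, 0), "ZXY")
  pts <- place(Rfe, c(0, 0, 0))
  for (i in 1:3) mk[[paste0("forearm_", i)]] <- pts[[i]]
  tr <- motion_trace((seq_len(n) - 1) / 120, mk)
  ja <- joint_angles(tr)
  expect_equal(unname(ja$elbow$angles[1, "FE"]), 90, tolerance = 0.5)
  expect_equal(max(abs(ja$shoulder$angles[1, ])), 0, tolerance = 0.5)
  # wrist sees the inverse rotation (hand at identity, forearm rotated)
  expect_equal(unname(ja$wrist$angles[1, "FE"]), -90, tolerance = 0.5)

  mk$forearm_3 <- mk$forearm_2   # collinear cluster
  tr_bad <- motion_trace((seq_len(n) - 1) / 120, mk)
  expect_error(joint_angles(tr_bad), "forearm")
})

test_that("loudness envelope: RMS identity, silence, f0 of a pure tone", {
  n <- 120
  tr <- generate_avatar(tiny_score(n = 2, duration = 0.5))$trace
  fs <- 48000
  t <- seq(0, 1.1, by = 1 / fs)
  a <- audio_signal(0.6 * sin(2 * pi * 440 * t), fs)
  env <- loudness_envelope(a, tr, window = 0.05)
  expect_equal(stats::median(env$loudness), 0.6 / sqrt(2), tolerance = 1e-3)
  silent <- audio_signal(numeric(length(t)), fs)
  expect_equal(max(loudness_envelope(silent, tr)$loudness), 0)
  envf <- loudness_envelope(a, tr, compute_f0 = TRUE)
  voiced <- !is.na(envf$f0)
  expect_gt(mean(voiced), 0.5)
  expect_lt(max(abs(envf$f0[voiced] - 440)), 1)
  short <- audio_signal(a$samples[1:1000], fs)
  expect_error(loudness_envelope(short, tr), "shorter than the motion span")
})
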