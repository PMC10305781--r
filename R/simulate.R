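BOW_LENGTH_MM <- 650
STRING_LENGTH_MM <- 330

# Smooth bow-bridge drift used by the synthetic performer: keeps the 2D bowing
# curve (dist_frog, dist_bridge) genuinely two-dimensional and within the
# contact range reported for real playing (~45-65 mm from the bridge).
bridge_drift <- function(t) 50 + 8 * sin(2 * pi * 0.11 * t) + 3 * sin(2 * pi * 0.23 * t + 1)

# Build the bow-path (dist_frog over time) implied by a score: minimum-jerk
# displacement within each stroke, hold during rests.
score_bow_path <- function(score) {
  st <- score$strokes
  fs <- score$rate_motion
  durs <- st$duration + st$rest_after
  onsets <- cumsum(c(0, durs))[seq_len(nrow(st))]
  total <- sum(durs)
  t <- (0:floor(total * fs + 1e-9)) / fs
  d0 <- 60
  d <- rep(NA_real_, length(t))
  pos <- d0
  windows <- data.frame(onset = onsets, offset = onsets + st$duration,
                        start_pos = NA_real_, end_pos = NA_real_)
  for (k in seq_len(nrow(st))) {
    sgn <- if (st$direction[k] == "down") 1 else -1
    tau <- (t - onsets[k]) / st$duration[k]
    inwin <- tau >= 0 & tau < 1
    d[inwin] <- pos + sgn * st$length[k] * min_jerk_s(tau[inwin])
    windows$start_pos[k] <- pos
    pos <- pos + sgn * st$length[k]
    windows$end_pos[k] <- pos
    hold <- t >= windows$offset[k] & (k == nrow(st) | t < onsets[min(k + 1L, nrow(st))])
    d[hold] <- pos
  }
  d[is.na(d)] <- pos
  if (any(d < 5 | d > BOW_LENGTH_MM - 5))
    stop("score drives the bow past its length; reduce stroke lengths")
  list(time = t, d = d, windows = windows, total = total)
}

# Marker-set builder shared by avatar and follower: given the bow path
# (dist_frog, dist_bridge per frame) reconstruct the full marker roster.
# Violin fixed at the origin with the string along +y; bow along +x through
# the contact point; arm segment triads driven by the normalized bow position.
build_trace_from_path <- function(time, d, y0, rate) {
  n <- length(time)
  ones <- rep(1, n)
  frog <- cbind(-d, y0, 0 * ones)
  tip <- cbind(BOW_LENGTH_MM - d, y0, 0 * ones)
  markers <- list(
    bow_frog = frog, bow_tip = tip,
    violin_bridge = cbind(0 * ones, 0 * ones, 0 * ones),
    violin_scroll = cbind(0 * ones, STRING_LENGTH_MM * ones, 0 * ones)
  )
  u <- (d - 60) / 400
  seg <- function(origin, az, ax) {
    tri <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0))
    lapply(1:3, function(i) {
      p <- tri[i, ]
      # Rz(az) then Rx(ax) applied per frame, plus origin
      x1 <- cos(az) * p[1] - sin(az) * p[2]
      y1 <- sin(az) * p[1] + cos(az) * p[2]
      z1 <- p[3]
      y2 <- cos(ax) * y1 - sin(ax) * z1
      z2 <- sin(ax) * y1 + cos(ax) * z1
      cbind(origin[1] + x1, origin[2] + y2, origin[3] + z2)
    })
  }
  clusters <- list(
    thorax = seg(c(-300, -150, 200), 0 * u, 0 * u),
    upper_arm = seg(c(-250, -100, 300), 0.30 * u, 0.25 + 0.10 * u),
    forearm = seg(c(-150, -50, 250), 0.80 * u, 0.35 + 0.15 * u),
    hand = seg(c(-80, 0, 150), 1.10 * u, 0.40 + 0.20 * u)
  )
  for (s in names(clusters)) for (i in 1:3)
    markers[[paste0(s, "_", i)]] <- clusters[[s]][[i]]
  motion_trace(time, markers, rate = rate)
}

#' Generate a synthetic leader ("avatar") performance
#'
#' Synthesizes the reference performance a follower will imitate: bow position
#' along each stroke follows a minimum-jerk displacement profile
#' `x(tau) = L (10 tau^3 - 15 tau^4 + 6 tau^5)` (peak speed `1.875 L / T`),
#' the marker roster covers bow, violin and right-arm segment triads, and the
#' audio is an amplitude-gated 440 Hz tone whose RMS envelope is proportional
#' to the stroke dynamic and near zero during rests. Motion and audio share
#' `t = 0`. The avatar is deterministic given the score; `seed` is accepted
#' for interface symmetry with the stochastic generators.
#'
#' @param score a [score_spec()].
#' @param seed ignored by this generator (kept for a uniform interface).
#' @return an object of class `avatar_performance`: a list with `trace`
#'   ([motion_trace()]), `audio` ([audio_signal()]), `path` (bow path per
#'   frame) and `strokes` (the ground-truth stroke windows).
#' @export
generate_avatar <- function(score, seed = 0L) {
  stopifnot(inherits(score, "score_spec"))
  if (nrow(score$strokes) == 0L) stop("empty score")
  path <- score_bow_path(score)
  y0 <- bridge_drift(path$time)
  trace <- build_trace_from_path(path$time, path$d, y0, score$rate_motion)

  fs_a <- score$rate_audio
  na <- ceiling(path$total * fs_a) + 1L
  ta <- (seq_len(na) - 1L) / fs_a
  amp <- numeric(na)
  ramp <- 0.02
  st <- score$strokes
  for (k in seq_len(nrow(st))) {
    t0 <- path$windows$onset[k]; t1 <- path$windows$offset[k]
    idx <- ta >= t0 & ta < t1
    tt <- ta[idx]
    env <- rep(1, sum(idx))
    env[tt < t0 + ramp] <- 0.5 * (1 - cos(pi * (tt[tt < t0 + ramp] - t0) / ramp))
    env[tt > t1 - ramp] <- 0.5 * (1 - cos(pi * (t1 - tt[tt > t1 - ramp]) / ramp))
    amp[idx] <- st$dynamic[k] * env
  }
  audio <- audio_signal(amp * sin(2 * pi * 440 * ta), fs_a)
  structure(list(trace = trace, audio = audio, path = list(time = path$time, d = path$d, y0 = y0),
                 strokes = cbind(path$windows, st), score = score),
            class = "avatar_performance")
}

#' Fidelity parameters for the synthetic follower
#'
#' Knobs controlling how faithfully the synthetic follower tracks the avatar.
#' They map directly onto the downstream metrics: `spatial_noise_sd`, `offset`
#' and `gain_error` degrade gesture similarity (Procrustes distance), while
#' `tremor_amp`/`tremor_freq` inject a high-frequency component that lowers
#' movement smoothness (SPARC). With everything neutral (noise 0, lag 0,
#' gain 1, offset 0, tremor 0) the follower reproduces the avatar exactly.
#'
#' @param spatial_noise_sd positional noise SD in mm (Gaussian, low-passed at
#'   20 Hz, rescaled to this SD after filtering).
#' @param tracking_lag follower delay in s.
#' @param gain_error multiplicative bias on stroke excursion (1 = none).
#' @param offset constant displacement along the bow in mm.
#' @param tremor_amp amplitude in mm of a sinusoidal tremor on bow position.
#' @param tremor_freq tremor frequency in Hz (must be below the motion Nyquist).
#' @param seed integer seed; identical seeds reproduce identical followers.
#' @return an object of class `fidelity_params`.
#' @export
fidelity_params <- function(spatial_noise_sd = 0, tracking_lag = 0, gain_error = 1,
                            offset = 0, tremor_amp = 0, tremor_freq = 8, seed = 1L) {
  if (spatial_noise_sd < 0) stop("spatial_noise_sd must be >= 0")
  if (tremor_amp < 0) stop("tremor_amp must be >= 0")
  structure(list(spatial_noise_sd = spatial_noise_sd, tracking_lag = tracking_lag,
                 gain_error = gain_error, offset = offset, tremor_amp = tremor_amp,
                 tremor_freq = tremor_freq, seed = as.integer(seed)),
            class = "fidelity_params")
}

is_neutral <- function(p) {
  p$spatial_noise_sd == 0 && p$tracking_lag == 0 && p$gain_error == 1 &&
    p$offset == 0 && p$tremor_amp == 0
}

#' Generate a synthetic follower performance
#'
#' Produces a follower trace as a time-lagged, gain-scaled, offset, noise- and
#' tremor-perturbed copy of the avatar's bow kinematics, re-expressed as
#' marker positions via the same marker-set builder the avatar uses (so a
#' neutral parameter set reproduces the avatar bit for bit).
#'
#' @param avatar an `avatar_performance` (preferred) or a bare
#'   [motion_trace()], in which case the bow path is recovered with
#'   [bow_contact_kinematics()].
#' @param params a [fidelity_params()].
#' @return a [motion_trace()] for the follower.
#' @export
generate_follower <- function(avatar, params) {
  stopifnot(inherits(params, "fidelity_params"))
  if (inherits(avatar, "avatar_performance")) {
    time <- avatar$path$time; d <- avatar$path$d; y0 <- avatar$path$y0
    rate <- avatar$trace$rate
  } else if (inherits(avatar, "motion_trace")) {
    kin <- bow_contact_kinematics(avatar)
    time <- avatar$time; d <- kin$dist_frog; y0 <- kin$dist_bridge
    rate <- avatar$rate
  } else stop("avatar must be an avatar_performance or motion_trace")
  dur <- time[length(time)] - time[1L]
  if (params$tracking_lag >= dur) stop("tracking_lag exceeds the performance duration")
  if (params$tremor_freq >= rate / 2) stop("tremor_freq must be below the motion Nyquist")
  if (is_neutral(params)) return(build_trace_from_path(time, d, y0, rate))

  lagged <- function(x) {
    if (params$tracking_lag == 0) x
    else stats::approx(time, x, xout = time - params$tracking_lag, rule = 2)$y
  }
  n <- length(time)
  noise_d <- noise_y <- numeric(n)
  if (params$spatial_noise_sd > 0) {
    raw <- with_seed(params$seed, matrix(stats::rnorm(2L * n), ncol = 2L))
    smooth <- apply(raw, 2L, lowpass_zerophase, fs = rate, cutoff = min(20, rate / 2 - 1))
    smooth <- sweep(smooth, 2L, apply(smooth, 2L, stats::sd), "/") * params$spatial_noise_sd
    noise_d <- smooth[, 1L]; noise_y <- smooth[, 2L]
  }
  tremor <- params$tremor_amp * sin(2 * pi * params$tremor_freq * time)
  dl <- lagged(d)
  mid <- mean(range(dl))
  d_f <- mid + params$gain_error * (dl - mid) + params$offset + noise_d + tremor
  d_f <- pmax(5, pmin(BOW_LENGTH_MM - 5, d_f))
  y_f <- pmax(5, pmin(STRING_LENGTH_MM - 5, lagged(y0) + noise_y))
  build_trace_from_path(time, d_f, y_f, rate)
}

#' Define a cohort design
#'
#' Describes a within-subject imitation study: every participant performs
#' every condition once per trial. The default mirrors a design of 11
#' participants, 2 display conditions and 4 trials (88 performance cells, and
#' 8 questionnaire administrations per participant), with participants split
#' over 2 pieces and 2 violin sections.
#'
#' @param n_participants number of participants (default 11).
#' @param conditions character vector of condition labels (default `"2D"`,
#'   `"3D"`).
#' @param n_trials number of trials (default 4).
#' @param condition_effects named list (per condition) of additive deltas on
#'   [fidelity_params()] fields (`gain_error` deltas are multiplicative). The
#'   default degrades the 2D condition (more positional noise and tremor),
#'   i.e. imitation is better with the 3D display.
#' @param presence_effects named numeric vector (per condition) of latent
#'   presence shifts in points of the 7-point scale; default gives 3D +0.5.
#' @param seed root seed for every random draw derived from the design.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_participants = 11, conditions = c("2D", "3D"),
                          n_trials = 4,
                          condition_effects = list(
                            "2D" = list(spatial_noise_sd = 1.5, tremor_amp = 0.7),
                            "3D" = list()
                          ),
                          presence_effects = c("2D" = 0, "3D" = 0.5),
                          seed = 1L) {
  stopifnot(n_participants >= 1, n_trials >= 1, length(conditions) >= 1)
  if (!all(names(condition_effects) %in% conditions))
    stop("condition_effects names must match conditions")
  if (!all(conditions %in% names(presence_effects)))
    presence_effects <- stats::setNames(rep(0, length(conditions)), conditions)
  pid <- seq_len(n_participants)
  assignment <- data.frame(
    participant = pid,
    piece = 1L + (pid - 1L) %% 2L,
    violin_section = 1L + ((pid - 1L) %/% 2L) %% 2L,
    first_condition = conditions[1L + (pid - 1L) %% length(conditions)]
  )
  structure(list(n_participants = n_participants, conditions = conditions,
                 n_trials = n_trials, condition_effects = condition_effects,
                 presence_effects = presence_effects, assignment = assignment,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

apply_effect_delta <- function(base, delta) {
  p <- base
  for (nm in names(delta)) {
    if (nm == "gain_error") p[[nm]] <- p[[nm]] * delta[[nm]]
    else p[[nm]] <- p[[nm]] + delta[[nm]]
  }
  p$spatial_noise_sd <- max(0, p$spatial_noise_sd)
  p$tremor_amp <- max(0, p$tremor_amp)
  p$tracking_lag <- max(0, p$tracking_lag)
  p
}

#' Generate a synthetic cohort
#'
#' Realizes one leader/follower pair per participant x condition x trial cell.
#' Per-participant baseline fidelity parameters are drawn from log-normal
#' distributions (so noise magnitudes stay positive); condition effects from
#' the design are applied on top. The returned bundle carries a ground-truth
#' ledger of every realized parameter and delta for recovery tests.
#'
#' @param design a [cohort_design()].
#' @param scores list of [score_spec()] keyed by piece number; default two
#'   slightly different alternating-stroke pieces.
#' @param realize if `TRUE` (default) build every follower trace now (avatars
#'   are cached per piece); if `FALSE` return only the cell table and
#'   parameters and realize cells on demand with [realize_cell()].
#' @return an object of class `cohort_bundle` with elements `design`, `cells`
#'   (one row per cell, with per-cell seeds), `params` (ground-truth ledger),
#'   `profiles` (participant demographics), `avatars`, and (when realized)
#'   `followers`.
#' @export
generate_cohort <- function(design, scores = NULL, realize = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(scores))
    scores <- list(default_score(n = 16, length = 300, duration = 0.5),
                   default_score(n = 16, length = 330, duration = 0.55))
  cells <- expand.grid(trial = seq_len(design$n_trials),
                       condition = design$conditions,
                       participant = seq_len(design$n_participants),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("participant", "condition", "trial")]
  cells <- merge(cells, design$assignment[, c("participant", "piece", "violin_section")],
                 by = "participant", sort = FALSE)
  cells <- cells[order(cells$participant, cells$condition, cells$trial), ]
  rownames(cells) <- NULL
  n_cells <- nrow(cells)

  seeds <- derive_seeds(design$seed, design$n_participants * 7L + n_cells)
  base <- with_seed(seeds[1L], data.frame(
    participant = seq_len(design$n_participants),
    spatial_noise_sd = stats::rlnorm(design$n_participants, log(3), 0.3),
    tremor_amp = stats::rlnorm(design$n_participants, log(1), 0.4),
    tracking_lag = stats::rlnorm(design$n_participants, log(0.05), 0.3),
    gain_error = exp(stats::rnorm(design$n_participants, 0, 0.03)),
    offset = stats::rnorm(design$n_participants, 0, 3)
  ))
  profiles <- with_seed(seeds[2L], data.frame(
    id = seq_len(design$n_participants),
    age = sample(18:45, design$n_participants, replace = TRUE),
    years_played = sample(8:30, design$n_participants, replace = TRUE),
    msi_score = round(stats::runif(design$n_participants, 3, 7), 1),
    itq_score = round(stats::runif(design$n_participants, 3, 7), 1),
    violin_section = design$assignment$violin_section
  ))

  params <- cells
  par_cols <- c("spatial_noise_sd", "tremor_amp", "tracking_lag", "gain_error", "offset")
  for (cc in par_cols) params[[cc]] <- NA_real_
  for (cc in par_cols) params[[paste0("delta_", cc)]] <- ifelse(cc == "gain_error", 1, 0)
  params$seed <- seeds[design$n_participants * 7L + seq_len(n_cells)]
  for (i in seq_len(n_cells)) {
    b <- base[base$participant == cells$participant[i], par_cols]
    p <- fidelity_params(b$spatial_noise_sd, b$tracking_lag, b$gain_error,
                         b$offset, b$tremor_amp, tremor_freq = 8,
                         seed = params$seed[i])
    delta <- design$condition_effects[[cells$condition[i]]] %||% list()
    p <- apply_effect_delta(p, delta)
    for (cc in par_cols) params[[cc]][i] <- p[[cc]]
    for (cc in intersect(names(delta), par_cols)) params[[paste0("delta_", cc)]][i] <- delta[[cc]]
  }

  avatars <- lapply(scores, generate_avatar)
  bundle <- structure(list(design = design, cells = cells, params = params,
                           profiles = profiles, scores = scores, avatars = avatars,
                           followers = NULL),
                      class = "cohort_bundle")
  if (realize)
    bundle$followers <- lapply(seq_len(n_cells), function(i) realize_cell(bundle, i))
  bundle
}

#' Realize one cohort cell
#'
#' Builds the follower trace for row `i` of the cohort's cell table (the
#' avatar for the cell's piece is shared from the bundle's cache).
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param i cell row index.
#' @return the follower [motion_trace()] for that cell.
#' @export
realize_cell <- function(bundle, i) {
  row <- bundle$params[i, ]
  p <- fidelity_params(row$spatial_noise_sd, row$tracking_lag, row$gain_error,
                       row$offset, row$tremor_amp, tremor_freq = 8, seed = row$seed)
  generate_follower(bundle$avatars[[row$piece]], p)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d participants x %d conditions x %d trials = %d cells%s\n",
              x$design$n_participants, length(x$design$conditions), x$design$n_trials,
              nrow(x$cells), if (is.null(x$followers)) " (unrealized)" else ""))
  invisible(x)
}

#' Generate synthetic questionnaire responses
#'
#' Simulates item-level presence-questionnaire responses for every cell of a
#' design. The latent presence per administration is the scale midpoint plus
#' the design's condition shift, a participant offset and cell noise; item
#' responses add item noise calibrated so the expected Cronbach's alpha
#' matches `reliability_target`, then are discretized (round half up, clipped)
#' to the scale's Likert range. WPQ items are on 1-7, MPQS/MPQP on 1-5, and
#' perceived difficulty is continuous on 0-100.
#'
#' @param design a [cohort_design()].
#' @param n_items named vector of item counts per scale (defaults
#'   `WPQ = 19`, `MPQS = 5`, `MPQP = 5`).
#' @param reliability_target target Cronbach's alpha in (0, 1).
#' @return data frame with one row per participant x condition x trial
#'   administration: item columns `WPQ_1..`, `MPQS_1..`, `MPQP_1..` and
#'   `difficulty`.
#' @export
generate_questionnaires <- function(design, n_items = c(WPQ = 19, MPQS = 5, MPQP = 5),
                                    reliability_target = 0.85) {
  stopifnot(inherits(design, "cohort_design"))
  if (reliability_target <= 0 || reliability_target >= 1)
    stop("reliability_target must lie strictly between 0 and 1")
  if (any(n_items < 2)) stop("need at least 2 items per scale")
  admin <- expand.grid(trial = seq_len(design$n_trials),
                       condition = design$conditions,
                       participant = seq_len(design$n_participants),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  admin <- admin[, c("participant", "condition", "trial")]
  admin <- admin[order(admin$participant, admin$condition, admin$trial), ]
  rownames(admin) <- NULL
  n <- nrow(admin)
  seeds <- derive_seeds(design$seed + 104729L, 2L)
  scales <- list(WPQ = c(lo = 1, hi = 7), MPQS = c(lo = 1, hi = 5), MPQP = c(lo = 1, hi = 5))
  shift <- design$presence_effects[admin$condition]

  out <- admin
  with_seed(seeds[1L], {
    b_p <- stats::rnorm(design$n_participants, 0, 0.8)
    for (sc in names(scales)) {
      lo <- scales[[sc]]["lo"]; hi <- scales[[sc]]["hi"]
      unit <- (hi - lo) / 6           # one point of the 7-point scale, rescaled
      theta <- (lo + hi) / 2 + unit * (as.numeric(shift) + b_p[admin$participant] +
                                         stats::rnorm(n, 0, 0.5))
      sd_theta <- unit * sqrt(0.8^2 + 0.5^2)
      k <- n_items[[sc]]
      r <- reliability_target / (k - reliability_target * (k - 1))
      # Likert rounding adds ~uniform(-1/2, 1/2) noise (variance 1/12), so the
      # continuous item noise is shrunk by that much to keep alpha on target
      sd_item <- sqrt(max(sd_theta^2 * (1 - r) / r - 1 / 12, 1e-6))
      items <- matrix(theta, n, k) + matrix(stats::rnorm(n * k, 0, sd_item), n, k)
      items <- floor(items + 0.5)                       # round half up
      items[items < lo] <- lo
      items[items > hi] <- hi
      colnames(items) <- paste0(sc, "_", seq_len(k))
      out <- cbind(out, items)
    }
    out$difficulty <- pmax(0, pmin(100, 50 - 10 * as.numeric(shift) +
                                     10 * b_p[admin$participant] + stats::rnorm(n, 0, 8)))
  })
  out
}
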