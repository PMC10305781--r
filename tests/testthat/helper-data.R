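# Shared fixtures, all generated in code.

# Small fast score: fewer strokes, low audio rate (audio content only matters
# through its RMS envelope).
tiny_score <- function(n = 10, length = 300, duration = 0.5, ...)
  default_score(n = n, length = length, duration = duration, rate_audio = 8000, ...)

# Simulate an 88-row (or scaled) cell dataset straight from the hierarchical
# model: condition difference `effect` in units of the pooled SD of the
# null response, varying intercepts per condition:participant and
# condition:trial.
sim_cell_dataset <- function(effect = 0, n_participants = 11, n_trials = 4,
                             sigma_u = 0.3, sigma_w = 0.1, sigma = 0.5,
                             seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n_participants),
                   condition = c("1", "2"), trial = seq_len(n_trials),
                   stringsAsFactors = FALSE)
  cp <- interaction(factor(d$condition), factor(d$participant))
  ct <- interaction(factor(d$condition), factor(d$trial))
  u <- rnorm(nlevels(cp), 0, sigma_u)
  w <- rnorm(nlevels(ct), 0, sigma_w)
  y0 <- u[as.integer(cp)] + w[as.integer(ct)] + rnorm(nrow(d), 0, sigma)
  delta <- effect * sd(y0)
  d$value <- y0 + ifelse(d$condition == "1", delta / 2, -delta / 2)
  d
}

# A quick reduced-sampler fit used across test files.
quick_fit <- function(data, ..., seed = 1)
  suppressWarnings(fit_hbm(data, chains = 4, warmup = 500, iter = 2500,
                           seed = seed, ...))

# Stroke-level metric table over a full design grid, one value per stroke,
# for exercising cell_medians/group_calibrate without the motion pipeline.
synthetic_stroke_values <- function(design, strokes_per_cell = 5, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(participant = seq_len(design$n_participants),
                       condition = design$conditions,
                       trial = seq_len(design$n_trials),
                       stringsAsFactors = FALSE)
  df <- cells[rep(seq_len(nrow(cells)), each = strokes_per_cell), ]
  df$value <- rnorm(nrow(df))
  rownames(df) <- NULL
  df
}
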