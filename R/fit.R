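#' Fit a hierarchical Bayesian varying-intercept model
#'
#' Fits the Gaussian cell-means model used for the imitation metrics and the
#' presence scales: `response ~ 0 + condition + (1 | condition:participant) +
#' (1 | condition:trial)`, optionally with a standardized covariate in
#' interaction with condition (fixed per-condition slopes) and varying
#' covariate slopes per grouping. Priors: cell means and fixed slopes
#' `Normal(0, 2.5 * sd(y))`; all group and residual SDs
#' `half-Student-t(3, 0, 2.5 * sd(y))`. Sampling is by Gibbs (JAGS), seeded
#' and reproducible. Convergence (split R-hat > 1.01) is flagged in the
#' returned object, never silently ignored.
#'
#' @param data data frame with columns `condition`, `trial`, `participant`,
#'   the response, and the covariate when requested.
#' @param response name of the response column (default `"value"`).
#' @param covariate optional name of a covariate column (e.g. perceived
#'   difficulty); standardized internally.
#' @param varying_slope give each grouping a varying covariate slope
#'   (default `TRUE` when a covariate is present); intercepts and slopes are
#'   modelled as independent.
#' @param chains,warmup,iter MCMC settings; `iter` is the total per chain
#'   including warmup (defaults 4 chains, 5000 warmup, 40000 iterations).
#' @param prior_scale prior scale multiplier on sd(y) (default 2.5).
#' @param seed integer seed; identical seeds reproduce identical fits.
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return an object of class `hbm_fit`.
#' @export
fit_hbm <- function(data, response = "value", covariate = NULL,
                    varying_slope = !is.null(covariate),
                    chains = 4, warmup = 5000, iter = 40000,
                    prior_scale = 2.5, seed = 1L, quiet = TRUE) {
  stopifnot(is.data.frame(data), iter > warmup, chains >= 1)
  need <- c("condition", "trial", "participant", response, covariate)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- as.numeric(data[[response]])
  if (anyNA(y)) stop("response contains NA")
  cond <- factor(data$condition)
  trial <- factor(data$trial)
  part <- factor(data$participant)
  cp <- interaction(cond, part, drop = FALSE, lex.order = TRUE)
  ct <- interaction(cond, trial, drop = FALSE, lex.order = TRUE)
  ct_map <- data.frame(level = seq_along(levels(ct)),
                       cond_idx = rep(seq_along(levels(cond)), each = nlevels(trial)),
                       trial_idx = rep(seq_along(levels(trial)), nlevels(cond)))
  sd_y <- stats::sd(y)
  if (sd_y == 0) sd_y <- 1
  s_scale <- prior_scale * sd_y
  x <- NULL
  if (!is.null(covariate)) {
    x <- as.numeric(data[[covariate]])
    sx <- stats::sd(x)
    x <- if (sx > 0) (x - mean(x)) / sx else x - mean(x)
  }

  jm <- c(
    "model {",
    "  for (i in 1:N) {",
    if (is.null(covariate))
      "    mu[i] <- beta[cond[i]] + u[cp[i]] + w[ct[i]]"
    else if (varying_slope)
      "    mu[i] <- beta[cond[i]] + g[cond[i]] * x[i] + u[cp[i]] + su[cp[i]] * x[i] + w[ct[i]] + sw[ct[i]] * x[i]"
    else
      "    mu[i] <- beta[cond[i]] + g[cond[i]] * x[i] + u[cp[i]] + w[ct[i]]",
    "    y[i] ~ dnorm(mu[i], tau_res)",
    "  }",
    "  for (c in 1:C) { beta[c] ~ dnorm(0, prec_beta) }",
    if (!is.null(covariate)) "  for (c in 1:C) { g[c] ~ dnorm(0, prec_beta) }",
    "  for (j in 1:NCP) { u[j] ~ dnorm(0, tau_u) }",
    "  for (k in 1:NCT) { w[k] ~ dnorm(0, tau_w) }",
    if (!is.null(covariate) && varying_slope) c(
      "  for (j in 1:NCP) { su[j] ~ dnorm(0, tau_su) }",
      "  for (k in 1:NCT) { sw[k] ~ dnorm(0, tau_sw) }",
      "  sigma_su ~ dt(0, prec_s, 3) T(0,)",
      "  tau_su <- pow(sigma_su, -2)",
      "  sigma_sw ~ dt(0, prec_s, 3) T(0,)",
      "  tau_sw <- pow(sigma_sw, -2)"),
    "  sigma_u ~ dt(0, prec_s, 3) T(0,)",
    "  tau_u <- pow(sigma_u, -2)",
    "  sigma_w ~ dt(0, prec_s, 3) T(0,)",
    "  tau_w <- pow(sigma_w, -2)",
    "  sigma ~ dt(0, prec_s, 3) T(0,)",
    "  tau_res <- pow(sigma, -2)",
    "}"
  )
  jdata <- list(y = y, N = length(y), cond = as.integer(cond),
                cp = as.integer(cp), ct = as.integer(ct),
                C = nlevels(cond), NCP = nlevels(cp), NCT = nlevels(ct),
                prec_beta = 1 / s_scale^2, prec_s = 1 / s_scale^2)
  if (!is.null(covariate)) jdata$x <- x
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 1009L + ch) %% .Machine$integer.max))
  monitors <- c("beta", "u", "w", "sigma_u", "sigma_w", "sigma")
  if (!is.null(covariate)) monitors <- c(monitors, "g")
  if (!is.null(covariate) && varying_slope)
    monitors <- c(monitors, "su", "sw", "sigma_su", "sigma_sw")

  run <- function() {
    model <- rjags::jags.model(textConnection(paste(jm, collapse = "\n")),
                               data = jdata, inits = inits, n.chains = chains,
                               n.adapt = min(1000L, warmup), quiet = TRUE)
    burn_left <- warmup - min(1000L, warmup)
    if (burn_left > 0) stats::update(model, burn_left, progress.bar = "none")
    rjags::coda.samples(model, monitors, n.iter = iter - warmup,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = nrow(samp[[1L]]))
  diag <- data.frame(
    parameter = colnames(draws),
    rhat = split_rhat(samp),
    ess = as.numeric(coda::effectiveSize(samp))[seq_len(ncol(draws))]
  )
  rownames(diag) <- NULL
  fit <- structure(list(
    draws = draws, chain = chain_id, diagnostics = diag,
    converged = all(is.finite(diag$rhat)) && max(diag$rhat, na.rm = TRUE) <= 1.01,
    y = y, cond = cond, trial = trial, participant = part, cp = cp, ct = ct,
    ct_map = ct_map, x = x, covariate = covariate,
    varying_slope = !is.null(covariate) && varying_slope,
    response = response, sd_y = sd_y, prior_scale = prior_scale,
    settings = list(chains = chains, warmup = warmup, iter = iter, seed = seed),
    model_string = paste(jm, collapse = "\n")
  ), class = "hbm_fit")
  if (!fit$converged)
    warning("possible non-convergence: max split R-hat = ",
            format(max(diag$rhat, na.rm = TRUE), digits = 4))
  fit
}

# Split R-hat: each chain is halved, then the standard potential scale
# reduction factor is computed over the 2*chains half-chains.
split_rhat <- function(samp) {
  mats <- lapply(samp, as.matrix)
  n <- nrow(mats[[1L]])
  h <- n %/% 2L
  halves <- unlist(lapply(mats, function(m)
    list(m[seq_len(h), , drop = FALSE], m[(n - h + 1L):n, , drop = FALSE])),
    recursive = FALSE)
  vapply(seq_len(ncol(mats[[1L]])), function(p) {
    xs <- vapply(halves, function(m) mean(m[, p]), numeric(1))
    ws <- vapply(halves, function(m) stats::var(m[, p]), numeric(1))
    W <- mean(ws)
    B <- h * stats::var(xs)
    if (W <= 0) return(NA_real_)
    sqrt(((h - 1) / h * W + B / h) / W)
  }, numeric(1))
}

mu_draws <- function(fit, draws = fit$draws, conditional = TRUE) {
  cidx <- as.integer(fit$cond)
  mu <- draws[, paste0("beta[", cidx, "]"), drop = FALSE]
  if (!is.null(fit$covariate))
    mu <- mu + draws[, paste0("g[", cidx, "]"), drop = FALSE] *
      matrix(fit$x, nrow(draws), length(fit$x), byrow = TRUE)
  if (conditional) {
    mu <- mu + draws[, paste0("u[", as.integer(fit$cp), "]"), drop = FALSE] +
      draws[, paste0("w[", as.integer(fit$ct), "]"), drop = FALSE]
    if (fit$varying_slope)
      mu <- mu + (draws[, paste0("su[", as.integer(fit$cp), "]"), drop = FALSE] +
                    draws[, paste0("sw[", as.integer(fit$ct), "]"), drop = FALSE]) *
        matrix(fit$x, nrow(draws), length(fit$x), byrow = TRUE)
  }
  unname(mu)
}

thin_draws <- function(fit, max_draws) {
  s <- nrow(fit$draws)
  if (s <= max_draws) return(seq_len(s))
  round(seq(1L, s, length.out = max_draws))
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf("<hbm_fit> %s ~ 0 + condition%s + (1%s | condition:participant) + (1%s | condition:trial)\n",
              x$response,
              if (is.null(x$covariate)) "" else paste0(" * ", x$covariate),
              if (x$varying_slope) paste0(" + ", x$covariate) else "",
              if (x$varying_slope) paste0(" + ", x$covariate) else ""))
  cat(sprintf("  %d obs, %d chains x %d draws; max split R-hat %.3f%s\n",
              length(x$y), x$settings$chains, nrow(x$draws) / x$settings$chains,
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(coef(x))
  invisible(x)
}

#' @export
coef.hbm_fit <- function(object, ...) {
  b <- object$draws[, grep("^beta\\[", colnames(object$draws)), drop = FALSE]
  stats::setNames(apply(b, 2L, stats::median),
                  paste0("condition", levels(object$cond)))
}

#' @export
summary.hbm_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  qs <- t(apply(object$draws, 2L, stats::quantile, probs = c(a, 0.5, 1 - a)))
  out <- data.frame(parameter = colnames(object$draws),
                    estimate = qs[, 2L], ci_lower = qs[, 1L], ci_upper = qs[, 3L],
                    rhat = object$diagnostics$rhat, ess = object$diagnostics$ess)
  rownames(out) <- NULL
  structure(list(table = out, converged = object$converged,
                 response = object$response), class = "summary.hbm_fit")
}

#' @export
print.summary.hbm_fit <- function(x, ...) {
  cat("Posterior summary for response", x$response,
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  main <- x$table[!grepl("^(u|w|su|sw)\\[", x$table$parameter), ]
  print(main, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.hbm_fit <- function(object, ...) {
  idx <- thin_draws(object, 4000L)
  colMeans(mu_draws(object, object$draws[idx, , drop = FALSE]))
}

#' @export
residuals.hbm_fit <- function(object, ...) object$y - stats::fitted(object)

#' @export
simulate.hbm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(nrow(object$draws), nsim, replace = nsim > nrow(object$draws))
  mu <- mu_draws(object, object$draws[idx, , drop = FALSE])
  sig <- object$draws[idx, "sigma"]
  out <- mu + matrix(stats::rnorm(length(mu)), nrow(mu)) * sig
  as.data.frame(t(out))
}

#' @export
plot.hbm_fit <- function(x, pars = NULL, ...) {
  pars <- pars %||% grep("^(beta\\[|sigma)", colnames(x$draws), value = TRUE)
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  per_chain <- nrow(x$draws) / x$settings$chains
  for (p in pars) {
    graphics::plot(NA, xlim = c(1, per_chain), ylim = range(x$draws[, p]),
                   ylab = p, xlab = "")
    for (ch in seq_len(x$settings$chains))
      graphics::lines(x$draws[x$chain == ch, p], col = ch)
  }
  invisible(x)
}

#' Posterior R-squared (conditional and marginal)
#'
#' Variance-components R-squared, per posterior draw: the marginal version is
#' the fixed-effect variance (condition cell means, covariate terms, realized
#' over the design) divided by the total of fixed, group and residual
#' variance; the conditional version adds the group-level variance to the
#' numerator. Conditional >= marginal holds in every draw. Posterior medians
#' are reported.
#'
#' @param fit an `hbm_fit`.
#' @param max_draws cap on draws used (evenly thinned).
#' @return list with `conditional`, `marginal` (medians) and per-draw vectors.
#' @export
bayes_r2 <- function(fit, max_draws = 4000L) {
  idx <- thin_draws(fit, max_draws)
  d <- fit$draws[idx, , drop = FALSE]
  sig2 <- d[, "sigma"]^2
  # variance-components form: fixed variance realized over the design,
  # group variance from the (independent) group SDs; covariate standardized
  # so slope groups contribute their SD^2 directly
  v_fix <- apply(mu_draws(fit, d, conditional = FALSE), 1L, stats::var)
  v_grp <- d[, "sigma_u"]^2 + d[, "sigma_w"]^2
  if (fit$varying_slope) v_grp <- v_grp + d[, "sigma_su"]^2 + d[, "sigma_sw"]^2
  denom <- v_fix + v_grp + sig2
  cond <- (v_fix + v_grp) / denom
  marg <- v_fix / denom
  list(conditional = stats::median(cond), marginal = stats::median(marg),
       draws = list(conditional = cond, marginal = marg))
}

#' Posterior predictive check
#'
#' Draws replicated datasets from the posterior predictive distribution and
#' compares summary statistics (mean, SD, median, 10%/90% quantiles, min,
#' max) of the observed data against the replicated distribution, plus a
#' density-overlay table on a common grid.
#'
#' @param fit an `hbm_fit`.
#' @param n_rep number of replicated datasets (default 200).
#' @param seed seed for the replicated noise.
#' @return an object of class `ppc_summary`: `stats` (one row per statistic:
#'   observed value, replicated 5%/50%/95% quantiles and tail probability)
#'   and `density` (grid, observed density, replicated density band).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200L, seed = 1L) {
  idx <- thin_draws(fit, n_rep)
  d <- fit$draws[idx, , drop = FALSE]
  mu <- mu_draws(fit, d)
  yrep <- with_seed(seed, mu + matrix(stats::rnorm(length(mu)), nrow(mu)) * d[, "sigma"])
  stat_fns <- list(mean = mean, sd = stats::sd, median = stats::median,
                   q10 = function(v) stats::quantile(v, 0.10),
                   q90 = function(v) stats::quantile(v, 0.90),
                   min = min, max = max)
  stats_tab <- do.call(rbind, lapply(names(stat_fns), function(s) {
    obs <- stat_fns[[s]](fit$y)
    rep_s <- apply(yrep, 1L, stat_fns[[s]])
    data.frame(statistic = s, observed = obs,
               rep_q05 = stats::quantile(rep_s, 0.05),
               rep_q50 = stats::quantile(rep_s, 0.50),
               rep_q95 = stats::quantile(rep_s, 0.95),
               p_rep_ge_obs = mean(rep_s >= obs))
  }))
  rownames(stats_tab) <- NULL
  rng <- range(c(fit$y, yrep))
  grid <- seq(rng[1L], rng[2L], length.out = 64L)
  bw <- stats::bw.nrd0(fit$y)
  dens <- function(v) stats::density(v, bw = bw, from = rng[1L], to = rng[2L], n = 64L)$y
  obs_d <- dens(fit$y)
  rep_d <- apply(yrep, 1L, dens)
  density_tab <- data.frame(grid = grid, observed = obs_d,
                            rep_q05 = apply(rep_d, 1L, stats::quantile, 0.05),
                            rep_q50 = apply(rep_d, 1L, stats::quantile, 0.50),
                            rep_q95 = apply(rep_d, 1L, stats::quantile, 0.95))
  structure(list(stats = stats_tab, density = density_tab), class = "ppc_summary")
}

#' @export
print.ppc_summary <- function(x, ...) {
  cat("Posterior predictive check (observed vs replicated):\n")
  print(x$stats, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Directed posterior contrasts
#'
#' Computes draw-wise contrasts of the condition/trial cell posteriors using
#' the label grammar `cXY` (condition X minus condition Y), `cXtAB` (within
#' condition X, trial A minus trial B, i.e. the difference of the
#' condition:trial intercepts) and `cXYtA` (condition X minus condition Y at
#' trial A). Indices refer to factor-level order. For each label the
#' posterior median, 95% equal-tailed interval and probability of direction
#' `post_prob = P(contrast > 0)` are reported.
#'
#' @param fit an `hbm_fit`.
#' @param labels character vector of contrast labels; by default the full
#'   grammar over all condition pairs and trial pairs.
#' @return data frame of class `contrast_table`: `label`, `estimate`,
#'   `ci_lower`, `ci_upper`, `post_prob`.
#' @export
contrasts_hbm <- function(fit, labels = NULL) {
  stopifnot(inherits(fit, "hbm_fit"))
  C <- nlevels(fit$cond); T_ <- nlevels(fit$trial)
  if (is.null(labels)) {
    labels <- character(0)
    for (i in seq_len(C)) for (j in seq_len(C)) if (i < j)
      labels <- c(labels, paste0("c", i, j))
    for (i in seq_len(C)) for (a in seq_len(T_)) for (b in seq_len(T_)) if (a < b)
      labels <- c(labels, paste0("c", i, "t", a, b))
    for (i in seq_len(C)) for (j in seq_len(C)) if (i < j)
      for (a in seq_len(T_)) labels <- c(labels, paste0("c", i, j, "t", a))
  }
  rows <- lapply(labels, function(lab) {
    dr <- contrast_draws(fit, lab)
    q <- stats::quantile(dr, c(0.025, 0.5, 0.975))
    data.frame(label = lab, estimate = q[2L], ci_lower = q[1L], ci_upper = q[3L],
               post_prob = mean(dr > 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

# Draw-wise contrast vector for one label.
contrast_draws <- function(fit, label) {
  m <- regmatches(label, regexec("^c([0-9])([0-9])?(?:t([0-9])([0-9])?)?$", label))[[1L]]
  if (!length(m)) stop("unknown contrast label: ", label)
  ci <- as.integer(m[2L]); cj <- if (nzchar(m[3L])) as.integer(m[3L]) else NA
  ta <- if (nzchar(m[4L])) as.integer(m[4L]) else NA
  tb <- if (nzchar(m[5L])) as.integer(m[5L]) else NA
  C <- nlevels(fit$cond); T_ <- nlevels(fit$trial)
  chk <- function(v, n, what) if (!is.na(v) && (v < 1 || v > n))
    stop("contrast label ", label, ": ", what, " index ", v, " out of range")
  chk(ci, C, "condition"); chk(cj, C, "condition"); chk(ta, T_, "trial"); chk(tb, T_, "trial")
  w_col <- function(c_idx, t_idx) {
    lev <- fit$ct_map$level[fit$ct_map$cond_idx == c_idx & fit$ct_map$trial_idx == t_idx]
    fit$draws[, paste0("w[", lev, "]")]
  }
  beta <- function(c_idx) fit$draws[, paste0("beta[", c_idx, "]")]
  if (!is.na(cj) && is.na(ta)) {                  # cXY
    beta(ci) - beta(cj)
  } else if (is.na(cj) && !is.na(ta) && !is.na(tb)) {  # cXtAB
    w_col(ci, ta) - w_col(ci, tb)
  } else if (!is.na(cj) && !is.na(ta) && is.na(tb)) {  # cXYtA
    (beta(ci) + w_col(ci, ta)) - (beta(cj) + w_col(cj, ta))
  } else stop("unknown contrast label: ", label)
}

# ---- marginal likelihood & model comparison ---------------------------------

# Fixed-effect design matrix (condition dummies, plus condition:covariate
# interactions when present) and group-indicator matrices; all columns carry
# the same Normal(0, prior_scale * sd_y) prior, so they can be integrated out.
model_matrices <- function(fit) {
  Xf <- stats::model.matrix(~ 0 + fit$cond)
  if (!is.null(fit$covariate)) Xf <- cbind(Xf, Xf * fit$x)
  Zu <- stats::model.matrix(~ 0 + fit$cp)
  Zw <- stats::model.matrix(~ 0 + fit$ct)
  out <- list(Xf = unname(Xf), groups = list(u = unname(Zu), w = unname(Zw)))
  if (fit$varying_slope) {
    out$groups$su <- unname(Zu * fit$x)
    out$groups$sw <- unname(Zw * fit$x)
  }
  out
}

# log p(y | sigmas): all linear effects integrated out analytically.
log_marg_given_sigma <- function(y, mm, s_beta, sig, group_sds) {
  n <- length(y)
  V <- diag(sig^2, n) + s_beta^2 * tcrossprod(mm$Xf)
  for (g in names(mm$groups))
    V <- V + group_sds[[g]]^2 * tcrossprod(mm$groups[[g]])
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

log_half_t <- function(x, scale, df = 3) {
  ifelse(x <= 0, -Inf, log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale))
}

#' Log marginal likelihood of a fitted model
#'
#' Estimates `log p(y)` by importance sampling over the variance parameters
#' only: all Gaussian linear effects (cell means, covariate slopes, group
#' intercepts/slopes) are integrated out in closed form, leaving a 3-5
#' dimensional integral over the log-SD parameters that is importance-sampled
#' with a moment-matched multivariate-t proposal built from the posterior
#' draws. Deterministic given `seed`.
#'
#' @param fit an `hbm_fit`.
#' @param n_is number of importance samples (default 4000).
#' @param seed seed for the proposal draws.
#' @return list with `logml`, `se` (delta-method standard error) and
#'   `ess` (effective sample size of the importance weights; a small value
#'   signals an unstable estimate).
#' @export
marginal_likelihood <- function(fit, n_is = 4000L, seed = 1L) {
  sd_pars <- grep("^sigma", colnames(fit$draws), value = TRUE)
  L <- log(fit$draws[, sd_pars, drop = FALSE])
  mu_q <- colMeans(L)
  S_q <- stats::cov(L) * 1.5^2 + diag(1e-8, length(sd_pars))
  ch_q <- chol(S_q)
  k <- length(sd_pars)
  df <- 4
  prop <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_is * k), n_is, k) %*% ch_q
    r <- sqrt(df / stats::rchisq(n_is, df))
    sweep(z * r, 2L, mu_q, "+")
  })
  # multivariate-t log density of the proposal
  qz <- forwardsolve(t(ch_q), t(sweep(prop, 2L, mu_q)))
  quad <- colSums(qz^2)
  logq <- lgamma((df + k) / 2) - lgamma(df / 2) - k / 2 * log(df * pi) -
    sum(log(diag(ch_q))) - (df + k) / 2 * log1p(quad / df)

  mm <- model_matrices(fit)
  s_scale <- fit$prior_scale * fit$sd_y
  lw <- vapply(seq_len(n_is), function(i) {
    sds <- exp(prop[i, ])
    names(sds) <- sd_pars
    gs <- list(u = sds[["sigma_u"]], w = sds[["sigma_w"]])
    if (fit$varying_slope) gs <- c(gs, list(su = sds[["sigma_su"]], sw = sds[["sigma_sw"]]))
    ll <- log_marg_given_sigma(fit$y, mm, s_scale, sds[["sigma"]], gs)
    lp <- sum(log_half_t(sds, s_scale)) + sum(prop[i, ])  # prior + log-Jacobian
    ll + lp - logq[i]
  }, numeric(1))
  logml <- log_sum_exp(lw) - log(n_is)
  wn <- exp(lw - max(lw)); wn <- wn / sum(wn)
  ess <- 1 / sum(wn^2)
  se <- stats::sd(exp(lw - logml)) / sqrt(n_is)  # delta-method SE of logml
  list(logml = logml, se = se, ess = ess)
}

# Pointwise leave-one-out elpd via truncated importance sampling.
loo_elpd <- function(fit, max_draws = 4000L) {
  idx <- thin_draws(fit, max_draws)
  d <- fit$draws[idx, , drop = FALSE]
  mu <- mu_draws(fit, d)
  sig <- d[, "sigma"]
  S <- nrow(mu)
  ll <- stats::dnorm(matrix(fit$y, S, length(fit$y), byrow = TRUE), mu, sig, log = TRUE)
  pointwise <- vapply(seq_len(ncol(ll)), function(i) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- pmin(w, mean(w) * sqrt(S))   # truncation stabilizes the weights
    log(sum(w * exp(ll[, i])) / sum(w))
  }, numeric(1))
  list(elpd = sum(pointwise), pointwise = pointwise)
}

#' Compare two fitted models
#'
#' Bayes factor of the first model over the second via marginal likelihoods
#' (see [marginal_likelihood()]), with a supplementary leave-one-out
#' cross-validation check (pointwise elpd difference and its standard error).
#' An unstable marginal-likelihood estimate (small importance-weight
#' effective sample size) triggers a warning carried in the result.
#'
#' @param fit_simple,fit_covariate two `hbm_fit` objects on the same data.
#' @param n_is importance samples for each marginal likelihood.
#' @param seed seed for the estimators.
#' @return object of class `model_comparison`: `bf` (simple over covariate),
#'   `log_bf`, per-model log marginal likelihoods and the LOO summary.
#' @export
compare_models <- function(fit_simple, fit_covariate, n_is = 4000L, seed = 1L) {
  if (!identical(fit_simple$y, fit_covariate$y))
    stop("models were not fitted to the same data")
  ml1 <- marginal_likelihood(fit_simple, n_is, seed)
  ml2 <- marginal_likelihood(fit_covariate, n_is, seed + 1L)
  warn <- character(0)
  if (ml1$ess < 100 || ml2$ess < 100)
    warn <- "unstable marginal-likelihood estimate (importance ESS < 100)"
  loo1 <- loo_elpd(fit_simple)
  loo2 <- loo_elpd(fit_covariate)
  diff_pw <- loo1$pointwise - loo2$pointwise
  structure(list(
    log_bf = ml1$logml - ml2$logml,
    bf = exp(ml1$logml - ml2$logml),
    logml_simple = ml1, logml_covariate = ml2,
    elpd_diff = sum(diff_pw),
    elpd_diff_se = stats::sd(diff_pw) * sqrt(length(diff_pw)),
    warnings = warn
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Bayes factor (simple / covariate): %.3g  (log BF %.3f)\n", x$bf, x$log_bf))
  cat(sprintf("LOO elpd difference (simple - covariate): %.2f (SE %.2f)\n",
              x$elpd_diff, x$elpd_diff_se))
  if (length(x$warnings)) cat("Warning:", x$warnings, "\n")
  invisible(x)
}
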