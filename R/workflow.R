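#' Default analysis configuration
#'
#' All thresholds default to the analysis conventions built into the package:
#' 150 mm length gate, 15% median-loudness gate, 80 ms / 10 mm segmentation
#' hysteresis, 100-point stroke resampling, SPARC at fc = 10 Hz with
#' amplitude threshold 0.05 and pad level 4, 12 Hz derivative smoothing, and
#' a 4-chain sampler with 5000 warmup of 40000 total iterations.
#'
#' @param ... named overrides of any config entry (nested lists merged one
#'   level deep for `sampler`).
#' @return a list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_length = 150, loudness_fraction = 0.15,
    min_duration = 0.08, min_excursion = 10,
    n_resample = 100, cutoff = 12,
    sparc_fc = 10, sparc_amp_threshold = 0.05, sparc_pad_level = 4,
    sampler = list(chains = 4, warmup = 5000, iter = 40000, prior_scale = 2.5),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "sampler") for (s in names(dots$sampler)) cfg$sampler[[s]] <- dots$sampler[[s]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON (lossless round trip)
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(v) if (is.list(v)) lapply(v, as.numeric) else as.numeric(v))
  cfg$seed <- as.integer(cfg$seed)
  do.call(default_config, cfg)
}

#' Stroke-level metrics for a whole cohort
#'
#' Runs kinematics, segmentation, gating, pairing and per-stroke metrics for
#' every cell of a cohort bundle, caching the avatar-side computation per
#' piece. Cells are realized one at a time so memory stays flat even for
#' large cohorts.
#'
#' @param cohort a `cohort_bundle` from [generate_cohort()].
#' @param config a `run_config` (default [default_config()]).
#' @return data frame with one row per surviving stroke per cell:
#'   `participant`, `condition`, `trial`, `piece`, `violin_section`,
#'   `stroke_index`, `pd`, `si_avatar`, `si_participant`, `dsi`, `length`,
#'   `mean_loudness`.
#' @export
cohort_metrics <- function(cohort, config = default_config()) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  avat <- lapply(cohort$avatars, function(av) {
    akin <- derivatives(bow_contact_kinematics(av$trace), config$cutoff)
    env <- loudness_envelope(av$audio, av$trace)
    st <- segment_strokes(akin, config$min_duration, config$min_excursion)
    st <- gate_loudness(gate_length(st, config$min_length), env, config$loudness_fraction)
    list(akin = akin, strokes = st)
  })
  out <- vector("list", nrow(cohort$cells))
  for (i in seq_len(nrow(cohort$cells))) {
    cell <- cohort$cells[i, ]
    follower <- if (!is.null(cohort$followers)) cohort$followers[[i]] else realize_cell(cohort, i)
    a <- avat[[cell$piece]]
    pkin <- derivatives(bow_contact_kinematics(follower), config$cutoff)
    pairs <- pair_strokes(a$akin, pkin, a$strokes, config$n_resample)
    if (!length(pairs)) next
    m <- do.call(rbind, lapply(pairs, stroke_metrics,
                               fc = config$sparc_fc,
                               amp_threshold = config$sparc_amp_threshold,
                               pad_level = config$sparc_pad_level))
    m$stroke_index <- seq_len(nrow(m))
    out[[i]] <- cbind(cell[rep(1L, nrow(m)),
                           c("participant", "condition", "trial", "piece", "violin_section")],
                      m[, c("stroke_index", "pd", "si_avatar", "si_participant",
                            "dsi", "length", "mean_loudness")])
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    stop("empty cell(s): no strokes survived segmentation and gating in any cell")
  rownames(res) <- NULL
  res
}

#' Build calibrated metric datasets from stroke-level metrics
#'
#' Standardizes each metric over all strokes, takes per-cell medians and
#' applies the (piece x violin section) group calibration.
#'
#' @param strokes output of [cohort_metrics()].
#' @param design the [cohort_design()].
#' @param metrics which metrics to calibrate (default PD and dSI).
#' @return named list of calibrated datasets (one per metric).
#' @export
calibrate_metrics <- function(strokes, design, metrics = c(PD = "pd", dSI = "dsi")) {
  out <- lapply(metrics, function(col) {
    df <- strokes[, c("participant", "condition", "trial")]
    df$value <- zscale(strokes[[col]])
    group_calibrate(cell_medians(df, design))
  })
  names(out) <- names(metrics)
  out
}

#' Full contrast-analysis workflow
#'
#' For every response (the calibrated metrics, then each questionnaire
#' scale): fit the simple varying-intercept model and the covariate model
#' (perceived difficulty for the metrics; the calibrated PD cell value for
#' the questionnaire scales), compare them by Bayes factor with a LOO check,
#' run diagnostics (posterior predictive check, posterior R-squared) on the
#' preferred model, and compute the full contrast table.
#'
#' @param metric_datasets named list of calibrated datasets from
#'   [calibrate_metrics()].
#' @param q_scores a `questionnaire_scores` object (or `NULL` to skip the
#'   presence workflow).
#' @param config a `run_config`; `config$sampler` controls the MCMC size.
#' @return object of class `workflow_report`: per response, the two fits,
#'   the comparison, diagnostics of the preferred model and its contrast
#'   table.
#' @export
run_workflow <- function(metric_datasets, q_scores = NULL, config = default_config()) {
  sp <- config$sampler
  seed <- config$seed
  analyze <- function(data, covariate, seed_offset) {
    fit1 <- fit_hbm(data, chains = sp$chains, warmup = sp$warmup, iter = sp$iter,
                    prior_scale = sp$prior_scale, seed = seed + seed_offset)
    fit2 <- if (!is.null(covariate) && covariate %in% names(data) &&
                stats::sd(data[[covariate]]) > 0)
      fit_hbm(data, covariate = covariate, chains = sp$chains, warmup = sp$warmup,
              iter = sp$iter, prior_scale = sp$prior_scale, seed = seed + seed_offset + 1L)
    else NULL
    cmp <- if (!is.null(fit2)) compare_models(fit1, fit2, seed = seed + seed_offset) else NULL
    best <- if (!is.null(cmp) && cmp$bf < 1) fit2 else fit1
    list(fit_simple = fit1, fit_covariate = fit2, comparison = cmp,
         best = if (!is.null(cmp) && cmp$bf < 1) "covariate" else "simple",
         r2 = bayes_r2(best),
         ppc = posterior_predictive_check(best, seed = seed + seed_offset),
         contrasts = contrasts_hbm(best))
  }

  report <- list()
  diffic <- NULL
  if (!is.null(q_scores)) {
    stopifnot(inherits(q_scores, "questionnaire_scores"))
    diffic <- q_scores$scores[, c("participant", "condition", "trial", "difficulty")]
  }
  off <- 0L
  for (resp in names(metric_datasets)) {
    data <- metric_datasets[[resp]]
    if (!is.null(diffic)) data <- merge(data, diffic,
                                        by = c("participant", "condition", "trial"),
                                        sort = FALSE)
    report[[resp]] <- analyze(data, if (!is.null(diffic)) "difficulty" else NULL, off)
    off <- off + 10L
  }
  if (!is.null(q_scores)) {
    pd_cells <- if ("PD" %in% names(metric_datasets))
      stats::setNames(metric_datasets$PD[, c("participant", "condition", "trial", "value")],
                      c("participant", "condition", "trial", "PD"))
    else NULL
    for (resp in c("WPQ", "MPQS", "MPQP", "difficulty")) {
      data <- q_scores$scores[, c("participant", "condition", "trial", resp)]
      names(data)[4L] <- "value"
      if (!is.null(pd_cells)) data <- merge(data, pd_cells,
                                            by = c("participant", "condition", "trial"),
                                            sort = FALSE)
      report[[resp]] <- analyze(data, if (!is.null(pd_cells)) "PD" else NULL, off)
      off <- off + 10L
    }
  }
  structure(list(responses = report, alpha = if (!is.null(q_scores)) q_scores$alpha,
                 config = config), class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  for (resp in names(x$responses)) {
    r <- x$responses[[resp]]
    c12 <- r$contrasts[r$contrasts$label == "c12", ]
    cat(sprintf("%-10s best=%s  BF=%.3g  R2(cond)=%.2f R2(marg)=%.2f  c12: %.3f [%.3f, %.3f] pd=%.2f\n",
                resp, r$best, if (is.null(r$comparison)) NA else r$comparison$bf,
                r$r2$conditional, r$r2$marginal,
                c12$estimate, c12$ci_lower, c12$ci_upper, c12$post_prob))
  }
  invisible(x)
}

contrast_csv_table <- function(ct) {
  stats::setNames(ct[, c("label", "estimate", "ci_lower", "ci_upper", "post_prob")],
                  c("Label", "Estimate", "CI.Lower", "CI.Upper", "Post.Prob"))
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Simulate -> kinematics -> strokes -> metrics -> calibration ->
#' questionnaires -> hierarchical models, comparisons and contrasts, writing
#' every artifact (stroke metrics CSV, calibrated dataset CSVs, contrast
#' table CSVs, diagnostics JSON) plus a manifest with content hashes, the
#' seed, stage timings and cell counts.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing).
#' @param design a [cohort_design()]; default the 11 x 2 x 4 design.
#' @param scores optional per-piece [score_spec()] list.
#' @return the `workflow_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("bowmimic_"),
                         design = cohort_design(seed = config$seed), scores = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, prev) {
    now <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(now - prev, 2)
    now
  }
  cohort <- generate_cohort(design, scores = scores, realize = FALSE)
  t1 <- tick("simulate", t0)
  strokes <- cohort_metrics(cohort, config)
  t2 <- tick("metrics", t1)
  datasets <- calibrate_metrics(strokes, design)
  q_tab <- generate_questionnaires(design)
  q_scores <- score_questionnaires(q_tab)
  t3 <- tick("calibrate", t2)
  report <- run_workflow(datasets, q_scores, config)
  t4 <- tick("stats", t3)

  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(strokes, "stroke_metrics.csv")
  for (nm in names(datasets)) wr(datasets[[nm]], paste0("calibrated_", nm, ".csv"))
  wr(q_scores$scores, "questionnaire_scores.csv")
  for (nm in names(report$responses))
    wr(contrast_csv_table(report$responses[[nm]]$contrasts),
       paste0("contrasts_", nm, ".csv"))
  diagnostics <- lapply(report$responses, function(r) list(
    best = r$best,
    bayes_factor = if (!is.null(r$comparison)) r$comparison$bf,
    elpd_diff = if (!is.null(r$comparison)) r$comparison$elpd_diff,
    r2_conditional = r$r2$conditional, r2_marginal = r$r2$marginal,
    max_rhat = max((if (r$best == "simple") r$fit_simple else r$fit_covariate)$diagnostics$rhat,
                   na.rm = TRUE)
  ))
  diag_path <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(diagnostics, diag_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, diag_path)
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    r_version = as.character(getRversion()),
    n_cells = nrow(cohort$cells),
    n_strokes = nrow(strokes),
    timings_s = timings,
    files = lapply(files, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
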