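#' Standardize a metric series
#'
#' Subtracts the mean and divides by the standard deviation, pooled over all
#' provided values (i.e. over all strokes of all cells for that metric).
#'
#' @param values numeric vector (length >= 2, nonzero SD).
#' @return standardized vector with mean 0 and SD 1.
#' @export
zscale <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values to scale")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation; cannot scale")
  (values - mean(values)) / s
}

#' Per-cell medians of a stroke-level metric
#'
#' Aggregates stroke-level values to one median per
#' participant x condition x trial cell. Every cell of the design must have
#' at least one surviving stroke.
#'
#' @param strokes data frame with columns `participant`, `condition`, `trial`
#'   and `value` (one row per stroke), plus optional `piece` and
#'   `violin_section` carried through.
#' @param design a [cohort_design()] giving the full cell grid.
#' @return data frame with one row per cell: `participant`, `condition`,
#'   `trial`, `piece`, `violin_section`, `value`.
#' @export
cell_medians <- function(strokes, design) {
  stopifnot(is.data.frame(strokes), inherits(design, "cohort_design"))
  grid <- expand.grid(trial = seq_len(design$n_trials),
                      condition = design$conditions,
                      participant = seq_len(design$n_participants),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- stats::aggregate(value ~ participant + condition + trial, data = strokes,
                          FUN = stats::median)
  merged <- merge(grid, agg, by = c("participant", "condition", "trial"),
                  all.x = TRUE, sort = FALSE)
  if (anyNA(merged$value)) {
    bad <- merged[is.na(merged$value), c("participant", "condition", "trial")]
    stop("empty cell(s): no surviving strokes for ",
         paste(sprintf("participant %s / %s / trial %s",
                       bad$participant, bad$condition, bad$trial), collapse = "; "))
  }
  merged <- merge(merged, design$assignment[, c("participant", "piece", "violin_section")],
                  by = "participant", sort = FALSE)
  merged <- merged[order(merged$participant, merged$condition, merged$trial),
                   c("participant", "condition", "trial", "piece", "violin_section", "value")]
  rownames(merged) <- NULL
  merged
}

#' Group calibration of the cell-median dataset
#'
#' Within every (piece x violin section) group the group median is subtracted,
#' removing stimulus-difficulty offsets; afterwards every group's median is
#' exactly zero.
#'
#' @param dataset output of [cell_medians()] (needs `piece` and
#'   `violin_section` columns).
#' @return the dataset with `value` replaced by its calibrated version.
#' @export
group_calibrate <- function(dataset) {
  stopifnot(all(c("piece", "violin_section", "value") %in% names(dataset)))
  key <- interaction(dataset$piece, dataset$violin_section, drop = TRUE)
  med <- tapply(dataset$value, key, stats::median)
  dataset$value <- dataset$value - as.numeric(med[as.character(key)])
  dataset
}

#' Cronbach's alpha of an item matrix
#'
#' `alpha = k/(k-1) * (1 - sum_i var(item_i) / var(total))` with sample
#' variances throughout.
#'
#' @param items respondents x items numeric matrix (>= 2 of each).
#' @return alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  if (nrow(items) < 2L) stop("need at least 2 respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total variance")
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / total_var)
}

#' Score presence questionnaires
#'
#' Computes per-administration scale means for the WPQ (7-point), MPQS and
#' MPQP (5-point) item sets, an MPQ composite (mean over the pooled MPQS and
#' MPQP item pool), and passes perceived difficulty through on its 0-100
#' scale. Cronbach's alpha is computed per scale across administrations.
#' Administrations with missing items are scored as the mean over available
#' items and flagged.
#'
#' @param table data frame as produced by [generate_questionnaires()]:
#'   columns `participant`, `condition`, `trial`, item columns named
#'   `WPQ_*`, `MPQS_*`, `MPQP_*`, and `difficulty`.
#' @return a list of class `questionnaire_scores`: `scores` (one row per
#'   administration with `WPQ`, `MPQS`, `MPQP`, `MPQ`, `difficulty`,
#'   `incomplete`) and `alpha` (named vector per scale).
#' @export
score_questionnaires <- function(table) {
  stopifnot(is.data.frame(table))
  scales <- c("WPQ", "MPQS", "MPQP")
  cols <- lapply(scales, function(sc) grep(paste0("^", sc, "_"), names(table), value = TRUE))
  names(cols) <- scales
  for (sc in scales) if (!length(cols[[sc]])) stop("no item columns found for scale ", sc)
  id_cols <- intersect(c("participant", "condition", "trial"), names(table))
  out <- table[, id_cols, drop = FALSE]
  incomplete <- rep(FALSE, nrow(table))
  for (sc in scales) {
    m <- as.matrix(table[, cols[[sc]], drop = FALSE])
    miss <- rowSums(is.na(m)) > 0
    if (any(miss)) {
      message(sum(miss), " administration(s) with missing ", sc,
              " items scored over available items")
      incomplete <- incomplete | miss
    }
    out[[sc]] <- rowMeans(m, na.rm = TRUE)
  }
  mpq_pool <- as.matrix(table[, c(cols$MPQS, cols$MPQP), drop = FALSE])
  out$MPQ <- rowMeans(mpq_pool, na.rm = TRUE)
  if ("difficulty" %in% names(table)) out$difficulty <- table$difficulty
  out$incomplete <- incomplete
  alpha <- vapply(scales, function(sc) {
    m <- table[, cols[[sc]], drop = FALSE]
    tryCatch(cronbach_alpha(m[stats::complete.cases(m), , drop = FALSE]),
             error = function(e) NA_real_)   # degenerate (constant) scales
  }, numeric(1))
  structure(list(scores = out, alpha = alpha), class = "questionnaire_scores")
}

#' @export
print.questionnaire_scores <- function(x, ...) {
  cat("<questionnaire_scores>", nrow(x$scores), "administrations\n")
  cat("Cronbach's alpha:",
      paste(sprintf("%s %.2f", names(x$alpha), x$alpha), collapse = ", "), "\n")
  invisible(x)
}
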