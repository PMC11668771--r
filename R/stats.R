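#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with midranks for ties:
#' the exact null distribution is used when both groups are small and the
#' data are tie-free, otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with `statistic` (the Mann-Whitney U of group `a`) and `p`
#'   (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Regression of a gaze metric on a clinical severity score
#'
#' Ordinary least squares fit of metric values on severity scores, with the
#' Pearson correlation and its two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param metric_values numeric vector.
#' @param severity_scores numeric vector, same length, not all equal;
#'   pairs with a missing value in either variable are dropped.
#' @return an object of class `regression_result`: list with `slope`,
#'   `intercept`, `r`, `p`, `n`.
#' @export
fit_metric_vs_severity <- function(metric_values, severity_scores) {
  stopifnot(length(metric_values) == length(severity_scores))
  ok <- !is.na(metric_values) & !is.na(severity_scores)
  y <- metric_values[ok]; x <- severity_scores[ok]
  if (length(y) < 3L)
    stop("need at least 3 complete (metric, severity) pairs", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("severity scores are all equal: no regression possible",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  n <- length(y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  regression_result(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r = r, p = p, n = n)
}

#' Construct a regression result
#'
#' Container for a linear metric-versus-severity fit; produced by
#' [fit_metric_vs_severity()], or built directly from published
#' coefficients to map a severity cutoff onto the metric scale.
#'
#' @param slope,intercept fitted line coefficients.
#' @param r Pearson correlation (optional, `NA` when unknown).
#' @param p two-sided p-value (optional).
#' @param n number of points (optional).
#' @return an object of class `regression_result`.
#' @export
regression_result <- function(slope, intercept, r = NA_real_, p = NA_real_,
                              n = NA_integer_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (!is.na(r) && (r < -1 || r > 1)) stop("r must lie in [-1, 1]",
                                           call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r = r, p = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> metric = %.6g * severity + %.6g (r=%.3f, p=%.3g, n=%s)\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' Map a severity cutoff onto the metric scale
#'
#' Evaluates a fitted (or published) regression line at a clinical severity
#' cutoff, yielding the corresponding metric threshold. The decision
#' direction follows the slope: a negative slope means lower metric values
#' go with higher severity, so values below the cutoff classify positive.
#'
#' @param fit a [regression_result()] with non-zero slope.
#' @param severity_cutoff severity score at which to evaluate the line
#'   (default 5, the consensus ADOS-2 CSS cutoff).
#' @return an object of class `cutoff_result` with provenance
#'   `"regression_mapped"`; sensitivity/specificity are `NA` until
#'   evaluated against data.
#' @export
severity_mapped_cutoff <- function(fit, severity_cutoff = 5) {
  stopifnot(inherits(fit, "regression_result"))
  if (fit$slope == 0)
    stop("slope is 0: the metric does not discriminate by severity",
         call. = FALSE)
  cutoff_result(metric = NA_character_,
                cutoff = fit$slope * severity_cutoff + fit$intercept,
                direction = if (fit$slope < 0) "below_positive"
                            else "above_positive",
                sensitivity = NA_real_, specificity = NA_real_,
                provenance = "regression_mapped")
}

#' Construct a diagnostic cutoff result
#'
#' @param metric metric name (may be `NA` before attachment).
#' @param cutoff threshold on the metric scale.
#' @param direction `"below_positive"` (values strictly below the cutoff
#'   classify positive) or `"above_positive"` (strictly above).
#' @param sensitivity,specificity fractions in `[0, 1]`, `NA` if not yet
#'   evaluated.
#' @param provenance `"regression_mapped"` or `"roc_scan"`.
#' @return an object of class `cutoff_result`.
#' @export
cutoff_result <- function(metric, cutoff, direction, sensitivity,
                          specificity, provenance) {
  direction <- match.arg(direction, c("below_positive", "above_positive"))
  provenance <- match.arg(provenance, c("regression_mapped", "roc_scan"))
  for (v in c(sensitivity, specificity))
    if (!is.na(v) && (v < 0 || v > 1))
      stop("sensitivity/specificity must lie in [0, 1]", call. = FALSE)
  structure(list(metric = metric, cutoff = cutoff, direction = direction,
                 sensitivity = sensitivity, specificity = specificity,
                 provenance = provenance),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> %s: cutoff=%.4g (%s, %s) sens=%.3g spec=%.3g\n",
              if (is.na(x$metric)) "?" else x$metric, x$cutoff,
              sub("_positive", " positive", x$direction), x$provenance,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify values against a cutoff
#'
#' Values strictly beyond the cutoff in the positive direction classify
#' positive; values equal to the cutoff classify negative.
#'
#' @param values numeric vector.
#' @param cutoff threshold.
#' @param direction `"below_positive"` or `"above_positive"`.
#' @return logical vector, `TRUE` = predicted positive (ASD).
#' @export
classify_by_cutoff <- function(values, cutoff, direction) {
  direction <- match.arg(direction, c("below_positive", "above_positive"))
  if (direction == "below_positive") values < cutoff else values > cutoff
}

#' Sensitivity and specificity of binary predictions
#'
#' Sensitivity is the true-positive rate over truly positive (ASD)
#' subjects; specificity the true-negative rate over truly negative
#' (non-ASD) subjects.
#'
#' @param predictions logical vector, `TRUE` = predicted positive.
#' @param truth logical vector, `TRUE` = ASD.
#' @return list with `sensitivity` and `specificity`.
#' @export
confusion_rates <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  if (!any(truth) || all(truth))
    stop("both classes must be present in the truth labels", call. = FALSE)
  list(sensitivity = sum(predictions & truth) / sum(truth),
       specificity = sum(!predictions & !truth) / sum(!truth))
}

#' ROC threshold scan with Youden-optimal cutoff
#'
#' Evaluates every useful threshold on a metric: candidate cutoffs are the
#' midpoints between adjacent distinct sorted values plus one sentinel
#' beyond each extreme, so every achievable (sensitivity, specificity)
#' operating point appears exactly once. The best cutoff maximises
#' Youden's J (= sensitivity + specificity - 1); ties break toward higher
#' sensitivity, then lower cutoff.
#'
#' @param values numeric metric values, one per subject.
#' @param truth logical vector, `TRUE` = ASD; both classes must be present.
#' @param direction `"below_positive"` or `"above_positive"`.
#' @param metric metric name recorded in the result.
#' @return list with `curve` (data frame: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`) and `best` (a [cutoff_result()] with
#'   provenance `"roc_scan"`).
#' @export
roc_scan <- function(values, truth, direction = "above_positive",
                     metric = NA_character_) {
  direction <- match.arg(direction, c("below_positive", "above_positive"))
  stopifnot(length(values) == length(truth), !anyNA(values))
  if (!any(truth) || all(truth))
    stop("both classes must be present in the truth labels", call. = FALSE)
  v <- sort(unique(values))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  rows <- lapply(cand, function(cut) {
    cr <- confusion_rates(classify_by_cutoff(values, cut, direction), truth)
    data.frame(cutoff = cut, sensitivity = cr$sensitivity,
               specificity = cr$specificity,
               youden_j = cr$sensitivity + cr$specificity - 1)
  })
  curve <- do.call(rbind, rows)
  ord <- order(-curve$youden_j, -curve$sensitivity, curve$cutoff)
  b <- curve[ord[1], ]
  best <- cutoff_result(metric = metric, cutoff = b$cutoff,
                        direction = direction,
                        sensitivity = b$sensitivity,
                        specificity = b$specificity,
                        provenance = "roc_scan")
  list(curve = curve, best = best)
}

#' Group comparison table for a metrics data frame
#'
#' One row per metric column: group means, standard deviations, group
#' sizes, and the two-sided Wilcoxon rank-sum p-value. Subjects with a
#' missing value for a metric are dropped from that metric's row. No
#' multiple-testing correction is applied; `n_tests` in the attribute
#' records how many tests the table contains.
#'
#' @param metrics data frame from [metrics_table()].
#' @param roster a `subject_roster` (see [read_roster()]).
#' @param metric_cols metric columns to compare; defaults to every numeric
#'   metric column.
#' @return data frame with columns `metric`, `mean_asd`, `sd_asd`, `n_asd`,
#'   `mean_nonasd`, `sd_nonasd`, `n_nonasd`, `p`.
#' @export
compare_groups <- function(metrics, roster, metric_cols = NULL) {
  grp <- roster$group[match(metrics$subject_id, roster$subject_id)]
  if (anyNA(grp))
    stop("metrics contain subject(s) absent from the roster", call. = FALSE)
  if (is.null(metric_cols)) {
    skip <- c("subject_id", "stimulus_id", "offscreen", "invalid",
              "n_samples")
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                 logical(1))], skip)
  }
  rows <- lapply(metric_cols, function(mc) {
    v <- metrics[[mc]]
    ok <- !is.na(v)
    a <- v[ok & grp == "ASD"]; b <- v[ok & grp == "non-ASD"]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    p <- if (length(unique(c(a, b))) < 2L) 1 else rank_sum_test(a, b)$p
    data.frame(metric = mc,
               mean_asd = mean(a), sd_asd = stats::sd(a), n_asd = length(a),
               mean_nonasd = mean(b), sd_nonasd = stats::sd(b),
               n_nonasd = length(b), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}
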