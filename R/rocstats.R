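#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval from beta quantiles: lower bound
#' `qbeta(alpha/2, x, n - x + 1)`, upper `qbeta(1 - alpha/2, x + 1, n - x)`,
#' with the conventions `low = 0` at `x = 0` and `high = 100` at `x = n`.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(low, high)` in percent.
#' @examples
#' round(clopper_pearson(9, 9), 1) # 66.4 100.0
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (successes < 0 || successes > n) stop("successes out of range", call. = FALSE)
  a <- 1 - level
  low <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(low = 100 * low, high = 100 * high)
}

#' Diagnostic accuracy table with exact intervals
#'
#' Builds the five rule-out metrics -- sensitivity, specificity, NPV, PPV and
#' benign call rate (fraction of negative tests) -- with Clopper-Pearson
#' intervals, from either labels + test results or a 2x2 contingency count.
#' True-positive means test-positive and malignant/borderline; the benign
#' call rate is `(tn + fn) / n`, the potential surgery-avoidance yield.
#' Metrics with a zero denominator are reported as `NA`, never `0/0`.
#'
#' @param labels Binary reference labels (see [compute_auc()]).
#' @param test_positive Logical test results.
#' @param stratum Optional stratum label stored in the output.
#' @param cut_off Optional cut-off value stored in the output.
#' @param level Confidence level.
#' @return Tibble, one row per metric: `stratum`, `cut_off`, `tp`, `fp`,
#'   `tn`, `fn`, `metric`, `numerator`, `denominator`, `estimate`
#'   (percent), `ci_low`, `ci_high`.
#' @export
diagnostic_table <- function(labels, test_positive, stratum = "all",
                             cut_off = NA_real_, level = 0.95) {
  y <- as_binary_label(labels)
  stopifnot(length(y) == length(test_positive))
  tp <- sum(y == 1 & test_positive)
  fp <- sum(y == 0 & test_positive)
  tn <- sum(y == 0 & !test_positive)
  fn <- sum(y == 1 & !test_positive)
  diagnostic_table_from_counts(tp, fp, tn, fn,
    stratum = stratum,
    cut_off = cut_off, level = level
  )
}

#' @rdname diagnostic_table
#' @param tp,fp,tn,fn Contingency counts.
#' @export
diagnostic_table_from_counts <- function(tp, fp, tn, fn, stratum = "all",
                                         cut_off = NA_real_, level = 0.95) {
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty table", call. = FALSE)
  metrics <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    npv = c(tn, tn + fn),
    ppv = c(tp, tp + fp),
    benign_call_rate = c(tn + fn, n)
  )
  purrr::map_dfr(names(metrics), function(m) {
    num <- metrics[[m]][1]
    den <- metrics[[m]][2]
    if (den == 0) {
      est <- lo <- hi <- NA_real_
    } else {
      ci <- clopper_pearson(num, den, level)
      est <- 100 * num / den
      lo <- ci[["low"]]
      hi <- ci[["high"]]
    }
    tibble::tibble(
      stratum = stratum, cut_off = cut_off, tp = tp, fp = fp, tn = tn, fn = fn,
      metric = m, numerator = num, denominator = den,
      estimate = est, ci_low = lo, ci_high = hi
    )
  })
}

#' Rule-out cut-off at a sensitivity floor
#'
#' Test-positive means `value >= cut_off` (higher SUV is more suspicious).
#' Among the observed values (optionally rounded to one decimal for
#' published-style presentation) the function returns the *largest* cut-off
#' whose sensitivity is at least `min_sensitivity`; the largest such
#' threshold also maximises specificity among equally sensitive ones.
#'
#' @param values Numeric marker values (e.g. SUVmax).
#' @param labels Binary labels.
#' @param min_sensitivity Sensitivity floor, default 0.95.
#' @param rounded Select among 1-decimal rounded candidates instead of exact
#'   observed values.
#' @return The selected cut-off (numeric scalar).
#' @export
find_cutoff <- function(values, labels, min_sensitivity = 0.95,
                        rounded = FALSE) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  v <- if (rounded) round(values, 1) else values
  cand <- sort(unique(v))
  pos <- v[y == 1]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  ok <- which(sens >= min_sensitivity)
  if (length(ok) == 0) {
    warning("no cut-off attains the requested sensitivity; returning the minimum value")
    return(min(cand))
  }
  cand[max(ok)]
}

#' Empirical ROC curve with AUC and DeLong interval
#'
#' Full empirical ROC over the observed thresholds (positive when
#' `value >= threshold`), trapezoidal AUC (identical to the rank AUC of
#' [compute_auc()]), and a DeLong 95% interval for the AUC (via pROC).
#'
#' @param values Numeric marker values.
#' @param labels Binary labels.
#' @param metric Optional metric name stored in the result.
#' @param stratum Optional stratum label.
#' @param level Confidence level for the AUC interval.
#' @return A `roc_result`: tibble `curve` (threshold, sensitivity,
#'   specificity), `auc`, `auc_ci`, `metric`, `stratum`.
#' @export
roc_with_auc <- function(values, labels, metric = "value", stratum = "all",
                         level = 0.95) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  thr <- c(sort(unique(values)), Inf)
  sens <- vapply(thr, function(t) mean(values[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[y == 0] < t), numeric(1))
  # trapezoid over (FPR, TPR), thresholds descending = FPR increasing
  fpr <- rev(1 - spec)
  tpr <- rev(sens)
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # pROC warns that a degenerate (AUC = 1) curve has a point-mass interval
  ci <- suppressWarnings(suppressMessages(pROC::ci.auc(
    pROC::roc(
      response = y, predictor = values,
      direction = "<", levels = c(0, 1), quiet = TRUE
    ),
    conf.level = level, method = "delong"
  )))
  structure(
    list(
      curve = tibble::tibble(
        threshold = thr,
        sensitivity = sens, specificity = spec
      ),
      auc = auc, auc_ci = c(low = ci[1], high = ci[3]),
      metric = metric, stratum = stratum, level = level
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %s in stratum '%s': AUC %.3f (%.0f%% CI %.3f-%.3f)\n",
    x$metric, x$stratum, x$auc, 100 * x$level, x$auc_ci["low"], x$auc_ci["high"]
  ))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.roc_result <- function(x, ...) x$curve

#' @export
#' @importFrom generics glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, stratum = x$stratum, auc = x$auc,
    ci_low = unname(x$auc_ci["low"]), ci_high = unname(x$auc_ci["high"])
  )
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.roc_result <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("%s (%s): AUC %.3f", object$metric, object$stratum, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Stratified rule-out threshold analysis
#'
#' For each stratum (all nodules, non-Hurthle, Hurthle, FDG-positive
#' non-Hurthle) and each SUV metric, selects the rule-out cut-off at the
#' sensitivity floor and emits the diagnostic table and ROC result.
#'
#' @param cohort Tibble with columns `label`, `hurthle`, `visual_positive`
#'   and the metric columns.
#' @param metrics Metric column names.
#' @param min_sensitivity Sensitivity floor for [find_cutoff()].
#' @param rounded Passed to [find_cutoff()].
#' @return List with `tables` (bound [diagnostic_table()] rows, including a
#'   visual-assessment row set per stratum) and `rocs` (named list of
#'   `roc_result`). Empty strata are skipped with a warning.
#' @export
stratified_analysis <- function(cohort,
                                metrics = c(
                                  "suv_max", "suv_peak",
                                  "suv_max_ratio", "suv_peak_ratio"
                                ),
                                min_sensitivity = 0.95, rounded = FALSE) {
  strata <- list(
    all = rep(TRUE, nrow(cohort)),
    non_hurthle = !cohort$hurthle,
    hurthle = cohort$hurthle,
    fdg_positive_non_hurthle = cohort$visual_positive & !cohort$hurthle
  )
  tables <- list()
  rocs <- list()
  for (s in names(strata)) {
    sub <- cohort[strata[[s]], , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("empty stratum skipped: ", s)
      next
    }
    if (length(unique(sub$label)) < 2) {
      warning("single-class stratum skipped: ", s)
      next
    }
    tables[[length(tables) + 1]] <- diagnostic_table(
      sub$label, sub$visual_positive,
      stratum = paste0(s, "/visual")
    )
    for (m in metrics) {
      co <- find_cutoff(sub[[m]], sub$label, min_sensitivity, rounded)
      tables[[length(tables) + 1]] <- diagnostic_table(
        sub$label, sub[[m]] >= co,
        stratum = paste0(s, "/", m), cut_off = co
      )
      rocs[[paste0(s, "/", m)]] <- roc_with_auc(
        sub[[m]], sub$label,
        metric = m, stratum = s
      )
    }
  }
  list(tables = dplyr::bind_rows(tables), rocs = rocs)
}
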