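#' Rank-based AUC of the ROC curve
#'
#' Probability that a random positive case scores above a random negative
#' case, ties counted one half (the Mann-Whitney U formulation; identical to
#' the trapezoidal area under the empirical ROC curve).
#'
#' @param predicted_scores Numeric scores, higher = more suspicious.
#' @param labels Binary labels (logical, 0/1, or a factor/character whose
#'   second sorted level / `"malignant_or_borderline"` is positive).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(predicted_scores, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  rk <- rank(predicted_scores)
  (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) {
    return(as.integer(labels))
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  lab <- as.character(labels)
  pos <- if ("malignant_or_borderline" %in% lab) {
    "malignant_or_borderline"
  } else {
    sort(unique(lab))[2]
  }
  as.integer(lab == pos)
}

#' Elastic-net logistic classifier
#'
#' Penalised logistic regression with mixing parameter `l1_ratio` (alpha in
#' glmnet's parameterisation): penalty
#' `lambda * (l1_ratio * |b|_1 + (1 - l1_ratio)/2 * |b|_2^2)`, intercept
#' unpenalised, predictors standardised internally. When `penalty_strength`
#' is `NULL` it is chosen by internal cross-validation on the training data.
#'
#' @param scores Cases x predictors numeric matrix (e.g. factor scores).
#' @param labels Binary training labels (see [compute_auc()]).
#' @param l1_ratio Elastic-net mixing parameter in `[0, 1]`, default 0.5.
#' @param penalty_strength Penalty `lambda`; `NULL` selects it by `nfolds`
#'   cross-validation.
#' @param nfolds Folds for the internal lambda search.
#' @return An `elastic_net_fit`: coefficients, intercept, `lambda`,
#'   `l1_ratio`, and a `predict()` method returning linear scores.
#' @export
fit_elastic_net <- function(scores, labels, l1_ratio = 0.5,
                            penalty_strength = NULL, nfolds = 5) {
  x <- as.matrix(scores)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `.pad` = 0) # glmnet needs two columns
  if (is.null(penalty_strength)) {
    # deterministic folds: stratified round-robin by class
    foldid <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- which(y == cl)
      foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    cv <- glmnet::cv.glmnet(x, y,
      family = "binomial", alpha = l1_ratio,
      foldid = foldid, standardize = TRUE
    )
    penalty_strength <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = l1_ratio,
    lambda = penalty_strength, standardize = TRUE,
    thresh = 1e-12
  )
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != ".pad"]
  structure(
    list(
      coefficients = beta, intercept = as.numeric(fit$a0),
      lambda = penalty_strength, l1_ratio = l1_ratio, glmnet_fit = fit
    ),
    class = "elastic_net_fit"
  )
}

#' @export
predict.elastic_net_fit <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- as.numeric(as.matrix(newdata) %*% object$coefficients + object$intercept)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
#' @importFrom generics tidy
tidy.elastic_net_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Corrected resampled t-test confidence interval
#'
#' Confidence interval for the mean of `k` repeated train/test-split
#' estimates using the variance correction
#' `s^2 * (1/k + n_test/n_train)` (Nadeau-Bengio), which accounts for the
#' overlap between training sets. Bounds are clipped to `[0, 1]`.
#'
#' @param aucs Numeric vector of `k >= 2` per-split estimates.
#' @param n_train,n_test Realised split sizes.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(low, high)`.
#' @export
corrected_resampled_ci <- function(aucs, n_train, n_test, level = 0.95) {
  k <- length(aucs)
  if (k < 2) stop("need at least two splits", call. = FALSE)
  m <- mean(aucs)
  s2 <- stats::var(aucs)
  if (s2 == 0) {
    return(c(low = m, high = m))
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  hw <- tq * sqrt(s2 * (1 / k + n_test / n_train))
  c(low = max(0, m - hw), high = min(1, m + hw))
}

default_split_fitter <- function(threshold = 0.9, l1_ratio = 0.5,
                                 penalty_strength = NULL) {
  function(train_x, train_y) {
    model <- reduce_dimension(train_x, threshold = threshold)
    s_train <- project_scores(model, train_x)
    fit <- fit_elastic_net(s_train, train_y,
      l1_ratio = l1_ratio,
      penalty_strength = penalty_strength
    )
    function(new_x) predict(fit, project_scores(model, new_x))
  }
}

#' Repeated stratified random-split evaluation
#'
#' Evaluates a modelling pipeline in `k` repeated random splits (80%
#' training / 20% test by default, stratified by outcome). The entire
#' pipeline -- standardisation, redundancy filtering, factor analysis and
#' the elastic net, including its penalty search -- is refit on each
#' training split; the test split only ever passes through `predict`.
#' Performance is the mean test AUC with a corrected resampled t-test
#' confidence interval.
#'
#' @param features Cases x features data frame or matrix.
#' @param labels Binary labels, length `nrow(features)`.
#' @param k Number of splits, default 20.
#' @param train_frac Training fraction, default 0.8.
#' @param seed Integer seed (local to this call).
#' @param stratified Stratify splits by label (default `TRUE`).
#' @param fit_fun Pipeline constructor `function(train_x, train_y)` returning
#'   a prediction `function(new_x)`; defaults to redundancy filter + factor
#'   analysis + elastic net.
#' @param level Confidence level for the corrected interval.
#' @return A `split_evaluation`: per-split AUCs, `mean_auc`, `ci_low`,
#'   `ci_high`, split sizes and the seed.
#' @export
repeated_split_eval <- function(features, labels, k = 20, train_frac = 0.8,
                                seed = NULL, stratified = TRUE,
                                fit_fun = default_split_fitter(),
                                level = 0.95) {
  x <- as.matrix(features)
  y <- as_binary_label(labels)
  n <- length(y)
  stopifnot(nrow(x) == n)
  with_seed(seed, {
    aucs <- numeric(k)
    n_tr <- n_te <- integer(k)
    for (s in seq_len(k)) {
      repeat {
        tr <- draw_split(y, train_frac, stratified)
        te <- setdiff(seq_len(n), tr)
        if (length(unique(y[te])) == 2 && length(unique(y[tr])) == 2) break
        # single-class split: redraw (logged); cannot occur when stratified
        message("single-class split redrawn at repetition ", s)
      }
      pred <- fit_fun(x[tr, , drop = FALSE], y[tr])
      aucs[s] <- compute_auc(pred(x[te, , drop = FALSE]), y[te])
      n_tr[s] <- length(tr)
      n_te[s] <- length(te)
    }
    ci <- corrected_resampled_ci(aucs, n_tr[1], n_te[1], level)
    structure(
      list(
        aucs = aucs, mean_auc = mean(aucs),
        ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
        k = k, n_train = n_tr[1], n_test = n_te[1],
        level = level, seed = seed
      ),
      class = "split_evaluation"
    )
  })
}

draw_split <- function(y, train_frac, stratified) {
  n <- length(y)
  if (!stratified) {
    return(sort(sample.int(n, round(train_frac * n))))
  }
  idx <- unlist(lapply(unique(y), function(cl) {
    cls <- which(y == cl)
    sample(cls, round(train_frac * length(cls)))
  }))
  sort(idx)
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf(
    "<split_evaluation> %d splits (train %d / test %d)\n  mean test AUC %.3f (%.0f%% CI %.3f-%.3f)\n",
    x$k, x$n_train, x$n_test, x$mean_auc, 100 * x$level, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.split_evaluation <- function(x, ...) {
  tibble::tibble(split = seq_len(x$k), auc = x$aucs)
}

#' @export
#' @importFrom generics glance
glance.split_evaluation <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_train = x$n_train, n_test = x$n_test,
    mean_auc = x$mean_auc, ci_low = x$ci_low, ci_high = x$ci_high,
    level = x$level
  )
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.split_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = max(5, object$k %/% 2), fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_auc, colour = "red") +
    ggplot2::geom_vline(
      xintercept = c(object$ci_low, object$ci_high),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "test-set AUC per split", y = "splits",
      title = sprintf(
        "mean AUC %.3f (%.0f%% CI %.3f-%.3f)",
        object$mean_auc, 100 * object$level, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}
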