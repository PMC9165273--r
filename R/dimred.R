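#' Greedy redundancy filtering of correlated features
#'
#' Removes features until no retained pair has `|Pearson r|` above the
#' threshold. Removal is greedy: at each step the feature with the largest
#' number of super-threshold partners is dropped (ties broken by feature
#' name, so the result is deterministic). Constant features (undefined
#' correlation) are removed first with a warning.
#'
#' @param train_features Numeric matrix or data frame, cases x features, with
#'   column names.
#' @param threshold Absolute correlation threshold, default 0.9.
#' @return Character vector of retained feature names (original order).
#' @export
redundancy_filter <- function(train_features, threshold = 0.9) {
  x <- as.matrix(train_features)
  if (nrow(x) < 2) stop("need at least two cases", call. = FALSE)
  if (is.null(colnames(x))) stop("features must be named", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("constant features removed before redundancy filtering")
    x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  keep <- colnames(x)
  r <- abs(stats::cor(x))
  diag(r) <- 0
  repeat {
    over <- r > threshold
    deg <- rowSums(over)
    if (all(deg == 0)) break
    drop <- names(sort(deg[deg > 0], decreasing = TRUE))
    drop <- drop[order(-deg[drop], drop)][1]
    keep <- setdiff(keep, drop)
    r <- r[keep, keep, drop = FALSE]
  }
  colnames(x)[colnames(x) %in% keep]
}

#' Factor-per-ten-subjects rule
#'
#' Number of factors retained: one per ten training subjects, at least one.
#'
#' @param n_train Number of training cases.
#' @return Integer factor count `max(1, floor(n_train / 10))`.
#' @examples
#' n_factors_rule(68) # 6
#' @export
n_factors_rule <- function(n_train) {
  max(1L, as.integer(floor(n_train / 10)))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(partial^2))` over off-diagonal entries,
#' where partial correlations come from the inverse (anti-image) of the
#' correlation matrix. A near-singular correlation matrix is ridge
#' regularised with the smallest `lambda` in `10^(-6:0)` restoring
#' invertibility (a message records the value).
#'
#' @param train_features Cases x features matrix/data frame, or a
#'   correlation matrix (square, unit diagonal).
#' @return KMO statistic in `[0, 1]`.
#' @export
compute_kmo <- function(train_features) {
  x <- as.matrix(train_features)
  r <- if (nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-12)) x else stats::cor(x)
  p <- ncol(r)
  if (p < 2) stop("need at least two features", call. = FALSE)
  inv <- NULL
  for (lam in c(0, 10^(-6:0))) {
    rr <- (r + lam * diag(p)) / (1 + lam)
    inv <- tryCatch(solve(rr), error = function(e) NULL)
    if (!is.null(inv)) {
      if (lam > 0) message("correlation matrix regularised with lambda = ", lam)
      break
    }
  }
  if (is.null(inv)) stop("correlation matrix is singular after regularisation", call. = FALSE)
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Maximum-likelihood factor model on a training split
#'
#' Fits maximum-likelihood factor analysis (via [stats::factanal()]) on the
#' training correlation matrix with varimax rotation, orders factors by
#' explained common variance, and stores regression (Thomson) score weights
#' `W = R^-1 L` together with the training standardisation statistics, so
#' that test cases can be projected without influencing the fit.
#'
#' @param train_features Cases x features matrix/data frame (training split
#'   only).
#' @param n_factors Number of factors (default from [n_factors_rule()]).
#' @param rotation Rotation passed to `factanal` (default `"varimax"`).
#' @return A `factor_model` object: loadings, uniquenesses, score weights,
#'   training means/sds, `n_factors`, `kmo`.
#' @export
fit_factor_model <- function(train_features, n_factors = NULL,
                             rotation = "varimax") {
  x <- as.matrix(train_features)
  n <- nrow(x)
  if (is.null(n_factors)) n_factors <- n_factors_rule(n)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1) stop("need at least one factor", call. = FALSE)
  if (n <= n_factors) stop("need more cases than factors", call. = FALSE)
  p <- ncol(x)
  # ML factor analysis is identified only with positive degrees of freedom
  dof <- ((p - n_factors)^2 - (p + n_factors)) / 2
  if (dof < 0) {
    stop("too few features (", p, ") for ", n_factors, " factors", call. = FALSE)
  }
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant feature in training data", call. = FALSE)
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  r <- stats::cor(z)
  fit <- NULL
  # Heywood-prone fits: retry with a larger lower bound on the uniquenesses
  for (lower in c(0.005, 0.01, 0.05)) {
    fit <- tryCatch(
      stats::factanal(
        covmat = r, factors = n_factors, n.obs = n, rotation = rotation,
        control = list(lower = lower)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      if (lower > 0.005) {
        warning("factor fit required uniqueness lower bound ", lower)
      }
      break
    }
  }
  if (is.null(fit)) {
    stop("maximum-likelihood factor analysis did not converge", call. = FALSE)
  }
  l <- unclass(fit$loadings)
  # order factors by explained common variance
  ord <- order(colSums(l^2), decreasing = TRUE)
  l <- l[, ord, drop = FALSE]
  colnames(l) <- paste0("factor_", seq_len(n_factors))
  # Thomson regression weights on standardised features; ridge fallback for
  # a near-singular training correlation matrix
  w <- tryCatch(solve(r, l), error = function(e) {
    warning("correlation matrix near-singular; ridge-regularised score weights")
    solve(r + 1e-6 * diag(p), l)
  })
  structure(
    list(
      feature_names = colnames(x), loadings = l,
      uniquenesses = fit$uniquenesses, weights = w,
      n_factors = n_factors, rotation = rotation,
      means = mu, sds = sds, kmo = compute_kmo(r),
      n_train = n, correlation = r
    ),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> %d factors on %d features (n = %d), KMO = %.3f\n",
    x$n_factors, length(x$feature_names), x$n_train, x$kmo
  ))
  invisible(x)
}

#' Project cases onto fitted factors
#'
#' Standardises with the *training* means/sds stored in the model and applies
#' the regression score weights; test cases never influence the weights.
#'
#' @param model A `factor_model` from [fit_factor_model()].
#' @param features Cases x features matrix/data frame containing all retained
#'   feature columns.
#' @return Numeric matrix cases x factors.
#' @export
project_scores <- function(model, features) {
  x <- as.matrix(features)
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols) > 0) {
    stop(
      "missing feature columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[, model$feature_names, drop = FALSE]
  z <- sweep(sweep(x, 2, model$means), 2, model$sds, "/")
  s <- z %*% model$weights
  rownames(s) <- rownames(features)
  s
}

#' @export
#' @importFrom generics tidy
tidy.factor_model <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    feature = rep(rownames(l), ncol(l)),
    factor = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l),
    uniqueness = rep(unname(x$uniquenesses[rownames(l)]), ncol(l))
  )
}

#' @export
#' @importFrom generics glance
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names), n_factors = x$n_factors,
    n_train = x$n_train, kmo = x$kmo,
    explained_common_variance = sum(x$loadings^2) / length(x$feature_names)
  )
}

#' Combined per-split dimensionality reduction
#'
#' Standardise on the training split, filter redundant features, fit one
#' factor per ten training subjects, and return the model. This is the
#' reduction refit inside every repeated random split.
#'
#' @inheritParams redundancy_filter
#' @inheritParams fit_factor_model
#' @param threshold Redundancy threshold on `|r|`.
#' @return A `factor_model` whose `retained` element lists the post-filter
#'   feature names.
#' @export
reduce_dimension <- function(train_features, threshold = 0.9, n_factors = NULL) {
  retained <- redundancy_filter(train_features, threshold)
  x <- as.matrix(train_features)[, retained, drop = FALSE]
  # the training correlation matrix must be well conditioned (p < n) for
  # maximum-likelihood factoring: continue the greedy removal -- drop the
  # feature with the largest mean absolute correlation -- until p fits
  max_p <- max(2L, nrow(x) - 2L)
  while (ncol(x) > max_p) {
    r <- abs(stats::cor(x))
    diag(r) <- 0
    score <- colMeans(r)
    drop <- colnames(x)[order(-score, colnames(x))][1]
    x <- x[, colnames(x) != drop, drop = FALSE]
  }
  retained <- colnames(x)
  if (is.null(n_factors)) n_factors <- n_factors_rule(nrow(x))
  # cap the factor count at the largest identifiable value for p features
  p <- ncol(x)
  while (n_factors > 1 && ((p - n_factors)^2 - (p + n_factors)) / 2 < 0) {
    n_factors <- n_factors - 1L
  }
  model <- fit_factor_model(x, n_factors)
  model$retained <- retained
  model$threshold <- threshold
  model
}
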