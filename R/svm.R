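# Platt scaling: fit P(symmetric | decision value) = 1/(1 + exp(A*dv + B))
# by cross-entropy with Platt's smoothed targets, so the mapping is finite
# even when the training data are perfectly separable. Deterministic.
platt_fit <- function(dv, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  t <- ifelse(is_positive, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * dv + par[2]
    # stable cross-entropy: log(1 + exp(z)) - (1 - t) * z, p = sigma(-z)
    sum(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - (1 - t) * z)
  }
  fit <- stats::optim(c(A = 0, B = log((n0 + 1) / (n1 + 1))), nll,
                      method = "BFGS", control = list(maxit = 200))
  fit$par
}

platt_predict <- function(par, dv) {
  1 / (1 + exp(par[1] * dv + par[2]))
}

# internal: pull the feature matrix + label factor out of a feature tibble
feature_matrix <- function(data, feature_cols = NULL, label_col = "label") {
  feature_cols <- feature_cols %||% intersect(feature_keys(), names(data))
  if (length(feature_cols) == 0) abort("no feature columns found")
  X <- as.matrix(data[, feature_cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    abort("feature matrix contains missing or non-finite values")
  }
  y <- NULL
  if (!is.null(label_col) && label_col %in% names(data)) {
    y <- choro_label_factor(data[[label_col]])
  }
  list(X = X, y = y, feature_cols = feature_cols)
}

# stratified fold ids for internal CV (no RNG side effects)
internal_folds <- function(y, k, seed) {
  with_seed_if(seed, stratified_kfold(y, k))
}

# accuracy of an RBF-SVM under internal stratified k-fold CV; used as the
# GA fitness and for the hyperparameter grid. No probability model (not
# needed for accuracy), which keeps it fast.
svm_cv_accuracy <- function(X, y, cost, gamma, k = 5, seed = NULL) {
  folds <- internal_folds(y, k, seed)
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], mu, sg)
    Xte <- scale(X[!tr, , drop = FALSE], mu, sg)
    if (nlevels(droplevels(y[tr])) < 2) next
    fit <- e1071::svm(Xtr, y[tr], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    correct <- correct + sum(predict(fit, Xte) == y[!tr])
  }
  correct / length(y)
}

#' Train an RBF-kernel SVM on the 28 engineered features
#'
#' Features are z-scored with training-set statistics, an RBF-kernel SVM
#' is fitted on the selected features, and the decision values are
#' Platt-calibrated (a regularized sigmoid fitted to the training
#' decision values) so the model emits a confidence score CS in \[0, 1\]
#' with 1 = confidently symmetric. The in-package calibration is
#' deterministic and monotone in the decision value, so the CS > 0.5 rule
#' agrees with the fitted decision boundary up to the class-balance
#' offset. Unstated hyperparameters default to an internal 5-fold grid
#' search over `cost` in \{0.1, 1, 10, 100\} and `gamma` in
#' \{0.001, 0.01, 0.1, 1\}.
#'
#' @param data tibble with feature columns and a label column
#'   (`symmetric` / `asymmetric`).
#' @param feature_cols feature column names (default: all 28 keys present).
#' @param label_col label column name.
#' @param mask optional logical vector over `feature_cols` (e.g. from
#'   [gafs_select()]): only `TRUE` features are used.
#' @param hyper `"search"` for the grid search, or `list(cost=, gamma=)`.
#' @param seed seed for the internal CV splits.
#' @return A fitted classifier of class `choro_svm` understood by
#'   [predict_cs()].
#' @export
train_svm <- function(data, feature_cols = NULL, label_col = "label",
                      mask = NULL, hyper = "search", seed = NULL) {
  fm <- feature_matrix(data, feature_cols, label_col)
  y <- fm$y
  if (is.null(y)) abort("label column not found")
  if (nlevels(droplevels(y)) < 2) abort("training labels contain one class")
  if (min(table(y)) < 2) abort("need at least 2 samples per class")
  mask <- mask %||% rep(TRUE, ncol(fm$X))
  if (length(mask) != ncol(fm$X)) abort("`mask` length must match features")
  if (!any(mask)) abort("`mask` selects no features")
  X <- fm$X[, mask, drop = FALSE]

  if (identical(hyper, "search")) {
    grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                        gamma = c(0.001, 0.01, 0.1, 1))
    acc <- mapply(function(co, ga) {
      svm_cv_accuracy(X, y, co, ga, k = 5, seed = seed)
    }, grid$cost, grid$gamma)
    best <- grid[which.max(acc), ]
    hyper <- list(cost = best$cost, gamma = best$gamma)
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- scale(X, mu, sg)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = hyper$cost,
                    gamma = hyper$gamma, scale = FALSE)
  dv <- as.numeric(attr(predict(fit, Xs, decision.values = TRUE),
                        "decision.values"))
  platt <- platt_fit(dv, y == "symmetric")
  structure(
    list(
      kind = "svm_rbf", fit = fit, feature_cols = fm$feature_cols,
      mask = mask, center = mu, scale = sg, hyper = hyper,
      platt = platt, levels = levels(y)
    ),
    class = c("choro_svm", "choro_classifier")
  )
}

#' Confidence scores from a trained classifier
#'
#' Returns the confidence score CS in \[0, 1\] for each row: the
#' calibrated probability of the symmetric class (CS of 1 means
#' confidently symmetric; the score for the positive asymmetric class is
#' `1 - CS`). Classification uses the 0.5 threshold with the tie (CS
#' exactly 0.5) going to the symmetric (negative) class.
#'
#' @param model a `choro_svm` or `choro_rf` fit.
#' @param data tibble (or matrix) with the columns the model was trained
#'   on.
#' @return Numeric vector of CS values in \[0, 1\].
#' @export
predict_cs <- function(model, data) {
  UseMethod("predict_cs")
}

#' @export
predict_cs.default <- function(model, data) {
  abort("`model` is not a fitted choroviz classifier")
}

#' @export
predict_cs.choro_svm <- function(model, data) {
  X <- if (is.matrix(data)) data else
    as.matrix(data[, model$feature_cols, drop = FALSE])
  X <- X[, model$mask, drop = FALSE]
  Xs <- scale(X, model$center, model$scale)
  dv <- as.numeric(attr(predict(model$fit, Xs, decision.values = TRUE),
                        "decision.values"))
  unname(platt_predict(model$platt, dv))
}

#' Predicted class labels at the 0.5 threshold
#'
#' @inheritParams predict_cs
#' @return Character vector of `"symmetric"` / `"asymmetric"`.
#' @export
predict_label <- function(model, data) {
  cs <- predict_cs(model, data)
  ifelse(cs < 0.5, "asymmetric", "symmetric")
}
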