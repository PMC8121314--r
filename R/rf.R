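#' Train the fused random forest
#'
#' Fits a random forest on the concatenation of the 28 engineered
#' features and the PCA-reduced image embedding (100 dimensions by
#' default, giving 128 fused columns). The confidence score CS of an eye
#' is the fraction of trees voting for the symmetric class. Feature
#' importances (mean decrease in Gini) are jointly normalized to sum 1.
#'
#' The published model used 100000 trees; `n_trees = 500` is a practical
#' desk-scale override that leaves the vote-fraction CS nearly unchanged.
#'
#' @param X28 tibble or matrix of the engineered features (rows = eyes).
#' @param Epca matrix of PCA-reduced embeddings, row-aligned with `X28`
#'   (or `NULL` to fit on the engineered features alone).
#' @param y labels (`symmetric` / `asymmetric`).
#' @param n_trees number of trees (default 100000 per the published
#'   configuration).
#' @param seed RNG seed for tree construction.
#' @return A fitted classifier of class `choro_rf` understood by
#'   [predict_cs()]: fields `fit`, `importance` (normalized), `columns`.
#' @export
train_random_forest <- function(X28, Epca = NULL, y, n_trees = 100000,
                                seed = NULL) {
  X <- as.matrix(X28)
  storage.mode(X) <- "double"
  if (!is.null(Epca)) {
    if (nrow(Epca) != nrow(X)) {
      abort("engineered-feature and embedding matrices are misaligned")
    }
    colnames(Epca) <- colnames(Epca) %||% paste0("pc", seq_len(ncol(Epca)))
    X <- cbind(X, Epca)
  }
  if (anyNA(X)) abort("fused feature matrix contains missing values")
  yf <- droplevels(choro_label_factor(y))
  if (nlevels(yf) < 2) abort("training labels contain one class")
  fit <- with_seed_if(seed, randomForest::randomForest(
    x = X, y = yf, ntree = n_trees, importance = FALSE
  ))
  imp <- fit$importance[, "MeanDecreaseGini"]
  structure(
    list(
      kind = "random_forest", fit = fit,
      columns = colnames(X),
      importance = imp / sum(imp),
      levels = levels(yf)
    ),
    class = c("choro_rf", "choro_classifier")
  )
}

#' @export
predict_cs.choro_rf <- function(model, data) {
  X <- as.matrix(data)
  missing <- setdiff(model$columns, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("prediction data lacks fused column(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  X <- X[, model$columns, drop = FALSE]
  pr <- predict(model$fit, X, type = "prob")
  unname(pr[, "symmetric"])
}
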