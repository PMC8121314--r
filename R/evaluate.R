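#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals it round-robin across
#' folds, so per-fold class proportions are within one sample of the
#' global proportions. Deterministic for a fixed seed.
#'
#' @param y label vector.
#' @param k number of folds.
#' @param seed RNG seed (`NULL` uses the current RNG stream).
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(y, k = 10, seed = NULL) {
  n <- length(y)
  if (n < k) abort("fewer samples than folds")
  if (any(table(y) < k)) {
    warn("a class has fewer members than folds; stratification is degenerate")
  }
  folds <- integer(n)
  with_seed_if(seed, {
    offset <- 0L
    for (cl in unique(y)) {
      id <- which(y == cl)
      id <- id[sample.int(length(id))]
      # continue the round-robin across classes so fold sizes stay even
      folds[id] <- ((seq_along(id) + offset - 1L) %% k) + 1L
      offset <- offset + length(id)
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC with tied scores averaged, computed via the
#' Mann-Whitney statistic. Asymmetry is the positive class: `scores`
#' must be the asymmetry score (`1 - CS`) and `labels` the true classes.
#'
#' @param scores numeric score for the positive (asymmetric) class.
#' @param labels true labels (`symmetric` / `asymmetric`, or a logical/
#'   0-1 vector marking positives).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels) || is.numeric(labels)) {
    labels == 1 | labels == TRUE
  } else {
    as.character(labels) == "asymmetric"
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, recall, precision and Cohen's kappa
#'
#' Binary classification metrics with asymmetry as the positive class.
#' Zero-denominator recall or precision yields 0 with a warning.
#'
#' @param pred predicted labels.
#' @param labels true labels.
#' @return A one-row tibble: `accuracy`, `recall`, `precision`, `kappa`.
#' @export
classification_metrics <- function(pred, labels) {
  stopifnot(length(pred) == length(labels))
  p <- as.character(pred) == "asymmetric"
  t <- as.character(labels) == "asymmetric"
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  if (tp + fn == 0) {
    warn("no positive cases; recall set to 0")
    rec <- 0
  } else {
    rec <- tp / (tp + fn)
  }
  if (tp + fp == 0) {
    warn("no positive predictions; precision set to 0")
    prec <- 0
  } else {
    prec <- tp / (tp + fp)
  }
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  # degenerate table (chance agreement 1): perfect agreement scores 1,
  # anything else 0
  kappa <- if (pe == 1) as.numeric(acc == 1) else (acc - pe) / (1 - pe)
  tibble(accuracy = acc, recall = rec, precision = prec, kappa = kappa)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences `a - b`. Zero differences are
#' dropped and tied absolute differences mid-ranked. For 15 or fewer
#' informative pairs the p-value is exact (full distribution of the
#' positive-rank sum over all sign assignments, computed by convolution);
#' beyond that a normal approximation with continuity and tie correction
#' is used.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @return A list: `statistic` (positive-rank sum W+), `p_value`,
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 15) {
    # exact: distribution of W+ over the 2^n equiprobable sign patterns.
    # Work in half-rank units so midranks are integers.
    r2 <- as.integer(round(2 * r))
    dist <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    dist <- dist / sum(dist)
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, n_effective = n,
                method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p_value = p, n_effective = n, method = "normal")
}

#' Model specifications for cross-validated comparison
#'
#' Constructors describing how each classifier configuration is fitted
#' inside a cross-validation fold. Everything data-dependent (feature
#' selection, hyperparameter search, embedding training, PCA) happens on
#' the training partition of each fold only.
#'
#' * `svm_model()`: RBF-SVM on the 28 features, optionally preceded by
#'   genetic-algorithm feature selection.
#' * `rf_model()`: fused random forest on the 28 features plus a
#'   PCA-reduced image embedding.
#' * `shuffled_model()`: a negative control; the base specification
#'   trained on permuted training labels.
#'
#' @param name display name.
#' @param gafs run [gafs_select()] inside each training fold.
#' @param ga a [gafs_config()] for the selection run.
#' @param hyper `"search"` or `list(cost=, gamma=)` for the SVM.
#' @return A model specification (class `choro_model_spec`).
#' @export
svm_model <- function(name = if (gafs) "svm_gafs" else "svm",
                      gafs = FALSE, ga = gafs_config(), hyper = "search") {
  structure(list(type = "svm", name = name, gafs = gafs, ga = ga,
                 hyper = hyper),
            class = "choro_model_spec")
}

#' @rdname svm_model
#' @param embedder an embedder (see [pixel_embedder()], [cnn_embedder()]).
#' @param pca_k embedding dimension after PCA.
#' @param n_trees trees per forest.
#' @export
rf_model <- function(name = "rf", embedder = pixel_embedder(),
                     pca_k = 100, n_trees = 500) {
  structure(list(type = "rf", name = name, embedder = embedder,
                 pca_k = pca_k, n_trees = n_trees),
            class = "choro_model_spec")
}

#' @rdname svm_model
#' @param base the model specification to sabotage.
#' @export
shuffled_model <- function(base = svm_model(), name = paste0(base$name, "_shuffled")) {
  structure(list(type = "shuffled", name = name, base = base),
            class = "choro_model_spec")
}

# fit one spec on a training partition; returns a closure scoring test rows
fit_spec <- function(spec, train_tbl, train_images, seed) {
  switch(spec$type,
    svm = {
      mask <- NULL
      if (spec$gafs) {
        sel <- gafs_select(train_tbl, ga = spec$ga, seed = seed)
        mask <- sel$selected_mask
      }
      model <- train_svm(train_tbl, mask = mask, hyper = spec$hyper,
                         seed = seed)
      function(test_tbl, test_images) predict_cs(model, test_tbl)
    },
    rf = {
      emb <- fit_embedder(spec$embedder, train_images,
                          labels = train_tbl$label, seed = seed)
      Etr <- embed_images(emb, train_images)
      pca <- reduce_pca(Etr, spec$pca_k)
      Xtr <- as.matrix(train_tbl[, intersect(feature_keys(), names(train_tbl)),
                                 drop = FALSE])
      Str <- pca$scores
      colnames(Str) <- paste0("pc", seq_len(ncol(Str)))
      model <- train_random_forest(Xtr, Str, train_tbl$label,
                                   n_trees = spec$n_trees, seed = seed)
      function(test_tbl, test_images) {
        Ete <- embed_images(emb, test_images)
        Ste <- predict(pca, Ete)
        colnames(Ste) <- paste0("pc", seq_len(ncol(Ste)))
        Xte <- as.matrix(test_tbl[, intersect(feature_keys(), names(test_tbl)),
                                  drop = FALSE])
        predict_cs(model, cbind(Xte, Ste))
      }
    },
    shuffled = {
      shuffled <- train_tbl
      shuffled$label <- with_seed_if(seed + 1L,
                                     sample(as.character(train_tbl$label)))
      fit_spec(spec$base, shuffled, train_images, seed)
    },
    abort(paste0("unknown model spec type: ", spec$type))
  )
}

#' Cross-validated comparison of classifier configurations
#'
#' Runs stratified k-fold cross-validation with the *same* fold split
#' shared by every model (required for the paired Wilcoxon comparison),
#' collects AUC, accuracy, recall, precision and Cohen's kappa per fold,
#' and tests each model pair on per-fold AUC and accuracy with the exact
#' Wilcoxon signed-rank test.
#'
#' @param features feature tibble (`eye_id`, 28 feature columns,
#'   `label`).
#' @param models named list of model specifications ([svm_model()],
#'   [rf_model()], [shuffled_model()]).
#' @param images optional list of [enface] images aligned with
#'   `features` rows (needed by `rf_model()`).
#' @param k folds (default 10).
#' @param seed seed controlling the fold split and all fold-level
#'   training randomness.
#' @return An object of class `choro_cv`: `folds` (per-model, per-fold
#'   metrics), `scores` (per-eye out-of-fold CS), `summary`
#'   (mean +/- SD), `comparisons` (pairwise Wilcoxon p-values),
#'   `fold_assignment`.
#' @export
run_model_comparison <- function(features, models, images = NULL, k = 10,
                                 seed = 1) {
  stopifnot(length(models) >= 1)
  y <- choro_label_factor(features$label)
  folds <- stratified_kfold(y, k, seed = seed)
  needs_images <- any(vapply(models, function(m) {
    m$type == "rf" || (m$type == "shuffled" && m$base$type == "rf")
  }, logical(1)))
  if (needs_images && is.null(images)) {
    abort("an rf_model() specification needs `images`")
  }

  fold_rows <- list()
  score_rows <- list()
  for (mi in seq_along(models)) {
    spec <- models[[mi]]
    for (f in seq_len(k)) {
      tr <- folds != f
      tr_imgs <- if (!is.null(images)) images[tr] else NULL
      te_imgs <- if (!is.null(images)) images[!tr] else NULL
      scorer <- fit_spec(spec, features[tr, , drop = FALSE], tr_imgs,
                         seed = seed * 1000L + f)
      cs <- scorer(features[!tr, , drop = FALSE], te_imgs)
      truth <- as.character(y[!tr])
      pred <- ifelse(cs < 0.5, "asymmetric", "symmetric")
      m <- classification_metrics(pred, truth)
      fold_rows[[length(fold_rows) + 1]] <- dplyr::bind_cols(
        tibble(model = spec$name, fold = f,
               auc = roc_auc(1 - cs, truth), n_test = sum(!tr)),
        m
      )
      score_rows[[length(score_rows) + 1]] <- tibble(
        model = spec$name, fold = f, eye_id = features$eye_id[!tr],
        cs = cs, label = truth
      )
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  scores_tbl <- dplyr::bind_rows(score_rows)

  summary_tbl <- folds_tbl |>
    tidyr::pivot_longer(c("auc", "accuracy", "recall", "precision", "kappa"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")

  comp_rows <- list()
  nms <- vapply(models, `[[`, character(1), "name")
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in (i + 1):length(nms)) {
        for (metric in c("auc", "accuracy")) {
          ai <- folds_tbl[[metric]][folds_tbl$model == nms[i]]
          aj <- folds_tbl[[metric]][folds_tbl$model == nms[j]]
          wt <- suppressWarnings(wilcoxon_signed_rank(ai, aj))
          comp_rows[[length(comp_rows) + 1]] <- tibble(
            model_a = nms[i], model_b = nms[j], metric = metric,
            statistic = wt$statistic, p_value = wt$p_value
          )
        }
      }
    }
  }

  structure(
    list(
      folds = folds_tbl, scores = scores_tbl, summary = summary_tbl,
      comparisons = dplyr::bind_rows(comp_rows),
      fold_assignment = folds, k = k, seed = seed
    ),
    class = "choro_cv"
  )
}

#' @export
print.choro_cv <- function(x, ...) {
  cat(sprintf("<choro_cv> %d-fold cross-validation, %d model(s)\n",
              x$k, length(unique(x$folds$model))))
  s <- x$summary |>
    dplyr::mutate(txt = sprintf("%.3f+/-%.3f", .data$mean, .data$sd)) |>
    dplyr::select("model", "metric", "txt") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "txt")
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}
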