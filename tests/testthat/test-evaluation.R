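test_that("stratified folds balance classes and partition the data", {
  y <- rep(c("symmetric", "asymmetric"), times = c(204, 209))
  f <- stratified_kfold(y, 10, seed = 4)
  sizes <- tabulate(f, 10)
  expect_true(all(sizes %in% c(41, 42)))
  expect_equal(sum(sizes), 413)
  # per-fold class counts within 1 of the ideal
  for (k in 1:10) {
    n_sym <- sum(y[f == k] == "symmetric")
    expect_lte(abs(n_sym - 20.4), 1.4)
  }
  expect_setequal(unique(f), 1:10)

  # leave-one-out degenerates gracefully
  y10 <- rep(c("a", "b"), 5)
  expect_warning(f10 <- stratified_kfold(y10, 10, seed = 1), "degenerate")
  expect_equal(sort(tabulate(f10, 10)), rep(1, 10))

  expect_identical(stratified_kfold(y, 10, seed = 9),
                   stratified_kfold(y, 10, seed = 9))
  expect_error(stratified_kfold(y[1:5], 10), "fewer samples")
})

test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("asymmetric", "asymmetric", "symmetric", "symmetric")), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("symmetric", "symmetric", "asymmetric", "asymmetric")), 0)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c("symmetric", "symmetric")), "both classes")

  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    sc <- round(runif(n), 2)          # rounding forces ties
    lab <- sample(c("symmetric", "asymmetric"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab))
  }
})

test_that("confusion metrics match hand computation, kappa included", {
  m <- classification_metrics(rep("asymmetric", 4), rep("asymmetric", 4))
  expect_equal(m$accuracy, 1)
  expect_equal(m$kappa, 1)

  # constant prediction on balanced labels: kappa 0
  labs <- rep(c("asymmetric", "symmetric"), 10)
  m0 <- suppressWarnings(
    classification_metrics(rep("symmetric", 20), labs)
  )
  expect_equal(m0$kappa, 0)
  expect_equal(m0$recall, 0)

  # TP=3 FP=1 FN=1 TN=5
  pred <- c(rep("asymmetric", 4), rep("symmetric", 6))
  truth <- c(rep("asymmetric", 3), "symmetric", "asymmetric", rep("symmetric", 5))
  m1 <- classification_metrics(pred, truth)
  expect_equal(m1$precision, 0.75)
  expect_equal(m1$recall, 0.75)
  expect_equal(m1$accuracy, 0.8)
  expect_equal(m1$kappa, (0.8 - 0.52) / (1 - 0.52), tolerance = 1e-12)
})

test_that("exact Wilcoxon matches full sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  expect_warning(r0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r0$p_value, 1)

  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    a <- round(runif(n), if (i %% 2) 1 else 3)   # ties on even reps
    b <- round(runif(n), if (i %% 2) 1 else 3)
    if (all(a == b)) next
    got <- suppressWarnings(wilcoxon_signed_rank(a, b))
    expect_equal(got$p_value, oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  }

  # agrees with stats::wilcox.test when there are no ties or zeros
  set.seed(31)
  a <- rnorm(12); b <- rnorm(12)
  got <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(got$statistic, unname(ref$statistic))

  # large-sample path: normal approximation close to the reference
  set.seed(37)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  got_n <- wilcoxon_signed_rank(a, b)
  ref_n <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                              correct = TRUE)
  expect_equal(got_n$method, "normal")
  expect_equal(got_n$p_value, unname(ref_n$p.value), tolerance = 1e-6)
})

test_that("model comparison shares folds and pairs the tests", {
  d <- make_cloud_data(n = 80, sep = 3, seed = 61)
  spec <- svm_model(name = "svm_a", hyper = list(cost = 1, gamma = 0.05))
  spec_b <- svm_model(name = "svm_b", hyper = list(cost = 1, gamma = 0.05))
  cv <- run_model_comparison(d |> dplyr::mutate(eye_id = paste0("e", 1:80)),
                             models = list(spec, spec_b), k = 5, seed = 2)

  # identical specifications: every paired p-value is 1
  expect_true(all(cv$comparisons$p_value == 1))

  # shared fold split: the same eyes are tested per fold for both models
  for (f in 1:5) {
    ids_a <- sort(cv$scores$eye_id[cv$scores$model == "svm_a" & cv$scores$fold == f])
    ids_b <- sort(cv$scores$eye_id[cv$scores$model == "svm_b" & cv$scores$fold == f])
    expect_identical(ids_a, ids_b)
  }
  # test folds partition the data
  ids <- cv$scores$eye_id[cv$scores$model == "svm_a"]
  expect_setequal(ids, paste0("e", 1:80))
  expect_equal(length(ids), 80)

  # summary means equal the fold means
  a_auc <- cv$folds$auc[cv$folds$model == "svm_a"]
  expect_equal(cv$summary$mean[cv$summary$model == "svm_a" &
                                 cv$summary$metric == "auc"], mean(a_auc))
})

test_that("cross-validated accuracy tracks the label-noise floor", {
  set.seed(71)
  n <- 500
  y_true <- rep(c("symmetric", "asymmetric"), length.out = n)
  X <- matrix(rnorm(n * 28, sd = 0.3), n, 28)
  X[, 1] <- X[, 1] + ifelse(y_true == "symmetric", 1, -1)
  X[, 2] <- X[, 2] + ifelse(y_true == "symmetric", 1, -1)
  colnames(X) <- feature_keys()
  flip <- sample(n, round(0.1 * n))
  y <- y_true
  y[flip] <- ifelse(y_true[flip] == "symmetric", "asymmetric", "symmetric")
  d <- dplyr::bind_cols(tibble::as_tibble(X),
                        tibble::tibble(label = y, eye_id = paste0("e", 1:n)))
  cv <- run_model_comparison(
    d, models = list(svm_model(hyper = list(cost = 1, gamma = 0.05))),
    k = 5, seed = 3
  )
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_lt(abs(acc - 0.9), 0.05)
})
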