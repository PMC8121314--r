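test_that("the RBF-SVM separates separable clouds and validates input", {
  d <- make_cloud_data(n = 100, sep = 4, seed = 11)
  fit <- train_svm(d, hyper = list(cost = 10, gamma = 0.05), seed = 1)
  cs <- predict_cs(fit, d)
  expect_true(all(cs >= 0 & cs <= 1))
  acc <- mean(predict_label(fit, d) == d$label)
  expect_gte(acc, 0.99)

  d_na <- d; d_na$f01_vessel_area_upper_mm2[3] <- NA
  expect_error(train_svm(d_na), "missing")
  expect_error(train_svm(d, mask = rep(FALSE, 28)), "no features")
  d_one <- d; d_one$label <- "symmetric"
  expect_error(train_svm(d_one), "one class")
  expect_error(predict_cs(structure(list(), class = "lm"), d), "not a fitted")

  # grid search picks hyperparameters without touching the interface
  fit2 <- train_svm(d[1:60, ], hyper = "search", seed = 2)
  expect_true(fit2$hyper$cost %in% c(0.1, 1, 10, 100))
  expect_true(fit2$hyper$gamma %in% c(0.001, 0.01, 0.1, 1))
})

test_that("classification threshold is 0.5 with ties going symmetric", {
  d <- make_cloud_data(n = 60, sep = 3, seed = 3)
  fit <- train_svm(d, hyper = list(cost = 1, gamma = 0.05))
  cs <- predict_cs(fit, d)
  lab <- predict_label(fit, d)
  expect_identical(lab, ifelse(cs < 0.5, "asymmetric", "symmetric"))
})

test_that("GA feature selection honors its published defaults and contract", {
  ga <- gafs_config()
  expect_equal(ga$population_size, 20)
  expect_equal(ga$crossover_prob, 0.7)
  expect_equal(ga$mutation_prob, 0.2)
  expect_equal(ga$tournament_size, 2)
  expect_equal(ga$max_generations, 1000)
  expect_gte(ga$patience, 1)
  expect_error(gafs_config(population_size = 7), "population_size")

  d <- make_cloud_data(n = 120, k_inf = 2, sep = 3, seed = 21)
  sel <- gafs_select(d, ga = gafs_config(max_generations = 15, patience = 6),
                     seed = 5)
  expect_s3_class(sel, "choro_gafs")
  expect_gte(sel$n_selected, 1)
  # elitism: best-so-far fitness history is nondecreasing
  expect_true(all(diff(sel$fitness_history) >= 0))
  # the informative pair dominates the fitness signal
  expect_true(all(sel$selected_mask[1:2]))
  # reproducible under the same seed
  sel2 <- gafs_select(d, ga = gafs_config(max_generations = 15, patience = 6),
                      seed = 5)
  expect_identical(sel$selected_mask, sel2$selected_mask)
})

test_that("pixel embeddings are deterministic with fixed geometry", {
  imgs <- lapply(1:4, function(i) {
    synth_image(synth_config(alpha = 0.2), seed = 200 + i)$image
  })
  emb <- fit_embedder(pixel_embedder(size = 16), imgs)
  E <- embed_images(emb, imgs)
  expect_equal(dim(E), c(4, 256))
  # the same image twice embeds to identical rows
  E2 <- embed_images(emb, list(imgs[[2]], imgs[[2]]))
  expect_identical(E2[1, ], E2[2, ])
})

test_that("the compact CNN trains, embeds deterministically, and separates", {
  n <- 60
  man <- synth_dataset(n = n, seed = 31,
                       cfg_symmetric = synth_config(alpha = 0.05),
                       cfg_asymmetric = synth_config(alpha = 0.95))
  imgs <- lapply(attr(man, "samples"), function(s) s$image)
  emb <- cnn_embedder(input_size = 64, epochs = 4)
  expect_error(embed_images(emb, imgs), "not fitted")
  expect_error(fit_embedder(emb, imgs), "labels")
  fitted <- fit_embedder(emb, imgs, man$label, seed = 9)
  E <- embed_images(fitted, imgs)
  expect_equal(nrow(E), n)
  expect_equal(ncol(E), 7 * 7 * 16)
  # inference is deterministic for fixed weights
  E2 <- embed_images(fitted, imgs[1:2])
  expect_identical(E[1:2, ], E2)

  # a linear probe on held-out embeddings separates the extreme classes
  tr <- seq_len(40); te <- 41:n
  pc <- reduce_pca(E[tr, ], 10)
  df_tr <- data.frame(pc$scores, y = factor(man$label[tr]))
  df_te <- data.frame(predict(pc, E[te, ]))
  colnames(df_te) <- colnames(pc$scores)
  probe <- suppressWarnings(stats::glm(y ~ ., data = df_tr, family = binomial))
  p <- predict(probe, df_te, type = "response")
  acc <- mean((p > 0.5) == (man$label[te] == "symmetric"))
  expect_gt(acc, 0.8)
})

test_that("PCA reduction respects the rank bound and orders variance", {
  # rank-1 matrix: one non-negligible component
  u <- rnorm(30); v <- rnorm(12)
  E <- outer(u, v)
  pc <- reduce_pca(E, 5)
  vars <- apply(pc$scores, 2, var)
  expect_equal(sum(vars > 1e-10 * vars[1]), 1)

  set.seed(8)
  E2 <- matrix(rnorm(50 * 120), 50, 120)
  expect_warning(pc2 <- reduce_pca(E2, 100), "truncated")
  expect_equal(ncol(pc2$scores), 49)

  # reconstruction error is nonincreasing in k and matches the SVD oracle
  Ec <- scale(E2, scale = FALSE)
  sv <- svd(Ec)
  errs <- vapply(c(5, 10, 20, 40), function(k) {
    pck <- suppressWarnings(reduce_pca(E2, k))
    rec <- pck$scores %*% t(pck$rotation)
    sum((Ec - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  oracle_err <- sum(sv$d[-(1:10)]^2)
  pc10 <- reduce_pca(E2, 10)
  expect_equal(sum((Ec - pc10$scores %*% t(pc10$rotation))^2), oracle_err,
               tolerance = 1e-8)
})

test_that("the fused random forest votes, normalizes importances, validates", {
  # published default is 100000 trees; desk runs override it
  expect_equal(formals(train_random_forest)$n_trees, 100000)

  d <- make_cloud_data(n = 80, sep = 3, seed = 41)
  X28 <- d[, feature_keys()]
  E <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("pc", 1:10)))
  fit <- train_random_forest(X28, E, d$label, n_trees = 200, seed = 1)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  cs <- predict_cs(fit, cbind(as.matrix(X28), E))
  expect_true(all(cs >= 0 & cs <= 1))
  expect_gt(roc_auc(1 - cs, d$label), 0.95)

  expect_error(train_random_forest(X28, E[1:40, ], d$label, n_trees = 50),
               "misaligned")

  # prediction is invariant to fused column order (matched by name)
  perm <- sample(ncol(cbind(as.matrix(X28), E)))
  cs_perm <- predict_cs(fit, cbind(as.matrix(X28), E)[, perm])
  expect_identical(cs, cs_perm)

  # pure noise: out-of-bag accuracy hovers at chance
  noise <- make_cloud_data(n = 200, k_inf = 0, seed = 43)
  fit_n <- train_random_forest(noise[, feature_keys()], NULL, noise$label,
                               n_trees = 500, seed = 2)
  oob_acc <- sum(diag(fit_n$fit$confusion[, 1:2])) / 200
  expect_gt(oob_acc, 0.4)
  expect_lt(oob_acc, 0.6)
})

test_that("fold-internal fitting leaks nothing into test scores", {
  d <- make_cloud_data(n = 80, sep = 2, seed = 51)
  tr <- d[1:60, ]; te <- d[61:80, ]
  fit <- train_svm(tr, hyper = list(cost = 1, gamma = 0.05), seed = 1)
  cs1 <- predict_cs(fit, te)
  te_perm <- te
  te_perm$label <- sample(te$label)
  cs2 <- predict_cs(fit, te_perm)
  expect_identical(cs1, cs2)
})
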