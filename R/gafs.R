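#' Genetic-algorithm feature selection configuration
#'
#' Defaults follow the published search settings: population 20,
#' crossover probability 0.7, mutation probability 0.2, tournament size
#' 2, up to 1000 generations with early stopping. The mutation
#' probability is read as a per-individual mutation event; a mutated
#' individual flips each gene independently with probability
#' `1/n_features` (per-gene semantics are available via `per_gene`).
#'
#' @param population_size even number of individuals.
#' @param crossover_prob one-point crossover probability.
#' @param mutation_prob per-individual mutation probability.
#' @param tournament_size tournament size for parent selection.
#' @param max_generations generation cap.
#' @param patience generations without best-fitness improvement before
#'   early stop.
#' @param per_gene if `TRUE`, `mutation_prob` applies per gene instead.
#' @param cv_folds internal CV folds for the wrapped-SVM fitness.
#' @param svm_cost,svm_gamma fixed SVM hyperparameters for the fitness
#'   (`NULL` gamma = 1 / number of selected features).
#' @return A list of class `gafs_config`.
#' @export
gafs_config <- function(population_size = 20, crossover_prob = 0.7,
                        mutation_prob = 0.2, tournament_size = 2,
                        max_generations = 1000, patience = 100,
                        per_gene = FALSE, cv_folds = 5,
                        svm_cost = 1, svm_gamma = NULL) {
  stopifnot(
    population_size %% 2 == 0, population_size >= 2,
    crossover_prob >= 0, crossover_prob <= 1,
    mutation_prob >= 0, mutation_prob <= 1,
    patience >= 1, max_generations >= 1
  )
  structure(
    list(
      population_size = population_size, crossover_prob = crossover_prob,
      mutation_prob = mutation_prob, tournament_size = tournament_size,
      max_generations = max_generations, patience = patience,
      per_gene = per_gene, cv_folds = cv_folds,
      svm_cost = svm_cost, svm_gamma = svm_gamma
    ),
    class = "gafs_config"
  )
}

#' Genetic-algorithm feature selection for the RBF-SVM
#'
#' Evolves binary feature-inclusion masks. Fitness is the mean accuracy
#' of an RBF-SVM under internal stratified cross-validation on the
#' supplied (training) data only. Selection is by tournament, variation
#' by one-point crossover and bit-flip mutation, with elitism (the best
#' individual always survives), so the best-so-far fitness is
#' nondecreasing. All-zero masks are repaired by switching one random
#' gene on. The search stops early after `patience` improvement-free
#' generations.
#'
#' @inheritParams train_svm
#' @param ga a [gafs_config()].
#' @param seed RNG seed for the whole search.
#' @return An object of class `choro_gafs`: `selected_mask` (logical),
#'   `n_selected`, `fitness_history` (best-so-far per generation),
#'   `best_fitness`, `generations`, `feature_cols`.
#' @export
gafs_select <- function(data, feature_cols = NULL, label_col = "label",
                        ga = gafs_config(), seed = NULL) {
  stopifnot(inherits(ga, "gafs_config"))
  fm <- feature_matrix(data, feature_cols, label_col)
  X <- fm$X
  y <- fm$y
  if (is.null(y)) abort("label column not found")
  p <- ncol(X)

  cache <- new.env(parent = emptyenv())
  fold_seed <- 0L   # fixed internal folds per search; reset under `seed`
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    gamma <- ga$svm_gamma %||% (1 / sum(mask))
    acc <- svm_cv_accuracy(X[, mask, drop = FALSE], y,
                           cost = ga$svm_cost, gamma = gamma,
                           k = ga$cv_folds, seed = fold_seed)
    cache[[key]] <- acc
    acc
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(p, 1)] <- TRUE
    mask
  }
  mutate_ind <- function(mask) {
    if (ga$per_gene) {
      flip <- runif(p) < ga$mutation_prob
    } else {
      flip <- if (runif(1) < ga$mutation_prob) runif(p) < 1 / p else rep(FALSE, p)
    }
    repair(xor(mask, flip))
  }

  with_seed_if(seed, {
    fold_seed <- sample.int(.Machine$integer.max - 1, 1)
    pop <- lapply(seq_len(ga$population_size), function(i) {
      repair(runif(p) < 0.5)
    })
    fit <- vapply(pop, fitness, numeric(1))
    best_i <- which.max(fit)
    best_mask <- pop[[best_i]]
    best_fit <- fit[best_i]
    history <- numeric(0)
    stale <- 0L
    gen <- 0L
    while (gen < ga$max_generations && stale < ga$patience) {
      gen <- gen + 1L
      tournament <- function() {
        cand <- sample.int(ga$population_size, ga$tournament_size,
                           replace = TRUE)
        cand[which.max(fit[cand])]
      }
      nextgen <- vector("list", ga$population_size)
      i <- 1L
      while (i < ga$population_size) {
        a <- pop[[tournament()]]
        b <- pop[[tournament()]]
        if (runif(1) < ga$crossover_prob && p > 1) {
          cut <- sample.int(p - 1, 1)
          tmp <- a
          a <- c(a[1:cut], b[(cut + 1):p])
          b <- c(b[1:cut], tmp[(cut + 1):p])
        }
        nextgen[[i]] <- mutate_ind(a)
        nextgen[[i + 1L]] <- mutate_ind(b)
        i <- i + 2L
      }
      nextgen[[1L]] <- best_mask               # elitism
      pop <- nextgen
      fit <- vapply(pop, fitness, numeric(1))
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_mask <- pop[[gen_best]]
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      history <- c(history, best_fit)
    }
    structure(
      list(
        selected_mask = best_mask,
        n_selected = sum(best_mask),
        fitness_history = history,
        best_fitness = best_fit,
        generations = gen,
        feature_cols = fm$feature_cols
      ),
      class = "choro_gafs"
    )
  })
}

#' @export
print.choro_gafs <- function(x, ...) {
  cat(sprintf(
    "<choro_gafs> %d/%d features selected, fitness %.4f after %d generations\n",
    x$n_selected, length(x$selected_mask), x$best_fitness, x$generations
  ))
  invisible(x)
}
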