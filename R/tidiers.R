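#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns per-unit detail rows,
#' `glance()` a one-row (or one-row-per-model) summary.
#'
#' @param x a fitted/summary object from this package.
#' @param ... unused.
#' @return A tibble.
#' @name choroviz-tidiers
NULL

#' @rdname choroviz-tidiers
#' @export
tidy.choro_cv <- function(x, ...) x$folds

#' @rdname choroviz-tidiers
#' @export
glance.choro_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' @rdname choroviz-tidiers
#' @export
tidy.choro_gafs <- function(x, ...) {
  tibble(
    feature = x$feature_cols,
    name = feature_names()[match(x$feature_cols, feature_keys())],
    selected = x$selected_mask
  )
}

#' @rdname choroviz-tidiers
#' @export
glance.choro_gafs <- function(x, ...) {
  tibble(n_selected = x$n_selected, best_fitness = x$best_fitness,
         generations = x$generations)
}

#' @rdname choroviz-tidiers
#' @export
tidy.choro_rf <- function(x, ...) {
  tibble(feature = names(x$importance),
         importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname choroviz-tidiers
#' @export
glance.choro_svm <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_features = sum(x$mask),
    cost = x$hyper$cost,
    gamma = x$hyper$gamma,
    n_support_vectors = nrow(x$fit$SV)
  )
}
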