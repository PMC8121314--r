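#' Confidence-score strength and bins
#'
#' The strength of self-confidence of a classifier judgment is the
#' distance of its confidence score from indecision,
#' `strength = |CS - 0.5|` in \[0, 0.5\]. Strength is cut into thirds:
#' below 1/6 is `unconfident`, from 1/6 up to 1/3 is
#' `moderately_confident`, and 1/3 or more is `confident` (the exact
#' thirds that the conventional 3-decimal bounds 0.166/0.167 and
#' 0.332/0.333 truncate). The binning is symmetric under
#' `CS -> 1 - CS`.
#'
#' @param cs numeric vector of confidence scores in \[0, 1\].
#' @return `confidence_strength()`: numeric vector;
#'   `confidence_bin()`: factor with levels `unconfident`,
#'   `moderately_confident`, `confident`.
#' @export
confidence_bin <- function(cs) {
  if (any(is.na(cs)) || any(cs < 0 | cs > 1)) {
    abort("confidence scores must lie in [0, 1]")
  }
  s <- abs(cs - 0.5)
  # tiny guard so scores sitting exactly on a printed bound (e.g. cs =
  # 0.5 + 1/6) are not pushed down a bin by representation noise
  eps <- 1e-9
  out <- ifelse(s < 1 / 6 - eps, "unconfident",
                ifelse(s < 1 / 3 - eps, "moderately_confident", "confident"))
  factor(out, levels = c("unconfident", "moderately_confident", "confident"))
}

#' @rdname confidence_bin
#' @export
confidence_strength <- function(cs) {
  if (any(is.na(cs)) || any(cs < 0 | cs > 1)) {
    abort("confidence scores must lie in [0, 1]")
  }
  abs(cs - 0.5)
}

.agreement_levels <- c("disagreement", "partial_disagreement",
                       "partial_agreement", "agreement")

#' Human agreement grouping
#'
#' Counts how many of three independent raters match the supervised
#' (consensus) label of each eye and maps the count to the agreement
#' group: 3 matches = `agreement`, 2 = `partial_agreement`,
#' 1 = `partial_disagreement`, 0 = `disagreement`.
#'
#' @param supervised supervised labels (`symmetric` / `asymmetric`).
#' @param raters data frame or matrix with exactly three columns of
#'   rater labels, row-aligned with `supervised`.
#' @return A tibble: `supervised`, `rater1..3`, `n_match`, `group`
#'   (ordered factor).
#' @export
agreement_group <- function(supervised, raters) {
  raters <- as.data.frame(raters)
  if (ncol(raters) != 3) abort("exactly 3 rater label columns are required")
  supervised <- as.character(choro_label_factor(supervised))
  for (j in 1:3) raters[[j]] <- as.character(choro_label_factor(raters[[j]]))
  n_match <- rowSums(raters == supervised)
  tibble(
    supervised = supervised,
    rater1 = raters[[1]], rater2 = raters[[2]], rater3 = raters[[3]],
    n_match = as.integer(n_match),
    group = factor(.agreement_levels[n_match + 1],
                   levels = rev(.agreement_levels), ordered = TRUE)
  )
}

#' Agreement-group by confidence-bin cross-tabulation
#'
#' Joins classifier confidence records with human agreement records on
#' `eye_id` and tabulates, within each agreement group, the percentage
#' of eyes falling in each confidence bin (rows sum to 100%).
#'
#' @param confidence tibble with columns `eye_id`, `cs`.
#' @param agreement tibble with columns `eye_id`, `group` (e.g.
#'   [agreement_group()] output plus `eye_id`).
#' @return An object of class `choro_crosstab`: tibble with `group`,
#'   `bin`, `n`, `pct`, plus attribute `group_totals` (per-group counts
#'   and percentages of all eyes).
#' @export
confidence_crosstab <- function(confidence, agreement) {
  stopifnot(all(c("eye_id", "cs") %in% names(confidence)),
            all(c("eye_id", "group") %in% names(agreement)))
  joined <- dplyr::inner_join(confidence, agreement, by = "eye_id")
  if (nrow(joined) == 0) abort("no eyes in common between the two tables")
  joined$bin <- confidence_bin(joined$cs)
  tab <- joined |>
    dplyr::count(.data$group, .data$bin, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup()
  totals <- joined |>
    dplyr::count(.data$group, .drop = FALSE, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
  structure(tab, group_totals = totals, class = c("choro_crosstab",
                                                  class(tab)))
}

#' Simulate independent human raters
#'
#' Each simulated rater independently flips every true label with the
#' rater's error probability; optionally, per-eye difficulty weights
#' scale those probabilities (harder eyes are misread more often),
#' which reproduces the empirical link between rater disagreement and
#' classifier uncertainty.
#'
#' @param labels true labels.
#' @param error length-3 vector of per-rater error probabilities in
#'   \[0, 0.5\].
#' @param difficulty optional per-eye multiplier (>= 0) applied to the
#'   error probabilities (capped at 0.5).
#' @param seed RNG seed.
#' @return A tibble with columns `rater1`, `rater2`, `rater3`.
#' @export
simulate_raters <- function(labels, error = c(0.1, 0.1, 0.1),
                            difficulty = NULL, seed = NULL) {
  if (length(error) != 3 || any(error < 0 | error > 0.5)) {
    abort("`error` must be 3 probabilities in [0, 0.5]")
  }
  labels <- as.character(choro_label_factor(labels))
  n <- length(labels)
  difficulty <- difficulty %||% rep(1, n)
  other <- ifelse(labels == "symmetric", "asymmetric", "symmetric")
  with_seed_if(seed, {
    out <- lapply(1:3, function(j) {
      pj <- pmin(0.5, error[j] * difficulty)
      ifelse(runif(n) < pj, other, labels)
    })
    tibble(rater1 = out[[1]], rater2 = out[[2]], rater3 = out[[3]])
  })
}
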