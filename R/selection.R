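# Wrapper forward feature selection driven by cross-validated CART loss.

#' Number of candidate feature subsets
#'
#' `sum_{k=1}^{max_size} choose(n_features, k)`, the number of non-empty
#' subsets of at most `max_size` features, in exact integer arithmetic.
#'
#' @param n_features Total number of features.
#' @param max_size Largest subset size considered.
#' @return The exact count (numeric, integer-valued).
#' @examples
#' count_subsets(50, 5)  # 2369935
#' count_subsets(16, 5)  # 6884
#' @export
count_subsets <- function(n_features, max_size) {
  if (max_size < 1 || max_size > n_features)
    stop("need 1 <= max_size <= n_features")
  sum(choose(n_features, seq_len(max_size)))
}

#' Feature-selection configuration
#'
#' @param max_subset_size Cap on the number of accepted features; the
#'   default of 5 keeps the subset size at or below half the
#'   training-observation count used to justify the cap (N = 36, so
#'   N_Sub < 6).
#' @param cv_folds Number of cross-validation folds.
#' @param rng_seed Seed for the fold partition.
#' @param one_use One-use-per-feature rule passed to [fit_cart()].
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(max_subset_size = 5L, cv_folds = 5L,
                             rng_seed = 1L, one_use = "global") {
  stopifnot(max_subset_size >= 1, cv_folds >= 2)
  structure(list(max_subset_size = as.integer(max_subset_size),
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed),
                 one_use = one_use),
            class = "selection_config")
}

# Category-stratified fold assignment. Draws are re-attempted with the
# next derived seed (up to max_attempts) if any fold ends up with a
# single class among its training rows or no held-out rows.
stratified_folds <- function(categories, k, seed, max_attempts = 10L) {
  n <- length(categories)
  for (attempt in seq_len(max_attempts)) {
    fold <- integer(n)
    ok <- TRUE
    fold <- with_seed(derive_seed(seed, attempt), {
      fl <- integer(n)
      for (cat in unique(categories)) {
        idx <- which(categories == cat)
        fl[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fl
    })
    for (f in seq_len(k)) {
      train_cats <- categories[fold != f]
      if (sum(fold == f) == 0 || length(unique(train_cats)) < 2) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(fold)
  }
  stop("could not draw folds with both classes in every training split")
}

#' Cross-validated misclassification rate of a feature subset
#'
#' Stratified-by-category k-fold cross-validation: per fold a CART tree
#' is fit on the training rows restricted to `features` and evaluated on
#' the held-out rows; the loss is the pooled misclassification count over
#' all folds divided by the number of rows. Accuracy is `1 - loss`.
#'
#' @param fm A `feature_matrix`.
#' @param features Non-empty character vector of feature names.
#' @param config A [selection_config()].
#' @return Misclassification rate in `[0, 1]`.
#' @export
cv_loss <- function(fm, features, config = selection_config()) {
  if (length(features) == 0) stop("feature subset must be non-empty")
  missing <- setdiff(features, feature_columns(fm))
  if (length(missing))
    stop("features not in matrix: ", paste(missing, collapse = ", "))
  fold <- stratified_folds(fm$category, config$cv_folds, config$rng_seed)
  wrong <- 0L
  for (f in seq_len(config$cv_folds)) {
    train <- fm[fold != f, , drop = FALSE]
    test <- fm[fold == f, , drop = FALSE]
    tree <- fit_cart(train[unique(features)], train$category,
                     features = unique(features), one_use = config$one_use)
    pred <- predict(tree, test[unique(features)])
    wrong <- wrong + sum(pred != test$category)
  }
  wrong / nrow(fm)
}

#' Wrapper forward feature selection
#'
#' Greedy search starting from the empty subset: at every step each
#' not-yet-accepted feature is appended to the current subset and scored
#' with [cv_loss()]; the best candidate (ties broken towards the
#' lexicographically smallest name) is accepted if it strictly improves on
#' the current loss, otherwise the search stops. The empty-model baseline
#' loss is the minority-class proportion (the best label-only
#' classifier). The subset size is capped at
#' `config$max_subset_size`.
#'
#' @param fm A `feature_matrix` with at least 2 rows per category.
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: `accepted_features`
#'   (ordered), `step_losses`, `baseline_loss`, `candidate_evaluations`,
#'   `stopped_reason` (`"no_improvement"` or `"cap_reached"`).
#' @export
forward_select <- function(fm, config = selection_config()) {
  tab <- table(fm$category)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 rows per category")
  all_feats <- sort(feature_columns(fm))
  accepted <- character(0)
  step_losses <- numeric(0)
  current_loss <- min(tab) / sum(tab)
  baseline_loss <- current_loss
  evaluations <- 0L
  stopped_reason <- "cap_reached"
  while (length(accepted) < config$max_subset_size) {
    remaining <- setdiff(all_feats, accepted)
    if (length(remaining) == 0) {
      stopped_reason <- "no_improvement"
      break
    }
    losses <- vapply(remaining, function(f)
      cv_loss(fm, c(accepted, f), config), numeric(1))
    evaluations <- evaluations + length(remaining)
    best <- which.min(losses)  # remaining is sorted: first = smallest name
    if (losses[best] < current_loss) {
      accepted <- c(accepted, remaining[best])
      current_loss <- unname(losses[best])
      step_losses <- c(step_losses, current_loss)
    } else {
      stopped_reason <- "no_improvement"
      break
    }
  }
  structure(list(accepted_features = accepted,
                 step_losses = step_losses,
                 baseline_loss = baseline_loss,
                 candidate_evaluations = evaluations,
                 stopped_reason = stopped_reason,
                 mode = attr(fm, "mode"),
                 sensor = attr(fm, "sensor"),
                 exercise = attr(fm, "exercise")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %s\n",
              x$exercise %||% "?", x$stopped_reason))
  if (length(x$accepted_features)) {
    for (i in seq_along(x$accepted_features)) {
      cat(sprintf("  %d. %-14s cv loss %.4f\n", i, x$accepted_features[i],
                  x$step_losses[i]))
    }
  } else {
    cat(sprintf("  no feature beat the baseline loss %.4f\n",
                x$baseline_loss))
  }
  invisible(x)
}
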