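# Classification metrics and leave-one-subject-out validation.

#' Confusion-based evaluation report
#'
#' Pools predictions into a confusion table with TCM as the positive
#' class and derives accuracy, sensitivity and specificity.
#'
#' @param truth,pred Character vectors of true and predicted labels
#'   (`"CPE"`/`"TCM"`).
#' @return An object of class `evaluation_report` with elements
#'   `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (named counts TP/TN/FP/FN) and `n`.
#' @export
evaluation_report <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% CATEGORIES), all(pred %in% CATEGORIES))
  tp <- sum(truth == "TCM" & pred == "TCM")
  tn <- sum(truth == "CPE" & pred == "CPE")
  fp <- sum(truth == "CPE" & pred == "TCM")
  fn <- sum(truth == "TCM" & pred == "CPE")
  n <- tp + tn + fp + fn
  structure(list(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    n = n),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n = %d: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    x$n, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  confusion (TCM positive): TP %d, TN %d, FP %d, FN %d\n",
              x$confusion["TP"], x$confusion["TN"], x$confusion["FP"],
              x$confusion["FN"]))
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' Each subject in turn is held out entirely: a CART tree is fit on all
#' other subjects' rows (restricted to `features`) and used to predict
#' the held-out subject's rows, so test data always comes from an unseen
#' individual. Confusion counts are pooled over subjects.
#'
#' With `scaling = "as_is"` the matrix is used as scaled once over all
#' rows (the study's normalization of the completed feature table; note
#' this lets scaling statistics leak across the split). With
#' `scaling = "train_only"` features are re-standardized per fold from
#' the raw values of the training subjects only.
#'
#' @param fm A `feature_matrix` with >= 2 subjects.
#' @param features Feature names to use; an empty set yields the
#'   majority-class model.
#' @param scaling `"as_is"` or `"train_only"`.
#' @param one_use One-use-per-feature rule passed to [fit_cart()].
#' @return An `evaluation_report` with an extra `per_subject` data frame
#'   (subject, rows, errors).
#' @export
loso_evaluate <- function(fm, features, scaling = c("as_is", "train_only"),
                          one_use = "global") {
  scaling <- match.arg(scaling)
  subjects <- unique(fm$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  features <- unique(features)
  truth <- character(0)
  pred <- character(0)
  per_subject <- list()
  raw <- attr(fm, "raw_features")
  for (s in subjects) {
    hold <- fm$subject_id == s
    if (length(features) == 0) {
      tab <- table(fm$category[!hold])
      maj <- if (isTRUE(tab["TCM"] > tab["CPE"])) "TCM" else "CPE"
      p <- rep(maj, sum(hold))
    } else if (scaling == "train_only") {
      if (is.null(raw)) stop("train_only scaling needs raw feature values")
      tr <- raw[!hold, features, drop = FALSE]
      mu <- colMeans(tr)
      sd_pop <- sqrt(colMeans(sweep(tr, 2, mu)^2))
      sd_pop[sd_pop == 0] <- 1
      scale_rows <- function(m)
        as.data.frame(sweep(sweep(m, 2, mu), 2, sd_pop, "/"))
      tree <- fit_cart(scale_rows(tr), fm$category[!hold],
                       features = features, one_use = one_use)
      p <- predict(tree, scale_rows(raw[hold, features, drop = FALSE]))
    } else {
      tree <- fit_cart(fm[!hold, features, drop = FALSE],
                       fm$category[!hold], features = features,
                       one_use = one_use)
      p <- predict(tree, fm[hold, features, drop = FALSE])
    }
    truth <- c(truth, fm$category[hold])
    pred <- c(pred, p)
    per_subject[[s]] <- data.frame(subject_id = s, rows = sum(hold),
                                   errors = sum(p != fm$category[hold]),
                                   stringsAsFactors = FALSE)
  }
  rep <- evaluation_report(truth, pred)
  rep$per_subject <- do.call(rbind, c(per_subject, make.row.names = FALSE))
  rep
}
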