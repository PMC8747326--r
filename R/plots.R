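# Scatter plots of the selected feature space with fitted split values.

# Split values used by a tree for a given feature (global one-use implies
# at most one).
tree_split_values <- function(node, feature) {
  if (node$type == "leaf") return(numeric(0))
  c(if (identical(node$feature, feature)) node$split_value,
    tree_split_values(node$left, feature),
    tree_split_values(node$right, feature))
}

#' Scatter plot of observations in the selected feature space
#'
#' One point per set, coloured by category, with dashed lines at the
#' fitted split values. One selected feature gives a one-dimensional
#' strip plot (feature value vs. set number), two give a plane.
#'
#' @param fm A `feature_matrix`.
#' @param features One or two feature names.
#' @param tree Optional `cart_tree`; its split values for `features` are
#'   drawn as dashed lines.
#' @param splits Optional named numeric vector of split values, used when
#'   no tree is given.
#' @return Invisibly, `NULL`.
#' @export
plot_decision_scatter <- function(fm, features, tree = NULL,
                                  splits = NULL) {
  stopifnot(length(features) %in% 1:2,
            all(features %in% feature_columns(fm)))
  split_for <- function(f) {
    if (!is.null(tree)) return(tree_split_values(tree$root, f))
    if (!is.null(splits) && f %in% names(splits)) return(splits[[f]])
    numeric(0)
  }
  col <- ifelse(fm$category == "TCM", "#d95f02", "#1b9e77")
  pch <- ifelse(fm$category == "TCM", 17, 16)
  if (length(features) == 1) {
    graphics::plot(seq_len(nrow(fm)), fm[[features]], col = col,
                   pch = pch, xlab = "set", ylab = features,
                   main = attr(fm, "exercise"))
    for (s in split_for(features))
      graphics::abline(h = s, lty = 2)
  } else {
    graphics::plot(fm[[features[1]]], fm[[features[2]]], col = col,
                   pch = pch, xlab = features[1], ylab = features[2],
                   main = attr(fm, "exercise"))
    for (s in split_for(features[1])) graphics::abline(v = s, lty = 2)
    for (s in split_for(features[2])) graphics::abline(h = s, lty = 2)
  }
  graphics::legend("topright", legend = c("CPE", "TCM"),
                   col = c("#1b9e77", "#d95f02"), pch = c(16, 17),
                   bty = "n")
  invisible(NULL)
}
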