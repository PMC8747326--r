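# Binary CART with Gini impurity and a one-use-per-feature rule.
#
# Split quality comparisons are done in exact integer arithmetic: for a
# split into (n_l, t_l) / (n_r, t_r) (sizes and positive-class counts)
# the child-count-weighted Gini is
#   w = (n_l g_l + n_r g_r) / n = n - (A/n_l + B/n_r), up to 1/n,
# with A = t_l^2 + (n_l - t_l)^2 and B likewise, so minimising w is
# equivalent to maximising the integer "purity score"
#   A * n_r + B * n_l   (common denominator n_l * n_r).
# All counts are bounded by the row count, so the products stay exact in
# doubles.

#' Gini impurity
#'
#' `G = 1 - sum(p_k^2)` over the class proportions of a node. For a binary
#' problem `G = 0` is perfect purity and `G = 0.5` an equal class split.
#'
#' @param p Numeric vector of non-negative class proportions summing to 1.
#' @return The Gini impurity.
#' @examples
#' gini_index(c(0.5, 0.5))  # 0.5
#' gini_index(c(1, 0))      # 0
#' @export
gini_index <- function(p) {
  if (!is.numeric(p) || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("class proportions must be non-negative and sum to 1")
  1 - sum(p^2)
}

gini_from_counts <- function(n_pos, n_tot) {
  if (n_tot == 0) return(0)
  p <- n_pos / n_tot
  1 - p^2 - (1 - p)^2
}

# Integer purity score of the trivial "no split" node, on the same
# n_l * n_r denominator scale is not comparable; instead the improvement
# test against the parent is done by cross-multiplication, see fit_cart.

#' Best Gini split of one feature
#'
#' Scans every midpoint between consecutive distinct sorted values of `x`
#' and returns the threshold minimising the child-count-weighted Gini
#' impurity; rows with `x < threshold` go left. Ties are broken towards
#' the smallest threshold.
#'
#' @param x Numeric feature values.
#' @param y Class labels (`"CPE"`/`"TCM"`).
#' @return `NULL` when `x` has fewer than 2 distinct values (no-split
#'   signal), else a list with `split_value`, `gini` (weighted child
#'   impurity) and the exact rational purity score (`score_num`,
#'   `score_den`) used for tie-free comparisons.
#' @export
best_split <- function(x, y) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  cut_after <- which(diff(xs) > 0)
  if (length(cut_after) == 0) return(NULL)
  cum_pos <- cumsum(ys == "TCM")
  t_tot <- cum_pos[n]
  n_l <- cut_after
  t_l <- cum_pos[cut_after]
  n_r <- n - n_l
  t_r <- t_tot - t_l
  a <- t_l^2 + (n_l - t_l)^2
  b <- t_r^2 + (n_r - t_r)^2
  # purity score as an exact rational num/den = A/n_l + B/n_r; maximise it
  num <- a * n_r + b * n_l
  den <- n_l * n_r
  # double ratio locates near-ties, exact cross-multiplication settles them
  rel <- num / den
  cand <- which(rel >= max(rel) * (1 - 1e-9))
  best <- cand[1]
  for (j in cand[-1]) {
    if (num[j] * den[best] > num[best] * den[j]) best <- j
  }
  i <- cut_after[best]
  g_l <- gini_from_counts(t_l[best], n_l[best])
  g_r <- gini_from_counts(t_r[best], n_r[best])
  list(split_value = (xs[i] + xs[i + 1]) / 2,
       gini = (n_l[best] * g_l + n_r[best] * g_r) / n,
       score_num = num[best], score_den = den[best])
}

#' Fit a CART decision tree
#'
#' Recursive binary splitting with Gini impurity. At each node the
#' (feature, threshold) pair minimising the child-count-weighted Gini
#' among the still-available features is chosen; splitting stops at pure
#' nodes, when the features are exhausted, or when no split reduces
#' impurity. Leaves carry the majority class, ties going to `"CPE"`
#' (compensation is only flagged on evidence). Each feature is used at
#' most once in the whole tree by default (`one_use = "global"`, the
#' strict reading of the rule); `"per_path"` restricts reuse only along
#' root-to-leaf paths.
#'
#' @param x Data frame or matrix of feature values.
#' @param y Class labels (`"CPE"`/`"TCM"`), one per row.
#' @param features Feature names usable by the tree (columns of `x`).
#' @param one_use `"global"` or `"per_path"`.
#' @return An object of class `cart_tree`.
#' @export
fit_cart <- function(x, y, features = colnames(x),
                     one_use = c("global", "per_path")) {
  one_use <- match.arg(one_use)
  x <- as.data.frame(x)
  if (nrow(x) < 1) stop("need at least one row")
  y <- as.character(y)
  stopifnot(length(y) == nrow(x), all(y %in% CATEGORIES))
  missing <- setdiff(features, colnames(x))
  if (length(missing))
    stop("features not in data: ", paste(missing, collapse = ", "))
  features <- sort(unique(features))

  env <- new.env(parent = emptyenv())
  env$used <- character(0)

  build <- function(rows) {
    n <- length(rows)
    n_pos <- sum(y[rows] == "TCM")
    counts <- c(CPE = n - n_pos, TCM = n_pos)
    g <- gini_from_counts(n_pos, n)
    majority <- if (n_pos > n - n_pos) "TCM" else "CPE"
    leaf <- list(type = "leaf", class = majority, counts = counts, gini = g)
    avail <- setdiff(features, env$used)
    if (g == 0 || n < 2 || length(avail) == 0) return(leaf)
    best <- NULL
    for (f in avail) {
      sp <- best_split(x[rows, f], y[rows])
      if (is.null(sp)) next
      if (is.null(best) ||
          sp$score_num * best$score_den > best$score_num * sp$score_den) {
        best <- sp
        best$feature <- f
      }
    }
    if (is.null(best)) return(leaf)
    # strict improvement over the parent, compared exactly:
    # weighted child impurity < parent impurity
    #   <=>  A/n_l + B/n_r > (t^2 + (n-t)^2) / n
    parent_num <- n_pos^2 + (n - n_pos)^2
    if (!(best$score_num * n > parent_num * best$score_den)) return(leaf)
    env$used <- c(env$used, best$feature)
    go_left <- x[rows, best$feature] < best$split_value
    # global one-use: the left subtree is grown first and its features are
    # excluded from the right subtree as well
    left <- build(rows[go_left])
    right <- build(rows[!go_left])
    list(type = "split", feature = best$feature,
         split_value = best$split_value, counts = counts, gini = g,
         left = left, right = right)
  }

  root <- if (one_use == "per_path") {
    build_pp <- function(rows, blocked) {
      n <- length(rows)
      n_pos <- sum(y[rows] == "TCM")
      counts <- c(CPE = n - n_pos, TCM = n_pos)
      g <- gini_from_counts(n_pos, n)
      majority <- if (n_pos > n - n_pos) "TCM" else "CPE"
      leaf <- list(type = "leaf", class = majority, counts = counts,
                   gini = g)
      avail <- setdiff(features, blocked)
      if (g == 0 || n < 2 || length(avail) == 0) return(leaf)
      best <- NULL
      for (f in avail) {
        sp <- best_split(x[rows, f], y[rows])
        if (is.null(sp)) next
        if (is.null(best) ||
            sp$score_num * best$score_den > best$score_num * sp$score_den) {
          best <- sp
          best$feature <- f
        }
      }
      parent_num <- n_pos^2 + (n - n_pos)^2
      if (is.null(best) ||
          !(best$score_num * n > parent_num * best$score_den)) return(leaf)
      go_left <- x[rows, best$feature] < best$split_value
      list(type = "split", feature = best$feature,
           split_value = best$split_value, counts = counts, gini = g,
           left = build_pp(rows[go_left], c(blocked, best$feature)),
           right = build_pp(rows[!go_left], c(blocked, best$feature)))
    }
    build_pp(seq_len(nrow(x)), character(0))
  } else {
    build(seq_len(nrow(x)))
  }

  structure(list(root = root, features = features, one_use = one_use,
                 n_train = nrow(x)),
            class = "cart_tree")
}

tree_features_used <- function(node) {
  if (node$type == "leaf") return(character(0))
  c(node$feature, tree_features_used(node$left),
    tree_features_used(node$right))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Predict classes with a fitted CART tree
#'
#' Deterministic root-to-leaf traversal; rows with feature value strictly
#' below a node's split value go left, all others (including values equal
#' to the split) go right.
#'
#' @param object A `cart_tree`.
#' @param newdata Data frame containing every feature used by the tree.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  used <- unique(tree_features_used(object$root))
  missing <- setdiff(used, colnames(newdata))
  if (length(missing))
    stop("newdata lacks tree feature(s): ", paste(missing, collapse = ", "))
  classify <- function(node, row) {
    while (node$type != "leaf") {
      v <- row[[node$feature]]
      if (is.na(v)) stop("missing value for feature ", node$feature)
      node <- if (v < node$split_value) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i)
    classify(object$root, newdata[i, , drop = FALSE]), character(1))
}

#' @export
print.cart_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s<leaf> %s (CPE %d / TCM %d, gini %.3f)\n", pad,
                  node$class, node$counts["CPE"], node$counts["TCM"],
                  node$gini))
    } else {
      cat(sprintf("%s%s < %.4g ? (CPE %d / TCM %d, gini %.3f)\n", pad,
                  node$feature, node$split_value, node$counts["CPE"],
                  node$counts["TCM"], node$gini))
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  cat(sprintf("<cart_tree> %d training rows, one_use = %s\n", x$n_train,
              x$one_use))
  show(x$root, 1)
  invisible(x)
}
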