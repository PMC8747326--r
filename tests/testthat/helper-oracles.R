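# Independent reference implementations used to cross-check the tree
# module: plain loop-based code with explicit subsetting, structured
# nothing like the vectorized package internals. Comparisons of split
# quality use exact rational arithmetic (cross-multiplied numerators), as
# any correct implementation must to be deterministic under ties.

oracle_gini_counts <- function(labels) {
  n <- length(labels)
  if (n == 0) return(0)
  p1 <- sum(labels == "TCM") / n
  1 - p1^2 - (1 - p1)^2
}

# Exhaustive scan over every midpoint between consecutive distinct sorted
# values; returns NULL when no split exists.
oracle_best_split <- function(x, y) {
  vals <- sort(unique(x))
  if (length(vals) < 2) return(NULL)
  n <- length(x)
  best <- NULL
  for (i in seq_len(length(vals) - 1)) {
    thr <- (vals[i] + vals[i + 1]) / 2
    left <- y[x < thr]
    right <- y[x >= thr]
    nl <- length(left)
    nr <- length(right)
    tl <- sum(left == "TCM")
    tr <- sum(right == "TCM")
    num <- (tl^2 + (nl - tl)^2) * nr + (tr^2 + (nr - tr)^2) * nl
    den <- nl * nr
    if (is.null(best) || num * best$den > best$num * den) {
      wg <- (nl * oracle_gini_counts(left) +
             nr * oracle_gini_counts(right)) / n
      best <- list(split_value = thr, gini = wg, num = num, den = den)
    }
  }
  best
}

# Greedy recursive partitioning with the global one-use rule, tracking
# used features through in-order (left before right) growth.
oracle_fit_cart <- function(x, y, features) {
  used <- character(0)
  grow <- function(rows) {
    lbl <- y[rows]
    n_pos <- sum(lbl == "TCM")
    n <- length(rows)
    leaf <- list(type = "leaf",
                 class = if (n_pos > n - n_pos) "TCM" else "CPE")
    avail <- setdiff(sort(features), used)
    if (n < 2 || n_pos == 0 || n_pos == n || length(avail) == 0)
      return(leaf)
    best <- NULL
    for (f in avail) {
      sp <- oracle_best_split(x[rows, f], lbl)
      if (is.null(sp)) next
      if (is.null(best) || sp$num * best$den > best$num * sp$den) {
        best <- sp
        best$feature <- f
      }
    }
    if (is.null(best)) return(leaf)
    parent_num <- n_pos^2 + (n - n_pos)^2
    if (!(best$num * n > parent_num * best$den)) return(leaf)
    used <<- c(used, best$feature)
    lrows <- rows[x[rows, best$feature] < best$split_value]
    rrows <- rows[x[rows, best$feature] >= best$split_value]
    lft <- grow(lrows)
    rgt <- grow(rrows)
    list(type = "split", feature = best$feature,
         split_value = best$split_value, left = lft, right = rgt)
  }
  grow(seq_len(nrow(x)))
}

oracle_predict_one <- function(node, row) {
  while (node$type != "leaf") {
    node <- if (row[[node$feature]] < node$split_value) node$left
            else node$right
  }
  node$class
}

oracle_training_errors <- function(node, x, y) {
  sum(vapply(seq_len(nrow(x)), function(i)
    oracle_predict_one(node, x[i, , drop = FALSE]), character(1)) != y)
}

# Minimum training errors over ALL trees that respect the global one-use
# rule, by brute-force enumeration (feasible for <= 3 features and a
# handful of rows). Features used in one subtree are unavailable in the
# other.
oracle_optimal_errors <- function(x, y, features) {
  solve <- function(rows, avail) {
    lbl <- y[rows]
    n_pos <- sum(lbl == "TCM")
    best <- min(n_pos, length(rows) - n_pos)  # best leaf
    if (best == 0 || length(avail) == 0) return(best)
    for (f in avail) {
      vals <- sort(unique(x[rows, f]))
      if (length(vals) < 2) next
      rest <- setdiff(avail, f)
      subsets <- list(character(0))
      for (r in rest) subsets <- c(subsets, lapply(subsets, c, r))
      for (i in seq_len(length(vals) - 1)) {
        thr <- (vals[i] + vals[i + 1]) / 2
        lrows <- rows[x[rows, f] < thr]
        rrows <- rows[x[rows, f] >= thr]
        for (sub in subsets) {
          e <- solve(lrows, sub) + solve(rrows, setdiff(rest, sub))
          if (e < best) best <- e
        }
      }
    }
    best
  }
  solve(seq_len(nrow(x)), sort(features))
}

# Strip a package cart_tree node down to the fields the oracle produces.
strip_tree <- function(node) {
  if (node$type == "leaf") return(list(type = "leaf", class = node$class))
  list(type = "split", feature = node$feature,
       split_value = node$split_value,
       left = strip_tree(node$left), right = strip_tree(node$right))
}

# Random small classification datasets with clumpy ("binary-ish") feature
# values so that ties and degenerate columns occur often.
random_small_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  p <- sample(1:3, 1)
  x <- as.data.frame(matrix(sample(1:4, n * p, replace = TRUE) +
                              sample(c(0, 0.5), n * p, replace = TRUE),
                            n, p))
  colnames(x) <- paste0("f", seq_len(p))
  y <- sample(c("CPE", "TCM"), n, replace = TRUE)
  list(x = x, y = y)
}

# Brute-force subset counter for small n.
oracle_count_subsets <- function(n, kmax) {
  total <- 0
  for (k in seq_len(kmax)) total <- total + nrow(t(utils::combn(n, k)))
  total
}
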