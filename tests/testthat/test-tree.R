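# CART: Gini impurity, split search, one-use rule, prediction, metrics.

test_that("gini index matches its defining endpoints and hand values", {
  expect_equal(gini_index(c(0.5, 0.5)), 0.5)
  expect_equal(gini_index(c(1, 0)), 0)
  expect_equal(gini_index(c(0.75, 0.25)), 0.375)
  expect_equal(gini_index(c(1 / 3, 1 / 3, 1 / 3)), 2 / 3)
  expect_error(gini_index(c(0.7, 0.7)), "sum to 1")
  expect_error(gini_index(c(-0.2, 1.2)), "non-negative")
})

test_that("best_split finds the pure midpoint and signals no-split", {
  sp <- best_split(c(1, 2, 3, 4), c("CPE", "CPE", "TCM", "TCM"))
  expect_equal(sp$split_value, 2.5)
  expect_equal(sp$gini, 0)
  expect_null(best_split(c(2, 2, 2), c("CPE", "TCM", "CPE")))
  # alternating labels: no pure split exists, impurity must stay positive
  sp2 <- best_split(c(1, 2, 3, 4), c("CPE", "TCM", "CPE", "TCM"))
  expect_gt(sp2$gini, 0)
  o <- oracle_best_split(c(1, 2, 3, 4), c("CPE", "TCM", "CPE", "TCM"))
  expect_equal(sp2$split_value, o$split_value)
  expect_equal(sp2$gini, o$gini)
})

test_that("best_split agrees with the exhaustive oracle on random data", {
  for (seed in 1:200) {
    d <- random_small_dataset(seed)
    sp <- best_split(d$x[[1]], d$y)
    o <- oracle_best_split(d$x[[1]], d$y)
    if (is.null(o)) {
      expect_null(sp)
    } else {
      expect_equal(sp$split_value, o$split_value, info = paste("seed", seed))
      expect_equal(sp$gini, o$gini, info = paste("seed", seed))
    }
  }
})

tree_features_used_test <- function(tree) {
  rec <- function(n) {
    if (n$type == "leaf") return(character(0))
    c(n$feature, rec(n$left), rec(n$right))
  }
  rec(tree$root)
}

test_that("fit_cart reproduces a hand-built two-feature truth table", {
  # TCM exactly when f1 high and f2 high: needs both features
  x <- data.frame(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  y <- c("CPE", "CPE", "CPE", "TCM")
  tree <- fit_cart(x, y)
  expect_equal(sort(unique(tree_features_used_test(tree))), c("f1", "f2"))
  expect_equal(predict(tree, x), y)
  # pure input: single leaf
  t2 <- fit_cart(x, rep("CPE", 4))
  expect_equal(t2$root$type, "leaf")
  expect_equal(t2$root$class, "CPE")
  # empty feature set: majority leaf, ties to CPE
  t3 <- fit_cart(x, c("CPE", "CPE", "TCM", "TCM"),
                 features = character(0))
  expect_equal(t3$root$type, "leaf")
  expect_equal(t3$root$class, "CPE")
})

test_that("every feature is used at most once in the whole tree", {
  for (seed in 1:50) {
    d <- random_small_dataset(seed)
    tree <- fit_cart(d$x, d$y)
    used <- tree_features_used_test(tree)
    expect_true(all(table(used) == 1), info = paste("seed", seed))
    expect_lte(length(used), ncol(d$x))
  }
})

test_that("splits never decrease purity along the tree", {
  walk <- function(node) {
    if (node$type == "leaf") return(invisible())
    n_l <- sum(node$left$counts)
    n_r <- sum(node$right$counts)
    weighted <- (n_l * node$left$gini + n_r * node$right$gini) /
      (n_l + n_r)
    expect_lt(weighted, node$gini + 1e-12)
    walk(node$left)
    walk(node$right)
  }
  for (seed in c(3, 17, 31)) {
    d <- random_small_dataset(seed)
    walk(fit_cart(d$x, d$y)$root)
  }
  fm <- small_feature_matrix()
  walk(fit_cart(fm[feature_columns(fm)], fm$category)$root)
})

test_that("prediction at the split boundary goes right and is pure", {
  x <- data.frame(f = c(1, 2, 3, 4))
  y <- c("CPE", "CPE", "TCM", "TCM")
  tree <- fit_cart(x, y)
  expect_equal(tree$root$split_value, 2.5)
  expect_equal(predict(tree, data.frame(f = 2.5)), "TCM")  # not-less goes right
  expect_equal(predict(tree, data.frame(f = 2.4999)), "CPE")
  # pure function: repeated calls identical
  nd <- data.frame(f = runif(20, 0, 5))
  expect_identical(predict(tree, nd), predict(tree, nd))
  expect_error(predict(tree, data.frame(g = 1)), "lacks tree feature")
})

test_that("fit_cart matches the loop-based greedy oracle exactly", {
  for (seed in 1:150) {
    d <- random_small_dataset(seed)
    tree <- fit_cart(d$x, d$y)
    oracle <- oracle_fit_cart(d$x, d$y, colnames(d$x))
    expect_identical(strip_tree(tree$root), oracle,
                     info = paste("seed", seed))
  }
})

test_that("greedy training loss is bounded below by the global optimum", {
  for (seed in 1:60) {
    d <- random_small_dataset(seed)
    tree <- fit_cart(d$x, d$y)
    greedy_err <- sum(predict(tree, d$x) != d$y)
    opt_err <- oracle_optimal_errors(d$x, d$y, colnames(d$x))
    expect_gte(greedy_err, opt_err)
  }
})

test_that("first split agrees with rpart on cleanly separable data", {
  skip_if_not_installed("rpart")
  set.seed(21)
  for (i in 1:10) {
    n <- 30
    y <- rep(c("CPE", "TCM"), each = n / 2)
    x <- data.frame(f = c(rnorm(n / 2, -2), rnorm(n / 2, 2)))
    mine <- fit_cart(x, y)
    rp <- rpart::rpart(factor(y) ~ f, data = x,
                       control = rpart::rpart.control(minsplit = 2,
                                                      cp = 0,
                                                      maxdepth = 1))
    expect_equal(mine$root$split_value, rp$splits[1, "index"],
                 tolerance = 1e-9)
    expect_equal(unname(predict(mine, x)), unname(as.character(
      predict(rp, x, type = "class"))))
  }
})

test_that("evaluation identities hold with TCM as the positive class", {
  truth <- c("TCM", "TCM", "TCM", "CPE", "CPE", "CPE", "CPE")
  pred <- c("TCM", "TCM", "CPE", "CPE", "CPE", "TCM", "CPE")
  r <- evaluation_report(truth, pred)
  cf <- r$confusion
  expect_equal(unname(cf), c(2, 3, 1, 1))  # TP TN FP FN
  expect_equal(r$accuracy, (cf["TP"] + cf["TN"]) / sum(cf),
               ignore_attr = TRUE)
  expect_equal(r$sensitivity, cf["TP"] / (cf["TP"] + cf["FN"]),
               ignore_attr = TRUE)
  expect_equal(r$specificity, cf["TN"] / (cf["TN"] + cf["FP"]),
               ignore_attr = TRUE)
})

test_that("LOSO holds each subject out exactly once", {
  fm <- separable_matrix()
  rep <- loso_evaluate(fm, "good_feature")
  expect_equal(nrow(rep$per_subject), 6)
  expect_equal(sum(rep$per_subject$rows), nrow(fm))
  expect_equal(rep$accuracy, 1)
  # two subjects: exactly two folds
  fm2 <- separable_matrix(n_subjects = 2)
  rep2 <- loso_evaluate(fm2, "good_feature")
  expect_equal(nrow(rep2$per_subject), 2)
  # empty feature set falls back to the majority model
  rep3 <- loso_evaluate(fm, character(0))
  expect_equal(rep3$accuracy, 0.5)
})

test_that("model JSON round-trips to identical predictions", {
  fm <- small_feature_matrix()
  feats <- c("var_Y2", "aRMS_Y2", "maxdphi_1_2")
  tree <- fit_cart(fm[feats], fm$category, features = feats)
  path <- file.path(tempdir(), "model_roundtrip.json")
  write_model_json(tree, path)
  back <- read_model_json(path)
  expect_equal(predict(back, fm[feats]), predict(tree, fm[feats]))
  unlink(path)
})
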