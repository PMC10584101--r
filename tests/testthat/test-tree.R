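test_that("Gini impurity follows its definition", {
  expect_equal(gini_impurity(c(50, 50)), 0.5)
  expect_equal(gini_impurity(c(100, 0)), 0)
  expect_equal(gini_impurity(c(70, 30)), 0.42)
  expect_error(gini_impurity(c(0, 0)), "not all zero")
  expect_error(gini_impurity(c(-1, 5)), "non-negative")
})

test_that("a perfectly separable feature yields a depth-1 pure tree", {
  feats <- data.frame(Lambda = c(runif(30, 0, 0.2), runif(30, 0.6, 1)))
  labels <- rep(c("normal", "glaucoma"), each = 30)
  tree <- fit_tree(feats, labels, n_perm = 199, seed = 1)
  expect_false(tree$root$is_leaf)
  expect_identical(tree$root$split_feature, "Lambda")
  expect_true(tree$root$left$is_leaf && tree$root$right$is_leaf)
  expect_equal(tree$root$left$gini, 0)
  expect_equal(tree$root$right$gini, 0)
  expect_lt(tree$root$p_value, 0.05)
  pred <- predict(tree, feats)
  expect_equal(as.character(pred), labels)
})

test_that("labels independent of features are rarely split", {
  accepted <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    feats <- data.frame(Lambda = runif(60), lambda_star = runif(60))
    labels <- sample(rep(c("normal", "glaucoma"), each = 30))
    tree <- fit_tree(feats, labels, n_perm = 299, seed = 2000 + s)
    !tree$root$is_leaf
  }, logical(1))
  expect_gte(sum(!accepted), 9L)
})

test_that("an upward Lambda shift in glaucoma puts the root split on Lambda", {
  set.seed(3)
  n <- 120
  labels <- rep(c("normal", "glaucoma"), each = n / 2)
  feats <- data.frame(
    Lambda = c(rbeta(n / 2, 1, 6), rbeta(n / 2, 4, 2)),
    noise = runif(n))
  tree <- fit_tree(feats, labels, n_perm = 499, seed = 4)
  expect_identical(tree$root$split_feature, "Lambda")
  expect_gt(tree$root$decrease, 0)
})

test_that("accepted splits strictly reduce impurity and partition counts", {
  set.seed(5)
  feats <- data.frame(Lambda = runif(100), lambda_star = runif(100))
  labels <- ifelse(feats$Lambda + 0.3 * feats$lambda_star +
                     rnorm(100, 0, 0.2) > 0.6, "glaucoma", "normal")
  tree <- fit_tree(feats, labels, n_perm = 199, seed = 6)
  walk <- function(node) {
    if (node$is_leaf) return(invisible(NULL))
    expect_gt(node$decrease, 0)
    expect_equal(node$left$class_counts + node$right$class_counts,
                 node$class_counts)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
})

test_that("an unconstrained tree drives training error to zero", {
  set.seed(7)
  feats <- data.frame(x = runif(40))
  labels <- sample(c("normal", "glaucoma"), 40, replace = TRUE)
  tree <- fit_tree(feats, labels, alpha_split = 1.01, min_node = 2L,
                   max_depth = 30L, n_perm = 9L, seed = 8)
  expect_equal(as.character(predict(tree, feats)), labels)
})

test_that("degenerate single-class input yields a split-free stump", {
  feats <- data.frame(Lambda = runif(20))
  tree <- fit_tree(feats, rep("normal", 20), n_perm = 49, seed = 9)
  expect_true(tree$root$is_leaf)
  expect_identical(tree$root$prediction, "normal")
})

test_that("classifier report matches a brute-force confusion oracle", {
  set.seed(10)
  for (rep_ in 1:5) {
    feats <- data.frame(Lambda = runif(80), lambda_star = runif(80))
    labels <- ifelse(feats$Lambda > runif(80, 0.2, 0.8), "glaucoma", "normal")
    tree <- fit_tree(feats, labels, n_perm = 99, seed = 20 + rep_)
    rep0 <- evaluate_classifier(tree, feats, labels)
    pred <- as.character(predict(tree, feats))
    tn <- sum(pred == "normal" & labels == "normal")
    fp <- sum(pred == "glaucoma" & labels == "normal")
    tp <- sum(pred == "glaucoma" & labels == "glaucoma")
    fn <- sum(pred == "normal" & labels == "glaucoma")
    expect_equal(rep0$specificity, tn / (tn + fp))
    expect_equal(rep0$sensitivity, tp / (tp + fn))
    expect_equal(sum(rep0$confusion), 80)
    expect_equal(sum(rep0$leaf_shares), 1)
  }
})

test_that("specificity extremes: perfect prediction and all-positive calls", {
  feats <- data.frame(Lambda = c(rep(0, 25), rep(1, 25)))
  labels <- rep(c("normal", "glaucoma"), each = 25)
  tree <- fit_tree(feats, labels, n_perm = 199, seed = 11)
  r <- evaluate_classifier(tree, feats, labels)
  expect_equal(r$specificity, 1); expect_equal(r$sensitivity, 1)
  # stump trained on all-glaucoma data predicts glaucoma for everyone
  stump <- fit_tree(data.frame(Lambda = runif(10)), rep("glaucoma", 10),
                    n_perm = 49, seed = 12)
  r2 <- evaluate_classifier(stump, feats, labels)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$sensitivity, 1)
})

test_that("cluster-wise trees generalize the single tree", {
  set.seed(13)
  feats <- data.frame(lambda_star = runif(60))
  labels <- ifelse(feats$lambda_star > 0.5, "glaucoma", "normal")
  single <- fit_tree(feats, labels, n_perm = 199, seed = 14)
  degenerate <- fit_tree_by_cluster(feats, labels, rep(1L, 60),
                                    n_perm = 199, seed = 14)
  expect_identical(as.character(predict(degenerate, feats, rep(1L, 60))),
                   as.character(predict(single, feats)))

  # two clusters with opposite lambda* thresholds: partitioned trees separate
  # what a single threshold cannot
  n2 <- 200
  cl <- rep(1:2, each = n2 / 2)
  ls <- c(runif(n2 / 2, 0, 1), runif(n2 / 2, 0, 1))
  lab2 <- ifelse(cl == 1, ifelse(ls > 0.6, "glaucoma", "normal"),
                 ifelse(ls < 0.4, "glaucoma", "normal"))
  f2 <- data.frame(lambda_star = ls)
  both <- fit_tree_by_cluster(f2, lab2, cl, n_perm = 199, seed = 15)
  pooled <- evaluate_classifier(both, f2, lab2, cluster_labels = cl)
  flat <- evaluate_classifier(fit_tree(f2, lab2, n_perm = 199, seed = 15),
                              f2, lab2)
  expect_gte(pooled$specificity, flat$specificity)
  expect_gt(pooled$specificity, 0.9)
})

test_that("tree text and DOT export reflect the fitted structure", {
  dir <- withr::local_tempdir()
  feats <- data.frame(Lambda = c(runif(20, 0, 0.3), runif(20, 0.7, 1)))
  labels <- rep(c("normal", "glaucoma"), each = 20)
  tree <- fit_tree(feats, labels, n_perm = 199, seed = 16)
  txt <- capture.output(print(tree))
  expect_true(any(grepl("Lambda <=", txt)))
  f <- file.path(dir, "tree.dot")
  export_tree_dot(tree, f)
  dot <- readLines(f)
  expect_true(any(grepl("digraph", dot)))
  expect_true(any(grepl("Lambda", dot)))
})
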