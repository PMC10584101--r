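# Binary decision trees for glaucomatous-versus-normal classification from
# the loss indices (Lambda, lambda*, ...).  Splits are CART-style: greedy
# maximization of the Gini impurity decrease, with a permutation p-value
# guarding each split (labels permuted within the node; the split is kept
# only when the observed best decrease is extreme under the permutation
# null).  Normal is the negative class throughout, so
# specificity = TN / (TN + FP) over normal eyes.

#' Gini impurity of a node
#'
#' `1 - sum_c (n_c / n)^2` over the class counts.
#'
#' @param class_counts non-negative counts, not all zero.
#' @return impurity in \[0, 0.5\] for two classes.
#' @examples
#' gini_impurity(c(70, 30))  # 0.42
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0)
    stop("class counts must be non-negative and not all zero")
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

CLASS_LEVELS <- c("normal", "glaucoma")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS))
    stop("labels must be 'normal' or 'glaucoma'")
  factor(labels, levels = CLASS_LEVELS)
}

# Best Gini split over all features: for each feature, thresholds at
# midpoints between adjacent distinct sorted values; returns the feature,
# threshold and impurity decrease of the best split (NULL when no split
# separates anything).
best_split <- function(features, y01) {
  n <- length(y01)
  parent_gini <- gini_impurity(c(n - sum(y01), sum(y01)))
  best <- NULL
  for (f in names(features)) {
    v <- features[[f]]
    ord <- order(v)
    vs <- v[ord]; ys <- y01[ord]
    cum1 <- cumsum(ys)
    cumn <- seq_len(n)
    # candidate boundaries: between positions i and i+1 with distinct values
    cand <- which(diff(vs) > 0)
    if (!length(cand)) next
    nl <- cumn[cand]; n1l <- cum1[cand]
    nr <- n - nl; n1r <- cum1[n] - n1l
    gl <- 1 - ((n1l / nl)^2 + ((nl - n1l) / nl)^2)
    gr <- 1 - ((n1r / nr)^2 + ((nr - n1r) / nr)^2)
    dec <- parent_gini - (nl * gl + nr * gr) / n
    i <- which.max(dec)
    if (is.null(best) || dec[i] > best$decrease) {
      best <- list(feature = f,
                   threshold = (vs[cand[i]] + vs[cand[i] + 1L]) / 2,
                   decrease = dec[i])
    }
  }
  best
}

# Permutation p-value of the observed best decrease: permute labels within
# the node, re-find the best decrease each time.
split_p_value <- function(features, y01, observed, n_perm) {
  null_dec <- vapply(seq_len(n_perm), function(b) {
    s <- best_split(features, sample(y01))
    if (is.null(s)) 0 else s$decrease
  }, numeric(1))
  (1 + sum(null_dec >= observed)) / (n_perm + 1)
}

grow_node <- function(features, y, depth, alpha_split, min_node, max_depth,
                      n_perm, root_counts) {
  y01 <- as.integer(y) - 1L  # 0 = normal, 1 = glaucoma
  counts <- c(normal = sum(y01 == 0L), glaucoma = sum(y01 == 1L))
  # prevalence-corrected leaf label (equal class priors): the predicted class
  # is the one over-represented relative to the training prevalence, so a
  # rare positive class is not swamped by imbalance; ties go to normal
  share <- ifelse(root_counts > 0L, counts / root_counts, -Inf)
  node <- list(n = length(y01), class_counts = counts,
               gini = gini_impurity(counts),
               prediction = CLASS_LEVELS[1L + (share[2L] > share[1L])],
               is_leaf = TRUE)
  if (depth >= max_depth || length(y01) < min_node ||
      any(counts == 0L) || ncol(features) == 0L)
    return(node)
  s <- best_split(features, y01)
  if (is.null(s) || s$decrease <= 0) return(node)
  p <- split_p_value(features, y01, s$decrease, n_perm)
  if (p >= alpha_split) return(node)
  left_idx <- features[[s$feature]] <= s$threshold
  node$is_leaf <- FALSE
  node$split_feature <- s$feature
  node$split_threshold <- s$threshold
  node$decrease <- s$decrease
  node$p_value <- p
  node$left <- grow_node(features[left_idx, , drop = FALSE], y[left_idx],
                         depth + 1L, alpha_split, min_node, max_depth, n_perm,
                         root_counts)
  node$right <- grow_node(features[!left_idx, , drop = FALSE], y[!left_idx],
                          depth + 1L, alpha_split, min_node, max_depth, n_perm,
                          root_counts)
  node
}

#' Fit a permutation-guarded CART classification tree
#'
#' Greedy binary Gini splitting on the supplied loss-index features.  Each
#' candidate split must pass a label-permutation test (p-value below
#' `alpha_split`) before it is accepted, so trees stay small and every split
#' carries a significance level.  With a single class present, the result is
#' a stump with no splits.
#'
#' @param features data.frame of numeric predictors (e.g. `Lambda`,
#'   `lambda_star`), all finite.
#' @param labels class labels, `"normal"` (negative) or `"glaucoma"`.
#' Leaves are labelled with equal class priors: a leaf predicts the class
#' that is over-represented relative to the training prevalence (ties go to
#' normal), so a rare glaucoma class is not silenced by cohort imbalance.
#'
#' @param alpha_split significance level a split must beat (default 0.05).
#' @param min_node minimum node size eligible for splitting (default 7).
#' @param max_depth maximum tree depth (default 3; root = depth 0).
#' @param n_perm label permutations per tested split (default 1000).
#' @param seed optional RNG seed for the permutation draws.
#' @return object of class `decay_tree` wrapping the recursive node
#'   structure; each internal node carries `split_feature`,
#'   `split_threshold`, `p_value`, `gini`, `class_counts`.
#' @export
fit_tree <- function(features, labels, alpha_split = 0.05, min_node = 7L,
                     max_depth = 3L, n_perm = 1000L, seed = NULL) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1))))
    stop("all features must be numeric")
  if (anyNA(features) || any(!vapply(features, function(v) all(is.finite(v)),
                                     logical(1))))
    stop("features must be finite and non-missing")
  y <- as_label_factor(labels)
  if (length(y) != nrow(features))
    stop("labels and features disagree in length")
  if (!is.null(seed)) set.seed(seed)
  root_counts <- c(normal = sum(y == "normal"), glaucoma = sum(y == "glaucoma"))
  root <- grow_node(features, y, 0L, alpha_split, min_node, max_depth, n_perm,
                    root_counts)
  structure(list(root = root, features = names(features),
                 alpha_split = alpha_split, max_depth = max_depth,
                 min_node = min_node),
            class = "decay_tree")
}

predict_node <- function(node, row) {
  while (!node$is_leaf) {
    node <- if (row[[node$split_feature]] <= node$split_threshold)
      node$left else node$right
  }
  node$prediction
}

#' @param object a `decay_tree`.
#' @param newdata data.frame with the tree's feature columns.
#' @param ... unused.
#' @rdname fit_tree
#' @export
predict.decay_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(miss, collapse = ", "))
  factor(vapply(seq_len(nrow(newdata)),
                function(i) predict_node(object$root, newdata[i, , drop = FALSE]),
                character(1)),
         levels = CLASS_LEVELS)
}

#' Fit one tree per circular cluster
#'
#' Partitions the eyes by their von Mises cluster label first, fits an
#' independent tree within each cluster, and reports pooled performance over
#' all eyes.  A cluster containing a single class yields a stump; an empty
#' cluster is skipped with a warning.
#'
#' @inheritParams fit_tree
#' @param cluster_labels integer (or factor) cluster membership per eye,
#'   e.g. from [assign_clusters()].
#' @return object of class `clustered_trees`: list with `trees` (one
#'   `decay_tree` per non-empty cluster, named by cluster) and `clusters`.
#' @export
fit_tree_by_cluster <- function(features, labels, cluster_labels,
                                alpha_split = 0.05, min_node = 7L,
                                max_depth = 3L, n_perm = 1000L, seed = NULL) {
  features <- as.data.frame(features)
  y <- as_label_factor(labels)
  cl <- as.character(cluster_labels)
  if (length(cl) != nrow(features))
    stop("cluster labels and features disagree in length")
  if (!is.null(seed)) set.seed(seed)
  trees <- list()
  for (g in sort(unique(cl))) {
    idx <- cl == g
    if (!any(idx)) { warning("empty cluster ", g, " skipped"); next }
    trees[[g]] <- fit_tree(features[idx, , drop = FALSE], y[idx],
                           alpha_split = alpha_split, min_node = min_node,
                           max_depth = max_depth, n_perm = n_perm, seed = NULL)
  }
  structure(list(trees = trees, clusters = sort(unique(cl))),
            class = "clustered_trees")
}

#' @param object a `clustered_trees`.
#' @param newdata data.frame of features.
#' @param cluster_labels cluster membership for the rows of `newdata`.
#' @param ... unused.
#' @rdname fit_tree_by_cluster
#' @export
predict.clustered_trees <- function(object, newdata, cluster_labels, ...) {
  newdata <- as.data.frame(newdata)
  cl <- as.character(cluster_labels)
  out <- factor(rep(CLASS_LEVELS[1L], nrow(newdata)), levels = CLASS_LEVELS)
  for (g in names(object$trees)) {
    idx <- cl == g
    if (any(idx))
      out[idx] <- predict(object$trees[[g]], newdata[idx, , drop = FALSE])
  }
  out
}

collect_leaves <- function(node) {
  if (node$is_leaf) return(list(node))
  c(collect_leaves(node$left), collect_leaves(node$right))
}

#' Evaluate a fitted classifier
#'
#' Confusion counts with normal as the negative class, specificity
#' `TN / (TN + FP)`, sensitivity `TP / (TP + FN)`, the maximum leaf Gini
#' impurity, and each leaf's share of the samples.
#'
#' @param model a `decay_tree` or `clustered_trees`.
#' @param features data.frame of features for the evaluated eyes.
#' @param labels true class labels.
#' @param cluster_labels required when `model` is a `clustered_trees`.
#' @return list of class `classifier_report`: `confusion` (2x2 table),
#'   `specificity`, `sensitivity`, `accuracy`, `max_leaf_gini`,
#'   `leaf_shares`.
#' @export
evaluate_classifier <- function(model, features, labels,
                                cluster_labels = NULL) {
  y <- as_label_factor(labels)
  pred <- if (inherits(model, "clustered_trees")) {
    if (is.null(cluster_labels))
      stop("cluster_labels are required for a clustered_trees model")
    predict(model, features, cluster_labels)
  } else predict(model, features)
  tn <- sum(pred == "normal" & y == "normal")
  fp <- sum(pred == "glaucoma" & y == "normal")
  tp <- sum(pred == "glaucoma" & y == "glaucoma")
  fn <- sum(pred == "normal" & y == "glaucoma")
  trees <- if (inherits(model, "clustered_trees")) model$trees
           else list(model)
  leaves <- unlist(lapply(trees, function(t) collect_leaves(t$root)),
                   recursive = FALSE)
  leaf_n <- vapply(leaves, `[[`, numeric(1), "n")
  structure(list(
    confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                       dimnames = list(predicted = CLASS_LEVELS,
                                       truth = CLASS_LEVELS)),
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tn + tp) / length(y),
    max_leaf_gini = max(vapply(leaves, `[[`, numeric(1), "gini")),
    leaf_shares = leaf_n / sum(leaf_n)
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> specificity %.4f, sensitivity %.4f, max leaf Gini %.4f\n",
              x$specificity, x$sensitivity, x$max_leaf_gini))
  print(x$confusion)
  invisible(x)
}

format_node <- function(node, indent, lines) {
  pad <- strrep("  ", indent)
  if (node$is_leaf) {
    c(lines, sprintf("%sleaf: predict %s (normal=%d, glaucoma=%d, gini=%.3f)",
                     pad, node$prediction, node$class_counts[1L],
                     node$class_counts[2L], node$gini))
  } else {
    lines <- c(lines, sprintf("%s%s <= %.4f (p=%.4g, gini=%.3f, n=%d)",
                              pad, node$split_feature, node$split_threshold,
                              node$p_value, node$gini, node$n))
    lines <- format_node(node$left, indent + 1L, lines)
    format_node(node$right, indent + 1L, lines)
  }
}

#' @export
print.decay_tree <- function(x, ...) {
  cat(paste(format_node(x$root, 0L, character(0)), collapse = "\n"), "\n")
  invisible(x)
}

#' Export a tree as a Graphviz DOT description
#' @param tree a `decay_tree`.
#' @param path output `.dot` path.
#' @return `path`, invisibly.
#' @export
export_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "decay_tree"))
  id <- 0L
  lines <- c("digraph decay_tree {", "  node [shape=box];")
  emit <- function(node) {
    my <- id <<- id + 1L
    lab <- if (node$is_leaf)
      sprintf("predict %s\\nN=%d G=%d\\ngini=%.3f", node$prediction,
              node$class_counts[1L], node$class_counts[2L], node$gini)
    else
      sprintf("%s <= %.4f\\np=%.3g", node$split_feature,
              node$split_threshold, node$p_value)
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", my, lab))
    if (!node$is_leaf) {
      l <- emit(node$left); r <- emit(node$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"yes\"];", my, l),
                  sprintf("  n%d -> n%d [label=\"no\"];", my, r))
    }
    my
  }
  emit(tree$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}
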