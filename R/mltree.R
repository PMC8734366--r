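# Minimal CART-style decision tree for the ML-export demonstration.
# No tree-learning package is available in the supported environment, and
# the exported feature tables are meant to be consumed by external ML
# frameworks anyway; this greedy Gini tree exists so the package can
# demonstrate (and test) that the exported features separate classes.

gini <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

grow_tree <- function(X, y, depth, min_n) {
  majority <- names(sort(table(y), decreasing = TRUE))[1L]
  if (depth == 0L || length(unique(y)) == 1L || nrow(X) < min_n) {
    return(list(leaf = TRUE, label = majority))
  }
  best <- NULL
  best_impurity <- Inf
  best_margin <- -Inf
  for (j in seq_len(ncol(X))) {
    v <- X[[j]]
    cuts <- sort(unique(v))
    if (length(cuts) < 2L) next
    spread <- cuts[length(cuts)] - cuts[1L]
    mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
    for (cut in mids) {
      left <- v <= cut
      imp <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / length(y)
      # ties on impurity resolved by the widest normalized gap around the
      # cut: prefers cleanly separated features over incidental splits
      margin <- (min(v[!left]) - max(v[left])) / spread
      if (imp < best_impurity - 1e-12 ||
          (abs(imp - best_impurity) <= 1e-12 && margin > best_margin + 1e-12)) {
        best_impurity <- imp
        best_margin <- margin
        best <- list(feature = j, cut = cut)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, label = majority))
  left <- X[[best$feature]] <= best$cut
  list(
    leaf = FALSE, feature = best$feature, cut = best$cut, label = majority,
    left = grow_tree(X[left, , drop = FALSE], y[left], depth - 1L, min_n),
    right = grow_tree(X[!left, , drop = FALSE], y[!left], depth - 1L, min_n)
  )
}

#' Fit a small decision tree (demonstration classifier)
#'
#' Greedy CART-style tree with Gini impurity on numeric features. Intended
#' for demonstrating that exported feature tables ([export_ml_features()])
#' separate sample classes, not as a general-purpose learner.
#'
#' @param X data.frame of numeric features.
#' @param y factor or character class labels.
#' @param max_depth maximum tree depth (default 3).
#' @param min_n minimum node size to split (default 2).
#' @return object of class `stump_tree`.
#' @export
stump_tree <- function(X, y, max_depth = 3L, min_n = 2L) {
  stopifnot(nrow(X) == length(y), nrow(X) > 0L)
  y <- as.character(y)
  structure(grow_tree(as.data.frame(X), y, max_depth, min_n),
    class = "stump_tree")
}

#' @export
predict.stump_tree <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$feature]] <= node$cut) node$left else node$right
    }
    node$label
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    one(object, as.numeric(newdata[i, , drop = TRUE]))
  }, character(1L))
}

#' k-fold cross-validated accuracy of the demonstration tree
#'
#' @param X data.frame of numeric features.
#' @param y class labels.
#' @param folds number of folds (default 3).
#' @param seed integer seed for the fold assignment (stratified).
#' @param max_depth passed to [stump_tree()].
#' @return mean held-out accuracy across folds.
#' @export
cv_tree_accuracy <- function(X, y, folds = 3L, seed = 1L, max_depth = 3L) {
  y <- as.character(y)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  accs <- vapply(seq_len(folds), function(f) {
    train <- fold_id != f
    if (length(unique(y[train])) < 2L) return(NA_real_)
    tree <- stump_tree(X[train, , drop = FALSE], y[train], max_depth = max_depth)
    pred <- predict(tree, X[!train, , drop = FALSE])
    mean(pred == y[!train])
  }, numeric(1L))
  mean(accs, na.rm = TRUE)
}
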