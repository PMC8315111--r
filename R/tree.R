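#' Regression-tree building blocks
#'
#' A tree is a nested list. A leaf is `list(leaf = TRUE, value, depth)`; an
#' internal node is `list(leaf = FALSE, var, split, left, right, depth)` with
#' the rule "x[var] <= split goes left". These are the single-tree primitives
#' of the sum-of-trees model; the fast sampler in [run_sampler()] uses an
#' equivalent serialized representation.
#'
#' @param value leaf value (response units).
#' @param depth node depth; the root has depth 0.
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
tree_leaf <- function(value = 0, depth = 0L) {
  list(leaf = TRUE, value = value, depth = as.integer(depth))
}

#' @rdname tree-nodes
#' @param var predictor index (1-based) of the split rule.
#' @param split threshold; rows with `x[var] <= split` go left.
#' @param left,right child nodes.
#' @export
tree_split <- function(var, split, left, right, depth = 0L) {
  node <- list(leaf = FALSE, var = as.integer(var), split = split,
               left = left, right = right, depth = as.integer(depth))
  node$left$depth <- node$depth + 1L
  node$right$depth <- node$depth + 1L
  node
}

#' Route one predictor vector through a tree
#'
#' Follows the split rules (`<=` goes left) until a terminal node is reached
#' and returns its leaf value.
#'
#' @param tree a tree built from [tree_leaf()] / [tree_split()].
#' @param x numeric predictor vector (or matrix with rows as observations).
#' @param p expected predictor count; when supplied, `x` of a different length
#'   is an error.
#' @return leaf value(s).
#' @export
tree_predict <- function(tree, x, p = NULL) {
  if (is.matrix(x)) return(apply(x, 1, function(r) tree_predict(tree, r, p)))
  if (!is.null(p) && length(x) != p) {
    stop("x has length ", length(x), ", expected ", p)
  }
  node <- tree
  while (!node$leaf) {
    if (node$var > length(x)) stop("x too short for split on predictor ", node$var)
    node <- if (x[node$var] <= node$split) node$left else node$right
  }
  node$value
}

#' Sum-of-trees prediction
#'
#' @param forest a list of trees.
#' @inheritParams tree_predict
#' @return sum over trees of [tree_predict()].
#' @export
forest_predict <- function(forest, x, p = NULL) {
  if (length(forest) == 0) stop("empty forest")
  preds <- lapply(forest, tree_predict, x = x, p = p)
  Reduce(`+`, preds)
}

#' Depth-dependent split probability
#'
#' The prior probability that a node at depth `d` is internal,
#' `alpha * (1 + d)^(-beta)` with `alpha` in (0, 1) and `beta >= 0`. Larger
#' `alpha` and `beta` favour smaller trees.
#'
#' @param depth nonnegative node depth (vectorized).
#' @param alpha base probability in (0, 1).
#' @param beta depth-decay power, >= 0.
#' @export
split_probability <- function(depth, alpha, beta) {
  stopifnot(all(depth >= 0), alpha > 0, alpha < 1, beta >= 0)
  alpha * (1 + depth)^(-beta)
}

tree_nodes <- function(tree) {
  if (tree$leaf) return(list(tree))
  c(list(tree), tree_nodes(tree$left), tree_nodes(tree$right))
}

tree_leaves <- function(tree) Filter(function(nd) nd$leaf, tree_nodes(tree))

tree_n_leaves <- function(tree) length(tree_leaves(tree))

#' Log prior probability of a tree structure
#'
#' Sums, over internal nodes, the log split probability at that depth plus the
#' log prior of the chosen split variable plus the log of the uniform
#' threshold probability (1 / number of unique observed values of that
#' predictor), and over leaves the log probability of not splitting.
#'
#' @param tree a tree.
#' @param alpha,beta depth-prior parameters (see [split_probability()]).
#' @param split_probs length-P simplex of split-variable probabilities.
#' @param n_unique integer vector: unique observed values per predictor; the
#'   thresholds of `tree` must belong to the training data's unique values.
#' @param cutpoints optional list of the unique observed values per predictor;
#'   when supplied, thresholds are checked against it.
#' @return log prior probability.
#' @export
log_tree_prior <- function(tree, alpha, beta, split_probs, n_unique,
                           cutpoints = NULL) {
  lp <- 0
  for (nd in tree_nodes(tree)) {
    ps <- split_probability(nd$depth, alpha, beta)
    if (nd$leaf) {
      lp <- lp + log(1 - ps)
    } else {
      if (!is.null(cutpoints) &&
          !any(abs(cutpoints[[nd$var]] - nd$split) < 1e-12)) {
        stop("threshold ", nd$split,
             " is not an observed value of predictor ", nd$var)
      }
      lp <- lp + log(ps) + log(split_probs[nd$var]) - log(n_unique[nd$var])
    }
  }
  lp
}
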