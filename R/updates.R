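# Reference (pure-R) implementations of the Gibbs / Metropolis-Hastings
# updates that make up one backfitting sweep.  The compiled sampler behind
# run_sampler() implements the same kernel; these functions are the readable
# single-step versions used for small problems and for oracle tests.

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1, shape = shape, rate = scale)

#' Conjugate full-conditional moments of a leaf value
#'
#' For a leaf with `n` assigned rows and partial-residual mean `rbar`, under
#' leaf prior Normal(`m0`, `sigma_mu2`) and noise variance `sigma2`, the full
#' conditional is Normal with precision `n/sigma2 + 1/sigma_mu2` and mean
#' `(n*rbar/sigma2 + m0/sigma_mu2) / precision`.
#'
#' @param n number of rows assigned to the leaf.
#' @param rbar mean of their partial residuals (0 if `n == 0`).
#' @param sigma2 residual variance.
#' @param sigma_mu2 leaf-value prior variance.
#' @param m0 leaf-value prior mean.
#' @return list with `mean` and `var`.
#' @export
leaf_full_conditional <- function(n, rbar, sigma2, sigma_mu2, m0 = 0) {
  prec <- n / sigma2 + 1 / sigma_mu2
  list(mean = (n * rbar / sigma2 + m0 / sigma_mu2) / prec, var = 1 / prec)
}

# leaf-marginalized log-likelihood terms that differ between trees sharing a
# row set (see the compiled sampler for the derivation)
leaf_marg_r <- function(n, s, sigma2, sigma_mu2, m0) {
  denom <- sigma2 + n * sigma_mu2
  0.5 * log(sigma2 / denom) + sigma_mu2 * (s - n * m0)^2 / (2 * sigma2 * denom)
}

# rows assigned to each leaf; returns list of row-index vectors, in the order
# of tree_leaves(tree)
leaf_assignment <- function(tree, X) {
  n <- nrow(X)
  paths <- collect_nodes(tree)
  leaf_paths <- Filter(function(e) e$node$leaf, paths)
  key <- vapply(seq_len(n), function(i) {
    node <- tree; path <- ""
    while (!node$leaf) {
      if (X[i, node$var] <= node$split) { node <- node$left; path <- paste0(path, "L") }
      else { node <- node$right; path <- paste0(path, "R") }
    }
    path
  }, character(1))
  lapply(leaf_paths, function(e) {
    which(key == paste(c("L", "R")[e$path], collapse = ""))
  })
}

marg_loglik <- function(tree, X, resid, sigma2, sigma_mu2, m0,
                        allow_empty = FALSE) {
  rows <- leaf_assignment(tree, X)
  tot <- 0
  for (ix in rows) {
    if (length(ix) == 0 && !allow_empty) return(-Inf)
    tot <- tot + leaf_marg_r(length(ix), sum(resid[ix]), sigma2, sigma_mu2, m0)
  }
  tot
}

#' Draw new leaf values from their conjugate full conditionals
#'
#' Each leaf value is redrawn given the partial residuals of the rows routed
#' to it (see [leaf_full_conditional()]); a leaf with no assigned rows is
#' drawn from its prior Normal(`m0`, `sigma_mu2`).
#'
#' @param tree a tree.
#' @param X training predictor matrix.
#' @param resid partial residuals: `y` minus the predictions of all the other
#'   trees.
#' @inheritParams leaf_full_conditional
#' @return the tree with new leaf values.
#' @export
update_leaf_values <- function(tree, X, resid, sigma2, sigma_mu2, m0 = 0) {
  if (tree$leaf) {
    fc <- if (nrow(X) == 0) list(mean = m0, var = sigma_mu2) else
      leaf_full_conditional(nrow(X), mean(resid), sigma2, sigma_mu2, m0)
    tree$value <- stats::rnorm(1, fc$mean, sqrt(fc$var))
    return(tree)
  }
  left <- X[, tree$var] <= tree$split
  tree$left <- update_leaf_values(tree$left, X[left, , drop = FALSE],
                                  resid[left], sigma2, sigma_mu2, m0)
  tree$right <- update_leaf_values(tree$right, X[!left, , drop = FALSE],
                                   resid[!left], sigma2, sigma_mu2, m0)
  tree
}

#' Gibbs update of the residual variance
#'
#' Draws from inverse-Gamma(`shape + n/2`, `scale + SS/2`) where `SS` is the
#' sum of squared residuals — the conjugate posterior under the noninformative
#' inverse-Gamma prior.
#'
#' @param residuals `y` minus the forest predictions, over all rows.
#' @param shape,scale prior inverse-Gamma parameters.
#' @return one draw, with attributes `shape` and `scale` giving the posterior
#'   parameters.
#' @export
update_sigma2 <- function(residuals, shape = 0.001, scale = 0.001) {
  post_shape <- shape + length(residuals) / 2
  post_scale <- scale + sum(residuals^2) / 2
  structure(rinvgamma1(post_shape, post_scale),
            shape = post_shape, scale = post_scale)
}

#' Gibbs update of the leaf-value variance
#'
#' Pools the leaf values of all trees and draws from
#' inverse-Gamma(`shape + L/2`, `scale + sum((mu - m0)^2)/2`).
#'
#' @param leaf_values numeric vector of all leaf values across the forest.
#' @param m0 leaf-value prior mean.
#' @param shape,scale prior inverse-Gamma parameters.
#' @return one draw, with attributes `shape` and `scale`.
#' @export
update_sigma_mu2 <- function(leaf_values, m0 = 0, shape = 3, scale = 1) {
  post_shape <- shape + length(leaf_values) / 2
  post_scale <- scale + sum((leaf_values - m0)^2) / 2
  structure(rinvgamma1(post_shape, post_scale),
            shape = post_shape, scale = post_scale)
}

#' Update the split-variable probabilities
#'
#' With sparsity enabled, draws from Dirichlet(`concentration/P + count_j`)
#' given the current per-predictor split counts (Dirichlet sparsity prior on
#' the splitting proportions); with sparsity disabled, returns the uniform
#' vector `1/P`.
#'
#' @param split_counts nonnegative integer vector of splits per predictor.
#' @param concentration Dirichlet concentration parameter.
#' @param sparsity enable the Dirichlet update?
#' @return simplex vector of length `P = length(split_counts)`.
#' @export
update_split_probs <- function(split_counts, concentration = 1, sparsity = TRUE) {
  P <- length(split_counts)
  if (!sparsity) return(rep(1 / P, P))
  g <- stats::rgamma(P, shape = concentration / P + split_counts, rate = 1)
  g / sum(g)
}

#' Number of splits per predictor in a forest
#' @param forest list of trees.
#' @param p number of predictors.
#' @return integer vector of length `p`.
#' @export
split_count_vector <- function(forest, p) {
  counts <- integer(p)
  for (tree in forest) {
    for (nd in tree_nodes(tree)) {
      if (!nd$leaf) counts[nd$var] <- counts[nd$var] + 1L
    }
  }
  counts
}

# ---- tree surgery helpers -------------------------------------------------

# all nodes with their path from the root (integer vector; 1 = left, 2 = right)
collect_nodes <- function(tree, path = integer()) {
  if (tree$leaf) return(list(list(node = tree, path = path)))
  c(list(list(node = tree, path = path)),
    collect_nodes(tree$left, c(path, 1L)),
    collect_nodes(tree$right, c(path, 2L)))
}

replace_at <- function(tree, path, newnode) {
  if (length(path) == 0) return(newnode)
  slot <- if (path[1] == 1L) "left" else "right"
  tree[[slot]] <- replace_at(tree[[slot]], path[-1], newnode)
  tree
}

fix_depths <- function(tree, depth = 0L) {
  tree$depth <- depth
  if (!tree$leaf) {
    tree$left <- fix_depths(tree$left, depth + 1L)
    tree$right <- fix_depths(tree$right, depth + 1L)
  }
  tree
}

n_prunable <- function(tree) {
  sum(vapply(collect_nodes(tree), function(e) {
    !e$node$leaf && e$node$left$leaf && e$node$right$leaf
  }, logical(1)))
}

n_internal <- function(tree) {
  sum(!vapply(collect_nodes(tree), function(e) e$node$leaf, logical(1)))
}

#' Propose a GROW, PRUNE or CHANGE move on a tree
#'
#' Moves are chosen with base probabilities 0.28 / 0.28 / 0.44; a move that is
#' impossible for the current structure (PRUNE or CHANGE on a stump) is
#' resampled, so a stump always receives GROW. GROW splits a uniformly chosen
#' leaf with a rule drawn from the split-variable probabilities and a
#' uniformly chosen observed threshold; PRUNE collapses a uniformly chosen
#' internal node whose children are both leaves; CHANGE redraws the rule of a
#' uniformly chosen internal node.
#'
#' @param tree current tree.
#' @param cutpoints list (length P) of the sorted unique observed values per
#'   predictor.
#' @param split_probs simplex vector of split-variable probabilities.
#' @param move_probs named base probabilities for `grow`, `prune`, `change`.
#' @return list with elements `tree` (the proposal), `move`, and
#'   `log_transition_ratio` = log q(T | T') - log q(T' | T), the
#'   Metropolis-Hastings proposal correction (rule-draw probabilities
#'   included; they cancel against [log_tree_prior()] terms in the acceptance
#'   ratio).
#' @export
propose_tree_move <- function(tree, cutpoints, split_probs,
                              move_probs = c(grow = 0.28, prune = 0.28,
                                             change = 0.44)) {
  P <- length(cutpoints)
  stump <- tree$leaf
  move <- if (stump) "grow" else {
    sample(names(move_probs), 1, prob = move_probs)
  }
  p_grow_here <- if (stump) 1 else unname(move_probs["grow"])

  draw_rule <- function() {
    var <- sample.int(P, 1, prob = split_probs)
    cut <- cutpoints[[var]][sample.int(length(cutpoints[[var]]), 1)]
    list(var = var, cut = cut)
  }

  nodes <- collect_nodes(tree)
  is_leaf <- vapply(nodes, function(e) e$node$leaf, logical(1))

  if (move == "grow") {
    leaves <- nodes[is_leaf]
    b <- length(leaves)
    pick <- leaves[[sample.int(b, 1)]]
    rule <- draw_rule()
    newnode <- tree_split(rule$var, rule$cut, tree_leaf(0), tree_leaf(0),
                          depth = pick$node$depth)
    prop <- replace_at(tree, pick$path, newnode)
    prop <- fix_depths(prop)
    w2p <- n_prunable(prop)
    ltr <- log(unname(move_probs["prune"])) - log(w2p) -
      log(p_grow_here) + log(b) -
      log(split_probs[rule$var]) + log(length(cutpoints[[rule$var]]))
    return(list(tree = prop, move = "grow", log_transition_ratio = ltr))
  }

  if (move == "prune") {
    prunable <- Filter(function(e) {
      !e$node$leaf && e$node$left$leaf && e$node$right$leaf
    }, nodes)
    w2 <- length(prunable)
    pick <- prunable[[sample.int(w2, 1)]]
    prop <- replace_at(tree, pick$path, tree_leaf(0, pick$node$depth))
    prop <- fix_depths(prop)
    p_grow_there <- if (prop$leaf) 1 else unname(move_probs["grow"])
    bp <- tree_n_leaves(prop)
    j <- pick$node$var
    ltr <- log(p_grow_there) - log(bp) +
      log(split_probs[j]) - log(length(cutpoints[[j]])) -
      log(unname(move_probs["prune"])) + log(w2)
    return(list(tree = prop, move = "prune", log_transition_ratio = ltr))
  }

  internal <- nodes[!is_leaf]
  pick <- internal[[sample.int(length(internal), 1)]]
  rule <- draw_rule()
  newnode <- pick$node
  j_old <- newnode$var
  newnode$var <- rule$var
  newnode$split <- rule$cut
  prop <- replace_at(tree, pick$path, newnode)
  ltr <- log(split_probs[j_old]) - log(length(cutpoints[[j_old]])) -
    log(split_probs[rule$var]) + log(length(cutpoints[[rule$var]]))
  list(tree = prop, move = "change", log_transition_ratio = ltr)
}

#' Initialize the reference sampler state
#'
#' @param X training predictor matrix.
#' @param y response vector.
#' @param priors a [bart_priors()] object.
#' @param m0 leaf prior mean; defaults to `(max(y) - min(y)) / (2 K)`.
#' @return a sampler state: forest of stumps, `sigma2`, `sigma_mu2`,
#'   `split_probs`, fitted-value cache, cutpoints and `m0`.
#' @export
init_sampler_state <- function(X, y, priors, m0 = NULL) {
  K <- priors$trees
  P <- ncol(X)
  if (is.null(m0)) m0 <- (max(y) - min(y)) / (2 * K)
  forest <- replicate(K, tree_leaf(mean(y) / K), simplify = FALSE)
  fit <- matrix(mean(y) / K, nrow(X), K)
  list(forest = forest,
       sigma2 = stats::var(y),
       sigma_mu2 = (max(y) - min(y))^2 / (16 * K),
       split_probs = rep(1 / P, P),
       fit = fit,
       cutpoints = lapply(seq_len(P), function(j) sort(unique(X[, j]))),
       m0 = m0)
}

#' One backfitting MCMC sweep (reference implementation)
#'
#' For each tree in turn: compute partial residuals, propose a
#' GROW/PRUNE/CHANGE move, accept or reject by Metropolis-Hastings with the
#' leaf-marginalized likelihood and the tree prior, then redraw the leaf
#' values from their conjugate full conditionals. Afterwards the residual
#' variance, the leaf variance and (if sparsity is enabled) the split
#' probabilities are redrawn. Proposals that would create an empty leaf are
#' rejected.
#'
#' @param state a sampler state from [init_sampler_state()].
#' @param X,y training data.
#' @param priors a [bart_priors()] object.
#' @param check assert the fitted-value cache against recomputation?
#' @return the updated state.
#' @export
backfit_iteration <- function(state, X, y, priors, check = FALSE) {
  K <- length(state$forest)
  n_unique <- lengths(state$cutpoints)
  total_fit <- rowSums(state$fit)
  for (k in seq_len(K)) {
    r <- y - total_fit + state$fit[, k]
    tree <- state$forest[[k]]
    prop <- propose_tree_move(tree, state$cutpoints, state$split_probs)
    ll_new <- marg_loglik(prop$tree, X, r, state$sigma2, state$sigma_mu2, state$m0)
    if (is.finite(ll_new)) {
      ll_old <- marg_loglik(tree, X, r, state$sigma2, state$sigma_mu2, state$m0)
      lp_new <- log_tree_prior(prop$tree, priors$alpha, priors$beta,
                               state$split_probs, n_unique)
      lp_old <- log_tree_prior(tree, priors$alpha, priors$beta,
                               state$split_probs, n_unique)
      log_acc <- (ll_new - ll_old) + (lp_new - lp_old) + prop$log_transition_ratio
      if (log(stats::runif(1)) < log_acc) tree <- prop$tree
    }
    tree <- update_leaf_values(tree, X, r, state$sigma2, state$sigma_mu2,
                               state$m0)
    state$forest[[k]] <- tree
    new_fit <- tree_predict(tree, X)
    total_fit <- total_fit - state$fit[, k] + new_fit
    state$fit[, k] <- new_fit
  }
  if (check) {
    for (k in seq_len(K)) {
      if (max(abs(state$fit[, k] - tree_predict(state$forest[[k]], X))) > 1e-8)
        stop("internal error: fit cache inconsistent with forest")
    }
  }
  resid <- y - total_fit
  state$sigma2 <- as.numeric(update_sigma2(resid, priors$sigma2_shape,
                                           priors$sigma2_scale))
  mu <- unlist(lapply(state$forest, function(t)
    vapply(tree_leaves(t), `[[`, numeric(1), "value")))
  state$sigma_mu2 <- as.numeric(update_sigma_mu2(mu, state$m0,
                                                 priors$sigmamu2_shape,
                                                 priors$sigmamu2_scale))
  if (priors$sparsity) {
    state$split_probs <- update_split_probs(
      split_count_vector(state$forest, length(state$split_probs)),
      priors$dirichlet_concentration)
  }
  state
}
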