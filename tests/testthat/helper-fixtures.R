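# Shared fixtures: everything is generated in code at test time.

# a small monitor-day dataset for fast model fits
tiny_dataset <- function(seed = 5L, n_monitors = 12L, n_days = 120L, ...) {
  net <- generate_network(n_monitors, seed = seed)
  generate_dataset(net, synthetic_config(n_monitors = n_monitors,
                                         n_days = n_days, seed = seed, ...))
}

tiny_control <- function(seed = 7L, burn_in = 200L, n_post = 200L) {
  sampler_control(burn_in = burn_in, n_post = n_post, seed = seed)
}

# independent naive re-implementation of the prediction metrics, used as the
# oracle for compute_metrics
naive_metrics <- function(obs, pred, lo, hi) {
  xb <- mean(obs); pb <- mean(pred)
  r <- sum((obs - xb) * (pred - pb)) /
    sqrt(sum((obs - xb)^2) * sum((pred - pb)^2))
  inside <- 0
  sq <- 0
  for (i in seq_along(obs)) {
    sq <- sq + (obs[i] - pred[i])^2
    if (obs[i] >= lo[i] && obs[i] <= hi[i]) inside <- inside + 1
  }
  list(r2 = r^2, rmse = sqrt(sq / length(obs)), cvg95 = inside / length(obs))
}

# a deterministic little two-split tree over P = 2 predictors
example_tree <- function() {
  tree_split(1, 0.5,
             tree_leaf(1), tree_split(2, 0, tree_leaf(2), tree_leaf(3)))
}

# random forest of small random trees (R representation) for routing oracles
random_forest <- function(K, P, depth_prob = 0.5) {
  rand_tree <- function(depth) {
    if (depth >= 3 || stats::runif(1) > depth_prob) {
      return(tree_leaf(stats::rnorm(1), depth))
    }
    tree_split(sample.int(P, 1), stats::runif(1, -1, 1),
               rand_tree(depth + 1), rand_tree(depth + 1), depth)
  }
  replicate(K, rand_tree(0), simplify = FALSE)
}
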