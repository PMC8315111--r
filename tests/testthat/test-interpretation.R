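# build a minimal bart_fit by hand around given forests / split counts
manual_fit <- function(forest_list, var_names, X_train, sigma2 = 0.1) {
  forests <- do.call(rbind, lapply(seq_along(forest_list), function(s) {
    bartpm:::serialize_forest(forest_list[[s]], draw = s)
  }))
  counts <- do.call(rbind, lapply(forest_list, function(f) {
    split_count_vector(f, length(var_names))
  }))
  colnames(counts) <- var_names
  structure(list(forests = forests, split_counts = counts,
                 n_post = length(forest_list),
                 sigma2 = rep(sigma2, length(forest_list)),
                 sigma_mu2 = rep(0.1, length(forest_list)),
                 y_center = 0, y_scale = 1, var_names = var_names,
                 X_train = X_train, test_pred = NULL,
                 train_pred = NULL), class = "bart_fit")
}

test_that("importance is the normalized split count, with edge cases flagged", {
  X <- matrix(runif(40), 20, 2)
  # all splits on predictor 1
  f1 <- manual_fit(list(list(tree_split(1, 0.5, tree_leaf(1), tree_leaf(2))),
                        list(tree_split(1, 0.2, tree_leaf(0), tree_leaf(1)))),
                   c("a", "b"), X)
  imp <- variable_importance(f1)
  expect_equal(imp$proportion[imp$predictor == "a"], 1)
  expect_equal(imp$proportion[imp$predictor == "b"], 0)

  # two predictors used equally
  f2 <- manual_fit(list(list(tree_split(1, 0.5, tree_leaf(1), tree_leaf(2)),
                             tree_split(2, 0.5, tree_leaf(1), tree_leaf(2)))),
                   c("a", "b"), X)
  expect_equal(variable_importance(f2)$proportion, c(0.5, 0.5))

  # stumps everywhere: all-zero flag rather than 0/0
  f3 <- manual_fit(list(list(tree_leaf(1)), list(tree_leaf(2))), c("a", "b"), X)
  imp3 <- variable_importance(f3)
  expect_equal(imp3$proportion, c(0, 0))
  expect_false(attr(imp3, "any_splits"))
})

test_that("importance normalizes and recovers the dominant planted predictor", {
  # a configuration where the CMAQ-like simulation is the only strong proxy
  net <- generate_network(10, seed = 41)
  d <- generate_dataset(net, synthetic_config(
    n_monitors = 10, n_days = 150, sampling_rate = 0.8,
    n_met = 0, n_landuse = 0, n_cmaq = 1, n_aod = 0, n_noise = 5,
    include_total_mass = FALSE, seed = 41))
  fit <- run_sampler(d, bart_priors(trees = 20),
                     tiny_control(seed = 42, burn_in = 200, n_post = 200),
                     keep_forests = FALSE)
  imp <- variable_importance(fit)
  expect_equal(sum(imp$proportion), 1, tolerance = 1e-12)
  expect_equal(imp$predictor[1], "cmaq_1")
  # rank of the dominant predictor is stable when the noise family is dropped
  fit2 <- run_sampler(d, bart_priors(trees = 20),
                      tiny_control(seed = 43, burn_in = 200, n_post = 200),
                      families = c("cmaq"), keep_forests = FALSE)
  expect_equal(variable_importance(fit2)$predictor[1], "cmaq_1")
})

test_that("partial dependence is flat for unused predictors and consistent on average", {
  set.seed(44)
  X <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  tr <- tree_split(1, 0.5, tree_leaf(1), tree_leaf(3))
  fit <- manual_fit(list(list(tr), list(tr)), c("a", "b"), X)
  # predictor b is never split on: curve constant and equal to the mean
  pd <- partial_dependence(fit, "b", n_grid = 7)
  overall <- mean(apply(X, 1, function(x) tree_predict(tr, x)))
  expect_equal(pd$mean, rep(overall, 7), tolerance = 1e-8)
  expect_equal(diff(range(pd$hi95 - pd$lo95)), 0, tolerance = 1e-10)

  # averaging the used predictor's curve over its empirical distribution
  # reproduces the overall mean prediction
  pd_a <- partial_dependence(fit, "a", grid = X[, 1])
  expect_equal(mean(pd_a$mean[match(X[, 1], pd_a$value)]), overall,
               tolerance = 1e-8)

  # grid strictly increasing; extrapolation warns
  expect_true(all(diff(pd_a$value) > 0))
  expect_warning(partial_dependence(fit, "a", grid = c(-5, 0.5)),
                 "outside the observed range")
  expect_error(partial_dependence(fit, "zz"), "unknown predictor")
})

test_that("partial dependence recovers a planted monotone association", {
  d <- tiny_dataset(seed = 45, n_monitors = 10, n_days = 150)
  fit <- run_sampler(d, bart_priors(),
                     tiny_control(seed = 46, burn_in = 300, n_post = 200))
  pd <- partial_dependence(fit, "cmaq_1", n_grid = 9, max_background = 300)
  # clear positive marginal association over the bulk of the range
  expect_gt(pd$mean[8] - pd$mean[2], 0)
  expect_gt(cor(pd$value, pd$mean, method = "spearman"), 0.8)
})

test_that("single-row backgrounds reduce the curve to that row's profile", {
  X <- matrix(c(0.3, 0.7), 1, 2, dimnames = list(NULL, c("a", "b")))
  tr <- tree_split(1, 0.5, tree_leaf(1), tree_leaf(3))
  fit <- manual_fit(list(list(tr)), c("a", "b"), X)
  pd <- suppressWarnings(partial_dependence(fit, "a", grid = c(0.2, 0.9)))
  expect_equal(pd$mean, c(1, 3))
})

test_that("grid prediction aggregates cell-days and flags missing columns", {
  d <- tiny_dataset(seed = 47, n_monitors = 8, n_days = 100)
  fit <- run_sampler(d, bart_priors(trees = 20),
                     tiny_control(seed = 48, burn_in = 200, n_post = 200))

  # identity: one cell, one day (var_names already includes lon and lat)
  g1 <- as.data.frame(d)[3, fit$var_names]
  g1$cell_id <- "c1"
  gp <- predict_grid(fit, g1, period = "one")
  ps <- predict_posterior(fit, as.matrix(as.data.frame(d)[3, fit$var_names]),
                          interval = "credible")
  expect_equal(gp$mean, ps$mean)
  expect_equal(gp$n_days, 1)
  expect_gt(gp$avg_pred_se, 0)

  # determinism: identical predictors give identical outputs
  g2 <- rbind(g1, g1)
  g2$cell_id <- c("c1", "c2")
  gp2 <- predict_grid(fit, g2)
  expect_equal(gp2$mean[1], gp2$mean[2])
  expect_equal(gp2$avg_pred_se[1], gp2$avg_pred_se[2])

  expect_error(predict_grid(fit, g1[, -3]), "missing predictor")
  expect_error(predict_grid(fit, subset(g1, select = -pm25_total)),
               "missing predictor")
  expect_error(predict_grid(fit, subset(g1, select = -cell_id)), "cell_id")
})

test_that("the planted high-concentration subregion shows the highest grid means", {
  net <- generate_network(25, seed = 49)
  d <- generate_dataset(net, synthetic_config(n_monitors = 25, n_days = 240,
                                              seed = 49))
  fit <- run_sampler(d, bart_priors(),
                     tiny_control(seed = 50, burn_in = 300, n_post = 200))
  # grid the fitted domain by averaging observed rows into coarse cells
  dd <- as.data.frame(d)
  dd$cell_id <- paste0(round(dd$lon), "_", round(dd$lat))
  gp <- predict_grid(fit, dd, period = "all")
  near <- sqrt((gp$lon + 120.5)^2 + (gp$lat - 37)^2) < 1.5
  expect_true(sum(near) > 0 && sum(!near) > 0)
  # cells near the planted bump are elevated on average, and predicted cell
  # means track the true latent cell means
  expect_gt(mean(gp$mean[near]), mean(gp$mean[!near]))
  true_cell <- tapply(d$true_mean, dd$cell_id, mean)
  expect_gt(cor(gp$mean, true_cell[gp$cell_id]), 0.9)
})
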