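test_that("the sampler is deterministic given its seed", {
  d <- tiny_dataset(seed = 21, n_monitors = 6, n_days = 60)
  ctl <- tiny_control(seed = 3, burn_in = 50, n_post = 50)
  pri <- bart_priors(trees = 10)
  f1 <- run_sampler(d, pri, ctl)
  f2 <- run_sampler(d, pri, ctl)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$train_pred, f2$train_pred)
  expect_identical(f1$forests, f2$forests)
  f3 <- run_sampler(d, pri, sampler_control(burn_in = 50, n_post = 50, seed = 4))
  expect_false(identical(f1$sigma2, f3$sigma2))
})

test_that("non-finite inputs are rejected with offending rows named", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10); y[4] <- NA
  expect_error(run_sampler(list(X = X, y = y), bart_priors(trees = 2),
                           tiny_control()), "row\\(s\\): 4")
  expect_error(run_sampler(list(X = X[0, ], y = numeric(0)),
                           bart_priors(trees = 2), tiny_control()), "empty")
})

test_that("with pure-noise predictors the residual variance is recovered", {
  set.seed(31)
  n <- 2000
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("noise_", 1:5)))
  y <- rnorm(n, 0, 1)   # f = 0, sigma_true = 1
  fit <- run_sampler(list(X = X, y = y), bart_priors(),
                     sampler_control(burn_in = 500, n_post = 500, seed = 8),
                     keep_forests = FALSE)
  expect_gt(mean(fit$sigma2), 0.9)
  expect_lt(mean(fit$sigma2), 1.1)
})

test_that("a single tree with a vanishing split prior reduces to the stump mean", {
  set.seed(32)
  X <- matrix(rnorm(200), 100, 2)
  y <- rnorm(100, 3, 0.3)
  fit <- run_sampler(list(X = X, y = y),
                     bart_priors(trees = 1, alpha = 1e-9, beta = 2),
                     sampler_control(burn_in = 200, n_post = 200, seed = 9),
                     keep_forests = FALSE)
  expect_equal(mean(colMeans(fit$train_pred)), mean(y), tolerance = 0.02)
})

test_that("rescaling the response rescales the variance draws exactly", {
  # the sampler standardizes internally, so same-seed chains on y and c*y are
  # the same chain; sigma2 and sigma_mu2 transform by c^2, predictions by c
  d <- tiny_dataset(seed = 22, n_monitors = 6, n_days = 60)
  ctl <- tiny_control(seed = 5, burn_in = 100, n_post = 100)
  pri <- bart_priors(trees = 10)
  X <- model_matrix(d)
  f1 <- run_sampler(list(X = X, y = d$y), pri, ctl, keep_forests = FALSE)
  f2 <- run_sampler(list(X = X, y = 3 * d$y), pri, ctl, keep_forests = FALSE)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-10)
  expect_equal(f2$sigma_mu2, 9 * f1$sigma_mu2, tolerance = 1e-10)
  expect_equal(f2$train_pred, 3 * f1$train_pred, tolerance = 1e-10)
})

test_that("compiled and reference engines agree on a small problem", {
  set.seed(33)
  n <- 80
  X <- matrix(runif(n * 2), n, 2)
  y <- 2 + sin(2 * pi * X[, 1]) + rnorm(n, 0, 0.3)
  ctl <- sampler_control(burn_in = 300, n_post = 300, seed = 12)
  pri <- bart_priors(trees = 10, sparsity = FALSE)
  fc <- run_sampler(list(X = X, y = y), pri, ctl, keep_forests = FALSE)
  fr <- run_sampler(list(X = X, y = y), pri, ctl, keep_forests = FALSE,
                    engine = "r")
  # same kernel, independent RNG streams: posterior summaries must agree to
  # Monte-Carlo accuracy
  expect_equal(mean(fr$sigma2), mean(fc$sigma2), tolerance = 0.2)
  expect_gt(cor(colMeans(fr$train_pred), colMeans(fc$train_pred)), 0.95)
  expect_equal(mean(abs(colMeans(fr$train_pred) - colMeans(fc$train_pred))),
               0, tolerance = 0.1)
})

test_that("the reference chain converges to the mean of stump-generated data", {
  set.seed(34)
  n <- 30
  X <- matrix(runif(n * 2), n, 2)
  y <- rnorm(n, 5, 0.2)   # generated from a stump forest
  pri <- bart_priors(trees = 3, sparsity = FALSE)
  fit <- run_sampler(list(X = X, y = y), pri,
                     sampler_control(burn_in = 100, n_post = 150, seed = 13),
                     keep_forests = FALSE, engine = "r")
  expect_equal(mean(colMeans(fit$train_pred)), mean(y), tolerance = 0.1)
})

test_that("the chain is self-consistent: independent runs share a stationary tree-size law", {
  # stationarity smoke test on an 8-row, 2-predictor problem: thinned
  # tree-size histograms from two independently seeded chains must agree
  set.seed(35)
  X <- matrix(runif(16), 8, 2)
  y <- rnorm(8)
  pri <- bart_priors(trees = 1, sparsity = FALSE)
  tree_sizes <- function(seed) {
    fit <- run_sampler(list(X = X, y = y), pri,
                       sampler_control(burn_in = 200, n_post = 200,
                                       thin = 10, seed = seed),
                       engine = "r")
    vapply(seq_len(fit$n_post), function(s) {
      sum(fit$forests[fit$forests[, "draw"] == s, "var"] == 0)
    }, numeric(1))
  }
  s1 <- table(factor(pmin(tree_sizes(14), 4), levels = 1:4))
  s2 <- table(factor(pmin(tree_sizes(15), 4), levels = 1:4))
  keep <- (s1 + s2) > 0
  suppressWarnings(
    p <- chisq.test(rbind(s1[keep], s2[keep]),
                    simulate.p.value = TRUE, B = 2000)$p.value)
  expect_gt(p, 0.01)
})

test_that("serialized forests predict identically to the R trees they encode", {
  set.seed(36)
  forest <- random_forest(K = 5, P = 3)
  mat <- bartpm:::serialize_forest(forest, draw = 1L)
  X <- matrix(rnorm(60), 20, 3)
  via_cpp <- as.numeric(bartpm:::bart_predict_cpp(mat, 1L, X))
  via_r <- apply(X, 1, function(x) forest_predict(forest, x))
  expect_equal(via_cpp, via_r, tolerance = 1e-12)
})

test_that("posterior prediction summaries follow the draws", {
  # degenerate posterior: all draws identical, zero residual variance
  fake <- structure(list(train_pred = matrix(2.5, 50, 4),
                         sigma2 = rep(0, 50), n_post = 50L,
                         test_pred = NULL, forests = NULL,
                         y_center = 0, y_scale = 1,
                         var_names = c("a", "b")), class = "bart_fit")
  ps <- predict_posterior(fake)
  expect_equal(ps$mean, rep(2.5, 4))
  expect_equal(ps$upper95 - ps$lower95, rep(0, 4))

  # standard-normal draws: interval approaches (-1.96, 1.96)
  set.seed(37)
  fake2 <- structure(list(train_pred = matrix(rnorm(20000), 20000, 1),
                          sigma2 = rep(0, 20000), n_post = 20000L,
                          test_pred = NULL, forests = NULL,
                          y_center = 0, y_scale = 1, var_names = "a"),
                     class = "bart_fit")
  ps2 <- predict_posterior(fake2)
  expect_equal(ps2$lower95, -1.96, tolerance = 0.05)
  expect_equal(ps2$upper95, 1.96, tolerance = 0.05)
})

test_that("fits serialize to JSON and reload for identical prediction", {
  d <- tiny_dataset(seed = 23, n_monitors = 5, n_days = 40)
  fit <- run_sampler(d, bart_priors(trees = 5),
                     tiny_control(seed = 6, burn_in = 30, n_post = 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  Xn <- model_matrix(d)[1:7, ]
  expect_equal(bartpm:::posterior_pred_draws(back, Xn),
               bartpm:::posterior_pred_draws(fit, Xn), tolerance = 1e-12)
  expect_equal(back$sigma2, fit$sigma2, tolerance = 1e-12)
})
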