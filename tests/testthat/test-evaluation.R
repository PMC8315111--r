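test_that("ordinary folds are balanced, exhaustive and reproducible", {
  d100 <- data.frame(site_id = rep("s", 100), date_index = 1:100, y = rnorm(100))
  f <- make_ordinary_folds(d100, 10, seed = 1)
  expect_equal(unname(tabulate(f$fold, 10)), rep(10, 10))

  d101 <- data.frame(site_id = rep("s", 101), date_index = 1:101, y = rnorm(101))
  f2 <- make_ordinary_folds(d101, 10, seed = 2)
  expect_lte(diff(range(tabulate(f2$fold, 10))), 1)

  expect_identical(make_ordinary_folds(d100, 10, seed = 3),
                   make_ordinary_folds(d100, 10, seed = 3))
  expect_error(make_ordinary_folds(d100, 1), "n_folds")
})

test_that("spatial folds keep each monitor's rows together", {
  net <- generate_network(55, seed = 4)
  d <- generate_dataset(net, synthetic_config(n_monitors = 55, n_days = 30,
                                              sampling_rate = 0.5, seed = 4))
  f <- make_spatial_folds(d, 10, seed = 5)
  site_folds <- tapply(f$fold, d$site_id, function(v) length(unique(v)))
  expect_true(all(site_folds == 1))
  # 55 sites in 10 folds: site counts per fold in {5, 6}
  sites_per_fold <- tapply(d$site_id, f$fold, function(s) length(unique(s)))
  expect_setequal(unique(unname(sites_per_fold)), c(5, 6))

  # leave-one-site-out boundary
  d10 <- generate_dataset(generate_network(10, seed = 6),
                          synthetic_config(n_monitors = 10, n_days = 20,
                                           sampling_rate = 1, seed = 6))
  f10 <- make_spatial_folds(d10, 10, seed = 6)
  expect_equal(sort(unname(tapply(d10$site_id, f10$fold,
                                  function(s) length(unique(s))))), rep(1, 10))
  expect_error(make_spatial_folds(d10, 11), "fewer sites")
})

test_that("cluster folds recover well-separated blobs and handle limits", {
  # two separated blobs: k-means with k = 2 must recover the partition
  net <- generate_network(12, seed = 7)
  net$lon <- c(rep(-122, 6), rep(-115, 6)) + rnorm(12, 0, 0.1)
  net$lat <- c(rep(40, 6), rep(33, 6)) + rnorm(12, 0, 0.1)
  d <- generate_dataset(net, synthetic_config(n_monitors = 12, n_days = 12,
                                              sampling_rate = 1, seed = 7))
  f <- make_cluster_folds(net, d, k = 2, seed = 8)
  blob <- ifelse(net$lon[match(d$site_id, net$site_id)] < -119, 1, 2)
  expect_equal(length(unique(f$fold[blob == 1])), 1)
  expect_equal(length(unique(f$fold[blob == 2])), 1)
  expect_false(unique(f$fold[blob == 1]) == unique(f$fold[blob == 2]))

  # k = number of sites: singleton clusters
  fs <- make_cluster_folds(net, d, k = 12, seed = 9)
  expect_equal(sort(unname(tapply(d$site_id, fs$fold,
                                  function(s) length(unique(s))))), rep(1, 12))

  expect_identical(make_cluster_folds(net, d, 3, seed = 10)$fold,
                   make_cluster_folds(net, d, 3, seed = 10)$fold)

  net$lon[] <- -120; net$lat[] <- 36
  expect_error(make_cluster_folds(net, d, 2, seed = 11), "degenerate")
})

test_that("metrics match hand-computed values and a naive oracle", {
  m <- compute_metrics(1:4, c(1, 2, 3, 4), rep(0, 4), rep(5, 4))
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$cvg95, 1)

  # four-point case worked by hand
  m2 <- compute_metrics(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5),
                        c(0, 0, 2, 2), c(3, 3, 5, 5))
  expect_equal(m2$rmse, 0.5)
  expect_equal(m2$cvg95, 1.0)
  expect_equal(m2$r2, 0.8)

  # intervals excluding every observation
  m3 <- compute_metrics(c(1, 2), c(1, 2), c(5, 5), c(6, 6))
  expect_equal(m3$cvg95, 0)

  # degenerate variance flagged, not reported as zero
  m4 <- compute_metrics(c(1, 1, 1), c(1, 2, 3), rep(0, 3), rep(2, 3))
  expect_true(is.na(m4$r2))
  expect_false(m4$r2_defined)

  set.seed(12)
  for (i in 1:5) {
    obs <- rnorm(50); pred <- obs + rnorm(50, 0, 0.5)
    lo <- pred - runif(50); hi <- pred + runif(50)
    got <- compute_metrics(obs, pred, lo, hi)
    want <- naive_metrics(obs, pred, lo, hi)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$cvg95, want$cvg95, tolerance = 1e-12)
  }
  expect_error(compute_metrics(1, 1, 1, 1), "at least 2")
  expect_error(compute_metrics(1:3, 1:2, 1:3, 1:3), "equal length")
})

test_that("cross-validation predicts every row exactly once and pools metrics", {
  d <- tiny_dataset(seed = 24, n_monitors = 8, n_days = 90)
  pri <- bart_priors(trees = 10)
  ctl <- tiny_control(seed = 15, burn_in = 100, n_post = 100)
  f <- make_ordinary_folds(d, 5, seed = 16)
  cv <- run_cv(d, f, pri, ctl)
  expect_setequal(cv$predictions$row, seq_len(nrow(d)))
  expect_equal(anyDuplicated(cv$predictions$row), 0)
  expect_equal(cv$pooled$n, nrow(d))
  expect_equal(nrow(cv$per_fold), 5)
  # pooled metrics equal metrics of the accumulated predictions
  want <- compute_metrics(cv$predictions$observed, cv$predictions$mean,
                          cv$predictions$lower95, cv$predictions$upper95)
  expect_equal(cv$pooled$r2, want$r2)

  # an empty fold is invalid
  bad <- f; bad$fold[bad$fold == 5] <- 4
  expect_error(run_cv(d, bad, pri, ctl), "at least one row")

  # undersized training folds are skipped with a warning, viable folds run
  d2 <- tiny_dataset(seed = 25, n_monitors = 4, n_days = 150)
  f2 <- make_ordinary_folds(d2, 2, seed = 17)
  f2$fold <- rep(c(1L, 2L), c(nrow(d2) - 10L, 10L))
  expect_warning(cv2 <- run_cv(d2, f2, pri, ctl), "skipped")
  expect_equal(unique(cv2$predictions$fold), 2L)
})

test_that("coverage tuning selects the candidate closest to the target", {
  d <- tiny_dataset(seed = 26, n_monitors = 8, n_days = 80)
  ctl <- tiny_control(seed = 18, burn_in = 150, n_post = 150)

  single <- tune_for_coverage(d, data.frame(trees = 10, alpha = 0.9, beta = 2),
                              ctl)
  expect_equal(single$selected$trees, 10)
  expect_equal(nrow(single$grid), 1)

  # with several candidates the selected one minimizes |coverage - target|
  two <- tune_for_coverage(
    d, data.frame(trees = c(1, 25), alpha = c(1e-9, 0.95), beta = c(2, 2)),
    ctl)
  expect_equal(abs(two$selected$coverage - 0.95),
               min(abs(two$grid$coverage - 0.95)))
  expect_true(all(two$grid$coverage >= 0 & two$grid$coverage <= 1))
  expect_equal(two$priors$trees, two$selected$trees)

  # tie-break: fewer trees, then larger beta
  g <- data.frame(trees = c(50, 20, 20), alpha = 0.95, beta = c(2, 3, 2),
                  coverage = c(0.93, 0.93, 0.93))
  sel <- bartpm:::select_tuning_candidate(g, 0.95)
  expect_equal(sel$trees, 20)
  expect_equal(sel$beta, 3)
  # closest coverage still dominates the tie-breaks
  g2 <- data.frame(trees = c(200, 10), alpha = 0.95, beta = c(2, 2),
                   coverage = c(0.951, 0.90))
  expect_equal(bartpm:::select_tuning_candidate(g2, 0.95)$trees, 200)
})
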