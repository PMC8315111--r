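#' Cross-validation fold assignments
#'
#' Three designs probe different prediction tasks: `ordinary` leaves out
#' random monitor-days (interpolation at monitored locations), `spatial`
#' leaves out random monitors (prediction at unmonitored locations), and
#' `spatial_cluster` leaves out k-means clusters of monitors (prediction in
#' regions without nearby monitors). In both spatial designs every row of a
#' site shares the site's fold.
#'
#' @param dataset a `species_dataset`.
#' @param n_folds number of folds (default 10, i.e. 10% left out per fold).
#' @param seed integer seed; assignments are deterministic given the seed.
#' @return object of class `fold_assignment`: list with `fold` (integer per
#'   row), `design`, `n_folds`.
#' @name folds
NULL

new_folds <- function(fold, design, n_folds) {
  structure(list(fold = as.integer(fold), design = design,
                 n_folds = as.integer(n_folds)), class = "fold_assignment")
}

#' @rdname folds
#' @export
make_ordinary_folds <- function(dataset, n_folds = 10L, seed = 1L) {
  n <- nrow(dataset)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < n_folds) stop("fewer rows than folds")
  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  new_folds(fold, "ordinary", n_folds)
}

#' @rdname folds
#' @export
make_spatial_folds <- function(dataset, n_folds = 10L, seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  sites <- unique(dataset$site_id)
  if (length(sites) < n_folds) {
    stop("fewer sites (", length(sites), ") than folds (", n_folds, ")")
  }
  site_fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(sites))))
  fold <- site_fold[match(dataset$site_id, sites)]
  new_folds(fold, "spatial", n_folds)
}

#' @rdname folds
#' @param network a `monitor_network` giving each site's coordinates; sites of
#'   `dataset` must all appear in it.
#' @param k number of k-means clusters (each cluster is one held-out fold).
#' @param nstart random restarts for k-means; the restart with the lowest
#'   within-cluster sum of squares is kept.
#' @export
make_cluster_folds <- function(network, dataset, k = 10L, seed = 1L,
                               nstart = 10L) {
  sites <- unique(dataset$site_id)
  net <- network[match(sites, network$site_id), , drop = FALSE]
  if (anyNA(net$lon)) stop("dataset contains sites absent from the network")
  if (length(sites) < k) stop("fewer sites than clusters")
  xy <- cbind(net$lon, net$lat)
  n_distinct <- nrow(unique(xy))
  if (n_distinct < 2) stop("degenerate geometry: all sites coincide")
  if (k >= length(sites)) {
    # singleton-cluster limit: each site is its own held-out cluster
    fold <- match(dataset$site_id, sites)
    f <- new_folds(fold, "spatial_cluster", length(sites))
    f$centers <- xy
    return(f)
  }
  km <- with_seed(seed, stats::kmeans(xy, centers = min(k, n_distinct),
                                      nstart = nstart, iter.max = 50))
  fold <- km$cluster[match(dataset$site_id, sites)]
  f <- new_folds(fold, "spatial_cluster", k)
  f$centers <- km$centers
  f
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> design=%s, %d folds, sizes: %s\n", x$design,
              x$n_folds, paste(tabulate(x$fold, x$n_folds), collapse = ", ")))
  invisible(x)
}

#' Prediction metrics: R2, RMSE and 95%-interval coverage
#'
#' `r2` is the squared Pearson correlation between observations and point
#' predictions, `rmse` the root-mean-square error, and `cvg95` the fraction of
#' observations inside the closed interval `[lower95, upper95]`. When either
#' the observations or the predictions have zero variance, R2 is undefined and
#' reported as `NA` with `r2_defined = FALSE` rather than silently as 0.
#'
#' @param observed,predicted_mean,lower95,upper95 equal-length numeric vectors
#'   (length >= 2).
#' @return list of class `cv_metrics` with `r2`, `rmse`, `cvg95`, `n`,
#'   `r2_defined`.
#' @export
compute_metrics <- function(observed, predicted_mean, lower95, upper95) {
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations")
  if (length(predicted_mean) != n || length(lower95) != n ||
      length(upper95) != n) {
    stop("all inputs must have equal length")
  }
  degenerate <- stats::sd(observed) == 0 || stats::sd(predicted_mean) == 0
  r2 <- if (degenerate) NA_real_ else
    stats::cor(observed, predicted_mean)^2
  structure(list(
    r2 = r2, r2_defined = !degenerate,
    rmse = sqrt(mean((observed - predicted_mean)^2)),
    cvg95 = mean(observed >= lower95 & observed <= upper95),
    n = n), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("R2 = %s, RMSE = %.4g, Cvg95 = %.3f (n = %d)\n",
              if (x$r2_defined) sprintf("%.3f", x$r2) else "undefined",
              x$rmse, x$cvg95, x$n))
  invisible(x)
}

#' Run a cross-validation experiment
#'
#' For each fold, fits the model on the complement, predicts the held-out rows
#' with 95% posterior prediction intervals, and accumulates the held-out
#' predictions. The headline metrics are pooled over all held-out predictions
#' jointly; per-fold metrics are also returned. Each fold uses its own
#' sampler seed derived from `control$seed` so partial reruns are
#' reproducible.
#'
#' @param dataset a `species_dataset`.
#' @param folds a `fold_assignment` from one of the fold makers.
#' @param priors a [bart_priors()].
#' @param control a [sampler_control()].
#' @param families optional predictor-family subset (see [model_matrix()]).
#' @param min_train minimum training rows per fold; smaller folds are skipped
#'   with a warning.
#' @param verbose print per-fold progress?
#' @return object of class `cv_result`: `pooled` ([compute_metrics()] output),
#'   `per_fold` data.frame, `predictions` data.frame of held-out predictions,
#'   `design`.
#' @export
run_cv <- function(dataset, folds, priors = bart_priors(),
                   control = sampler_control(), families = NULL,
                   min_train = 50L, verbose = FALSE) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (length(folds$fold) != nrow(dataset)) {
    stop("fold assignment length does not match dataset rows")
  }
  fold_ids <- sort(unique(folds$fold))
  if (any(tabulate(folds$fold, folds$n_folds) == 0) || length(fold_ids) < 2) {
    stop("invalid folds: every fold must hold out at least one row")
  }
  X <- model_matrix(dataset, families)
  preds <- vector("list", length(fold_ids))
  per_fold <- vector("list", length(fold_ids))
  for (f in fold_ids) {
    test <- folds$fold == f
    if (sum(!test) < min_train) {
      warning("fold ", f, " skipped: only ", sum(!test), " training rows")
      next
    }
    ctl <- control
    ctl$seed <- control$seed + f
    t0 <- Sys.time()
    fit <- run_sampler(list(X = X[!test, , drop = FALSE],
                            y = dataset$y[!test]),
                       priors, ctl, X_test = X[test, , drop = FALSE],
                       keep_forests = FALSE)
    ps <- predict_posterior(fit, seed = ctl$seed)
    m <- compute_metrics(dataset$y[test], ps$mean, ps$lower95, ps$upper95)
    preds[[f]] <- data.frame(fold = f, row = which(test),
                             observed = dataset$y[test], ps)
    per_fold[[f]] <- data.frame(design = folds$design, fold = f, r2 = m$r2,
                                rmse = m$rmse, cvg95 = m$cvg95, n_test = m$n)
    if (verbose) {
      message(sprintf("[%s] %s fold %d/%d: n_test=%d R2=%.3f RMSE=%.3f Cvg95=%.3f (seed %d)",
                      format(Sys.time(), "%H:%M:%S"), folds$design, f,
                      length(fold_ids), m$n, m$r2, m$rmse, m$cvg95, ctl$seed))
    }
  }
  preds <- do.call(rbind, preds)
  if (is.null(preds)) stop("no fold produced predictions")
  pooled <- compute_metrics(preds$observed, preds$mean, preds$lower95,
                            preds$upper95)
  structure(list(pooled = pooled, per_fold = do.call(rbind, per_fold),
                 predictions = preds, design = folds$design),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s CV, %d folds, pooled: ", x$design,
              nrow(x$per_fold)))
  print(x$pooled)
  invisible(x)
}

#' Tune tree count and depth prior for 95% interval coverage
#'
#' Fits each candidate `(trees, alpha, beta)` on the full dataset and computes
#' the empirical coverage of the 95% posterior prediction intervals for the
#' in-sample data. The selected candidate is the one whose coverage is
#' closest to `target`; ties are broken by fewer trees, then by larger `beta`
#' (a preference for smaller, shallower forests).
#'
#' @param dataset a `species_dataset`.
#' @param grid data.frame with columns `trees`, `alpha`, `beta` (one candidate
#'   per row).
#' @param control a [sampler_control()].
#' @param target nominal coverage (default 0.95).
#' @param families optional predictor-family subset.
#' @param priors_base a [bart_priors()] supplying all non-tuned settings.
#' @param verbose print per-candidate progress?
#' @return object of class `tuning_result`: the `grid` with an added
#'   `coverage` column, the `selected` row, the selected [bart_priors()]
#'   object, and the selection rule id.
#' @export
tune_for_coverage <- function(dataset, grid, control = sampler_control(),
                              target = 0.95, families = NULL,
                              priors_base = bart_priors(), verbose = FALSE) {
  stopifnot(nrow(grid) >= 1, all(c("trees", "alpha", "beta") %in% names(grid)))
  coverage <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pri <- priors_base
    pri$trees <- as.integer(grid$trees[i])
    pri$alpha <- grid$alpha[i]
    pri$beta <- grid$beta[i]
    fit <- run_sampler(dataset, pri, control, families = families,
                       keep_forests = FALSE)
    ps <- predict_posterior(fit, seed = control$seed)
    coverage[i] <- mean(dataset$y >= ps$lower95 & dataset$y <= ps$upper95)
    if (verbose) {
      message(sprintf("tune: trees=%d alpha=%.2f beta=%.1f -> in-sample Cvg95=%.3f",
                      pri$trees, pri$alpha, pri$beta, coverage[i]))
    }
  }
  grid$coverage <- coverage
  sel <- select_tuning_candidate(grid, target)
  pri <- priors_base
  pri$trees <- as.integer(sel$trees)
  pri$alpha <- sel$alpha
  pri$beta <- sel$beta
  structure(list(grid = grid, selected = sel, priors = pri,
                 rule = "closest-coverage, ties: fewer trees then larger beta",
                 target = target),
            class = "tuning_result")
}

# selection rule: coverage closest to target; ties broken by fewer trees,
# then larger beta (smaller, shallower forests)
select_tuning_candidate <- function(grid, target = 0.95) {
  ord <- order(abs(grid$coverage - target), grid$trees, -grid$beta)
  grid[ord[1], , drop = FALSE]
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> target coverage", x$target, "\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("selected: trees=%d alpha=%.2f beta=%.1f (coverage %.3f)\n",
              x$selected$trees, x$selected$alpha, x$selected$beta,
              x$selected$coverage))
  invisible(x)
}
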