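#' Prior configuration for the sum-of-trees model
#'
#' @param trees number of trees K.
#' @param alpha,beta depth-prior parameters: a node at depth `d` is internal
#'   with prior probability `alpha * (1 + d)^(-beta)`; `alpha` in (0, 1),
#'   `beta >= 0`. The defaults (50 trees, 0.95, 2) correspond to a
#'   coverage-tuned forest that is smaller than the common 200-tree default.
#' @param sigma2_shape,sigma2_scale noninformative inverse-Gamma hyperprior for
#'   the residual variance (on the standardized response scale).
#' @param sigmamu2_shape,sigmamu2_scale inverse-Gamma hyperprior for the leaf
#'   variance, shared across all trees (on the standardized response scale).
#' @param sparsity enable the Dirichlet sparsity prior on split-variable
#'   probabilities (variable selection)?
#' @param dirichlet_concentration Dirichlet concentration parameter.
#' @return list of class `bart_priors`.
#' @export
bart_priors <- function(trees = 50L, alpha = 0.95, beta = 2,
                        sigma2_shape = 0.001, sigma2_scale = 0.001,
                        sigmamu2_shape = 3, sigmamu2_scale = 1,
                        sparsity = TRUE, dirichlet_concentration = 1) {
  stopifnot(trees >= 1, alpha > 0, alpha < 1, beta >= 0,
            sigma2_shape > 0, sigma2_scale > 0,
            sigmamu2_shape > 0, sigmamu2_scale > 0,
            dirichlet_concentration > 0)
  structure(list(trees = as.integer(trees), alpha = alpha, beta = beta,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                 sigmamu2_shape = sigmamu2_shape,
                 sigmamu2_scale = sigmamu2_scale,
                 sparsity = isTRUE(sparsity),
                 dirichlet_concentration = dirichlet_concentration),
            class = "bart_priors")
}

#' Sampler configuration
#'
#' @param burn_in discarded warm-up iterations (full-scale exposure analyses
#'   typically use 8000; desk-scale runs use less).
#' @param n_post retained posterior draws S (full scale: 2000).
#' @param thin thinning interval, >= 1.
#' @param seed integer seed for the sampler's private RNG.
#' @return list of class `sampler_control`.
#' @export
sampler_control <- function(burn_in = 8000L, n_post = 2000L, thin = 1L,
                            seed = 1L) {
  stopifnot(burn_in >= 1, n_post >= 1, thin >= 1)
  structure(list(burn_in = as.integer(burn_in), n_post = as.integer(n_post),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "sampler_control")
}

#' Fit the sum-of-trees model by MCMC
#'
#' Runs the backfitting sampler for `burn_in` discarded iterations plus
#' `n_post * thin` further iterations, retaining every `thin`-th draw. The
#' response is internally centred and scaled to `[-0.5, 0.5]` for numerical
#' stability; the leaf prior mean `(max(y) - min(y)) / (2 K)` and the variance
#' hyperpriors are applied on that scale, and all outputs are transformed back
#' to response units. Per retained draw the sampler records the residual
#' variance, the leaf variance, the split counts per predictor, predictions
#' for `X_test` (if given), in-sample fitted values, and a serialized snapshot
#' of the forest for later prediction.
#'
#' @param data a `species_dataset` (see [generate_dataset()]), or a list with
#'   elements `X` (numeric matrix) and `y`.
#' @param priors a [bart_priors()] object.
#' @param control a [sampler_control()] object.
#' @param families optional predictor-family subset passed to
#'   [model_matrix()] when `data` is a dataset.
#' @param X_test optional matrix (same columns as the training predictors) for
#'   which per-draw predictions are recorded.
#' @param keep_forests store per-draw forest snapshots (needed by
#'   [predict_posterior()], [partial_dependence()], [predict_grid()])?
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; small problems only).
#' @return object of class `bart_fit` holding the posterior draws.
#' @export
run_sampler <- function(data, priors = bart_priors(),
                        control = sampler_control(), families = NULL,
                        X_test = NULL, keep_forests = TRUE,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(data, "species_dataset") || is.data.frame(data)) {
    X <- model_matrix(data, families)
    y <- data$y
  } else {
    X <- as.matrix(data$X)
    y <- data$y
  }
  if (nrow(X) == 0) stop("empty training data")
  bad <- which(!is.finite(y) | rowSums(!is.finite(X)) > 0)
  if (length(bad)) {
    stop("non-finite response or predictor values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(X_test)) {
    Xt <- matrix(0, 0, ncol(X))
  } else {
    Xt <- as.matrix(X_test)
    if (ncol(Xt) != ncol(X)) {
      stop("X_test has ", ncol(Xt), " columns, training data has ", ncol(X))
    }
  }

  rng_y <- max(y) - min(y)
  center <- (max(y) + min(y)) / 2
  scale <- if (rng_y > 0) rng_y else 1
  y_std <- (y - center) / scale
  m0_std <- 1 / (2 * priors$trees)   # (max(y) - min(y)) / (2K), standardized

  if (engine == "cpp") {
    res <- bart_mcmc_cpp(X, y_std, Xt,
                         priors$trees, priors$alpha, priors$beta, m0_std,
                         priors$sigma2_shape, priors$sigma2_scale,
                         priors$sigmamu2_shape, priors$sigmamu2_scale,
                         priors$sparsity, priors$dirichlet_concentration,
                         control$burn_in, control$n_post, control$thin,
                         as.double(control$seed), keep_forests, TRUE)
  } else {
    res <- run_sampler_r(X, y_std, Xt, priors, control, m0_std, keep_forests)
  }

  fit <- list(
    sigma2 = as.numeric(res$sigma2) * scale^2,
    sigma_mu2 = as.numeric(res$sigma_mu2) * scale^2,
    split_counts = res$split_counts,
    train_pred = res$train_pred * scale + center,
    test_pred = if (nrow(Xt) > 0) res$test_pred * scale + center else NULL,
    forests = if (keep_forests) res$forests else NULL,
    n_post = control$n_post,
    y_center = center, y_scale = scale,
    m0 = rng_y / (2 * priors$trees),
    var_names = colnames(X),
    X_train = X, y_train = y,
    priors = priors, control = control, engine = engine)
  colnames(fit$split_counts) <- colnames(X)
  class(fit) <- "bart_fit"
  fit
}

# reference-engine driver: same kernel as the compiled sampler, pure R
run_sampler_r <- function(X, y_std, Xt, priors, control, m0_std, keep_forests) {
  with_seed(control$seed, {
    state <- init_sampler_state(X, y_std, priors, m0 = m0_std)
    S <- control$n_post
    P <- ncol(X)
    sigma2 <- numeric(S); sigma_mu2 <- numeric(S)
    split_counts <- matrix(0L, S, P)
    train_pred <- matrix(0, S, nrow(X))
    test_pred <- matrix(0, S, nrow(Xt))
    forests <- vector("list", S)
    total <- control$burn_in + S * control$thin
    s <- 0L
    for (it in seq_len(total)) {
      state <- backfit_iteration(state, X, y_std, priors)
      if (it > control$burn_in &&
          ((it - control$burn_in) %% control$thin) == 0) {
        s <- s + 1L
        sigma2[s] <- state$sigma2
        sigma_mu2[s] <- state$sigma_mu2
        split_counts[s, ] <- split_count_vector(state$forest, P)
        train_pred[s, ] <- rowSums(state$fit)
        if (nrow(Xt) > 0) {
          test_pred[s, ] <- apply(Xt, 1, function(x)
            forest_predict(state$forest, x))
        }
        if (keep_forests) forests[[s]] <- serialize_forest(state$forest, s)
      }
    }
    list(sigma2 = sigma2, sigma_mu2 = sigma_mu2, split_counts = split_counts,
         train_pred = train_pred, test_pred = test_pred,
         forests = if (keep_forests) do.call(rbind, forests) else NULL)
  })
}

# preorder serialization matching the compiled sampler:
# columns draw, tree, var (0 = leaf else 1-based), value
serialize_tree_r <- function(tree) {
  if (tree$leaf) return(matrix(c(0, tree$value), 1, 2))
  rbind(matrix(c(tree$var, tree$split), 1, 2),
        serialize_tree_r(tree$left), serialize_tree_r(tree$right))
}

serialize_forest <- function(forest, draw = 1L) {
  rows <- do.call(rbind, lapply(seq_along(forest), function(k) {
    m <- serialize_tree_r(forest[[k]])
    cbind(draw, k, m)
  }))
  colnames(rows) <- c("draw", "tree", "var", "value")
  rows
}

#' Posterior prediction summaries
#'
#' For each row of `X_new`, forms the posterior predictive samples
#' (per-draw forest prediction plus a Normal(0, sigma2_draw) noise draw),
#' and returns their mean, standard deviation and empirical 2.5th / 97.5th
#' percentiles. The point prediction is the mean of all posterior samples and
#' the 95% prediction interval is the quantile band. With
#' `interval = "credible"` the noise draw is omitted and the band summarizes
#' the posterior of the mean function only.
#'
#' @param fit a `bart_fit` (the posterior draws).
#' @param X_new matrix or `species_dataset` rows to predict; `NULL` uses the
#'   per-draw test predictions stored at fit time, if any, else the training
#'   rows.
#' @param interval `"prediction"` (default; includes residual noise, the
#'   object evaluated by interval coverage) or `"credible"`.
#' @param seed seed for the predictive noise draws.
#' @return data.frame with columns `mean`, `sd`, `lower95`, `upper95`.
#' @export
predict_posterior <- function(fit, X_new = NULL,
                              interval = c("prediction", "credible"),
                              seed = 1L) {
  interval <- match.arg(interval)
  draws <- posterior_pred_draws(fit, X_new)
  if (interval == "prediction") {
    draws <- with_seed(seed, draws + matrix(
      stats::rnorm(length(draws), 0, rep(sqrt(fit$sigma2), ncol(draws))),
      nrow(draws), ncol(draws)))
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower95 = qs[1, ], upper95 = qs[2, ])
}

# per-draw forest predictions (S x n matrix), in response units
posterior_pred_draws <- function(fit, X_new = NULL) {
  if (is.null(X_new)) {
    if (!is.null(fit$test_pred)) return(fit$test_pred)
    return(fit$train_pred)
  }
  if (inherits(X_new, "species_dataset") || is.data.frame(X_new)) {
    miss <- setdiff(fit$var_names, names(X_new))
    if (length(miss)) {
      stop("prediction data missing predictor column(s): ",
           paste(miss, collapse = ", "))
    }
    X_new <- as.matrix(as.data.frame(X_new)[, fit$var_names, drop = FALSE])
  }
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$var_names)) {
    stop("X_new has ", ncol(X_new), " columns, expected ",
         length(fit$var_names))
  }
  if (is.null(fit$forests)) {
    stop("fit was run with keep_forests = FALSE; cannot predict new rows")
  }
  bart_predict_cpp(fit$forests, fit$n_post, X_new) * fit$y_scale + fit$y_center
}

#' @export
predict.bart_fit <- function(object, newdata = NULL, ...) {
  predict_posterior(object, newdata, ...)
}

#' @export
print.bart_fit <- function(x, ...) {
  cat(sprintf(
    "<bart_fit> %d trees, %d retained draws (burn-in %d), %d predictors\n",
    x$priors$trees, x$n_post, x$control$burn_in, length(x$var_names)))
  cat(sprintf("  posterior mean sigma^2 = %.4g, sigma_mu^2 = %.4g\n",
              mean(x$sigma2), mean(x$sigma_mu2)))
  invisible(x)
}

#' Serialize a fitted model to structured text
#'
#' Writes a JSON file with the priors, sampler settings, response transform,
#' per-draw variance parameters and split counts, and (optionally) the forest
#' snapshots so the model can be re-loaded for prediction.
#'
#' @param fit a `bart_fit`.
#' @param path output path.
#' @param forests include the serialized forests (needed to predict after
#'   reloading)?
#' @export
write_fit <- function(fit, path, forests = TRUE) {
  obj <- list(
    priors = unclass(fit$priors), control = unclass(fit$control),
    y_center = fit$y_center, y_scale = fit$y_scale, m0 = fit$m0,
    n_post = fit$n_post, var_names = fit$var_names,
    sigma2 = fit$sigma2, sigma_mu2 = fit$sigma_mu2,
    split_counts = fit$split_counts,
    forests = if (forests && !is.null(fit$forests)) fit$forests else NULL)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(
    sigma2 = obj$sigma2, sigma_mu2 = obj$sigma_mu2,
    split_counts = obj$split_counts,
    forests = if (!is.null(obj$forests)) {
      m <- as.matrix(obj$forests)
      colnames(m) <- c("draw", "tree", "var", "value")
      m
    } else NULL,
    n_post = obj$n_post, y_center = obj$y_center, y_scale = obj$y_scale,
    m0 = obj$m0, var_names = obj$var_names,
    priors = do.call(bart_priors, c(obj$priors[setdiff(names(obj$priors), "trees")],
                                    list(trees = obj$priors$trees))),
    control = do.call(sampler_control, obj$control))
  colnames(fit$split_counts) <- fit$var_names
  class(fit) <- "bart_fit"
  fit
}
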