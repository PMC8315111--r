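#' Split-count variable importance
#'
#' Importance of a predictor is the number of times it was used for splitting
#' nodes across all retained MCMC draws, as a proportion of all splits; every
#' internal node of every retained forest snapshot is counted. Proportions sum
#' to 1 across predictors. If no draw contains any split (a forest of stumps
#' throughout), all importances are 0 and `any_splits` is `FALSE`.
#'
#' @param fit a `bart_fit`.
#' @return data.frame of class `importance_table` with columns `predictor`,
#'   `family`, `proportion`, ordered by decreasing importance; attribute
#'   `any_splits`.
#' @export
variable_importance <- function(fit) {
  counts <- colSums(fit$split_counts)
  total <- sum(counts)
  prop <- if (total == 0) rep(0, length(counts)) else counts / total
  fam <- predictor_family(names(counts))
  out <- data.frame(predictor = names(counts), family = fam,
                    proportion = unname(prop), stringsAsFactors = FALSE)
  out <- out[order(-out$proportion, out$predictor), ]
  rownames(out) <- NULL
  attr(out, "any_splits") <- total > 0
  class(out) <- c("importance_table", "data.frame")
  out
}

predictor_family <- function(nm) {
  fam <- rep("other", length(nm))
  fam[nm %in% c("lon", "lat")] <- "coordinates"
  fam[startsWith(nm, "met_")] <- "meteorology"
  fam[startsWith(nm, "lu_")] <- "land_use"
  fam[startsWith(nm, "cmaq_")] <- "cmaq"
  fam[startsWith(nm, "aod_")] <- "aod"
  fam[startsWith(nm, "noise_")] <- "noise"
  fam[nm == "pm25_total"] <- "total_mass"
  fam
}

#' Partial dependence (marginal effect) curve
#'
#' The marginal effect of a predictor at value `v` is the average model
#' prediction over all background rows with that predictor set to `v`,
#' averaged over the posterior draws; pointwise 2.5%/97.5% bands are taken
#' over the draws. The background population defaults to the full training
#' set (capped at `max_background` rows, taken deterministically by an
#' evenly-spaced subsample, for tractability).
#'
#' @param fit a `bart_fit` fitted with `keep_forests = TRUE`.
#' @param predictor predictor name or 1-based column index.
#' @param grid numeric grid of predictor values; defaults to an
#'   evenly-spaced grid of `n_grid` values over the observed training range.
#'   Values outside the observed range trigger an extrapolation warning.
#' @param n_grid default grid size.
#' @param max_background cap on background rows.
#' @return data.frame of class `marginal_curve` with columns `predictor`,
#'   `value`, `mean`, `lo95`, `hi95`.
#' @export
partial_dependence <- function(fit, predictor, grid = NULL, n_grid = 20L,
                               max_background = 1000L) {
  if (is.character(predictor)) {
    j <- match(predictor, fit$var_names)
    if (is.na(j)) stop("unknown predictor: ", predictor)
  } else j <- as.integer(predictor)
  X <- fit$X_train
  if (is.null(X)) stop("fit does not carry its training rows")
  obs_range <- range(X[, j])
  if (is.null(grid)) {
    grid <- seq(obs_range[1], obs_range[2], length.out = n_grid)
  } else {
    grid <- sort(unique(grid))
    if (any(grid < obs_range[1] | grid > obs_range[2])) {
      warning("grid values outside the observed range of ",
              fit$var_names[j], "; curve extrapolates there")
    }
  }
  if (nrow(X) > max_background) {
    X <- X[round(seq(1, nrow(X), length.out = max_background)), , drop = FALSE]
  }
  means <- matrix(0, fit$n_post, length(grid))
  for (g in seq_along(grid)) {
    Xg <- X
    Xg[, j] <- grid[g]
    means[, g] <- rowMeans(posterior_pred_draws(fit, Xg))
  }
  qs <- apply(means, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(predictor = fit$var_names[j], value = grid,
                    mean = colMeans(means), lo95 = qs[1, ], hi95 = qs[2, ],
                    stringsAsFactors = FALSE)
  class(out) <- c("marginal_curve", "data.frame")
  out
}

#' Gridded period-average prediction with uncertainty
#'
#' For each grid cell, predicts every cell-day row, averages the daily
#' posterior-mean predictions into a period (e.g. annual) mean, and reports
#' uncertainty as the average over days of the daily posterior prediction
#' standard error. With `se = "period_mean"` the standard error of the period
#' mean itself (sd over draws of the within-cell average) is reported
#' instead.
#'
#' @param fit a `bart_fit` fitted with `keep_forests = TRUE`.
#' @param grid_table data.frame with columns `cell_id`, `lon`, `lat`, the
#'   predictor columns of the fit, and (optionally) `date_index`; one row per
#'   cell-day.
#' @param period label stored in the output (e.g. `"2010"`).
#' @param se `"daily_mean"` (default: mean of daily prediction SEs) or
#'   `"period_mean"`.
#' @return data.frame of class `grid_prediction` with columns `cell_id`,
#'   `lon`, `lat`, `period`, `mean`, `avg_pred_se`, `n_days`.
#' @export
predict_grid <- function(fit, grid_table, period = "all",
                         se = c("daily_mean", "period_mean")) {
  se <- match.arg(se)
  miss <- setdiff(fit$var_names, names(grid_table))
  if (length(miss)) {
    stop("grid_table missing predictor column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"cell_id" %in% names(grid_table)) stop("grid_table needs a cell_id column")
  X <- as.matrix(as.data.frame(grid_table)[, fit$var_names, drop = FALSE])
  draws <- posterior_pred_draws(fit, X)              # S x n
  daily_sd <- sqrt(apply(draws, 2, stats::var) + mean(fit$sigma2))
  cells <- unique(grid_table$cell_id)
  out <- do.call(rbind, lapply(cells, function(cid) {
    ix <- which(grid_table$cell_id == cid)
    cell_draw_mean <- rowMeans(draws[, ix, drop = FALSE])
    data.frame(cell_id = cid,
               lon = grid_table$lon[ix[1]], lat = grid_table$lat[ix[1]],
               period = period,
               mean = mean(colMeans(draws[, ix, drop = FALSE])),
               avg_pred_se = if (se == "daily_mean") mean(daily_sd[ix])
                             else stats::sd(cell_draw_mean),
               n_days = length(ix))
  }))
  class(out) <- c("grid_prediction", "data.frame")
  out
}

#' Write interpretation outputs as CSV
#'
#' `write_importance` writes `predictor,family,proportion`; `write_pdp`
#' writes `predictor,value,mean,lo95,hi95`; `write_grid` writes
#' `cell_id,lon,lat,mean,avg_pred_se`.
#'
#' @param x the corresponding object.
#' @param path output path.
#' @name interpretation-io
#' @export
write_importance <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname interpretation-io
#' @export
write_pdp <- write_importance

#' @rdname interpretation-io
#' @export
write_grid <- write_importance
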