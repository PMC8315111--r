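#' Configuration for an end-to-end experiment
#'
#' Describes one config-driven run of the full pipeline: data source,
#' predictor-set variants, model and sampler settings, and which
#' cross-validation designs to run. The baseline predictors (`lon`, `lat`,
#' `met_*`, `lu_*`) are always included; a variant names the optional families
#' added to the baseline (any of `"cmaq"`, `"aod"`, `"noise"`, `"total"`).
#'
#' @param synthetic a [synthetic_config()] used to generate the dataset, or
#'   `NULL` when `dataset_path` is given.
#' @param dataset_path path to a dataset CSV (see [read_dataset()]).
#' @param network_path optional network CSV (needed for cluster CV with
#'   `dataset_path`).
#' @param variants named list of character vectors of optional families.
#' @param priors a [bart_priors()].
#' @param control a [sampler_control()].
#' @param designs subset of `c("ordinary", "spatial", "cluster")`.
#' @param n_folds folds per design.
#' @param out_dir output directory (created if missing).
#' @param seed global seed, expanded deterministically into per-stage seeds.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              dataset_path = NULL, network_path = NULL,
                              variants = list(baseline = character(0),
                                              full = c("cmaq", "aod", "total")),
                              priors = bart_priors(),
                              control = sampler_control(burn_in = 1000L,
                                                        n_post = 500L),
                              designs = c("ordinary", "spatial", "cluster"),
                              n_folds = 10L, out_dir = "bartpm-results",
                              seed = 1L) {
  designs <- match.arg(designs, several.ok = TRUE)
  valid <- c("cmaq", "aod", "noise", "total")
  for (v in variants) {
    bad <- setdiff(v, valid)
    if (length(bad)) {
      stop("unknown predictor family: ", paste(bad, collapse = ", "),
           " (valid: ", paste(valid, collapse = ", "), ")")
    }
  }
  if (!is.null(dataset_path) && !file.exists(dataset_path)) {
    stop("dataset_path does not exist: ", dataset_path)
  }
  structure(list(synthetic = synthetic, dataset_path = dataset_path,
                 network_path = network_path, variants = variants,
                 priors = priors, control = control, designs = designs,
                 n_folds = as.integer(n_folds), out_dir = out_dir,
                 seed = as.integer(seed)), class = "experiment_config")
}

#' Read an experiment configuration from a flat-key YAML file
#'
#' Recognized keys: the [synthetic_config()] arguments prefixed with `data_`,
#' the flat sampler/prior keys `trees`, `alpha`, `beta`, `burn_in`, `n_post`,
#' `thin`, `seed`, `sparsity`, `dirichlet_concentration`, `sigma2_shape`,
#' `sigma2_scale`, `sigmamu2_shape`, `sigmamu2_scale`, plus `designs`,
#' `n_folds`, `out_dir`, `variants` (a mapping of variant name to family
#' list).
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  cfg <- yaml::read_yaml(path)
  pick <- function(keys, f) {
    args <- cfg[intersect(keys, names(cfg))]
    do.call(f, args)
  }
  syn_keys <- grep("^data_", names(cfg), value = TRUE)
  syn_args <- cfg[syn_keys]
  names(syn_args) <- sub("^data_", "", syn_keys)
  synthetic <- do.call(synthetic_config, syn_args)
  priors <- pick(c("trees", "alpha", "beta", "sparsity",
                   "dirichlet_concentration", "sigma2_shape", "sigma2_scale",
                   "sigmamu2_shape", "sigmamu2_scale"), bart_priors)
  control <- pick(c("burn_in", "n_post", "thin", "seed"), sampler_control)
  extra <- list(synthetic = synthetic, priors = priors, control = control)
  for (k in c("dataset_path", "network_path", "designs", "n_folds",
              "out_dir", "seed")) {
    if (!is.null(cfg[[k]])) extra[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$variants)) extra$variants <- lapply(cfg$variants, as.character)
  do.call(experiment_config, extra)
}

#' Run the experiment matrix (variants x CV designs)
#'
#' Generates or loads the dataset, and for every predictor-set variant and
#' every requested CV design fits and evaluates the model, writing a per-fold
#' metrics CSV (`design,fold,r2,rmse,cvg95,n_test`), a pooled summary CSV with
#' one row per variant and design, an importance CSV per variant, and a JSON
#' manifest (config echo, per-stage seeds, file checksums, wall-clock). The
#' global seed expands deterministically into the data seed, the fold seeds
#' and the per-fold sampler seeds.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress?
#' @return invisible list with the dataset, per-variant results and the
#'   manifest.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_data <- config$seed
  seed_folds <- config$seed + 1000L
  seed_fit <- config$seed + 2000L

  if (!is.null(config$dataset_path)) {
    dataset <- read_dataset(config$dataset_path)
    network <- if (!is.null(config$network_path)) {
      read_network(config$network_path)
    } else {
      agg <- unique(as.data.frame(dataset)[, c("site_id", "lon", "lat")])
      class(agg) <- c("monitor_network", "data.frame")
      agg
    }
  } else {
    syn <- config$synthetic
    syn$seed <- seed_data
    network <- generate_network(syn$n_monitors, seed = seed_data)
    dataset <- generate_dataset(network, syn)
    write_dataset(dataset, file.path(config$out_dir, "dataset.csv"))
    write_network(network, file.path(config$out_dir, "network.csv"))
  }

  fold_makers <- list(
    ordinary = function() make_ordinary_folds(dataset, config$n_folds,
                                              seed = seed_folds),
    spatial = function() make_spatial_folds(dataset, config$n_folds,
                                            seed = seed_folds),
    cluster = function() make_cluster_folds(network, dataset, config$n_folds,
                                            seed = seed_folds))

  pooled_rows <- list()
  results <- list()
  for (vn in names(config$variants)) {
    fams <- config$variants[[vn]]
    if (length(fams) == 0) fams <- character(0)
    vres <- list()
    for (ds in config$designs) {
      folds <- fold_makers[[ds]]()
      ctl <- config$control
      ctl$seed <- seed_fit + 10L * match(vn, names(config$variants)) +
        100L * match(ds, config$designs)
      cv <- run_cv(dataset, folds, config$priors, ctl, families = fams,
                   verbose = verbose)
      utils::write.csv(cv$per_fold,
                       file.path(config$out_dir,
                                 sprintf("metrics_%s_%s.csv", vn, ds)),
                       row.names = FALSE)
      pooled_rows[[paste(vn, ds)]] <- data.frame(
        variant = vn, design = cv$design, r2 = cv$pooled$r2,
        rmse = cv$pooled$rmse, cvg95 = cv$pooled$cvg95, n = cv$pooled$n)
      vres[[ds]] <- cv
      if (verbose) {
        message(sprintf("variant %s, %s CV: pooled R2=%.3f RMSE=%.3f Cvg95=%.3f",
                        vn, ds, cv$pooled$r2, cv$pooled$rmse, cv$pooled$cvg95))
      }
    }
    ctl <- config$control
    ctl$seed <- seed_fit + match(vn, names(config$variants))
    fit <- run_sampler(dataset, config$priors, ctl, families = fams)
    imp <- variable_importance(fit)
    write_importance(imp, file.path(config$out_dir,
                                    sprintf("importance_%s.csv", vn)))
    vres$fit <- fit
    vres$importance <- imp
    results[[vn]] <- vres
  }
  summary_df <- do.call(rbind, pooled_rows)
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    seed = config$seed,
    seeds = list(data = seed_data, folds = seed_folds, fit_base = seed_fit),
    designs = config$designs,
    variants = config$variants,
    priors = unclass(config$priors), control = unclass(config$control),
    package_version = as.character(utils::packageVersion("bartpm")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, network = network, results = results,
                 summary = summary_df, manifest = manifest))
}
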