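#' Configuration for the synthetic monitor-day generator
#'
#' Bundles every knob of the synthetic data generator that emulates a sparse
#' PM2.5 speciation monitoring design: a modest network of monitors, a
#' 1-in-6-day sampling schedule, and four predictor families (meteorology-like
#' temporal fields, static land-use-like site covariates, CMAQ-like noisy
#' simulations of the latent component means, and AOD-like fractional columns
#' of which only a documented subset is informative), plus pure-noise columns
#' and an optional total-mass column equal to the sum of the latent component
#' means plus measurement noise.
#'
#' @param n_monitors number of monitoring sites (>= 2).
#' @param n_days length of the daily time axis.
#' @param sampling_rate fraction of monitor-days observed, in (0, 1]; the
#'   default 1/6 mimics the 1-in-6-day regulatory schedule.
#' @param n_met,n_landuse,n_cmaq,n_aod,n_noise counts of predictors per family.
#' @param sigma_true residual standard deviation of the response around its
#'   latent mean, in micrograms per cubic metre.
#' @param include_total_mass append a `pm25_total` column (sum of latent
#'   component means plus noise)?
#' @param total_mass_noise_sd measurement noise of the total-mass column.
#' @param cmaq_noise_sd noise added to the latent component means to form the
#'   CMAQ-like columns.
#' @param n_components number of latent species components; component 1 is the
#'   response. At least `max(2, n_cmaq)` components are used.
#' @param seed integer seed; identical configurations give identical datasets.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_monitors = 40L, n_days = 720L,
                             sampling_rate = 1 / 6,
                             n_met = 3L, n_landuse = 3L, n_cmaq = 3L,
                             n_aod = 4L, n_noise = 3L,
                             sigma_true = 0.5,
                             include_total_mass = TRUE,
                             total_mass_noise_sd = 0.5,
                             cmaq_noise_sd = 0.5,
                             n_components = NULL,
                             seed = 1L) {
  counts <- c(n_monitors = n_monitors, n_days = n_days, n_met = n_met,
              n_landuse = n_landuse, n_cmaq = n_cmaq, n_aod = n_aod,
              n_noise = n_noise)
  if (any(counts < 0)) stop("all counts must be nonnegative")
  if (n_monitors < 2) stop("n_monitors must be >= 2")
  if (!(sampling_rate > 0 && sampling_rate <= 1)) {
    stop("sampling_rate must lie in (0, 1]")
  }
  if (sigma_true <= 0) stop("sigma_true must be positive")
  if (is.null(n_components)) n_components <- max(2L, n_cmaq)
  structure(list(
    n_monitors = as.integer(n_monitors), n_days = as.integer(n_days),
    sampling_rate = sampling_rate, n_met = as.integer(n_met),
    n_landuse = as.integer(n_landuse), n_cmaq = as.integer(n_cmaq),
    n_aod = as.integer(n_aod), n_noise = as.integer(n_noise),
    sigma_true = sigma_true, include_total_mass = isTRUE(include_total_mass),
    total_mass_noise_sd = total_mass_noise_sd,
    cmaq_noise_sd = cmaq_noise_sd,
    n_components = as.integer(max(n_components, n_cmaq, 1L)),
    seed = as.integer(seed)), class = "synthetic_config")
}

# evaluate code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a clustered synthetic monitor network
#'
#' Sites are placed over a California-sized lon/lat window by a clustered
#' point process: a few regional blobs (urban areas) plus a uniform background,
#' so that k-means cluster cross-validation on the coordinates is meaningful.
#' Each site also carries three standard-normal static land-use-like scores
#' that [generate_dataset()] recycles for its `lu_*` columns.
#'
#' @param n_monitors number of sites, >= 2.
#' @param seed integer seed; the same `(n_monitors, seed)` always returns the
#'   identical network.
#' @return a `data.frame` of class `monitor_network` with columns `site_id`,
#'   `lon`, `lat` and static covariates `lu_score1..3`.
#' @export
generate_network <- function(n_monitors, seed = 1L) {
  if (n_monitors < 2) stop("n_monitors must be >= 2")
  n_monitors <- as.integer(n_monitors)
  with_seed(seed, {
    n_blob <- 4L
    blob_lon <- runif(n_blob, -123, -115)
    blob_lat <- runif(n_blob, 33, 41)
    in_blob <- runif(n_monitors) < 0.6
    which_blob <- sample.int(n_blob, n_monitors, replace = TRUE)
    lon <- ifelse(in_blob, blob_lon[which_blob] + rnorm(n_monitors, 0, 0.45),
                  runif(n_monitors, -124, -114))
    lat <- ifelse(in_blob, blob_lat[which_blob] + rnorm(n_monitors, 0, 0.45),
                  runif(n_monitors, 32, 42))
    net <- data.frame(
      site_id = sprintf("site_%03d", seq_len(n_monitors)),
      lon = lon, lat = lat,
      lu_score1 = rnorm(n_monitors),
      lu_score2 = rnorm(n_monitors),
      lu_score3 = rnorm(n_monitors),
      stringsAsFactors = FALSE)
    class(net) <- c("monitor_network", "data.frame")
    net
  })
}

# smooth low-rank spatial basis used by the latent fields (not a full GP draw)
spatial_basis <- function(lon, lat) {
  lon0 <- (lon + 119) / 5    # roughly [-1, 1] over the domain
  lat0 <- (lat - 37) / 5
  cbind(
    bump = exp(-((lon + 120.5)^2 + (lat - 37)^2) / (2 * 1.5^2)),
    grad = lat0,
    wave = sin(pi * lon0) * cos(pi * lat0))
}

#' Generate a synthetic monitor-day dataset
#'
#' Builds a complete monitor-day table with response
#' `y = f(X) + Normal(0, sigma_true^2)`. The generating mean for the response
#' component is
#' \deqn{m_1 = 2 + 2\sin(\pi \tilde m_1 \tilde m_2) + 3(\tilde m_3 - 0.5)^2
#'   + 0.4\,lu_1 + 0.2\,lu_2 + g(lon, lat) + 0.4\sin(2\pi t/360 + 1)}
#' where \eqn{\tilde m_j = \mathrm{plogis}(met_j)} are squashed
#' meteorology-like fields (a Friedman-style interaction plus curvature term),
#' `lu_*` are the static site scores, and `g` is a smooth spatial surface with
#' a planted high-concentration bump (a "central-valley" analogue). Additional
#' latent components `m_2, ..., m_C` are independent smooth spatio-temporal
#' fields standing in for the other PM2.5 species. The observable proxies are
#' `cmaq_j = m_j + Normal(0, cmaq_noise_sd^2)` (a noisy simulation of each
#' component), informative `aod_*` columns mixing the latent means with noise
#' (only the first half of the AOD family loads on the response component),
#' pure-noise `noise_*` columns, and optionally
#' `pm25_total = sum_c m_c + Normal(0, total_mass_noise_sd^2)`.
#'
#' Monitor-days are retained completely at random with probability
#' `sampling_rate`. The latent response mean is stored in `true_mean`, and the
#' matrix of all latent component means is attached as attribute
#' `latent_means`.
#'
#' @param network a `monitor_network` from [generate_network()].
#' @param config a [synthetic_config()].
#' @return a `data.frame` of class `species_dataset` keyed by
#'   `(site_id, date_index)` with columns `site_id, date_index, lon, lat`,
#'   predictor columns prefixed by family, `y`, and `true_mean`.
#' @export
generate_dataset <- function(network, config) {
  if (!inherits(config, "synthetic_config")) stop("config must be a synthetic_config")
  if (nrow(network) < 1) stop("network is empty")
  cfg <- config
  with_seed(cfg$seed, {
    ns <- nrow(network)
    nd <- cfg$n_days
    site <- rep(seq_len(ns), each = nd)
    day <- rep(seq_len(nd), times = ns)
    keep <- runif(length(site)) < cfg$sampling_rate
    # guarantee at least one row per site so spatial folds stay meaningful
    first <- match(seq_len(ns), site)
    keep[first] <- TRUE
    site <- site[keep]; day <- day[keep]
    n <- length(site)

    lon <- network$lon[site]
    lat <- network$lat[site]
    sb <- spatial_basis(lon, lat)

    out <- data.frame(site_id = network$site_id[site], date_index = day,
                      lon = lon, lat = lat, stringsAsFactors = FALSE)

    # meteorology-like smooth temporal fields with day-to-day weather noise
    met <- matrix(0, n, cfg$n_met)
    if (cfg$n_met > 0) {
      for (j in seq_len(cfg$n_met)) {
        met[, j] <- 0.9 * sin(2 * pi * day / 360 + j) +
          0.25 * (lat - 37) / 5 + rnorm(n, 0, 0.6)
        out[[paste0("met_", j)]] <- met[, j]
      }
    }

    # static land-use-like site covariates
    if (cfg$n_landuse > 0) {
      lu_all <- as.matrix(network[, c("lu_score1", "lu_score2", "lu_score3")])
      for (j in seq_len(cfg$n_landuse)) {
        k <- ((j - 1) %% 3) + 1
        out[[paste0("lu_", j)]] <-
          if (j <= 3) lu_all[site, k] else lu_all[site, k] + rnorm(ns)[site]
      }
    }

    # response mean: Friedman-style meteorology term + land use + space +
    # latent seasonality not carried by any met column
    mt <- function(j) if (cfg$n_met >= j) stats::plogis(met[, j]) else rep(0.5, n)
    f_met <- 2 * sin(pi * mt(1) * mt(2)) + 3 * (mt(3) - 0.5)^2
    f_lu <- 0
    if (cfg$n_landuse >= 1) f_lu <- f_lu + 0.4 * out[["lu_1"]]
    if (cfg$n_landuse >= 2) f_lu <- f_lu + 0.2 * out[["lu_2"]]
    f_sp <- 1.0 * sb[, "bump"] + 0.25 * sb[, "grad"] + 0.3 * sb[, "wave"]
    f_seas <- 0.4 * sin(2 * pi * day / 360 + 1)
    # unmeasured day-to-day emission/transport variation: part of the latent
    # component mean that no met/lu/coordinate column carries, observable only
    # through the CMAQ-like and total-mass proxies
    xi <- rnorm(n, 0, 0.5)
    # sub-grid spatial structure that a coarse-resolution simulation misses:
    # an iid site-local effect plus a random regional field (low-rank Gaussian
    # bumps with ~1.2 degree range), both absent from the cmaq_* columns, so
    # leave-monitor-out prediction is genuinely harder than interpolation
    u_site <- rnorm(ns, 0, 0.2)[site]
    ctr <- expand.grid(lon = seq(-124, -114, length.out = 5),
                       lat = seq(32, 42, length.out = 5))
    phi <- exp(-(outer(lon, ctr$lon, "-")^2 + outer(lat, ctr$lat, "-")^2) /
                 (2 * 0.8^2))
    u_reg <- as.numeric(phi %*% rnorm(nrow(ctr), 0, 0.5))
    u_local <- u_site + u_reg
    m <- matrix(0, n, cfg$n_components)
    m[, 1] <- 2 + f_met + f_lu + f_sp + f_seas + xi + u_local
    if (cfg$n_components >= 2) {
      for (cc in 2:cfg$n_components) {
        m[, cc] <- 1.5 + 0.5 * sin(2 * pi * day / 360 + 2.1 * cc) +
          0.4 * sb[, ((cc - 1) %% 3) + 1] + rnorm(n, 0, 0.25)
      }
    }

    # CMAQ-like columns: noisy coarse-grid simulations of the latent component
    # means; the sub-grid site/regional structure of the response component is
    # not resolved by the simulation
    if (cfg$n_cmaq > 0) {
      for (j in seq_len(cfg$n_cmaq)) {
        sim <- if (j == 1) m[, 1] - u_local else m[, j]
        out[[paste0("cmaq_", j)]] <- sim + rnorm(n, 0, cfg$cmaq_noise_sd)
      }
    }

    # AOD-like fractional columns: the first ceiling(n_aod / 2) load on the
    # response component, the rest only on the other components
    if (cfg$n_aod > 0) {
      n_inf <- ceiling(cfg$n_aod / 2)
      for (j in seq_len(cfg$n_aod)) {
        other <- if (cfg$n_components >= 2) m[, 2 + (j %% (cfg$n_components - 1))] else 0
        # satellite columns resolve regional but not site-local variation
        base <- if (j <= n_inf) 0.45 * (m[, 1] - u_site) + 0.2 * other else 0.5 * other
        out[[paste0("aod_", j)]] <- base + rnorm(n, 0, 0.5)
      }
    }

    if (cfg$n_noise > 0) {
      for (j in seq_len(cfg$n_noise)) {
        out[[paste0("noise_", j)]] <- rnorm(n)
      }
    }

    if (cfg$include_total_mass) {
      out[["pm25_total"]] <- rowSums(m) +
        if (cfg$total_mass_noise_sd > 0) rnorm(n, 0, cfg$total_mass_noise_sd) else 0
    }

    out[["y"]] <- m[, 1] + rnorm(n, 0, cfg$sigma_true)
    out[["true_mean"]] <- m[, 1]
    attr(out, "latent_means") <- m
    attr(out, "config") <- cfg
    class(out) <- c("species_dataset", "data.frame")
    validate_dataset(out)
    out
  })
}

validate_dataset <- function(d) {
  req <- c("site_id", "date_index", "lon", "lat", "y")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("dataset missing required column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(d$site_id, d$date_index)
  if (anyDuplicated(key)) {
    stop("duplicate (site_id, date_index) key at row ",
         which(duplicated(key))[1], ": ", key[which(duplicated(key))[1]])
  }
  pc <- predictor_columns(d)
  for (cn in c(pc, "y")) {
    v <- d[[cn]]
    if (!is.numeric(v)) stop("non-numeric values in column ", cn)
    if (anyNA(v) || any(!is.finite(v))) {
      stop("missing or non-finite value in column ", cn, " at row ",
           which(!is.finite(v))[1])
    }
  }
  invisible(d)
}

#' Predictor columns of a dataset
#'
#' Returns the names of the model predictors: `lon`, `lat` and every column
#' prefixed by a family tag (`met_`, `lu_`, `cmaq_`, `aod_`, `noise_`) plus
#' `pm25_total` when present. `site_id`, `date_index`, `y` and `true_mean` are
#' never predictors.
#'
#' @param dataset a `species_dataset` (or any conforming data.frame).
#' @param families optional character vector restricting the optional families
#'   (`"cmaq"`, `"aod"`, `"noise"`, `"total"`); the baseline `lon`, `lat`,
#'   `met_*` and `lu_*` columns are always retained.
#' @return character vector of column names.
#' @export
predictor_columns <- function(dataset, families = NULL) {
  nm <- names(dataset)
  base <- c(intersect(c("lon", "lat"), nm),
            grep("^met_|^lu_", nm, value = TRUE))
  opt <- list(cmaq = grep("^cmaq_", nm, value = TRUE),
              aod = grep("^aod_", nm, value = TRUE),
              noise = grep("^noise_", nm, value = TRUE),
              total = intersect("pm25_total", nm))
  if (is.null(families)) families <- names(opt)
  bad <- setdiff(families, names(opt))
  if (length(bad)) {
    stop("unknown predictor famil", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), " (valid: ",
         paste(names(opt), collapse = ", "), ")")
  }
  c(base, unlist(opt[families], use.names = FALSE))
}

#' Extract the predictor matrix of a dataset
#'
#' @inheritParams predictor_columns
#' @return numeric matrix with one column per predictor.
#' @export
model_matrix <- function(dataset, families = NULL) {
  cols <- predictor_columns(dataset, families)
  as.matrix(as.data.frame(dataset)[, cols, drop = FALSE])
}

#' Write / read a monitor-day dataset as CSV
#'
#' The on-disk schema is a plain CSV with header; required columns are
#' `site_id,date_index,lon,lat,y`, predictor columns are prefixed by family,
#' and `true_mean` is optional. Missing predictor cells are not allowed
#' (datasets represent complete retrieval days).
#'
#' @param dataset a `species_dataset`.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `species_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"y" %in% names(d)) stop("parse error: file has no `y` column")
  class(d) <- c("species_dataset", "data.frame")
  validate_dataset(d)
  d
}

#' Write / read a monitor network as CSV (`site_id,lon,lat`, plus covariates)
#' @param network a `monitor_network`.
#' @param path file path.
#' @export
write_network <- function(network, path) {
  utils::write.csv(as.data.frame(network), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "lon", "lat")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("parse error: network missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$site_id)) stop("parse error: duplicate site_id")
  class(d) <- c("monitor_network", "data.frame")
  d
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("<species_dataset> %d monitor-days, %d sites, %d predictors\n",
              nrow(x), length(unique(x$site_id)),
              length(predictor_columns(x))))
  NextMethod()
}
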