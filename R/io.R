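.pkg_version <- function() {
  as.character(utils::packageVersion("tacbake"))
}

# polynomial rolling hash; used for provenance config fingerprints
.cfg_hash <- function(s) {
  h <- 17
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

.provenance <- function(seed = NA, config = NULL) {
  c(sprintf("# tacbake %s", .pkg_version()),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s",
            if (is.null(config)) "none"
            else .cfg_hash(jsonlite::toJSON(config, auto_unbox = TRUE))))
}

.write_csv_prov <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance(seed, config), con)
  utils::write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

.read_csv_prov <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column %s, row %d",
                   df[[cc]][bad[1]], cc, bad[1]))
    df[[cc]] <- v
  }
  df
}

#' Read and write kinetic-series CSV files
#'
#' CSV schema: \code{marker, variety, grain_type, temperature_C, time_s,
#' replicate, value, units}; header row, UTF-8, '.' decimal separator.
#' Files carry provenance comment lines (package version, seed, config
#' fingerprint) prefixed with \code{#}. Round-trips are lossless to 15
#' significant digits.
#'
#' @param series Kinetic-series data frame.
#' @param path File path.
#' @param seed,config Optional provenance metadata recorded in the header.
#' @return \code{read_kinetics_csv}: the series data frame;
#'   \code{write_kinetics_csv}: the path, invisibly.
#' @export
write_kinetics_csv <- function(series, path, seed = NA, config = NULL) {
  .check_series(series)
  .write_csv_prov(series, path, seed, config)
}

#' @rdname write_kinetics_csv
#' @export
read_kinetics_csv <- function(path) {
  df <- .read_csv_prov(
    path,
    required = c("marker", "variety", "grain_type", "temperature_C",
                 "time_s", "replicate", "value", "units"),
    numeric_cols = c("temperature_C", "time_s", "replicate", "value"))
  if (nrow(df) == 0L) {
    warning("empty kinetic-series file: ", path)
    return(df)
  }
  df
}

#' Read and write composition CSV files
#'
#' Schema: \code{variety, grain_type, protein, fiber} (g per 100 g d.m.).
#'
#' @inheritParams write_kinetics_csv
#' @param features Composition data frame.
#' @export
write_composition_csv <- function(features, path, seed = NA, config = NULL) {
  req <- c("variety", "grain_type", "protein", "fiber")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  .write_csv_prov(features, path, seed, config)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  .read_csv_prov(path,
                 required = c("variety", "grain_type", "protein", "fiber"),
                 numeric_cols = c("protein", "fiber"))
}

#' Read and write posterior-summary CSV files
#'
#' Machine-readable table of setting-level posterior medians, credible
#' intervals and diagnostics — the interchange format between the
#' Bayesian and surrogate levels.
#'
#' @inheritParams write_kinetics_csv
#' @param summary Posterior summary data frame (from
#'   \code{\link{fit_tac_bayes}}).
#' @export
write_posterior_csv <- function(summary, path, seed = NA, config = NULL) {
  if (inherits(summary, "tac_hbfit")) summary <- summary$summary
  .write_csv_prov(summary, path, seed, config)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  .read_csv_prov(
    path,
    required = c("setting", "variety", "temperature_C", "marker",
                 "parameter", "median", "q2.5", "q97.5", "rhat", "ess"),
    numeric_cols = c("temperature_C", "median", "q2.5", "q97.5",
                     "rhat", "ess"))
}

#' Write a surrogate model card (JSON)
#'
#' Records kernel family, bandwidth, selected cost and training R-squared
#' per (parameter, marker) model, plus provenance.
#'
#' @param surrogate A \code{tac_surrogate}.
#' @param path Output path.
#' @param seed Optional seed recorded in the card.
#' @export
write_model_card <- function(surrogate, path, seed = NA) {
  stopifnot(inherits(surrogate, "tac_surrogate"))
  card <- list(
    package = paste("tacbake", .pkg_version()),
    seed = seed,
    kernel = list(family = surrogate$kernel$family,
                  epsilon = surrogate$kernel$epsilon,
                  selection = surrogate$kernel$selection),
    rates = as.list(surrogate$rates),
    models = lapply(seq_len(nrow(surrogate$r2)), function(i) {
      r <- surrogate$r2[i, ]
      m <- surrogate$models[[paste(r$marker, r$parameter, sep = ".")]]
      list(marker = r$marker, parameter = r$parameter, cost = r$cost,
           gamma = m$gamma, training_r2 = r$training_r2)
    }))
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' Fully populated configuration reproducing the synthetic seven-setting
#' study; the same structure is read from YAML by
#' \code{\link{read_run_config}}. A committed copy lives at
#' \code{system.file("extdata", "default_config.yaml", package = "tacbake")}.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    markers = c("TP", "ORAC", "FRAP"),
    scaling = list(exponent_scale = 7500, response_scale = 1,
                   overflow_cap = 50),
    design = list(n_times = 16, time_max = 1500, replicates = 2,
                  noise_sd = 0.05, heteroscedastic = FALSE),
    priors = list(hyper_mean_loc = 1, hyper_mean_scale = 1,
                  hyper_sd_scale = 1, noise_sd_scale = 1,
                  hierarchy = "global"),
    mcmc = list(chains = 4, iterations = 3000, burnin = 1000, thin = 3,
                adapt = 1000),
    kernel = list(family = "laplacian", cost_grid = c(0.1, 1, 10, 100, 1000),
                  epsilon = 0.01, selection = "training"),
    rates = list(mode = "default", beta1 = 0.08, beta2 = 0.12),
    sweep = list(variable = "temperature"))
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to \code{\link{default_run_config}} values.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  .merge_config(default_run_config(), user)
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}
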