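#' Built-in reference curve parameters for the seven baking settings
#'
#' Posterior-median parameter triples (theta, alpha1, alpha2) for the seven
#' wheat/rye variety-by-temperature settings of the biscuit-baking study,
#' one triple per antioxidant marker (TP, ORAC, FRAP), on the normalized
#' response scale with rate constants fixed at beta1 = 0.08, beta2 = 0.12.
#' These are the package's default ground truth for simulation studies.
#'
#' @param marker Optional marker filter: \code{"TP"}, \code{"ORAC"} or
#'   \code{"FRAP"}; default returns all three.
#' @return Data frame with columns \code{variety}, \code{grain_type},
#'   \code{temperature_C}, \code{marker}, \code{theta}, \code{alpha1},
#'   \code{alpha2}.
#' @export
reference_curve_params <- function(marker = c("TP", "ORAC", "FRAP")) {
  marker <- match.arg(marker, several.ok = TRUE)
  settings <- data.frame(
    variety       = c("Berdun", "Igor", "Teodor", "Berdun",
                      "Loretto", "Berdun", "Loretto"),
    grain_type    = c("wheat", "rye", "rye", "wheat", "rye", "wheat", "rye"),
    temperature_C = c(180, 180, 180, 200, 200, 220, 220),
    stringsAsFactors = FALSE)
  vals <- list(
    TP = cbind(theta  = c(0.605, 1.497, 1.391, 0.431, 1.717, 0.309, 1.462),
               alpha1 = c(1.985, 0.850, 0.375, 1.960, 0.938, 1.976, 1.020),
               alpha2 = c(0.100, 0.573, 1.013, 0.265, 1.022, 0.566, 2.516)),
    ORAC = cbind(theta  = c(0.291, 0.317, 0.112, 1.875, 0.873, 1.371, 1.140),
                 alpha1 = c(0.826, 0.588, 0.926, 0.134, 1.016, 0.220, 0.062),
                 alpha2 = c(0.117, 0.106, 0.566, 0.564, 3.034, 0.450, 0.686)),
    FRAP = cbind(theta  = c(0.296, 0.231, 0.186, 1.285, 1.131, 1.278, 0.836),
                 alpha1 = c(0.297, 0.246, 0.409, 0.045, 0.090, 0.034, 0.025),
                 alpha2 = c(0.059, 0.061, 0.292, 1.020, 2.658, 0.680, 0.755)))
  out <- do.call(rbind, lapply(marker, function(m) {
    cbind(settings, marker = m, as.data.frame(vals[[m]]))
  }))
  rownames(out) <- NULL
  out[, c("variety", "grain_type", "temperature_C", "marker",
          "theta", "alpha1", "alpha2")]
}

#' Default (synthetic) composition features for the study varieties
#'
#' Protein and fiber contents for the four study varieties are not part of
#' the published record; these values are synthetic placeholders chosen
#' inside realistic wheat/rye ranges (g per 100 g dry matter) and are used
#' as the default second-level predictors.
#'
#' @return Data frame with columns \code{variety}, \code{grain_type},
#'   \code{protein}, \code{fiber}.
#' @export
default_grain_features <- function() {
  data.frame(
    variety    = c("Berdun", "Igor", "Teodor", "Loretto"),
    grain_type = c("wheat", "rye", "rye", "rye"),
    protein    = c(12.5, 9.5, 10.5, 10.0),
    fiber      = c(12.0, 15.5, 16.5, 17.5),
    stringsAsFactors = FALSE)
}

#' Study design for synthetic kinetic series
#'
#' @param settings Data frame with columns \code{variety},
#'   \code{grain_type}, \code{temperature_C}; default the seven study
#'   settings from \code{\link{reference_curve_params}}.
#' @param times Sampling times in seconds, default 16 equally spaced points
#'   in [0, 1500].
#' @param replicates Replicates per time point (default 2, matching baking
#'   in duplicate).
#' @param noise_sd Gaussian measurement noise SD in normalized units
#'   (default 0.05).
#' @param heteroscedastic If \code{TRUE}, the noise SD is
#'   \code{noise_sd * mean response} instead of constant.
#' @return An object of class \code{tac_design}.
#' @export
tac_design <- function(settings = NULL, times = seq(0, 1500, length.out = 16),
                       replicates = 2, noise_sd = 0.05,
                       heteroscedastic = FALSE) {
  if (is.null(settings)) {
    settings <- unique(reference_curve_params("TP")[
      , c("variety", "grain_type", "temperature_C")])
  }
  req <- c("variety", "grain_type", "temperature_C")
  if (!all(req %in% names(settings)))
    stop("settings must have columns: ", paste(req, collapse = ", "))
  key <- paste(settings$variety, settings$temperature_C)
  if (anyDuplicated(key))
    stop("duplicated setting label(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (length(times) == 0L || any(!is.finite(times)) || any(times < 0))
    stop("times must be a non-empty vector of non-negative numbers")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative")
  structure(list(settings = settings, times = sort(times),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 heteroscedastic = isTRUE(heteroscedastic)),
            class = "tac_design")
}

#' @export
print.tac_design <- function(x, ...) {
  cat(sprintf(paste0("TAC study design: %d setting(s), %d time points in ",
                     "[%g, %g] s, %d replicate(s), noise sd %g%s\n"),
              nrow(x$settings), length(x$times), min(x$times), max(x$times),
              x$replicates, x$noise_sd,
              if (x$heteroscedastic) " (proportional to mean)" else ""))
  invisible(x)
}

#' Simulate one kinetic series
#'
#' Draws replicate antioxidant readings around the double-exponential mean
#' curve with additive Gaussian noise.
#'
#' @param params \code{\link{tac_params}} generating truth for the setting.
#' @param variety,grain_type,temperature_C Setting labels.
#' @param marker Assay marker label ("TP", "ORAC" or "FRAP").
#' @param design \code{\link{tac_design}} (its \code{times},
#'   \code{replicates} and noise model are used).
#' @param scaling \code{\link{tac_scaling}}.
#' @return Kinetic-series data frame with columns \code{marker},
#'   \code{variety}, \code{grain_type}, \code{temperature_C},
#'   \code{time_s}, \code{replicate}, \code{value}, \code{units}.
#' @export
simulate_series <- function(params, variety, grain_type, temperature_C,
                            marker = "TP", design = tac_design(),
                            scaling = tac_scaling()) {
  stopifnot(inherits(params, "tac_params"), inherits(design, "tac_design"))
  mu <- evaluate_tac(params, design$times, temperature_C, scaling)
  n_t <- length(design$times)
  reps <- design$replicates
  mu_all <- rep(mu, each = reps)
  sd_all <- if (design$heteroscedastic) design$noise_sd * abs(mu_all)
            else rep(design$noise_sd, length(mu_all))
  eps <- if (design$noise_sd == 0) 0 else stats::rnorm(n_t * reps, 0, sd_all)
  data.frame(
    marker = marker, variety = variety, grain_type = grain_type,
    temperature_C = temperature_C,
    time_s = rep(design$times, each = reps),
    replicate = rep(seq_len(reps), times = n_t),
    value = mu_all + eps, units = "normalized",
    stringsAsFactors = FALSE)
}

#' Simulate a full multi-setting, multi-marker study
#'
#' Generates one kinetic series per (setting, marker) combination of the
#' design, emulating the seven-setting biscuit dataset. Fully reproducible
#' under a fixed seed.
#'
#' @param truth Data frame in the layout of
#'   \code{\link{reference_curve_params}} supplying the generating
#'   (theta, alpha1, alpha2) per setting and marker; default those
#'   reference values.
#' @param design \code{\link{tac_design}}.
#' @param scaling \code{\link{tac_scaling}}.
#' @param seed Integer RNG seed (default 1).
#' @param beta1,beta2 Fixed rate constants used for generation.
#' @return One kinetic-series data frame stacking all series.
#' @examples
#' study <- simulate_study(design = tac_design(), seed = 1)
#' nrow(unique(study[, c("variety", "temperature_C", "marker")]))  # 21
#' @export
simulate_study <- function(truth = reference_curve_params(),
                           design = tac_design(), scaling = tac_scaling(),
                           seed = 1, beta1 = 0.08, beta2 = 0.12) {
  stopifnot(inherits(design, "tac_design"))
  set.seed(seed)
  markers <- unique(truth$marker)
  out <- list()
  for (m in markers) {
    tm <- truth[truth$marker == m, ]
    for (i in seq_len(nrow(design$settings))) {
      s <- design$settings[i, ]
      row <- tm[tm$variety == s$variety &
                  tm$temperature_C == s$temperature_C, ]
      if (nrow(row) != 1L)
        stop(sprintf("no truth entry for setting '%s %g °C' marker %s",
                     s$variety, s$temperature_C, m))
      p <- tac_params(row$theta, row$alpha1, row$alpha2, beta1, beta2)
      out[[length(out) + 1L]] <- simulate_series(
        p, s$variety, s$grain_type, s$temperature_C, m, design, scaling)
    }
  }
  do.call(rbind, out)
}

#' Simulate a grain composition table
#'
#' Draws protein and fiber values uniformly within per-grain-type ranges
#' (g per 100 g dry matter). Defaults are synthetic wheat/rye ranges.
#'
#' @param n_per_type Number of rows per grain type (>= 1).
#' @param ranges Named list with entries \code{wheat} and \code{rye}, each a
#'   list with \code{protein} and \code{fiber} length-2 numeric ranges.
#' @param seed Integer RNG seed.
#' @return Data frame with columns \code{variety}, \code{grain_type},
#'   \code{protein}, \code{fiber}.
#' @export
simulate_grain_table <- function(n_per_type,
                                 ranges = list(
                                   wheat = list(protein = c(10, 16),
                                                fiber = c(10, 15)),
                                   rye = list(protein = c(8, 12),
                                              fiber = c(14, 20))),
                                 seed = 1) {
  if (n_per_type < 1) stop("n_per_type must be >= 1")
  for (g in names(ranges)) for (v in c("protein", "fiber")) {
    r <- ranges[[g]][[v]]
    if (length(r) != 2L || r[1] > r[2])
      stop(sprintf("invalid %s range for %s: bounds must be ordered", v, g))
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(names(ranges), function(g) {
    data.frame(
      variety = sprintf("%s_%02d", g, seq_len(n_per_type)),
      grain_type = g,
      protein = stats::runif(n_per_type, ranges[[g]]$protein[1],
                             ranges[[g]]$protein[2]),
      fiber = stats::runif(n_per_type, ranges[[g]]$fiber[1],
                           ranges[[g]]$fiber[2]),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
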