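#' Exploratory nonlinear least-squares fit of one kinetic series
#'
#' Bound-constrained Levenberg-Marquardt fit of the five-parameter
#' double-exponential curve to one setting's series, used to explore the
#' parameter space and to initialize the MCMC chains of
#' \code{\link{fit_tac_bayes}}. All parameters are constrained
#' non-negative; rates can be frozen at fixed values.
#'
#' @param series Kinetic-series data frame for a single setting (one
#'   temperature).
#' @param scaling \code{\link{tac_scaling}}.
#' @param fix_rates \code{NULL} to estimate beta1/beta2, or a length-2
#'   numeric \code{c(beta1, beta2)} to freeze them.
#' @param start Optional named start values.
#' @return List with \code{estimates} (named vector theta, alpha1, alpha2,
#'   beta1, beta2), \code{rss}, \code{converged}.
#' @export
nls_explore <- function(series, scaling = tac_scaling(), fix_rates = NULL,
                        start = NULL) {
  .check_series(series)
  temp <- unique(series$temperature_C)
  if (length(temp) != 1L)
    stop("nls_explore expects a single-setting series (one temperature)")
  n_free <- if (is.null(fix_rates)) 5L else 3L
  n_times <- length(unique(series$time_s))
  if (n_times < n_free + 1L)
    stop(sprintf(paste0("insufficient data: %d distinct time points for %d ",
                        "free parameters (need at least %d)"),
                 n_times, n_free, n_free + 1L))
  x <- series$time_s * series$temperature_C / scaling$exponent_scale
  y <- series$value
  if (is.null(start)) {
    y0 <- mean(y[series$time_s == min(series$time_s)])
    ymin <- min(tapply(y, series$time_s, mean))
    start <- list(theta = max(ymin, 0),
                  alpha1 = max(y0 - ymin, 0),
                  alpha2 = max((max(y) - ymin) * 100 /
                                 max(exp(0.12 * max(x)), 2), 0))
    if (is.null(fix_rates)) start <- c(start, list(beta1 = 0.08, beta2 = 0.12))
  }
  dat <- data.frame(x = x, y = y)
  fit <- if (is.null(fix_rates)) {
    try(minpack.lm::nlsLM(
      y ~ theta + alpha1 * exp(-beta1 * x) + (alpha2 / 100) * exp(beta2 * x),
      data = dat, start = start,
      lower = rep(0, 5), upper = rep(Inf, 5),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  } else {
    b1 <- fix_rates[1]; b2 <- fix_rates[2]
    try(minpack.lm::nlsLM(
      y ~ theta + alpha1 * exp(-b1 * x) + (alpha2 / 100) * exp(b2 * x),
      data = dat, start = start[c("theta", "alpha1", "alpha2")],
      lower = rep(0, 3), upper = rep(Inf, 3),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    est <- unlist(start)
    if (!is.null(fix_rates))
      est <- c(est[c("theta", "alpha1", "alpha2")],
               beta1 = fix_rates[1], beta2 = fix_rates[2])
    return(list(estimates = est, rss = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  if (!is.null(fix_rates))
    cf <- c(cf, beta1 = unname(fix_rates[1]), beta2 = unname(fix_rates[2]))
  cf <- cf[c("theta", "alpha1", "alpha2", "beta1", "beta2")]
  list(estimates = cf,
       rss = sum(stats::residuals(fit)^2),
       converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the rate constants to freeze
#'
#' The rate constants beta1 and beta2 have little influence on curve shape
#' compared with the amplitudes, so they are frozen before the Bayesian
#' stage. Default mode returns the conventional values (0.08, 0.12);
#' data-driven mode takes the medians of the exploratory estimates.
#'
#' @param explorations List of \code{\link{nls_explore}} results.
#' @param mode \code{"default"} or \code{"data"}.
#' @param defaults Length-2 fallback values.
#' @return Named numeric \code{c(beta1, beta2)} with attribute
#'   \code{"mode"} recording the provenance of the choice.
#' @export
fix_rate_constants <- function(explorations = list(), mode = c("default", "data"),
                               defaults = c(beta1 = 0.08, beta2 = 0.12)) {
  mode <- match.arg(mode)
  if (mode == "data") {
    ok <- Filter(function(e) isTRUE(e$converged), explorations)
    if (length(ok) == 0L) {
      warning("no converged explorations; falling back to default rates")
      return(structure(defaults, mode = "default-fallback"))
    }
    b1 <- stats::median(vapply(ok, function(e) e$estimates["beta1"], 0))
    b2 <- stats::median(vapply(ok, function(e) e$estimates["beta2"], 0))
    return(structure(c(beta1 = b1, beta2 = b2), mode = "data"))
  }
  structure(defaults, mode = "default")
}
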