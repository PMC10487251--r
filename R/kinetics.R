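#' Double-exponential kinetic parameters
#'
#' Constructs and validates the parameter vector of the baking kinetics
#' curve
#' \deqn{\hat{Y}(t, T) = \theta + \alpha_1 e^{-\beta_1 x} +
#'   \frac{\alpha_2}{100} e^{\beta_2 x}, \qquad x = tT/c,}
#' where the negative exponential describes thermal degradation of native
#' antioxidants and the positive exponential de novo formation of Maillard
#' reaction products. \code{c} is the exponent scale of
#' \code{\link{tac_scaling}}.
#'
#' @param theta Baseline asymptote, normalized response units (>= 0).
#' @param alpha1 Degradation amplitude, normalized units (>= 0).
#' @param alpha2 Formation amplitude, normalized units (>= 0); enters the
#'   model divided by 100.
#' @param beta1 Degradation rate constant (> 0), default 0.08.
#' @param beta2 Formation rate constant (> 0), default 0.12.
#' @return An object of class \code{tac_params}.
#' @examples
#' p <- tac_params(theta = 0.605, alpha1 = 1.985, alpha2 = 0.100)
#' evaluate_tac(p, time = 0, temperature = 180)  # 2.591
#' @export
tac_params <- function(theta, alpha1, alpha2, beta1 = 0.08, beta2 = 0.12) {
  vals <- c(theta = unname(theta), alpha1 = unname(alpha1),
            alpha2 = unname(alpha2), beta1 = unname(beta1),
            beta2 = unname(beta2))
  if (any(!is.finite(vals)))
    stop("all curve parameters must be finite")
  if (theta < 0 || alpha1 < 0 || alpha2 < 0)
    stop("theta, alpha1 and alpha2 must be non-negative")
  if (beta1 <= 0 || beta2 <= 0)
    stop("rate constants beta1 and beta2 must be positive")
  structure(as.list(vals), class = "tac_params")
}

#' @export
print.tac_params <- function(x, ...) {
  cat("Double-exponential TAC curve parameters\n")
  cat(sprintf("  theta  = %.4f   (baseline)\n", x$theta))
  cat(sprintf("  alpha1 = %.4f   (degradation amplitude)\n", x$alpha1))
  cat(sprintf("  alpha2 = %.4f   (formation amplitude, /100 in model)\n",
              x$alpha2))
  cat(sprintf("  beta1  = %.4f, beta2 = %.4f (rate constants)\n",
              x$beta1, x$beta2))
  invisible(x)
}

#' Scaling conventions for the kinetic model
#'
#' The raw product of time (s) and temperature (degC) is divided by
#' \code{exponent_scale} before entering the exponentials, so that the
#' dimensionless argument \code{x = t*T/exponent_scale} stays in a range
#' where rate constants of order 0.1 are meaningful over a 0--1500 s bake
#' at 175--225 degC. Responses are divided by \code{response_scale} to map
#' raw assay units (mg GAE, umol TE, umol Fe per 100 g d.m.) onto the
#' normalized scale the curve parameters live on.
#'
#' @param exponent_scale Positive divisor applied to t*T (default 7500).
#' @param response_scale Positive factor mapping raw assay units to the
#'   normalized scale (default 1, i.e. data already normalized).
#' @param overflow_cap Maximum allowed value of \code{beta2 * x}; larger
#'   arguments raise an error instead of silently overflowing (default 50).
#' @return An object of class \code{tac_scaling}.
#' @export
tac_scaling <- function(exponent_scale = 7500, response_scale = 1,
                        overflow_cap = 50) {
  if (!is.finite(exponent_scale) || exponent_scale <= 0)
    stop("exponent_scale must be a positive number")
  if (!is.finite(response_scale) || response_scale <= 0)
    stop("response_scale must be a positive number")
  if (!is.finite(overflow_cap) || overflow_cap <= 0)
    stop("overflow_cap must be a positive number")
  structure(list(exponent_scale = exponent_scale,
                 response_scale = response_scale,
                 overflow_cap = overflow_cap),
            class = "tac_scaling")
}

#' Evaluate the baking kinetics curve
#'
#' Computes the normalized antioxidant response at given baking times and
#' temperatures. Vectorized over \code{time} and \code{temperature}
#' (recycled against each other).
#'
#' @param params A \code{\link{tac_params}} object.
#' @param time Baking time in seconds (>= 0).
#' @param temperature Baking temperature in degC (> 0).
#' @param scaling A \code{\link{tac_scaling}} object.
#' @return Numeric vector of normalized responses.
#' @export
evaluate_tac <- function(params, time, temperature, scaling = tac_scaling()) {
  stopifnot(inherits(params, "tac_params"), inherits(scaling, "tac_scaling"))
  if (length(time) == 0L || length(temperature) == 0L)
    stop("time and temperature must be non-empty")
  if (any(!is.finite(time)) || any(!is.finite(temperature)))
    stop("time and temperature must be finite")
  if (any(time < 0)) stop("time must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive")
  x <- time * temperature / scaling$exponent_scale
  if (any(params$beta2 * x > scaling$overflow_cap))
    stop(sprintf(paste0("formation exponential overflows: beta2 * t*T/%g ",
                        "exceeds the cap %g; check exponent_scale"),
                 scaling$exponent_scale, scaling$overflow_cap))
  params$theta +
    params$alpha1 * exp(-params$beta1 * x) +
    (params$alpha2 / 100) * exp(params$beta2 * x)
}

#' Turning point of the kinetic curve
#'
#' Time at which the curve switches from net degradation to net formation.
#' In the scaled coordinate \code{x = t*T/c} the interior minimizer is
#' closed-form:
#' \deqn{x^* = \frac{\log(100\,\alpha_1 \beta_1 / (\alpha_2 \beta_2))}
#'   {\beta_1 + \beta_2}.}
#'
#' @inheritParams evaluate_tac
#' @param time_max Upper edge of the observation window in seconds
#'   (default 1500); minima beyond it are flagged out-of-window.
#' @return A list with elements \code{x_star} (scaled minimizer),
#'   \code{time_s} (minimizer in seconds, \code{NA} when monotone), and
#'   \code{status}: \code{"interior"}, \code{"out_of_window"} (t* beyond
#'   \code{time_max}), \code{"before_window"} (x* <= 0, curve increasing
#'   throughout), or \code{"monotone"} (alpha1 or alpha2 zero).
#' @export
turning_point <- function(params, temperature, scaling = tac_scaling(),
                          time_max = 1500) {
  stopifnot(inherits(params, "tac_params"), inherits(scaling, "tac_scaling"))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive number")
  if (params$alpha1 == 0 || params$alpha2 == 0)
    return(list(x_star = NA_real_, time_s = NA_real_, status = "monotone"))
  x_star <- log(100 * params$alpha1 * params$beta1 /
                  (params$alpha2 * params$beta2)) /
    (params$beta1 + params$beta2)
  if (x_star <= 0)
    return(list(x_star = x_star, time_s = NA_real_, status = "before_window"))
  t_star <- x_star * scaling$exponent_scale / temperature
  status <- if (t_star > time_max) "out_of_window" else "interior"
  list(x_star = x_star, time_s = t_star, status = status)
}

#' Normalize or denormalize a kinetic series
#'
#' Divides (or multiplies) the \code{value} column of a kinetic-series data
#' frame by the \code{response_scale} of a \code{\link{tac_scaling}},
#' flipping the \code{units} flag between \code{"raw"} and
#' \code{"normalized"}.
#'
#' @param series A kinetic-series data frame (see
#'   \code{\link{simulate_series}} for the schema).
#' @param scaling A \code{\link{tac_scaling}} with the per-marker
#'   \code{response_scale}.
#' @return The series with rescaled \code{value} and updated \code{units}.
#' @export
normalize_response <- function(series, scaling) {
  stopifnot(inherits(scaling, "tac_scaling"))
  .check_series(series)
  if (any(series$units == "normalized"))
    warning("series already flagged normalized; rescaling anyway")
  series$value <- series$value / scaling$response_scale
  series$units <- "normalized"
  series
}

#' @rdname normalize_response
#' @export
denormalize_response <- function(series, scaling) {
  stopifnot(inherits(scaling, "tac_scaling"))
  .check_series(series)
  series$value <- series$value * scaling$response_scale
  series$units <- "raw"
  series
}

#' Grand-mean response scale for a series
#'
#' Convenience helper implementing the default normalization: the
#' arithmetic mean of all response values of one marker's series.
#'
#' @param series A kinetic-series data frame.
#' @return Positive scalar suitable as \code{response_scale}.
#' @export
grand_mean_scale <- function(series) {
  .check_series(series)
  m <- mean(series$value)
  if (!is.finite(m) || m <= 0)
    stop("grand mean of the series is not a positive number")
  m
}

.check_series <- function(series) {
  req <- c("marker", "variety", "grain_type", "temperature_C",
           "time_s", "replicate", "value", "units")
  miss <- setdiff(req, names(series))
  if (length(miss))
    stop("kinetic series is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(series) == 0L) stop("kinetic series has no observations")
  if (any(!is.finite(series$value))) stop("non-finite response values")
  if (any(series$time_s < 0)) stop("negative times in series")
  invisible(TRUE)
}
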