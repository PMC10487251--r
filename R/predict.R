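#' End-to-end predicted TAC curve
#'
#' Composes the two modelling levels: the surrogate predicts the curve
#' parameters from (grain type, protein, fiber, temperature), and the
#' double-exponential forward model evaluates them over a time grid.
#'
#' @param surrogate A \code{\link{fit_tac_surrogate}} model.
#' @param grain_type,protein,fiber,temperature Input features.
#' @param times Time grid in seconds (default 16 points in [0, 1500]).
#' @param marker Marker to predict.
#' @param scaling \code{\link{tac_scaling}}.
#' @return Data frame of class \code{tac_curve}: columns \code{marker},
#'   \code{grain_type}, \code{protein}, \code{fiber},
#'   \code{temperature_C}, \code{time_s}, \code{value} (normalized), plus
#'   attribute \code{"params"} (the predicted \code{\link{tac_params}}).
#' @export
predict_tac_curve <- function(surrogate, grain_type, protein, fiber,
                              temperature,
                              times = seq(0, 1500, length.out = 16),
                              marker = "TP", scaling = tac_scaling()) {
  if (length(times) == 0L) stop("time grid must be non-empty")
  p <- predict_params(surrogate, grain_type, protein, fiber, temperature,
                      marker)
  out <- data.frame(marker = marker, grain_type = grain_type,
                    protein = protein, fiber = fiber,
                    temperature_C = temperature, time_s = times,
                    value = evaluate_tac(p, times, temperature, scaling),
                    stringsAsFactors = FALSE)
  attr(out, "params") <- p
  class(out) <- c("tac_curve", "data.frame")
  out
}

#' R-squared of a predicted curve against reference observations
#'
#' Matches reference observation times to the prediction grid (linear
#' interpolation of the prediction when times differ) and computes
#' \code{\link{r_squared}} of reference values against predicted values.
#'
#' @param predicted A \code{tac_curve} from \code{\link{predict_tac_curve}}
#'   (or any data frame with \code{time_s} and \code{value}).
#' @param reference A kinetic-series data frame.
#' @param interpolate Allow linear interpolation of the prediction at
#'   reference times not on the grid (default \code{TRUE}).
#' @return Scalar R-squared.
#' @export
curve_r_squared <- function(predicted, reference, interpolate = TRUE) {
  .check_series(reference)
  tr <- reference$time_s
  tp <- predicted$time_s
  if (!interpolate && !all(tr %in% tp))
    stop("reference times not contained in prediction grid; enable interpolation")
  if (min(tr) < min(tp) || max(tr) > max(tp))
    stop("no usable time overlap between prediction grid and reference")
  pred_at <- stats::approx(tp, predicted$value, xout = tr)$y
  r_squared(reference$value, pred_at)
}

#' One-at-a-time local sensitivity sweep
#'
#' Varies one input (temperature, protein or fiber) over a grid while all
#' other features stay fixed, predicting one full TAC curve per grid
#' value. Default temperature grid: 175 to 225 degC in 5 degC steps.
#'
#' @param surrogate A \code{tac_surrogate}.
#' @param base Named list/row with \code{grain_type}, \code{protein},
#'   \code{fiber}, \code{temperature} — the reference input.
#' @param variable One of \code{"temperature"}, \code{"protein"},
#'   \code{"fiber"}.
#' @param grid Grid of values for the swept variable; defaults:
#'   temperature \code{seq(175, 225, 5)}, protein/fiber base value
#'   +/- 20\% in 5 steps.
#' @param times Prediction time grid (default 16 points in [0, 1500] s).
#' @param marker Marker to predict.
#' @param scaling \code{\link{tac_scaling}}.
#' @return Object of class \code{tac_sweep}: \code{curves} (stacked
#'   prediction data frame with a \code{grid_value} column), \code{summary}
#'   (final-time value per grid value, their range, and the local slope of
#'   the final value in the swept variable).
#' @export
sensitivity_sweep <- function(surrogate, base, variable = "temperature",
                              grid = NULL,
                              times = seq(0, 1500, length.out = 16),
                              marker = "TP", scaling = tac_scaling()) {
  valid <- c("temperature", "protein", "fiber")
  if (!variable %in% valid)
    stop("unknown variable '", variable, "'; must be one of: ",
         paste(valid, collapse = ", "))
  if (is.null(grid)) {
    grid <- if (variable == "temperature") seq(175, 225, by = 5)
            else seq(0.8, 1.2, length.out = 5) * base[[variable]]
  }
  if (length(grid) == 0L) stop("grid must be non-empty")
  curves <- lapply(grid, function(v) {
    inp <- base
    inp[[variable]] <- v
    cv <- suppressWarnings(predict_tac_curve(
      surrogate, inp$grain_type, inp$protein, inp$fiber, inp$temperature,
      times, marker, scaling))
    cv$grid_value <- v
    cv
  })
  stacked <- do.call(rbind, curves)
  t_end <- max(times)
  finals <- vapply(curves, function(cv) cv$value[cv$time_s == t_end][1], 0)
  slope <- if (length(grid) > 1 && stats::var(grid) > 0)
    unname(stats::coef(stats::lm(finals ~ grid))[2]) else NA_real_
  structure(list(
    variable = variable, grid = grid, base = base, marker = marker,
    curves = stacked,
    summary = list(final_values = finals,
                   final_range = diff(range(finals)),
                   final_slope = slope, time_end = t_end)),
    class = "tac_sweep")
}

#' Spread of predictions across the sweep at a given time
#'
#' @param sweep A \code{tac_sweep}.
#' @param time_s Time (s) at which to measure the across-grid spread; must
#'   be on the prediction grid.
#' @return Range (max - min) of predicted values across the sweep grid.
#' @export
sweep_spread <- function(sweep, time_s) {
  stopifnot(inherits(sweep, "tac_sweep"))
  v <- sweep$curves$value[sweep$curves$time_s == time_s]
  if (length(v) == 0L) stop("time_s not on the prediction grid")
  diff(range(v))
}

#' @export
print.tac_sweep <- function(x, ...) {
  cat(sprintf("Local sensitivity sweep of %s (%s marker): %d curves\n",
              x$variable, x$marker, length(x$grid)))
  cat(sprintf("  grid: %s\n", paste(signif(x$grid, 4), collapse = ", ")))
  cat(sprintf("  value range at t = %g s: %.4f; local slope: %.5f per unit %s\n",
              x$summary$time_end, x$summary$final_range,
              x$summary$final_slope, x$variable))
  invisible(x)
}

#' @export
plot.tac_sweep <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$grid), "Zissou 1")
  sp <- split(x$curves, x$curves$grid_value)
  ylim <- range(x$curves$value)
  graphics::plot(NULL, xlim = range(x$curves$time_s), ylim = ylim,
                 xlab = "time (s)", ylab = "predicted normalized response",
                 main = sprintf("Sensitivity to %s (%s)", x$variable,
                                x$marker), ...)
  for (i in seq_along(sp))
    graphics::lines(sp[[i]]$time_s, sp[[i]]$value, col = cols[i], lwd = 1.5)
  graphics::legend("topleft", legend = signif(sort(x$grid), 4), col = cols,
                   lwd = 1.5, cex = 0.6, title = x$variable, bty = "n")
  invisible(x)
}
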