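#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. Unbounded below: a model fitting
#' worse than the mean predictor yields a negative value.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return Scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("non-finite values in observed or predicted")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R-squared undefined: observed values are all identical")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' SVR kernel configuration
#'
#' The surrogate uses an exponential (Laplacian) kernel
#' \eqn{K(u,v) = \exp(-\gamma \|u - v\|)} by default; a squared-exponential
#' (Gaussian RBF) option is available.
#'
#' @param family \code{"laplacian"} or \code{"rbf"}.
#' @param gamma Kernel bandwidth (> 0); default \code{NULL} means
#'   1/(number of features) after standardization.
#' @param cost_grid Candidate SVR cost values C (> 0).
#' @param epsilon SVR tube width (>= 0) on the normalized parameter scale.
#' @param selection \code{"training"} R-squared (default) or \code{"loo"}
#'   leave-one-out R-squared for cost selection.
#' @return An object of class \code{tac_kernel}.
#' @export
tac_kernel <- function(family = c("laplacian", "rbf"), gamma = NULL,
                       cost_grid = c(0.1, 1, 10, 100, 1000),
                       epsilon = 0.01, selection = c("training", "loo")) {
  family <- match.arg(family)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  if (any(cost_grid <= 0)) stop("all costs must be positive")
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(list(family = family, gamma = gamma, cost_grid = cost_grid,
                 epsilon = epsilon, selection = match.arg(selection)),
            class = "tac_kernel")
}

#' Build per-parameter training tables from a posterior summary
#'
#' Joins setting-level posterior medians with the composition features,
#' producing one table per (parameter, marker) pair with predictors
#' grain type (wheat = 0, rye = 1), protein, fiber, temperature.
#'
#' @param posterior Posterior summary data frame (the \code{summary} of a
#'   \code{\link{fit_tac_bayes}} fit, or the same schema read from CSV), or
#'   a \code{tac_hbfit}.
#' @param features Data frame with \code{variety}, \code{grain_type},
#'   \code{protein}, \code{fiber} (default
#'   \code{\link{default_grain_features}}).
#' @return Named list of training tables, names \code{"<marker>.<param>"};
#'   each a data frame with columns \code{grain}, \code{protein},
#'   \code{fiber}, \code{temperature}, \code{target}.
#' @export
build_training_table <- function(posterior,
                                 features = default_grain_features()) {
  if (inherits(posterior, "tac_hbfit")) posterior <- posterior$summary
  req <- c("variety", "temperature_C", "marker", "parameter", "median")
  if (!all(req %in% names(posterior)))
    stop("posterior summary must have columns: ", paste(req, collapse = ", "))
  posterior <- posterior[posterior$parameter %in%
                           c("theta", "alpha1", "alpha2"), ]
  fi <- match(posterior$variety, features$variety)
  if (anyNA(fi)) {
    bad <- unique(paste(posterior$variety[is.na(fi)],
                        posterior$temperature_C[is.na(fi)]))
    stop("no composition features for setting(s): ",
         paste(bad, collapse = ", "))
  }
  grain01 <- ifelse(features$grain_type[fi] == "rye", 1, 0)
  out <- split(
    data.frame(grain = grain01, protein = features$protein[fi],
               fiber = features$fiber[fi],
               temperature = posterior$temperature_C,
               target = posterior$median),
    paste(posterior$marker, posterior$parameter, sep = "."))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

.make_kernel <- function(kernel, gamma) {
  if (kernel$family == "laplacian") kernlab::laplacedot(sigma = gamma)
  else kernlab::rbfdot(sigma = gamma)
}

#' Train one support-vector regression on a training table
#'
#' Standardizes the features (zero-variance columns are dropped with a
#' warning), fits an epsilon-SVR for every cost in the grid and keeps the
#' cost maximizing R-squared (training by default, leave-one-out
#' optionally). Deterministic given table and configuration.
#'
#' @param table One training table from \code{\link{build_training_table}}.
#' @param kernel \code{\link{tac_kernel}}.
#' @return List with the fitted \code{ksvm} model, \code{cost},
#'   \code{r2}, standardization constants \code{center}/\code{scale} and
#'   the retained feature names.
#' @export
train_svr <- function(table, kernel = tac_kernel()) {
  stopifnot(inherits(kernel, "tac_kernel"))
  if (nrow(table) < 2L) stop("training table needs at least 2 rows")
  if (anyNA(table)) stop("training table contains missing values")
  y <- table$target
  if (stats::var(y) == 0)
    stop("untrainable target: all target values identical (R-squared undefined)")
  X <- as.matrix(table[, setdiff(names(table), "target"), drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0L) stop("no informative features left")
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  gamma <- kernel$gamma %||% (1 / ncol(Xs))
  kern <- .make_kernel(kernel, gamma)

  fit_one <- function(Xm, ym, C) {
    kernlab::ksvm(Xm, ym, type = "eps-svr", kernel = kern, C = C,
                  epsilon = kernel$epsilon, scaled = FALSE)
  }
  score <- vapply(kernel$cost_grid, function(C) {
    if (kernel$selection == "loo") {
      pred <- vapply(seq_len(nrow(Xs)), function(i) {
        m <- fit_one(Xs[-i, , drop = FALSE], y[-i], C)
        as.numeric(kernlab::predict(m, Xs[i, , drop = FALSE]))
      }, 0)
    } else {
      m <- fit_one(Xs, y, C)
      pred <- as.numeric(kernlab::predict(m, Xs))
    }
    r_squared(y, pred)
  }, 0)
  best <- which.max(score)
  model <- fit_one(Xs, y, kernel$cost_grid[best])
  list(model = model, cost = kernel$cost_grid[best], r2 = score[best],
       gamma = gamma, center = ctr, scale = sds, features = colnames(X))
}

#' Fit the second-level SVR surrogate
#'
#' Trains one support-vector regression per (curve parameter, marker)
#' pair, regressing the setting-level posterior medians on grain type,
#' protein, fiber and baking temperature.
#'
#' @param posterior A \code{tac_hbfit}, a list of them (one per marker), or
#'   a posterior summary data frame covering one or more markers.
#' @param features Composition features (see
#'   \code{\link{build_training_table}}).
#' @param kernel \code{\link{tac_kernel}}.
#' @param rates Fixed \code{c(beta1, beta2)} attached to predictions.
#' @return Object of class \code{tac_surrogate}: per-pair models, training
#'   R-squared table, feature ranges for extrapolation checks.
#' @export
fit_tac_surrogate <- function(posterior, features = default_grain_features(),
                              kernel = tac_kernel(),
                              rates = fix_rate_constants()) {
  if (inherits(posterior, "tac_hbfit")) posterior <- posterior$summary
  if (is.list(posterior) && !is.data.frame(posterior))
    posterior <- do.call(rbind, lapply(posterior, function(p) {
      if (inherits(p, "tac_hbfit")) p$summary else p
    }))
  tables <- build_training_table(posterior, features)
  models <- lapply(tables, train_svr, kernel = kernel)
  r2 <- data.frame(
    marker = sub("\\..*", "", names(models)),
    parameter = sub(".*\\.", "", names(models)),
    cost = vapply(models, `[[`, 0, "cost"),
    training_r2 = vapply(models, `[[`, 0, "r2"),
    stringsAsFactors = FALSE)
  rownames(r2) <- NULL
  Xall <- tables[[1]][, c("grain", "protein", "fiber", "temperature")]
  structure(list(models = models, kernel = kernel, rates = rates,
                 features = features, r2 = r2,
                 ranges = apply(as.matrix(Xall), 2, range)),
            class = "tac_surrogate")
}

#' @export
print.tac_surrogate <- function(x, ...) {
  cat(sprintf("SVR surrogate (%s kernel, epsilon = %g): %d models\n",
              x$kernel$family, x$kernel$epsilon, length(x$models)))
  print(transform(x$r2, training_r2 = round(training_r2, 3)))
  invisible(x)
}

#' @export
summary.tac_surrogate <- function(object, ...) object$r2

#' Predict curve parameters from composition and temperature
#'
#' Evaluates the per-parameter SVRs of one marker at the supplied
#' features. Rate constants are attached at their frozen values; negative
#' SVR outputs are clamped to zero (with a warning) so the result is a
#' valid parameter set. Features outside the training ranges trigger an
#' extrapolation warning.
#'
#' @param surrogate A \code{tac_surrogate}.
#' @param grain_type \code{"wheat"} or \code{"rye"}.
#' @param protein,fiber Composition in g per 100 g d.m.
#' @param temperature Baking temperature in degC.
#' @param marker Marker whose parameters to predict.
#' @return A \code{\link{tac_params}} object.
#' @export
predict_params <- function(surrogate, grain_type, protein, fiber,
                           temperature, marker = "TP") {
  stopifnot(inherits(surrogate, "tac_surrogate"))
  grain_type <- match.arg(grain_type, c("wheat", "rye"))
  xnew <- c(grain = if (grain_type == "rye") 1 else 0,
            protein = protein, fiber = fiber, temperature = temperature)
  rng <- surrogate$ranges
  outside <- xnew < rng[1, colnames(rng)] | xnew > rng[2, colnames(rng)]
  if (any(outside))
    warning("extrapolating beyond training range for: ",
            paste(names(xnew)[outside], collapse = ", "))
  val <- vapply(c("theta", "alpha1", "alpha2"), function(pp) {
    key <- paste(marker, pp, sep = ".")
    m <- surrogate$models[[key]]
    if (is.null(m)) stop("no trained model for ", key)
    xs <- (xnew[m$features] - m$center) / m$scale
    as.numeric(kernlab::predict(m$model, matrix(xs, nrow = 1,
                                                dimnames = list(NULL, m$features))))
  }, 0)
  if (any(val < 0)) {
    warning("negative SVR output clamped to 0 for: ",
            paste(names(val)[val < 0], collapse = ", "))
    val <- pmax(val, 0)
  }
  tac_params(val["theta"], val["alpha1"], val["alpha2"],
             surrogate$rates[1], surrogate$rates[2])
}

#' @export
predict.tac_surrogate <- function(object, newdata, marker = "TP", ...) {
  req <- c("grain_type", "protein", "fiber", "temperature")
  if (!all(req %in% names(newdata)))
    stop("newdata must have columns: ", paste(req, collapse = ", "))
  lapply(seq_len(nrow(newdata)), function(i) {
    predict_params(object, newdata$grain_type[i], newdata$protein[i],
                   newdata$fiber[i], newdata$temperature[i], marker)
  })
}
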