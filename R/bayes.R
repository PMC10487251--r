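#' Prior configuration for the hierarchical fit
#'
#' Weakly informative priors on the normalized response scale, where the
#' curve amplitudes lie roughly in [0, 3]: setting-level theta, alpha1,
#' alpha2 are Normal(hyper-mean, hyper-SD) truncated at zero; hyper-means
#' are Normal(\code{hyper_mean_loc}, \code{hyper_mean_scale}) truncated at
#' zero; hyper-SDs and the observation-noise SD are half-Normal.
#'
#' @param hyper_mean_loc,hyper_mean_scale Location and scale of the
#'   truncated-Normal hyper-mean prior (defaults 1, 1).
#' @param hyper_sd_scale Half-Normal scale of the hyper-SD priors
#'   (default 1).
#' @param noise_sd_scale Half-Normal scale of the observation-noise SD
#'   prior (default 1).
#' @param hierarchy \code{"global"}: all settings share one hyperprior per
#'   parameter; \code{"grain"}: separate hyperpriors per grain type.
#' @return An object of class \code{tac_priors}.
#' @export
tac_priors <- function(hyper_mean_loc = 1, hyper_mean_scale = 1,
                       hyper_sd_scale = 1, noise_sd_scale = 1,
                       hierarchy = c("global", "grain")) {
  if (hyper_mean_scale <= 0 || hyper_sd_scale <= 0 || noise_sd_scale <= 0)
    stop("prior scales must be positive")
  structure(list(hyper_mean_loc = hyper_mean_loc,
                 hyper_mean_scale = hyper_mean_scale,
                 hyper_sd_scale = hyper_sd_scale,
                 noise_sd_scale = noise_sd_scale,
                 hierarchy = match.arg(hierarchy)),
            class = "tac_priors")
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2, default 4).
#' @param iterations Post-burn-in iterations per chain (default 3000).
#' @param burnin Burn-in iterations (default 1000).
#' @param thin Thinning interval (default 3).
#' @param adapt JAGS adaptation steps (default 1000).
#' @return An object of class \code{tac_mcmc}.
#' @export
tac_mcmc <- function(chains = 4, iterations = 3000, burnin = 1000,
                     thin = 3, adapt = 1000) {
  if (chains < 2) stop("at least 2 chains are required for diagnostics")
  if (iterations <= 0) stop("iterations must be positive")
  if (burnin < 0) stop("burnin must be >= 0")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 adapt = as.integer(adapt)),
            class = "tac_mcmc")
}

.jags_model_string <- function(hierarchy) {
  hyper <- if (hierarchy == "grain") {
    "
  for (g in 1:G) {
    mu_theta[g]  ~ dnorm(hm_loc, hm_prec) T(0,)
    mu_alpha1[g] ~ dnorm(hm_loc, hm_prec) T(0,)
    mu_alpha2[g] ~ dnorm(hm_loc, hm_prec) T(0,)
    sigma_theta[g]  ~ dnorm(0, hs_prec) T(1.0E-6,)
    sigma_alpha1[g] ~ dnorm(0, hs_prec) T(1.0E-6,)
    sigma_alpha2[g] ~ dnorm(0, hs_prec) T(1.0E-6,)
  }
  for (j in 1:S) {
    theta[j]  ~ dnorm(mu_theta[grp[j]],  pow(sigma_theta[grp[j]],  -2)) T(0,)
    alpha1[j] ~ dnorm(mu_alpha1[grp[j]], pow(sigma_alpha1[grp[j]], -2)) T(0,)
    alpha2[j] ~ dnorm(mu_alpha2[grp[j]], pow(sigma_alpha2[grp[j]], -2)) T(0,)
  }"
  } else {
    "
  mu_theta  ~ dnorm(hm_loc, hm_prec) T(0,)
  mu_alpha1 ~ dnorm(hm_loc, hm_prec) T(0,)
  mu_alpha2 ~ dnorm(hm_loc, hm_prec) T(0,)
  sigma_theta  ~ dnorm(0, hs_prec) T(1.0E-6,)
  sigma_alpha1 ~ dnorm(0, hs_prec) T(1.0E-6,)
  sigma_alpha2 ~ dnorm(0, hs_prec) T(1.0E-6,)
  for (j in 1:S) {
    theta[j]  ~ dnorm(mu_theta,  pow(sigma_theta,  -2)) T(0,)
    alpha1[j] ~ dnorm(mu_alpha1, pow(sigma_alpha1, -2)) T(0,)
    alpha2[j] ~ dnorm(mu_alpha2, pow(sigma_alpha2, -2)) T(0,)
  }"
  }
  paste0("model {
  for (i in 1:N) {
    mu[i] <- theta[s[i]] + alpha1[s[i]] * exp(-beta1 * x[i]) +
             (alpha2[s[i]] / 100) * exp(beta2 * x[i])
    y[i] ~ dnorm(mu[i], tau_y)
  }", hyper, "
  sigma_y ~ dnorm(0, ns_prec) T(1.0E-6,)
  tau_y <- pow(sigma_y, -2)
}")
}

#' Fit the hierarchical Bayesian kinetic model
#'
#' First modelling level: for one antioxidant marker, jointly estimates the
#' setting-level parameters (theta, alpha1, alpha2) of the
#' double-exponential curve across all variety-by-temperature settings,
#' with shared truncated-Normal hyperpriors and a Gaussian likelihood.
#' Rate constants beta1, beta2 are fixed (see
#' \code{\link{fix_rate_constants}}). Chains are initialized from jittered
#' \code{\link{nls_explore}} point estimates and run with JAGS.
#'
#' @param data Kinetic-series data frame (normalized units) covering one or
#'   more settings; filtered to \code{marker}.
#' @param marker Which marker to fit (default the single marker present).
#' @param priors \code{\link{tac_priors}}.
#' @param mcmc \code{\link{tac_mcmc}}.
#' @param scaling \code{\link{tac_scaling}}.
#' @param rates Fixed \code{c(beta1, beta2)}; default from
#'   \code{\link{fix_rate_constants}}.
#' @param seed Integer seed driving initialization jitter and all chain
#'   RNGs; fixed seed + fixed config gives identical summaries.
#' @param quiet Suppress JAGS progress output (default \code{TRUE}).
#' @return An object of class \code{tac_hbfit} with components
#'   \code{summary} (per-parameter posterior medians, 95\% credible
#'   intervals, split-Rhat and effective sample size), \code{settings},
#'   \code{draws} (a \code{coda::mcmc.list}), \code{rates}, \code{marker},
#'   \code{data}, \code{converged}.
#' @export
fit_tac_bayes <- function(data, marker = NULL, priors = tac_priors(),
                          mcmc = tac_mcmc(), scaling = tac_scaling(),
                          rates = fix_rate_constants(), seed = 1,
                          quiet = TRUE) {
  .check_series(data)
  stopifnot(inherits(priors, "tac_priors"), inherits(mcmc, "tac_mcmc"))
  if (is.null(marker)) {
    mk <- unique(data$marker)
    if (length(mk) != 1L)
      stop("data contains several markers; pick one with `marker`")
    marker <- mk
  }
  data <- data[data$marker == marker, , drop = FALSE]
  if (nrow(data) == 0L) stop("no observations for marker ", marker)

  settings <- unique(data[, c("variety", "grain_type", "temperature_C")])
  rownames(settings) <- NULL
  settings$setting <- paste(settings$variety, settings$temperature_C)
  skey <- paste(data$variety, data$temperature_C)
  s_idx <- match(skey, settings$setting)

  for (j in seq_len(nrow(settings))) {
    nt <- length(unique(data$time_s[s_idx == j]))
    if (nt < 4L)
      stop(sprintf("insufficient data: setting '%s' has %d distinct times (need >= 4)",
                   settings$setting[j], nt))
  }

  # NLS starting points, jittered per chain
  set.seed(seed)
  expl <- lapply(seq_len(nrow(settings)), function(j) {
    nls_explore(data[s_idx == j, , drop = FALSE], scaling,
                fix_rates = rates)
  })
  est <- t(vapply(expl, function(e) e$estimates[c("theta", "alpha1", "alpha2")],
                  numeric(3)))

  S <- nrow(settings)
  jdata <- list(N = nrow(data), S = S, y = data$value, s = s_idx,
                x = data$time_s * data$temperature_C / scaling$exponent_scale,
                beta1 = unname(rates[1]), beta2 = unname(rates[2]),
                hm_loc = priors$hyper_mean_loc,
                hm_prec = priors$hyper_mean_scale^-2,
                hs_prec = priors$hyper_sd_scale^-2,
                ns_prec = priors$noise_sd_scale^-2)
  if (priors$hierarchy == "grain") {
    grp <- as.integer(factor(settings$grain_type))
    jdata$grp <- grp
    jdata$G <- max(grp)
  }

  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    jit <- function(v) pmax(v * exp(stats::rnorm(length(v), 0, 0.05)), 1e-3)
    list(theta = jit(est[, 1]), alpha1 = jit(est[, 2]), alpha2 = jit(est[, 3]),
         sigma_y = 0.05 * exp(stats::rnorm(1, 0, 0.1)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + ch) %% .Machine$integer.max)
  })

  run <- function() {
    jm <- rjags::jags.model(textConnection(.jags_model_string(priors$hierarchy)),
                            data = jdata, inits = inits,
                            n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                            quiet = quiet)
    if (mcmc$burnin > 0)
      stats::update(jm, n.iter = mcmc$burnin, progress.bar = "none")
    rjags::coda.samples(jm, c("theta", "alpha1", "alpha2", "sigma_y"),
                        n.iter = mcmc$iterations, thin = mcmc$thin,
                        progress.bar = "none")
  }
  draws <- if (quiet) suppressWarnings(run()) else run()

  vars <- coda::varnames(draws)
  mat <- do.call(rbind, lapply(draws, as.matrix))
  qs <- t(apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  rhat <- vapply(vars, function(v) .split_rhat(draws, v), 0)
  ess <- coda::effectiveSize(draws)[vars]

  param <- sub("\\[.*", "", vars)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]", "\\1", vars)))
  summ <- data.frame(
    setting = ifelse(is.na(idx), NA, settings$setting[idx]),
    variety = ifelse(is.na(idx), NA, settings$variety[idx]),
    temperature_C = ifelse(is.na(idx), NA, settings$temperature_C[idx]),
    marker = marker, parameter = param,
    median = qs[, 1], q2.5 = qs[, 2], q97.5 = qs[, 3],
    rhat = rhat, ess = as.numeric(ess),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL

  bad <- summ$parameter != "sigma_y" & summ$rhat > 1.1
  if (any(bad, na.rm = TRUE))
    warning("convergence: split-Rhat > 1.1 for ",
            paste(vars[bad], collapse = ", "))

  structure(list(summary = summ, settings = settings, draws = draws,
                 rates = rates, marker = marker, priors = priors,
                 mcmc = mcmc, scaling = scaling, seed = seed, data = data,
                 nls = expl,
                 converged = !any(bad, na.rm = TRUE)),
            class = "tac_hbfit")
}

# split-Rhat: halve each chain, then standard potential scale reduction
.split_rhat <- function(draws, var) {
  seqs <- list()
  for (ch in draws) {
    v <- as.matrix(ch)[, var]
    n <- length(v)
    h <- n %/% 2
    seqs <- c(seqs, list(v[1:h], v[(h + 1):(2 * h)]))
  }
  n <- length(seqs[[1]])
  means <- vapply(seqs, mean, 0)
  vars_ <- vapply(seqs, stats::var, 0)
  W <- mean(vars_)
  B <- n * stats::var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.tac_hbfit <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian TAC kinetics fit (%s marker)\n", x$marker))
  cat(sprintf("  %d settings, %d observations, beta1 = %g, beta2 = %g (fixed)\n",
              nrow(x$settings), nrow(x$data), x$rates[1], x$rates[2]))
  cat(sprintf("  %d chains x %d kept draws; %s\n",
              x$mcmc$chains, nrow(as.matrix(x$draws[[1]])),
              if (x$converged) "all split-Rhat <= 1.1"
              else "CONVERGENCE WARNINGS (see summary)"))
  cat("\nPosterior medians:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.tac_hbfit <- function(object, ...) object$summary

#' Posterior-median curve parameters per setting
#'
#' @param object A \code{tac_hbfit}.
#' @param ... Unused.
#' @return Matrix (settings x theta/alpha1/alpha2) of posterior medians.
#' @export
coef.tac_hbfit <- function(object, ...) {
  s <- object$summary
  s <- s[s$parameter %in% c("theta", "alpha1", "alpha2"), ]
  out <- tapply(s$median, list(s$setting, s$parameter), identity)
  out <- out[object$settings$setting, c("theta", "alpha1", "alpha2")]
  out
}

#' Fitted curves from the posterior medians
#'
#' @param object A \code{tac_hbfit}.
#' @param times Time grid in seconds (default 0 to 1500, 76 points).
#' @param ... Unused.
#' @return Data frame (setting, variety, temperature_C, time_s, value).
#' @export
predict.tac_hbfit <- function(object, times = seq(0, 1500, by = 20), ...) {
  cf <- coef(object)
  out <- lapply(seq_len(nrow(object$settings)), function(j) {
    s <- object$settings[j, ]
    p <- tac_params(cf[j, "theta"], cf[j, "alpha1"], cf[j, "alpha2"],
                    object$rates[1], object$rates[2])
    data.frame(setting = s$setting, variety = s$variety,
               temperature_C = s$temperature_C, time_s = times,
               value = evaluate_tac(p, times, s$temperature_C,
                                    object$scaling),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.tac_hbfit <- function(object, ...) {
  cf <- coef(object)
  key <- paste(object$data$variety, object$data$temperature_C)
  j <- match(key, object$settings$setting)
  mu <- vapply(seq_len(nrow(object$data)), function(i) {
    p <- tac_params(cf[j[i], "theta"], cf[j[i], "alpha1"], cf[j[i], "alpha2"],
                    object$rates[1], object$rates[2])
    evaluate_tac(p, object$data$time_s[i], object$data$temperature_C[i],
                 object$scaling)
  }, 0)
  object$data$value - mu
}

#' @export
plot.tac_hbfit <- function(x, ...) {
  fitted <- predict(x)
  op <- graphics::par(mfrow = grDevices::n2mfrow(nrow(x$settings)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(nrow(x$settings))) {
    s <- x$settings[j, ]
    d <- x$data[paste(x$data$variety, x$data$temperature_C) == s$setting, ]
    f <- fitted[fitted$setting == s$setting, ]
    graphics::plot(d$time_s, d$value, pch = 1, xlab = "time (s)",
                   ylab = "normalized response", main = s$setting, ...)
    graphics::lines(f$time_s, f$value, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' @param object A \code{tac_hbfit}.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param design \code{\link{tac_design}} describing the grid; noise SD
#'   defaults to the posterior-median observation noise.
#' @param ... Unused.
#' @return List of kinetic-series data frames.
#' @export
simulate.tac_hbfit <- function(object, nsim = 1, seed = 1,
                               design = NULL, ...) {
  cf <- coef(object)
  sig <- object$summary$median[object$summary$parameter == "sigma_y"]
  if (is.null(design))
    design <- tac_design(settings = object$settings, noise_sd = sig)
  truth <- data.frame(object$settings[, c("variety", "grain_type",
                                          "temperature_C")],
                      marker = object$marker,
                      theta = cf[, "theta"], alpha1 = cf[, "alpha1"],
                      alpha2 = cf[, "alpha2"], stringsAsFactors = FALSE)
  lapply(seq_len(nsim), function(i) {
    simulate_study(truth, design, object$scaling, seed = seed + i - 1L,
                   beta1 = object$rates[1], beta2 = object$rates[2])
  })
}

#' Convergence diagnostics table
#'
#' @param fit A \code{tac_hbfit}.
#' @param rhat_max Flag threshold for split-Rhat (default 1.1).
#' @param ess_min Flag threshold for effective sample size (default 200).
#' @return Data frame (parameter, setting, rhat, ess, flag); one row per
#'   setting-level parameter plus one for the noise SD.
#' @export
convergence_report <- function(fit, rhat_max = 1.1, ess_min = 200) {
  stopifnot(inherits(fit, "tac_hbfit"))
  s <- fit$summary
  data.frame(parameter = s$parameter, setting = s$setting,
             rhat = s$rhat, ess = s$ess,
             flag = s$rhat > rhat_max | s$ess < ess_min,
             stringsAsFactors = FALSE)
}
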