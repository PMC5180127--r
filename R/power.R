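# Monte Carlo power model for detecting migration between aggregation sites
# by photo-identification.
#
# The deterministic kernel answers: if a proportion MR of a source population
# of size P_source relocates to a sink of size P_sink each year, and N_source
# individuals are catalogued yearly at the source, how many individuals must
# be identified at the sink in one year to reach a detection demand DP?
# Migrants make up MR*P_source/(P_sink + MR*P_source) of the augmented sink
# pool, and a fraction N_source/P_source of them are already catalogued, so a
# sink sample of size N yields N * (MR*N_source)/(P_sink + MR*P_source)
# expected catalogued-migrant matches. Requiring DP expected matches gives
#   N_sink = DP * (P_sink + MR*P_source) / (MR * N_source).

#' Required yearly sink identifications to detect migration
#'
#' Deterministic kernel of the power analysis:
#' `N_sink = DP * (P_sink + MR * P_source) / (MR * N_source)`, the number of
#' unique individuals that must be identified at the sink in a single year so
#' that the expected number of matches to catalogued source migrants equals
#' the detection demand `DP`. Strictly decreasing in `MR` and `N_source`,
#' increasing in `P_sink`, linear in `DP`.
#'
#' `orientation = "yield"` instead returns the expected matched-migrant yield
#' per unit demand, `DP * MR * N_source / (P_sink + MR * P_source)` — the
#' algebraic reciprocal, useful for diagnostics (it is the expected number of
#' catalogued-migrant matches per sink identification, scaled by DP).
#'
#' @param dp detection demand in (0, 1]: the expected number of
#'   catalogued-migrant matches required (the working definition of an
#'   80% or 95% "detection probability" target). `dp = 0` returns 0.
#' @param mr migration rate in (0, 1], the proportion of the source
#'   population relocating to the sink per year. May be a vector.
#' @param n_source unique individuals identified yearly at the source.
#' @param p_source,p_sink source and sink population sizes (individuals).
#' @param orientation `"required"` (default) or `"yield"`.
#' @return required sink identifications per year (individuals), vectorised
#'   over `mr`.
#' @examples
#' required_sink_sample(0.8, 0.05, n_source = 59, p_source = 513, p_sink = 380)
#' @export
required_sink_sample <- function(dp, mr, n_source, p_source, p_sink,
                                 orientation = c("required", "yield")) {
  orientation <- match.arg(orientation)
  if (any(mr <= 0) || any(mr > 1)) stop("mr must lie in (0, 1]")
  if (any(c(n_source, p_source, p_sink) <= 0)) {
    stop("n_source, p_source and p_sink must be positive")
  }
  if (any(dp < 0) || any(dp > 1)) stop("dp must lie in [0, 1]")
  if (orientation == "required") {
    dp * (p_sink + mr * p_source) / (mr * n_source)
  } else {
    dp * (mr * n_source) / (p_sink + mr * p_source)
  }
}

.draw_truncated_normal <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  if (stats::pnorm(0, mean, se) > 0.5) {
    stop(sprintf(
      "degenerate input: normal(mean=%.3g, se=%.3g) is negative more than half the time",
      mean, se))
  }
  x <- stats::rnorm(n, mean, se)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, se)
  x
}

#' Monte Carlo power curve for migration detection
#'
#' Propagates uncertainty in the source identification rate and the two
#' population sizes through the [required_sink_sample()] kernel. Each of
#' `n_draws` Monte Carlo draws samples `N_source`, `P_source` and `P_sink`
#' from normal distributions (negative or zero draws are rejected and
#' resampled, i.e. truncation at zero); the kernel is evaluated on the whole
#' migration-rate grid for every draw, and the per-rate median, 2.5th and
#' 97.5th percentiles of the required sink sample are reported. Sharing draws
#' across the grid makes every draw's curve, and hence the median curve,
#' strictly decreasing in the migration rate.
#'
#' @param n_source mean unique individuals identified per year at the source.
#' @param p_source,p_sink [population_estimate()] objects (or any list with
#'   `mean` and `se`) for the source and sink populations.
#' @param dp detection demand (default 0.8).
#' @param mr_grid migration rates to evaluate (default 0.5%-25% in 0.5%
#'   steps).
#' @param n_draws Monte Carlo draws (default 10000).
#' @param seed RNG seed.
#' @param n_source_se standard error of the yearly source identification
#'   count; the year-to-year variation is rarely published, so the default is
#'   10% of the mean.
#' @param sink_obs optional observed yearly identification count at the sink;
#'   stored for [detection_threshold()], `summary()` and `plot()`.
#' @param labels optional `c(source, sink)` site labels for printing.
#' @return an object of class `migration_power` with elements `curve` (data
#'   frame `mr`, `median`, `lower`, `upper`), `dp`, `n_draws`, `seed`,
#'   `sink_obs`, `inputs` and `call`. Methods: `print`, `summary`, `plot`,
#'   `predict`, `coef`.
#' @seealso [detection_threshold()], [simulate_detection_oracle()]
#' @examples
#' sey <- population_estimate("seychelles", 469, 557)
#' nin <- population_estimate("ningaloo", 320, 440)
#' fit <- migration_power(n_source = 59, p_source = sey, p_sink = nin,
#'                        dp = 0.8, n_draws = 2000, seed = 1, sink_obs = 104)
#' detection_threshold(fit)
#' @export
migration_power <- function(n_source, p_source, p_sink, dp = 0.8,
                            mr_grid = seq(0.005, 0.25, by = 0.005),
                            n_draws = 10000, seed = NULL,
                            n_source_se = 0.1 * n_source,
                            sink_obs = NULL, labels = NULL) {
  stopifnot(n_draws >= 1, length(mr_grid) >= 1, all(diff(mr_grid) > 0))
  if (is.na(p_source$mean) || is.na(p_sink$mean)) {
    stop("population estimate is missing (n.d. site): supply an explicit estimate")
  }
  if (!is.null(seed)) set.seed(seed)
  ns <- .draw_truncated_normal(n_draws, n_source, n_source_se)
  ps <- .draw_truncated_normal(n_draws, p_source$mean, p_source$se)
  pk <- .draw_truncated_normal(n_draws, p_sink$mean, p_sink$se)

  qs <- vapply(mr_grid, function(mr) {
    req <- dp * (pk + mr * ps) / (mr * ns)
    stats::quantile(req, c(0.5, 0.025, 0.975), names = FALSE)
  }, numeric(3))

  curve <- data.frame(mr = mr_grid, median = qs[1, ],
                      lower = qs[2, ], upper = qs[3, ])
  structure(list(curve = curve, dp = dp, n_draws = n_draws, seed = seed,
                 sink_obs = sink_obs,
                 inputs = list(n_source = n_source, n_source_se = n_source_se,
                               p_source = p_source, p_sink = p_sink),
                 labels = labels, call = match.call()),
            class = "migration_power")
}

#' @export
print.migration_power <- function(x, ...) {
  lab <- if (!is.null(x$labels)) paste(x$labels, collapse = " -> ") else
    paste(x$inputs$p_source$site %||% "source", "->",
          x$inputs$p_sink$site %||% "sink")
  cat(sprintf("Monte Carlo migration-detection power curve (%s)\n", lab))
  cat(sprintf("  DP = %g, %d draws, MR grid %.1f%%-%.1f%% (%d points)\n",
              x$dp, x$n_draws, 100 * min(x$curve$mr), 100 * max(x$curve$mr),
              nrow(x$curve)))
  cat(sprintf("  median required sink identifications: %.1f at MR=%.1f%%, %.1f at MR=%.1f%%\n",
              x$curve$median[1], 100 * x$curve$mr[1],
              x$curve$median[nrow(x$curve)], 100 * x$curve$mr[nrow(x$curve)]))
  if (!is.null(x$sink_obs)) {
    cat(sprintf("  observed sink identifications/yr: %g\n", x$sink_obs))
  }
  invisible(x)
}

#' @export
summary.migration_power <- function(object, ...) {
  out <- list(fit = object,
              threshold = if (!is.null(object$sink_obs))
                detection_threshold(object) else NULL)
  class(out) <- "summary.migration_power"
  out
}

#' @export
print.summary.migration_power <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

#' @export
coef.migration_power <- function(object, ...) {
  with(object$inputs,
       c(dp = object$dp, n_source = n_source, n_source_se = n_source_se,
         p_source = p_source$mean, p_source_se = p_source$se,
         p_sink = p_sink$mean, p_sink_se = p_sink$se))
}

#' Predict required sink identifications at new migration rates
#'
#' Interpolates the fitted Monte Carlo median (and percentile band) linearly
#' at new migration rates inside the fitted grid, and also reports the
#' deterministic kernel value.
#'
#' @param object a `migration_power` fit.
#' @param mr migration rates (defaults to the fitted grid).
#' @param ... unused.
#' @return data frame `mr`, `median`, `lower`, `upper`, `kernel`.
#' @export
predict.migration_power <- function(object, mr = NULL, ...) {
  cv <- object$curve
  if (is.null(mr)) mr <- cv$mr
  if (any(mr < min(cv$mr)) || any(mr > max(cv$mr))) {
    stop("mr outside the fitted grid")
  }
  interp <- function(y) stats::approx(cv$mr, y, xout = mr)$y
  data.frame(mr = mr,
             median = interp(cv$median),
             lower = interp(cv$lower),
             upper = interp(cv$upper),
             kernel = required_sink_sample(object$dp, mr,
                                           object$inputs$n_source,
                                           object$inputs$p_source$mean,
                                           object$inputs$p_sink$mean))
}

#' Plot a migration-detection power curve
#'
#' Median required sink identifications against migration rate (solid), the
#' 2.5th/97.5th percentile band (dashed), and the observed yearly sink
#' identification count as a horizontal red line when available. The
#' crossing of the red line and the median curve is the detection threshold.
#'
#' @param x a `migration_power` fit.
#' @param log_y log-scale the y axis (default `TRUE`; required counts span
#'   orders of magnitude across the grid).
#' @param ... passed to [graphics::plot()].
#' @export
plot.migration_power <- function(x, log_y = TRUE, ...) {
  cv <- x$curve
  ylim <- range(cv$lower, cv$upper, x$sink_obs, na.rm = TRUE)
  graphics::plot(100 * cv$mr, cv$median, type = "l", lwd = 2,
                 log = if (log_y) "y" else "",
                 xlab = "migration rate (% of source population per year)",
                 ylab = "required sink identifications per year",
                 ylim = ylim, ...)
  graphics::lines(100 * cv$mr, cv$lower, lty = 2)
  graphics::lines(100 * cv$mr, cv$upper, lty = 2)
  if (!is.null(x$sink_obs)) {
    graphics::abline(h = x$sink_obs, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Smallest detectable migration rate
#'
#' Solves for the detection threshold: the smallest migration rate on the
#' fitted grid at which the median required sink sample does not exceed the
#' observed yearly identification count at the sink. A refined estimate is
#' obtained by linear interpolation of the median curve between the
#' bracketing grid points. When the observed line lies above the whole curve
#' the threshold saturates at the smallest grid rate; when it lies below the
#' whole curve the migration rate is flagged as not detectable on the grid
#' (`mr_star = NA`).
#'
#' @param fit a [migration_power()] object.
#' @param n_sink_obs observed unique individuals identified per year at the
#'   sink; defaults to the `sink_obs` stored in the fit.
#' @return object of class `detection_threshold`: `mr_star` (interpolated),
#'   `mr_grid_star` (first grid point at or past the crossing), `bracket`,
#'   `saturated`, `detectable`, `n_sink_obs`.
#' @export
detection_threshold <- function(fit, n_sink_obs = fit$sink_obs) {
  if (is.null(n_sink_obs) || n_sink_obs <= 0) {
    stop("n_sink_obs must be a positive count")
  }
  cv <- fit$curve
  hit <- which(cv$median <= n_sink_obs)
  if (length(hit) == 0L) {
    out <- list(mr_star = NA_real_, mr_grid_star = NA_real_,
                bracket = c(NA_real_, NA_real_), saturated = FALSE,
                detectable = FALSE, n_sink_obs = n_sink_obs, dp = fit$dp)
  } else {
    i <- hit[1]
    if (i == 1L) {
      out <- list(mr_star = cv$mr[1], mr_grid_star = cv$mr[1],
                  bracket = c(cv$mr[1], cv$mr[1]), saturated = TRUE,
                  detectable = TRUE, n_sink_obs = n_sink_obs, dp = fit$dp)
    } else {
      # median is decreasing: interpolate the crossing inside the bracket
      mr_star <- cv$mr[i - 1] +
        (cv$mr[i] - cv$mr[i - 1]) *
        (cv$median[i - 1] - n_sink_obs) / (cv$median[i - 1] - cv$median[i])
      out <- list(mr_star = mr_star, mr_grid_star = cv$mr[i],
                  bracket = c(cv$mr[i - 1], cv$mr[i]), saturated = FALSE,
                  detectable = TRUE, n_sink_obs = n_sink_obs, dp = fit$dp)
    }
  }
  structure(out, class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  if (!x$detectable) {
    cat(sprintf(
      "Migration not detectable on the fitted grid at %g sink identifications/yr (DP=%g)\n",
      x$n_sink_obs, x$dp))
  } else if (x$saturated) {
    cat(sprintf(
      "Detection threshold at or below the smallest grid rate: MR* <= %.2f%% (DP=%g)\n",
      100 * x$mr_star, x$dp))
  } else {
    cat(sprintf(
      "Detection threshold: MR* = %.2f%% of source population per year (DP=%g,\n  grid crossing at %.2f%%, observed %g sink identifications/yr)\n",
      100 * x$mr_star, x$dp, 100 * x$mr_grid_star, x$n_sink_obs))
  }
  invisible(x)
}

#' Agent-based sampling oracle for migration detection
#'
#' Independent validation of the power kernel by direct simulation of the
#' sampling process. Per replicate: `n_source` of the `p_source` source
#' individuals are catalogued; `round(mr * p_source)` source individuals
#' (chosen independently of cataloguing) relocate to the sink; `n_sink`
#' individuals are then sampled without replacement from the augmented sink
#' pool of `p_sink + migrants`; detection means at least one sampled
#' individual is a catalogued migrant.
#'
#' The expected number of matches is hypergeometric:
#' `n_sink * m * n_source / p_source / (p_sink + m)` with
#' `m = round(mr * p_source)` — for exact `m = mr * p_source` this is the
#' kernel's expected-match quantity `n_sink * mr * n_source /
#' (p_sink + mr * p_source)`.
#'
#' @param p_source,p_sink integer population sizes.
#' @param n_source catalogued individuals at the source (<= `p_source`).
#' @param n_sink individuals sampled at the sink (<= `p_sink + migrants`).
#' @param mr migration rate in \[0, 1\].
#' @param n_reps replicates (default 10000).
#' @param seed optional RNG seed.
#' @return list `detection_prob` (fraction of replicates with >= 1 match),
#'   `mean_matches`, `expected_matches` (analytic hypergeometric mean),
#'   `n_migrants`, `n_reps`.
#' @export
simulate_detection_oracle <- function(p_source, p_sink, n_source, n_sink,
                                      mr, n_reps = 10000, seed = NULL) {
  stopifnot(mr >= 0, mr <= 1, n_source <= p_source)
  m <- as.integer(round(mr * p_source))
  if (n_sink > p_sink + m) stop("n_sink exceeds the augmented sink pool")
  if (m == 0L) {
    return(list(detection_prob = 0, mean_matches = 0, expected_matches = 0,
                n_migrants = 0L, n_reps = n_reps))
  }
  if (!is.null(seed)) set.seed(seed)
  # catalogued migrants: overlap of m migrants with the n_source catalogued
  k <- stats::rhyper(n_reps, n_source, p_source - n_source, m)
  # matches: overlap of the n_sink sink sample with the k catalogued migrants
  matches <- stats::rhyper(n_reps, k, p_sink + m - k, n_sink)
  list(detection_prob = mean(matches >= 1),
       mean_matches = mean(matches),
       expected_matches = n_sink * m * (n_source / p_source) / (p_sink + m),
       n_migrants = m, n_reps = n_reps)
}
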