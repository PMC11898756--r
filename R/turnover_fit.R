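#' Ordinary least-squares fit of log10(value) against time
#'
#' Fits `log10(value) ~ time` by OLS. Time is taken in minutes and the slope
#' is reported in log10 units per hour; the intercept is the fitted log10
#' value at t = 0. No model-quality judgment is made here (see
#' [gate_quality()]).
#'
#' @param times sampling times in minutes.
#' @param values positive measurements (intensities or H/L ratios).
#' @return An object of class `"linear_fit"`: a list with `slope` (log10/h),
#'   `intercept` (log10 at t = 0), `r_squared`, `n_obs`, `removed_points`
#'   (indices into the input removed as outliers), and `passed_quality`
#'   (`NA` until gated). Fewer than 2 usable points, or zero time variance,
#'   yield a no-fit result (`slope = NA`, `passed_quality = FALSE`).
#' @export
#' @examples
#' f <- fit_log_linear(c(15, 30, 45, 60), 10^(0.5 + 0.002 * c(15, 30, 45, 60)))
#' f$slope   # 0.12 log10/h
fit_log_linear <- function(times, values) {
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (any(values <= 0)) stop("values must be positive for log transformation")
  n <- length(times)
  if (n < 2L || stats::var(times) == 0)
    return(no_fit(n))
  y <- log10(values)
  hours <- times / 60
  if (stats::var(y) == 0) {
    # degenerate flat response: slope 0, R^2 defined as 0
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          n_obs = n, removed_points = integer(0),
                          passed_quality = NA,
                          times = times, log10_values = y),
                     class = "linear_fit"))
  }
  m <- stats::lm(y ~ hours)
  ss_res <- sum(stats::residuals(m)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 n_obs = n, removed_points = integer(0),
                 passed_quality = NA,
                 times = times, log10_values = y),
            class = "linear_fit")
}

no_fit <- function(n) {
  structure(list(slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, n_obs = n,
                 removed_points = integer(0), passed_quality = FALSE,
                 times = numeric(0), log10_values = numeric(0)),
            class = "linear_fit")
}

#' Apply the model-quality gate
#'
#' A turnover model passes only when it explains at least `r2_min` of the
#' variation and rests on at least `min_obs` observations.
#'
#' @param fit a `"linear_fit"`.
#' @param r2_min minimum coefficient of determination (default 0.70).
#' @param min_obs minimum number of observations (default 4).
#' @return The fit with `passed_quality` set.
#' @export
gate_quality <- function(fit, r2_min = 0.70, min_obs = 4L) {
  fit$passed_quality <- !is.na(fit$slope) &&
    fit$n_obs >= min_obs &&
    is.finite(fit$r_squared) && fit$r_squared >= r2_min
  fit
}

#' Remove a single MAD-flagged outlier and refit once
#'
#' For a model that failed the quality gate, observations whose absolute
#' residual exceeds the median absolute residual plus `mad_k` times the MAD
#' of the absolute residuals (consistency constant 1.4826) are flagged; the
#' single worst one is removed, the model refit once, and the quality gate
#' re-applied. If no observation qualifies, or removal would leave fewer than
#' `min_obs` points, the original (failed) fit is returned, in the latter
#' case marked discarded.
#'
#' @param fit the initial `"linear_fit"` (with its data attached).
#' @param r2_min,min_obs quality-gate settings, as in [gate_quality()].
#' @param mad_k multiplier on the MAD (default 2).
#' @return A refit (or unchanged) `"linear_fit"` with `removed_points`
#'   recording any removal.
#' @export
remove_single_outliers <- function(fit, r2_min = 0.70, min_obs = 4L,
                                   mad_k = 2) {
  if (is.na(fit$slope) || fit$n_obs < 2L) return(fit)
  res <- fit$log10_values -
    (fit$intercept + fit$slope * fit$times / 60)
  ares <- abs(res)
  thr <- stats::median(ares) + mad_k * stats::mad(ares, constant = 1.4826)
  flagged <- which(ares > thr)
  if (length(flagged) == 0L) return(fit)
  worst <- flagged[which.max(ares[flagged])]
  if (fit$n_obs - 1L < min_obs) {
    fit$passed_quality <- FALSE
    return(fit)
  }
  refit <- fit_log_linear(fit$times[-worst], 10^fit$log10_values[-worst])
  refit$removed_points <- worst
  gate_quality(refit, r2_min = r2_min, min_obs = min_obs)
}

# initial fit -> gate -> (on failure) one outlier-removal pass -> gate
fit_with_quality <- function(times, values, r2_min = 0.70, min_obs = 4L,
                             mad_k = 2, max_outliers = 1L) {
  fit <- gate_quality(fit_log_linear(times, values), r2_min, min_obs)
  if (!fit$passed_quality && max_outliers >= 1L && fit$n_obs >= 2L &&
      !is.na(fit$slope))
    fit <- remove_single_outliers(fit, r2_min, min_obs, mad_k)
  if (is.na(fit$passed_quality)) fit <- gate_quality(fit, r2_min, min_obs)
  fit
}

#' Protein replacement time from a fitted H/L-ratio model
#'
#' The replacement time is the moment the heavy (post-shift) protein pool
#' equals the light (pre-shift) pool, i.e. where the fitted log10 H/L ratio
#' crosses zero: `-intercept/slope`, converted to minutes.
#'
#' @param fit a quality-gated `"linear_fit"` of log10(H/L) against time.
#' @return Replacement time in minutes, or `NA` with attribute `reason` set
#'   to `"quality_fail"` (model rejected) or `"non_crossing"` (slope <= 0:
#'   the ratio never reaches 1; these proteins are the production-stagnation
#'   candidates).
#' @export
replacement_time <- function(fit) {
  if (is.na(fit$passed_quality) || !fit$passed_quality)
    return(structure(NA_real_, reason = "quality_fail"))
  if (fit$slope <= 0)
    return(structure(NA_real_, reason = "non_crossing"))
  structure(60 * (-fit$intercept / fit$slope), reason = "ok")
}

#' Disappearance or production rate of one labeled component
#'
#' Divides the light or heavy intensities of one protein by the per-sample
#' totals (relative iBAQ, correcting for sample-to-sample variation),
#' log10-transforms, and fits the slope over time with the same quality gate
#' and single-outlier machinery as the ratio models. For the light component
#' the negated slope is the disappearance rate; for the heavy component the
#' slope is the production rate.
#'
#' @param series a data.frame for one protein with columns `sample`,
#'   `time_min`, `intensity_L`, `intensity_H`.
#' @param component `"light"` or `"heavy"`.
#' @param sample_totals named numeric vector of per-sample summed light+heavy
#'   intensity over all proteins.
#' @param r2_min,min_obs,mad_k,max_outliers quality settings.
#' @return A `"linear_fit"` on the log10 relative abundances; heavy fits
#'   exclude the unlabeled t0 samples, light fits include them as baseline.
#' @export
component_rate <- function(series, component = c("light", "heavy"),
                           sample_totals, r2_min = 0.70, min_obs = 4L,
                           mad_k = 2, max_outliers = 1L) {
  component <- match.arg(component)
  vals <- if (component == "light") series$intensity_L else series$intensity_H
  times <- series$time_min
  if (component == "heavy") {
    keep <- series$time_min > 0
    vals <- vals[keep]; times <- times[keep]
    totals <- sample_totals[series$sample[keep]]
  } else {
    totals <- sample_totals[series$sample]
  }
  rel <- vals / totals
  ok <- is.finite(rel) & rel > 0
  if (sum(ok) < 2L) return(no_fit(sum(ok)))
  fit_with_quality(times[ok], rel[ok], r2_min, min_obs, mad_k, max_outliers)
}
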