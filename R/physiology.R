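#' Maximal specific growth rate from an OD600 curve
#'
#' Automated reading of "the slope of the linear part of the log-transformed
#' optical density", following the sliding-window strategy of Hall et al.
#' (2014, Mol Biol Evol 31:232) as implemented in growth-curve packages:
#' the natural log of OD600 is regressed on time (hours) in every window of
#' `min_window` consecutive points; among windows with R^2 >= `r2_min` the
#' steepest is located, all qualifying windows whose slope reaches `quota`
#' times that maximum are pooled, and the growth rate is the slope refit
#' over the pooled points. Pooling the near-maximal windows averages out
#' reading noise that a single steepest window would otherwise maximize
#' over. If no window reaches `r2_min`, the best-R^2 window's slope is
#' returned with a warning.
#'
#' @param curve data.frame with columns `time_min` (strictly increasing) and
#'   `od600` (> 0).
#' @param min_window window width in points (default 5, the published
#'   default of the method).
#' @param r2_min window acceptance threshold (default 0.99).
#' @param quota fraction of the maximal window slope above which windows are
#'   pooled (default 0.95).
#' @return A list: `mu` (h^-1), `window` (integer indices into the curve
#'   used for the final fit), `r_squared` (of the final fit).
#' @export
#' @examples
#' crv <- simulate_growth_curve(growth_sim_spec(mu = 0.64, noise_cv = 0))
#' max_growth_rate(crv)$mu
max_growth_rate <- function(curve, min_window = 5L, r2_min = 0.99,
                            quota = 0.95) {
  stopifnot(all(c("time_min", "od600") %in% names(curve)))
  if (any(curve$od600 <= 0)) stop("od600 must be positive")
  if (is.unsorted(curve$time_min, strictly = TRUE))
    stop("time_min must be strictly increasing")
  n <- nrow(curve)
  if (n < min_window) stop("need at least ", min_window, " points")
  x <- curve$time_min / 60
  y <- log(curve$od600)
  h <- min_window
  win_fit <- function(idx) {
    yi <- y[idx]; xi <- x[idx]
    if (stats::var(yi) == 0)
      return(list(slope = 0, r_squared = 1))  # flat: linear with slope 0
    m <- stats::lm(yi ~ xi)
    list(slope = unname(stats::coef(m)[2]),
         r_squared = 1 - sum(stats::residuals(m)^2) /
           sum((yi - mean(yi))^2))
  }
  nw <- n - h + 1L
  slopes <- r2s <- numeric(nw)
  for (i in seq_len(nw)) {
    f <- win_fit(i:(i + h - 1L))
    slopes[i] <- f$slope; r2s[i] <- f$r_squared
  }
  ok <- which(r2s >= r2_min)
  if (length(ok) == 0L) {
    warning("no window reached R^2 >= ", r2_min,
            "; returning the best-R^2 window")
    ok <- which.max(r2s)
  }
  imax <- ok[which.max(slopes[ok])]
  sel <- ok[slopes[ok] >= quota * slopes[imax]]
  idx <- sort(unique(unlist(lapply(sel, function(i) i:(i + h - 1L)))))
  f <- win_fit(idx)
  list(mu = f$slope, window = idx, r_squared = f$r_squared)
}

#' Fermentation profile from relative NMR peak intensities
#'
#' Rescales the acetate/lactate balance to [0, 1]: the acetic fraction is
#' acetate / (acetate + lactate) and the lactic fraction its complement
#' (homolactic fermentation gives a lactic fraction near 1, mixed-acid
#' fermentation a substantial acetic share). Ornithine — the arginine
#' deiminase (ADI) pathway proxy — is normalized by the harvest cell density
#' (OD600). Raw peak tables are total-normalized first; the fractions are
#' unaffected, the ornithine proxy uses the normalized intensity.
#'
#' @param table data.frame with columns `lactate`, `acetate`, and optionally
#'   `ornithine`, `other`, `od600`, `condition`, `replicate` (the layout of
#'   [simulate_nmr_tables()]).
#' @return The table with `lactic_fraction`, `acetic_fraction`, and (when
#'   ornithine and od600 are present) `ornithine_per_od` appended. Rows with
#'   acetate + lactate = 0 get `NA` fractions.
#' @export
fermentation_fractions <- function(table) {
  stopifnot(all(c("lactate", "acetate") %in% names(table)))
  mets <- intersect(c("lactate", "acetate", "ornithine", "other"),
                    names(table))
  tot <- rowSums(table[, mets, drop = FALSE])
  norm <- table
  renorm <- tot > 0 & abs(tot - 1) > 1e-6   # raw table: total-normalize
  for (m in mets) norm[[m]] <- ifelse(renorm, table[[m]] / tot, table[[m]])
  denom <- norm$lactate + norm$acetate
  norm$acetic_fraction <- ifelse(denom > 0, norm$acetate / denom, NA_real_)
  norm$lactic_fraction <- 1 - norm$acetic_fraction
  if (all(c("ornithine", "od600") %in% names(norm)))
    norm$ornithine_per_od <- norm$ornithine / norm$od600
  norm
}

#' Two-sided Welch test between two conditions
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate zero-variance groups with
#' equal means give t = 0, p = 1; unequal means with zero variance in both
#' groups give p = 0.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return A list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
condition_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
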