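#' Ordinary least-squares fit of cell area on distance to an infected cell
#'
#' Fits `area = b0 + b1 * distance` by least squares and reports the sample
#' Pearson correlation and the two-sided significance of the slope from the
#' exact t distribution on n - 2 degrees of freedom.
#'
#' @param distance Either a numeric vector of distances (um) or a data.frame
#'   with columns `distance_um` and `area_um2` (the cell-table dialect);
#'   rows with missing distance (GFP+ cells) are dropped.
#' @param area Numeric vector of cell areas (um^2); ignored when `distance`
#'   is a data.frame.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`, `residual_sd`.
#' @examples
#' fit_ols(c(0, 1, 2), c(1, 3, 5))  # exact line: slope 2, R = 1
#' @export
fit_ols <- function(distance, area = NULL) {
  if (is.data.frame(distance)) {
    if (!all(c("distance_um", "area_um2") %in% names(distance)))
      stop_data("data.frame input needs columns distance_um and area_um2")
    area <- distance$area_um2
    distance <- distance$distance_um
  }
  keep <- !is.na(distance) & !is.na(area)
  x <- as.numeric(distance[keep])
  y <- as.numeric(area[keep])
  n <- length(x)
  if (n < 3) stop_data("at least 3 complete (distance, area) pairs are required")
  if (stats::var(x) == 0) stop_data("degenerate design: all distances identical")

  m <- stats::lm(y ~ x)
  slope <- unname(stats::coef(m)[2])
  intercept <- unname(stats::coef(m)[1])
  # Pearson R is undefined for a constant response (legal input: slope 0)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  sse <- sum(stats::residuals(m)^2)
  residual_sd <- sqrt(sse / (n - 2))
  # two-sided t test of the slope; identical Y values give slope 0, p = 1
  se_slope <- residual_sd / sqrt(sum((x - mean(x))^2))
  p <- if (se_slope == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  }

  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 p_value = p, n = n, residual_sd = residual_sd),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Distance-area regression: area = %.3f + %.3f * distance\n",
              x$intercept, x$slope))
  cat(sprintf("  Pearson R = %.3f, p = %.4g, n = %d, residual SD = %.1f um^2\n",
              x$pearson_r, x$p_value, x$n, x$residual_sd))
  invisible(x)
}

#' Mean and t-based confidence interval of a cell-area sample
#'
#' The interval is `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)`; its lower
#' bound is the hypertrophy threshold intersected with the regression line
#' by [effective_range()].
#'
#' @param areas Numeric vector of cell areas (um^2), n >= 2.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An object of class `area_threshold` with fields `mean`,
#'   `lower_ci`, `upper_ci`, `sd`, `n`, `level`.
#' @examples
#' mean_lower_ci(c(300, 300, 300, 300))  # zero variance: lower_ci == mean
#' @export
mean_lower_ci <- function(areas, level = 0.95) {
  areas <- as.numeric(areas[!is.na(areas)])
  n <- length(areas)
  if (n < 2) stop_data("at least 2 areas are required for a confidence interval")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_config("level must be in (0, 1)")
  m <- mean(areas)
  s <- stats::sd(areas)
  half <- stats::qt((1 + level) / 2, df = n - 1) * s / sqrt(n)
  structure(list(mean = m, lower_ci = m - half, upper_ci = m + half,
                 sd = s, n = n, level = level),
            class = "area_threshold")
}

#' @export
print.area_threshold <- function(x, ...) {
  cat(sprintf("Hypertrophic area threshold: mean %.1f um^2, %g%% CI [%.1f, %.1f] (n = %d)\n",
              x$mean, 100 * x$level, x$lower_ci, x$upper_ci, x$n))
  invisible(x)
}

#' Effective paracrine range: regression line meets the hypertrophy bound
#'
#' Solves `intercept + slope * X = L` for the distance `X*` at which treated
#' cells' fitted area reaches the lower confidence bound `L` of the
#' hypertrophic-area mean. Cells closer than `X*` to an infected cell are,
#' on average, below hypertrophic size: `X*` is the effective reach of the
#' secreted factor. A genuine crossing needs a positive slope (area grows
#' with distance from the protective source) and a non-negative `X*`; a flat
#' or descending line, or a line already above the bound at distance zero in
#' the control arm's manner, is reported with `crossing = FALSE`.
#'
#' @param fit A [fit_ols()] result, or any list with `slope` and `intercept`.
#' @param threshold An [mean_lower_ci()] result, or a single number taken as
#'   the lower bound `L` (um^2).
#' @return An object of class `effective_range` with fields `x_star` (um;
#'   `NA` for a zero slope) and `crossing` (logical).
#' @examples
#' effective_range(list(slope = 1.193, intercept = 202.723), 304.7)
#' @export
effective_range <- function(fit, threshold) {
  slope <- fit$slope
  intercept <- fit$intercept
  if (!is.numeric(slope) || !is.numeric(intercept))
    stop_data("fit must provide numeric slope and intercept")
  L <- if (is.numeric(threshold)) threshold else threshold$lower_ci
  if (!is.numeric(L)) stop_data("threshold must provide a numeric lower bound")

  if (slope == 0) {
    x_star <- NA_real_
    crossing <- FALSE
  } else {
    x_star <- (L - intercept) / slope
    crossing <- slope > 0 && x_star >= 0
  }
  structure(list(x_star = x_star, crossing = crossing,
                 threshold_lower = L, slope = slope, intercept = intercept),
            class = "effective_range")
}

#' @export
print.effective_range <- function(x, ...) {
  if (isTRUE(x$crossing)) {
    cat(sprintf("Effective paracrine range X* = %.2f um (line crosses the %.1f um^2 bound from below)\n",
                x$x_star, x$threshold_lower))
  } else {
    cat(sprintf("No upward crossing of the %.1f um^2 bound (X* = %s)\n",
                x$threshold_lower,
                if (is.na(x$x_star)) "undefined, zero slope" else sprintf("%.2f um", x$x_star)))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the effective range
#'
#' Optional extra (no uncertainty on `X*` is part of the core report):
#' resamples the regression points and the threshold areas independently,
#' recomputes `X*` for each resample, and returns percentile bounds over
#' resamples with a genuine crossing.
#'
#' @param points data.frame with `distance_um`, `area_um2`.
#' @param areas Hypertrophic areas (um^2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level for both the threshold and the percentile
#'   interval.
#' @return List with `x_star` (point estimate), `lower`, `upper`,
#'   `prop_crossing` (share of resamples with a crossing).
#' @export
bootstrap_effective_range <- function(points, areas, n_boot = 1000,
                                      level = 0.95) {
  fit0 <- fit_ols(points)
  thr0 <- mean_lower_ci(areas, level)
  est <- effective_range(fit0, thr0)
  n_p <- nrow(points)
  n_a <- length(areas)
  xs <- vapply(seq_len(n_boot), function(i) {
    f <- fit_ols(points[sample.int(n_p, replace = TRUE), , drop = FALSE])
    t <- mean_lower_ci(sample(areas, n_a, replace = TRUE), level)
    r <- effective_range(f, t)
    if (isTRUE(r$crossing)) r$x_star else NA_real_
  }, numeric(1))
  ok <- xs[!is.na(xs)]
  alpha <- (1 - level) / 2
  list(x_star = est$x_star,
       lower = if (length(ok)) unname(stats::quantile(ok, alpha)) else NA_real_,
       upper = if (length(ok)) unname(stats::quantile(ok, 1 - alpha)) else NA_real_,
       prop_crossing = length(ok) / n_boot)
}

#' Smallest sample size consistent with a printed correlation and p-value
#'
#' Inverts the t test of a Pearson correlation,
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with two-sided tail on n - 2 degrees
#' of freedom, returning the smallest `n >= 3` whose p-value for the given
#' `r` does not exceed `p`. Used as a consistency check to back-solve the
#' unreported sample size behind a printed (R, p) pair.
#'
#' @param r Pearson correlation, 0 < |r| < 1.
#' @param p Two-sided p-value, in (0, 1).
#' @param n_max Give up beyond this n.
#' @return Integer sample size.
#' @examples
#' infer_sample_size(0.999, 0.05)
#' @export
infer_sample_size <- function(r, p, n_max = 1e6) {
  if (!is.numeric(r) || abs(r) <= 0 || abs(r) >= 1)
    stop_config("need 0 < |r| < 1")
  if (!is.numeric(p) || p <= 0 || p >= 1) stop_config("need 0 < p < 1")
  # p(n) is decreasing in n; scan in vectorized blocks
  lo <- 3
  block <- 10000
  while (lo <= n_max) {
    n <- lo:min(lo + block - 1, n_max)
    tt <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
    pv <- 2 * stats::pt(-tt, df = n - 2)
    hit <- which(pv <= p)
    if (length(hit)) return(as.integer(n[hit[1]]))
    lo <- lo + block
  }
  stop_data(sprintf("no n <= %g reaches p <= %g for |r| = %g", n_max, p, abs(r)))
}
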