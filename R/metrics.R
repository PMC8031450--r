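#' Regression-line SD of a scoring function
#'
#' Fits measured = a + b * predicted by ordinary least squares and returns
#' sqrt( sum(residuals^2) / (N - 1) ): the spread of the measured affinities
#' around the regression line on the predictions, the standard correlation
#' companion metric in scoring-function benchmarks.
#'
#' @param predicted Numeric vector of predictions (the regressor).
#' @param measured Numeric vector of measured affinities (the response).
#' @return Non-negative scalar.
#' @export
sd_metric <- function(predicted, measured) {
  n <- length(predicted)
  if (length(measured) != n) stop("length mismatch")
  if (n < 3) stop("SD needs at least 3 points (got ", n, ")")
  vx <- stats::var(predicted)
  if (!is.finite(vx) || vx == 0)
    stop("SD undefined: predictions have zero variance")
  b <- stats::cov(predicted, measured) / vx
  a <- mean(measured) - b * mean(predicted)
  res <- measured - (a + b * predicted)
  sqrt(sum(res^2) / (n - 1))
}

#' Evaluate predictions against measured affinities
#'
#' Computes the four standard scoring-function metrics: RMSE (root mean
#' squared error), MAE (mean absolute error), Pearson product-moment
#' correlation, and the regression-line SD (\code{\link{sd_metric}}).
#' Pearson R and SD need at least 3 points and nonzero variance; with only
#' 2 points RMSE/MAE are still returned and the correlation metrics are NA
#' with a warning. Zero variance in either vector makes Pearson an error.
#'
#' @inheritParams sd_metric
#' @return An \code{eval_report}: list with \code{rmse}, \code{mae},
#'   \code{pearson_r}, \code{sd}, \code{n}.
#' @export
evaluate_predictions <- function(predicted, measured) {
  n <- length(predicted)
  if (length(measured) != n) stop("length mismatch")
  if (n < 2) stop("insufficient data: need at least 2 points")
  if (any(!is.finite(predicted)) || any(!is.finite(measured)))
    stop("non-finite values in predictions or measurements")
  diffs <- predicted - measured
  rmse <- sqrt(mean(diffs^2))
  mae <- mean(abs(diffs))
  if (n < 3) {
    warning("fewer than 3 points: Pearson R and SD not computed")
    r <- NA_real_
    sdv <- NA_real_
  } else {
    if (stats::var(predicted) == 0 || stats::var(measured) == 0)
      stop("Pearson correlation undefined: zero variance")
    r <- sum((predicted - mean(predicted)) * (measured - mean(measured))) /
      sqrt(sum((predicted - mean(predicted))^2) *
             sum((measured - mean(measured))^2))
    sdv <- sd_metric(predicted, measured)
  }
  structure(list(rmse = rmse, mae = mae, pearson_r = r, sd = sdv, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Affinity prediction evaluation (n = ", x$n, ")\n",
      "  RMSE ", format(x$rmse, digits = digits),
      " | MAE ", format(x$mae, digits = digits),
      " | Pearson R ", format(x$pearson_r, digits = digits),
      " | SD ", format(x$sd, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, pearson_r = x$pearson_r,
             sd = x$sd, n = x$n)
}
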