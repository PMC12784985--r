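#' Model performance criteria
#'
#' The three criteria used throughout the package to score live-weight
#' predictions: coefficient of determination (R^2), root mean square error
#' (RMSE, in the units of the response, grams here) and mean absolute
#' percentage error (MAPE, percent). All three use population denominators
#' (n), with no degrees-of-freedom adjustment.
#'
#' @param observed numeric vector of measured values (grams).
#' @param predicted numeric vector of predicted values, same length.
#' @return `r_squared()` a dimensionless value (<= 1, may be negative for
#'   predictors worse than the mean); `rmse()` a non-negative error in the
#'   units of `observed`; `mape()` a non-negative percentage.
#' @examples
#' r_squared(c(100, 200), c(110, 190)) # 0.96
#' rmse(c(100, 200), c(110, 190))      # 10
#' mape(c(100, 200), c(110, 190))      # 7.5
#' @name metrics
NULL

check_paired <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty series", call. = FALSE)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("missing values in paired series", call. = FALSE)
  invisible(TRUE)
}

#' @rdname metrics
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("r_squared undefined: observed values are constant", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @rdname metrics
#' @export
rmse <- function(observed, predicted) {
  check_paired(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname metrics
#' @export
mape <- function(observed, predicted) {
  check_paired(observed, predicted)
  if (any(observed == 0))
    stop("mape undefined: zero observed value", call. = FALSE)
  mean(abs((observed - predicted) / observed)) * 100
}

#' All three criteria at once
#'
#' @inheritParams metrics
#' @return named list with elements `r2`, `rmse`, `mape`.
#' @export
regression_metrics <- function(observed, predicted) {
  list(
    r2 = r_squared(observed, predicted),
    rmse = rmse(observed, predicted),
    mape = mape(observed, predicted)
  )
}
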