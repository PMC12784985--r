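#' Fit the log-transformed image-based weight model
#'
#' Ordinary least squares of log LW on (1, Day, log P, Day x log P) over
#' the training subset of a record-level train/test split — the same split
#' used by the ML benchmarking harness, so image-based and
#' morphometric-based predictions are compared on identical held-out
#' records. Coefficient standard errors and two-sided t-test p-values come
#' from the standard OLS covariance; R^2 is reported on the log scale fit,
#' while RMSE and MAPE are computed on back-transformed grams for both
#' subsets. The interaction enters exactly as Day x log P (never centred).
#'
#' @param records data frame with `day`, `pixel_area`, `live_weight_g`
#'   (and `sex` unless `group = "mixed"`).
#' @param group `"mixed"` (default), `"male"` or `"female"`.
#' @param split a list with `train` and `test` integer indices into
#'   `records` (e.g. from [split_records()]); if NULL a fresh 80/20
#'   day-band-stratified split is drawn with `split_seed`.
#' @param split_seed seed used when `split` is NULL.
#' @param log_base 10 (default) or exp(1); recorded in the model so
#'   generation and fitting always agree.
#' @return object of class `log_pixel_model`: `coefficients` (b0..b3),
#'   `se`, `p_values`, train/test `r2`, `rmse_g`, `mape_pct`, `log_base`,
#'   `group`, and the record counts.
#' @export
fit_log_model <- function(records, group = c("mixed", "male", "female"),
                          split = NULL, split_seed = 1L, log_base = 10) {
  group <- match.arg(group)
  stopifnot(all(c("day", "pixel_area", "live_weight_g") %in% names(records)))
  if (group != "mixed") records <- records[records$sex == group, , drop = FALSE]
  bad <- which(!(records$pixel_area > 0) | !(records$live_weight_g > 0) |
                 is.na(records$pixel_area))
  if (length(bad))
    stop("non-positive or missing pixel_area/live_weight in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (is.null(split))
    split <- split_records(records, test_fraction = 0.2, seed = split_seed)

  d <- data.frame(
    log_lw = log(records$live_weight_g, base = log_base),
    day = records$day,
    log_p = log(records$pixel_area, base = log_base))
  tr <- d[split$train, ]
  te <- d[split$test, ]
  X <- stats::model.matrix(~ day + log_p + day:log_p, data = tr)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (e.g. a single day of data)", call. = FALSE)
  fit <- stats::lm(log_lw ~ day + log_p + day:log_p, data = tr)
  sm <- summary(fit)

  back <- function(sub) log_base^stats::predict(fit, newdata = sub)
  lw_tr <- log_base^tr$log_lw
  lw_te <- log_base^te$log_lw
  # R^2 is undefined for a constant response; report NA rather than fail
  safe_metrics <- function(obs, pred) list(
    r2 = tryCatch(r_squared(obs, pred), error = function(e) NA_real_),
    rmse = rmse(obs, pred), mape = mape(obs, pred))
  m_tr <- safe_metrics(lw_tr, back(tr))
  m_te <- if (nrow(te)) safe_metrics(lw_te, back(te)) else
    list(r2 = NA_real_, rmse = NA_real_, mape = NA_real_)

  cf <- stats::coef(fit)
  names(cf) <- c("b0", "b1_day", "b2_logp", "b3_day_logp")
  se <- sm$coefficients[, "Std. Error"]
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(se) <- names(pv) <- names(cf)
  structure(list(
    group = group, coefficients = cf, se = se, p_values = pv,
    r2_log_train = sm$r.squared,
    r2_train = m_tr$r2, rmse_g_train = m_tr$rmse, mape_pct_train = m_tr$mape,
    r2_test = m_te$r2, rmse_g_test = m_te$rmse, mape_pct_test = m_te$mape,
    log_base = log_base, n_train = nrow(tr), n_test = nrow(te),
    split = split
  ), class = "log_pixel_model")
}

#' @export
print.log_pixel_model <- function(x, ...) {
  b <- x$coefficients
  cat(sprintf(
    "log LW = %.3f + (%.3f x Day) + (%.3f x logP) + (%.3f x Day x logP)   [base %s, %s]\n",
    b[1], b[2], b[3], b[4],
    if (abs(x$log_base - exp(1)) < 1e-9) "e" else format(x$log_base), x$group))
  cat(sprintf("  train: R2 %.3f, RMSE %.3f g, MAPE %.3f%% (n=%d)\n",
              x$r2_train, x$rmse_g_train, x$mape_pct_train, x$n_train))
  if (x$n_test)
    cat(sprintf("  test:  R2 %.3f, RMSE %.3f g, MAPE %.3f%% (n=%d)\n",
                x$r2_test, x$rmse_g_test, x$mape_pct_test, x$n_test))
  invisible(x)
}

#' Predict live weight from day and pixel area
#'
#' Applies base^(b0 + b1 Day + b2 log P + b3 Day log P). No smearing
#' correction is applied to the back-transform. Days outside 1..42 are
#' allowed but raise a warning (extrapolation).
#'
#' @param model a `log_pixel_model`, or a list with `coefficients`
#'   (b0..b3) and `log_base`.
#' @param day age in days (vectorized).
#' @param pixel_area foreground pixel count(s), > 0.
#' @return predicted weight, grams (strictly positive).
#' @export
predict_weight <- function(model, day, pixel_area) {
  if (any(pixel_area <= 0)) stop("pixel_area must be positive", call. = FALSE)
  if (any(day < 1 | day > 42))
    warning("day outside 1..42: extrapolating beyond the fitted range")
  b <- model$coefficients
  lp <- log(pixel_area, base = model$log_base)
  model$log_base^(b[[1]] + b[[2]] * day + b[[3]] * lp + b[[4]] * day * lp)
}

day_bands <- function() {
  data.frame(lo = seq(1, 36, by = 7), hi = seq(7, 42, by = 7),
             label = c("1-7", "8-14", "15-21", "22-28", "29-35", "36-42"))
}

#' Weekly error stratification of a log-pixel model
#'
#' Groups test-set residuals (in grams, after back-transform) into the six
#' 7-day age bands and reports per-band RMSE and MAPE. Empty bands yield a
#' row with n = 0 and NA metrics.
#'
#' @param model a `log_pixel_model`.
#' @param test_records data frame of held-out records (`day`,
#'   `pixel_area`, `live_weight_g`), spanning at least two bands.
#' @return data frame of class `weekly_error_table`: `days`, `rmse_g`,
#'   `mape_pct`, `n`.
#' @export
weekly_errors <- function(model, test_records) {
  stopifnot(all(c("day", "pixel_area", "live_weight_g") %in% names(test_records)))
  bands <- day_bands()
  band_of <- findInterval(test_records$day, bands$lo)
  if (length(unique(band_of[band_of >= 1 & band_of <= 6])) < 2)
    stop("test records must span at least two weekly bands", call. = FALSE)
  pred <- predict_weight(model, test_records$day, test_records$pixel_area)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- band_of == i
    if (!any(sel))
      return(data.frame(days = bands$label[i], rmse_g = NA_real_,
                        mape_pct = NA_real_, n = 0L))
    data.frame(days = bands$label[i],
               rmse_g = rmse(test_records$live_weight_g[sel], pred[sel]),
               mape_pct = mape(test_records$live_weight_g[sel], pred[sel]),
               n = sum(sel))
  })
  out <- do.call(rbind, out)
  class(out) <- c("weekly_error_table", "data.frame")
  out
}
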