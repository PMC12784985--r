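#' Richards growth-curve parameters
#'
#' Container for the four parameters of the Richards sigmoidal growth
#' function LW(t) = A (1 + B exp(-k t))^(-1/m): `A` the asymptotic mature
#' weight (g), `B` a dimensionless integration constant fixing the initial
#' condition, `k` the growth-rate constant (per day) and `m` a shape
#' parameter that moves the inflection point (m = 1 recovers the logistic).
#'
#' @param A asymptotic weight, g; must be > 0.
#' @param B integration constant; must be >= 0 (B = 0 degenerates to the
#'   constant curve LW = A).
#' @param k growth-rate constant per day; must be > 0.
#' @param m shape parameter; must be > 0.
#' @return an object of class `richards_params`.
#' @export
richards_params <- function(A, B, k, m) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(k), is.numeric(m))
  if (A <= 0) stop("A must be positive", call. = FALSE)
  if (B < 0) stop("B must be non-negative", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (m <= 0) stop("m must be positive", call. = FALSE)
  structure(list(A = A, B = B, k = k, m = m), class = "richards_params")
}

#' @export
print.richards_params <- function(x, ...) {
  cat(sprintf("Richards parameters: A = %.4f g, B = %.4f, k = %.5f /day, m = %.4f\n",
              x$A, x$B, x$k, x$m))
  invisible(x)
}

#' Evaluate the Richards growth function
#'
#' @param params a [richards_params()] object (or list with A, B, k, m).
#' @param t age in days (vectorized, t >= 0 allowed).
#' @return live weight in grams at each `t`.
#' @export
richards_evaluate <- function(params, t) {
  if (params$A <= 0 || params$k <= 0 || params$m <= 0)
    stop("A, k and m must be positive", call. = FALSE)
  base <- 1 + params$B * exp(-params$k * t)
  if (any(base <= 0)) stop("1 + B exp(-k t) must be positive", call. = FALSE)
  params$A * base^(-1 / params$m)
}

richards_sse <- function(par, t, w) {
  pred <- par[["A"]] * (1 + par[["B"]] * exp(-par[["k"]] * t))^(-1 / par[["m"]])
  sum((w - pred)^2)
}

#' Fit the Richards growth function by nonlinear least squares
#'
#' Fits LW(t) = A (1 + B exp(-k t))^(-1/m) to (day, live weight) pairs,
#' pooled over the requested sex group. Because the Richards surface has
#' local minima in (k, m), the optimizer is multi-started over a coarse
#' (k, m) grid; box constraints keep A inside (max observed weight,
#' 20 x max], preventing degenerate exponential fits. Each start runs
#' L-BFGS-B on the residual sum of squares and the best solution is
#' polished with `nls(algorithm = "port")`. Deterministic given the data
#' and the start grid.
#'
#' @param records data frame with columns `day` and `live_weight_g`
#'   (a cohort from [generate_cohort()], or any such table); a `sex`
#'   column is required unless `group = "mixed"`.
#' @param group one of `"mixed"`, `"male"`, `"female"`: which records to
#'   pool before fitting.
#' @param by_bird if `TRUE`, fit one curve per `bird_id` instead of the
#'   pooled group curve, returning a list of fits.
#' @param k_grid,m_grid multi-start grids for the growth-rate and shape
#'   parameters.
#' @return an object of class `growth_fit`: the fitted [richards_params()],
#'   fit metrics (`r2`, `rmse_g`, `mape_pct`), a `converged` flag, `n_obs`
#'   and `group`. Non-convergence from every start yields
#'   `converged = FALSE` with the best-SSE parameters found, never a
#'   silent answer.
#' @export
fit_richards <- function(records, group = c("mixed", "male", "female"),
                         by_bird = FALSE,
                         k_grid = seq(0.05, 0.3, by = 0.05),
                         m_grid = c(0.3, 1, 3)) {
  group <- match.arg(group)
  stopifnot(is.data.frame(records),
            all(c("day", "live_weight_g") %in% names(records)))
  if (group != "mixed") {
    if (!"sex" %in% names(records)) stop("records need a sex column", call. = FALSE)
    records <- records[records$sex == group, , drop = FALSE]
  }
  if (by_bird) {
    if (!"bird_id" %in% names(records)) stop("records need bird_id", call. = FALSE)
    fits <- lapply(split(records, records$bird_id), fit_richards,
                   group = "mixed", k_grid = k_grid, m_grid = m_grid)
    return(fits)
  }
  t <- records$day
  w <- records$live_weight_g
  if (any(w <= 0)) stop("live weights must be positive", call. = FALSE)
  if (length(unique(t)) < 8) stop("need at least 8 distinct days", call. = FALSE)

  wmax <- max(w)
  lower <- c(A = wmax * (1 + 1e-9), B = 1e-8, k = 1e-4, m = 1e-3)
  upper <- c(A = 20 * wmax, B = 1e8, k = 2, m = 50)
  best <- NULL
  for (k0 in k_grid) {
    for (m0 in m_grid) {
      A0 <- min(max(2 * wmax, lower[["A"]] * 1.01), upper[["A"]])
      # B start from the earliest observation under (A0, k0, m0)
      i1 <- which.min(t)
      B0 <- ((A0 / w[i1])^m0 - 1) * exp(k0 * t[i1])
      B0 <- min(max(B0, lower[["B"]]), upper[["B"]])
      par0 <- c(A = A0, B = B0, k = k0, m = m0)
      opt <- tryCatch(
        stats::optim(par0, richards_sse, t = t, w = w,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 1e4,
                                    parscale = c(wmax, B0 + 1, 0.1, 1))),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  par <- best$par
  converged <- is.finite(best$value)
  # polish with nls (port respects the same box constraints)
  pol <- tryCatch(
    stats::nls(w ~ A * (1 + B * exp(-k * t))^(-1 / m),
               start = as.list(par), algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(pol)) {
    cp <- stats::coef(pol)
    if (richards_sse(cp, t, w) <= best$value + 1e-12) par <- cp
  }

  params <- richards_params(par[["A"]], par[["B"]], par[["k"]], par[["m"]])
  pred <- richards_evaluate(params, t)
  structure(list(
    params = params,
    r2 = r_squared(w, pred),
    rmse_g = rmse(w, pred),
    mape_pct = mape(w, pred),
    converged = converged,
    n_obs = length(w),
    group = group
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Richards fit (%s, n = %d)%s\n", x$group, x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$params)
  cat(sprintf("  R2 = %.4f, RMSE = %.3f g, MAPE = %.3f%%\n",
              x$r2, x$rmse_g, x$mape_pct))
  invisible(x)
}
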