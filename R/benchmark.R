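#' Min-max scaling fitted on the training subset
#'
#' Scales each feature to (x - min_train) / (max_train - min_train). The
#' scaler is fitted on the training features only and then applied to any
#' other set; applied values may fall outside \[0, 1\] (allowed, but
#' flagged per row).
#'
#' @param train numeric matrix/data frame of training features; every
#'   feature needs at least two distinct values.
#' @param apply_to optional features to transform with the train-fitted
#'   scaler (defaults to `train`).
#' @return list with `scaled` (transform of `apply_to`), `train_scaled`,
#'   `min`, `max`, and `out_of_range` (logical per row of `apply_to`).
#' @export
minmax_scale <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  if (any(maxs - mins == 0))
    stop("constant feature: min-max scaling undefined", call. = FALSE)
  sc <- function(m) sweep(sweep(m, 2, mins), 2, maxs - mins, "/")
  scaled <- sc(apply_to)
  list(scaled = scaled, train_scaled = sc(train), min = mins, max = maxs,
       out_of_range = apply(scaled < 0 | scaled > 1, 1, any))
}

#' Record-level train/test split
#'
#' Randomly partitions record indices into train and test, reproducibly by
#' seed. By default the split is stratified by the six 7-day age bands so
#' every growth stage is represented in both subsets (plain random is
#' available with `stratify = FALSE`).
#'
#' @param records data frame (needs a `day` column when stratifying).
#' @param test_fraction fraction of records held out (default 0.2).
#' @param seed integer seed.
#' @param stratify stratify by weekly day band (default TRUE).
#' @return list with sorted integer vectors `train` and `test`; disjoint
#'   and jointly exhaustive.
#' @export
split_records <- function(records, test_fraction = 0.2, seed = 1L,
                          stratify = TRUE) {
  n <- nrow(records)
  stopifnot(test_fraction > 0, test_fraction < 1)
  strata <- if (stratify && "day" %in% names(records)) {
    pmin(pmax(findInterval(records$day, seq(1, 36, by = 7)), 1L), 6L)
  } else rep(1L, n)
  set.seed(seed)
  test <- integer(0)
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    k <- round(length(idx) * test_fraction)
    if (k >= 1) test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  train <- setdiff(seq_len(n), test)
  if (length(train) == 0 || length(test) == 0)
    stop("too few records to populate both subsets", call. = FALSE)
  list(train = train, test = test)
}

#' Default hyperparameter search grids
#'
#' The published best-tuned values for each learner plus immediate
#' neighbours; MLR has no tunables.
#'
#' @return named list of data-frame grids keyed by algorithm.
#' @export
default_grids <- function() {
  list(
    rf = expand.grid(n_estimators = c(100, 150), max_depth = 5,
                     min_samples_split = c(2, 5), min_samples_leaf = c(1, 2)),
    xgb = expand.grid(n_estimators = c(100, 200), learning_rate = 0.05,
                      max_depth = 3, subsample = c(0.8, 1.0)),
    svr = expand.grid(C = c(100, 1000), epsilon = c(0.01, 0.5)),
    knn = expand.grid(n_neighbors = c(9, 11, 13), power = c(1, 2)),
    mlr = data.frame()
  )
}

#' Benchmark protocol configuration
#'
#' @param dataset `"mixed"`, `"male"` or `"female"`: which records enter
#'   the benchmark.
#' @param test_fraction held-out fraction per repeat (default 0.2).
#' @param tuning_fraction_of_train fraction of the training set used for
#'   hyperparameter tuning (default 0.9).
#' @param n_repeats number of repeated random sub-sampling rounds
#'   (default 10).
#' @param cv_folds folds of the inner grid-search cross-validation
#'   (default 5).
#' @param grids per-algorithm hyperparameter grids (default
#'   [default_grids()]); algorithms run in this order. An empty grid
#'   means no tuning (the learner's defaults are used).
#' @param algorithms subset of `names(grids)` to run.
#' @param seed base seed; repeat r uses `seed + r`.
#' @param stratify stratified splitting by day band (default TRUE).
#' @param shapley_n_instances test instances audited per model for the
#'   Shapley feature-importance summary (default 20).
#' @param shapley_background_n training rows in the Shapley background
#'   set (default 50).
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(dataset = c("mixed", "male", "female"),
                             test_fraction = 0.2,
                             tuning_fraction_of_train = 0.9,
                             n_repeats = 10L, cv_folds = 5L,
                             grids = default_grids(),
                             algorithms = names(grids),
                             seed = 1L, stratify = TRUE,
                             shapley_n_instances = 20L,
                             shapley_background_n = 50L) {
  dataset <- match.arg(dataset)
  stopifnot(test_fraction > 0, test_fraction < 1,
            tuning_fraction_of_train > 0, tuning_fraction_of_train <= 1,
            n_repeats >= 1, cv_folds >= 2,
            all(algorithms %in% names(grids)))
  structure(list(dataset = dataset, test_fraction = test_fraction,
                 tuning_fraction_of_train = tuning_fraction_of_train,
                 n_repeats = as.integer(n_repeats),
                 cv_folds = as.integer(cv_folds),
                 grids = grids, algorithms = algorithms,
                 seed = as.integer(seed), stratify = stratify,
                 shapley_n_instances = as.integer(shapley_n_instances),
                 shapley_background_n = as.integer(shapley_background_n)),
            class = "benchmark_config")
}

grid_cv_rmse <- function(algorithm, combo, x, y, fold_id, seed) {
  errs <- vapply(sort(unique(fold_id)), function(f) {
    hold <- fold_id == f
    set.seed(seed)
    fit <- fit_regressor(algorithm, x[!hold, , drop = FALSE], y[!hold],
                         params = as.list(combo))
    rmse(y[hold], predict_regressor(fit, x[hold, , drop = FALSE]))
  }, 0)
  mean(errs)
}

#' Run the full benchmarking protocol
#'
#' For each of `n_repeats` rounds: draw a fresh record-level 80/20 split;
#' min-max scale features on the training subset; carve out the 90% tuning
#' subset; grid-search each algorithm by k-fold cross-validated RMSE on
#' the tuning subset (ties broken by grid order); retrain the winning
#' configuration on the entire training set; score train and test subsets
#' with R^2/RMSE/MAPE; and audit a sample of test instances with exact
#' two-feature Shapley attribution. Tuning never touches the test subset;
#' the returned split bookkeeping allows asserting this.
#'
#' @param records cohort data frame (`sex`, `back_length_mm`,
#'   `back_width_mm`, `live_weight_g`, and `day` if stratifying).
#' @param config a [benchmark_config()].
#' @return object of class `evaluation_report`: `$metrics` (one row per
#'   algorithm x repeat with chosen hyperparameters), `$shapley` (mean
#'   absolute Shapley value per feature, algorithm and repeat), and
#'   `$splits` (per-repeat train/test indices).
#' @export
tune_and_evaluate <- function(records, config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  if (config$dataset != "mixed")
    records <- records[records$sex == config$dataset, , drop = FALSE]
  feats <- c("back_length_mm", "back_width_mm")
  stopifnot(all(c(feats, "live_weight_g") %in% names(records)))
  X <- as.matrix(records[, feats])
  y <- records$live_weight_g

  metrics <- list()
  shap <- list()
  splits <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rseed <- config$seed + r
    sp <- split_records(records, config$test_fraction, seed = rseed,
                        stratify = config$stratify)
    splits[[r]] <- sp
    sc <- minmax_scale(X[sp$train, , drop = FALSE])
    x_tr <- sc$train_scaled
    x_te <- minmax_scale(X[sp$train, , drop = FALSE],
                         X[sp$test, , drop = FALSE])$scaled
    y_tr <- y[sp$train]
    y_te <- y[sp$test]

    set.seed(rseed * 7L)
    n_tune <- floor(config$tuning_fraction_of_train * length(sp$train))
    tune_idx <- sort(sample(seq_along(sp$train), n_tune))
    fold_id <- sample(rep(seq_len(config$cv_folds), length.out = n_tune))
    if (min(table(fold_id)) < 2)
      stop("cross-validation fold smaller than 2 samples", call. = FALSE)

    for (alg in config$algorithms) {
      grid <- config$grids[[alg]]
      if (is.null(grid)) {
        warning("empty grid for ", alg, ": skipped")
        next
      }
      chosen <- list()
      if (nrow(grid) > 1) {
        cv <- vapply(seq_len(nrow(grid)), function(i)
          grid_cv_rmse(alg, grid[i, , drop = FALSE],
                       x_tr[tune_idx, , drop = FALSE], y_tr[tune_idx],
                       fold_id, seed = rseed * 31L + i), 0)
        chosen <- as.list(grid[which.min(cv), , drop = FALSE])
      } else if (nrow(grid) == 1) {
        chosen <- as.list(grid[1, , drop = FALSE])
      }
      set.seed(rseed * 131L)
      fit <- fit_regressor(alg, x_tr, y_tr, params = chosen)
      m_tr <- regression_metrics(y_tr, predict_regressor(fit, x_tr))
      m_te <- regression_metrics(y_te, predict_regressor(fit, x_te))
      metrics[[length(metrics) + 1L]] <- data.frame(
        algorithm = alg, rep = r,
        r2_train = m_tr$r2, rmse_train = m_tr$rmse, mape_train = m_tr$mape,
        r2_test = m_te$r2, rmse_test = m_te$rmse, mape_test = m_te$mape,
        hyperparameters = if (length(chosen))
          paste(names(chosen), unlist(chosen), sep = "=", collapse = ", ")
          else "",
        stringsAsFactors = FALSE)

      # exact Shapley audit on a sample of test instances
      set.seed(rseed * 977L)
      inst_idx <- sample(nrow(x_te), min(config$shapley_n_instances, nrow(x_te)))
      bg_idx <- sample(nrow(x_tr), min(config$shapley_background_n, nrow(x_tr)))
      bg <- x_tr[bg_idx, , drop = FALSE]
      pf <- function(m) predict_regressor(fit, m)
      phis <- vapply(inst_idx, function(i)
        shapley_two_feature(pf, x_te[i, ], bg)$phi, numeric(2))
      shap[[length(shap) + 1L]] <- data.frame(
        algorithm = alg, rep = r,
        feature = c("back_length", "back_width"),
        mean_abs_shap = rowMeans(abs(phis)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 shapley = do.call(rbind, shap),
                 splits = splits, config = config),
            class = "evaluation_report")
}

#' @export
summary.evaluation_report <- function(object, ...) {
  m <- object$metrics
  agg <- do.call(rbind, lapply(split(m, m$algorithm), function(d) data.frame(
    algorithm = d$algorithm[1], n_repeats = nrow(d),
    r2_test_mean = mean(d$r2_test), r2_test_sd = stats::sd(d$r2_test),
    rmse_test_mean = mean(d$rmse_test), rmse_test_sd = stats::sd(d$rmse_test),
    mape_test_mean = mean(d$mape_test), mape_test_sd = stats::sd(d$mape_test))))
  rownames(agg) <- NULL
  agg[order(agg$rmse_test_mean), ]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Benchmark: %s dataset, %d repeats, %d algorithm(s)\n",
              x$config$dataset, x$config$n_repeats,
              length(unique(x$metrics$algorithm))))
  print(summary(x), digits = 4)
  invisible(x)
}

#' Exact Shapley values for a two-feature regressor
#'
#' With exactly two features the Shapley value is the average over the two
#' feature orderings of the marginal contribution, with absent features
#' marginalized over a background set:
#' phi_1 = 1/2 \[(fbar(x1, B2) - fbar(B1, B2)) + (f(x1, x2) - fbar(B1, x2))\],
#' where fbar averages predictions over background replacements, and
#' symmetrically for phi_2. By construction
#' phi_1 + phi_2 = f(x) - base_value (local accuracy).
#'
#' @param predict_fn function taking a feature matrix, returning numeric
#'   predictions.
#' @param instance numeric vector of length 2 (the audited point).
#' @param background matrix with 2 columns: the background (reference)
#'   data set; must be nonempty.
#' @return list with `phi` (named length-2 vector), `base_value` (mean
#'   background prediction) and `prediction` (f at the instance).
#' @export
shapley_two_feature <- function(predict_fn, instance, background) {
  background <- as.matrix(background)
  if (length(instance) != 2 || ncol(background) != 2)
    stop("exactly two features required", call. = FALSE)
  if (nrow(background) == 0) stop("background set is empty", call. = FALSE)
  f_x <- predict_fn(matrix(instance, nrow = 1))
  base <- mean(predict_fn(background))
  f_1 <- mean(predict_fn(cbind(instance[1], background[, 2])))
  f_2 <- mean(predict_fn(cbind(background[, 1], instance[2])))
  phi1 <- ((f_1 - base) + (f_x - f_2)) / 2
  phi2 <- ((f_2 - base) + (f_x - f_1)) / 2
  nm <- names(instance)
  if (is.null(nm)) nm <- c("feature1", "feature2")
  list(phi = stats::setNames(c(phi1, phi2), nm),
       base_value = base, prediction = unname(f_x))
}
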