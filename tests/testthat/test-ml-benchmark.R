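test_that("min-max scaling follows the training-range formula", {
  sc <- minmax_scale(matrix(c(0, 10)), matrix(5))
  expect_equal(sc$scaled[1, 1], 0.5)
  sc2 <- minmax_scale(matrix(c(0, 3, 10)), matrix(c(0, 10)))
  expect_equal(as.vector(sc2$scaled), c(0, 1))
  expect_false(any(sc2$out_of_range))
  # test value beyond the training range: 1.2, flagged
  sc3 <- minmax_scale(matrix(c(0, 10)), matrix(12))
  expect_equal(sc3$scaled[1, 1], 1.2)
  expect_true(sc3$out_of_range[1])
  expect_error(minmax_scale(matrix(c(2, 2, 2))), "constant feature")
})

test_that("record-level splits are exact, reproducible and conservative", {
  rec <- data.frame(day = rep(1:42, times = 100), x = 1)
  sp <- split_records(rec, 0.2, seed = 4)
  expect_length(sp$train, 3360)
  expect_length(sp$test, 840)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(4200))
  expect_identical(split_records(rec, 0.2, seed = 4), sp)
  expect_false(identical(split_records(rec, 0.2, seed = 5), sp))
  # stratification puts every week band in both subsets
  band <- findInterval(rec$day, seq(1, 36, by = 7))
  expect_setequal(unique(band[sp$test]), 1:6)
  expect_error(split_records(rec[1, , drop = FALSE], 0.2, seed = 1),
               "too few")
})

test_that("the in-package KNN matches the FNN oracle on tie-free data", {
  set.seed(8)
  x <- matrix(runif(120), ncol = 2)
  y <- rnorm(60)
  xq <- matrix(runif(30), ncol = 2)
  fit <- fit_regressor("knn", x, y, list(n_neighbors = 5L, power = 2))
  mine <- predict_regressor(fit, xq)
  oracle <- FNN::knn.reg(train = x, test = xq, y = y, k = 5)$pred
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("each learner fits the signal it is designed for", {
  set.seed(21)
  n <- 250
  x <- cbind(runif(n), runif(n))
  y_lin <- 4 * x[, 1] - 2 * x[, 2] + 5
  fit_mlr <- fit_regressor("mlr", x, y_lin)
  expect_lt(rmse(y_lin, predict_regressor(fit_mlr, x)), 1e-8)

  y_nl <- sin(6 * x[, 1]) + (x[, 2] - 0.5)^2 * 8
  base_rmse <- rmse(y_nl, rep(mean(y_nl), n))
  for (alg in c("rf", "xgb", "svr", "knn")) {
    set.seed(5)
    f <- fit_regressor(alg, x, y_nl,
                       list(n_estimators = 60L, n_neighbors = 5L,
                            C = 100, epsilon = 0.01))
    expect_lt(rmse(y_nl, predict_regressor(f, x)), 0.4 * base_rmse,
              label = paste(alg, "training rmse"))
  }
  expect_error(fit_regressor("ann", x, y_lin), "unknown algorithm")
})

test_that("exact two-feature Shapley values satisfy their axioms", {
  set.seed(33)
  bg <- matrix(runif(40), ncol = 2)
  # additive model: phi for feature 1 ignores the instance's feature 2
  f_add <- function(m) 3 * m[, 1]^2 + exp(m[, 2])
  s1 <- shapley_two_feature(f_add, c(0.4, 0.1), bg)
  s2 <- shapley_two_feature(f_add, c(0.4, 0.9), bg)
  expect_equal(s1$phi[[1]], s2$phi[[1]], tolerance = 1e-12)
  # multiplicative toy: f = L*W at (2,3), background {(0,0)} -> phi = (3,3)
  f_prod <- function(m) m[, 1] * m[, 2]
  sp <- shapley_two_feature(f_prod, c(2, 3), matrix(c(0, 0), 1))
  expect_equal(unname(sp$phi), c(3, 3))
  expect_equal(sp$base_value, 0)
  expect_error(shapley_two_feature(f_prod, c(1, 2, 3), bg), "two features")
  expect_error(shapley_two_feature(f_prod, c(1, 2), bg[0, , drop = FALSE]),
               "empty")
})

test_that("closed form equals brute-force permutation enumeration", {
  # independent oracle: enumerate both orderings with the
  # background-marginalized coalition value function
  brute_shapley <- function(f, x, bg) {
    v <- function(S) {
      m <- bg
      for (j in S) m[, j] <- x[j]
      mean(f(m))
    }
    phi <- numeric(2)
    for (perm in list(c(1, 2), c(2, 1))) {
      S <- integer(0)
      for (j in perm) {
        phi[j] <- phi[j] + (v(c(S, j)) - v(S)) / 2
        S <- c(S, j)
      }
    }
    phi
  }
  set.seed(44)
  x_tr <- matrix(runif(160), ncol = 2)
  y_tr <- x_tr[, 1] * exp(x_tr[, 2]) + rnorm(80, 0, 0.05)
  set.seed(9)
  fit <- fit_regressor("rf", x_tr, y_tr, list(n_estimators = 25L))
  pf <- function(m) predict_regressor(fit, m)
  bg <- x_tr[1:30, ]
  for (i in c(2, 17, 55)) {
    closed <- shapley_two_feature(pf, x_tr[i, ], bg)
    expect_equal(unname(closed$phi), brute_shapley(pf, x_tr[i, ], bg),
                 tolerance = 1e-12)
    # local accuracy identity
    expect_equal(sum(closed$phi), closed$prediction - closed$base_value,
                 tolerance = 1e-10)
  }
})

test_that("MLR solves perfectly linear data through the full protocol", {
  rec <- linear_records(n = 300, seed = 6)
  cfg <- benchmark_config(dataset = "mixed", n_repeats = 2, seed = 2,
                          stratify = FALSE,
                          grids = list(mlr = data.frame()),
                          algorithms = "mlr")
  rep <- tune_and_evaluate(rec, cfg)
  expect_true(all(rep$metrics$r2_test > 1 - 1e-10))
  expect_true(all(rep$metrics$rmse_test < 1e-6))
})

test_that("report cardinality is algorithms x repeats and tuning is honest", {
  coh <- small_cohort(n_birds = 8, seed = 12)
  grids <- list(
    rf = data.frame(n_estimators = 20L, max_depth = 5),
    xgb = data.frame(n_estimators = 20L, max_depth = 3, learning_rate = 0.3),
    svr = data.frame(C = 1000, epsilon = 0.5),
    knn = expand.grid(n_neighbors = c(5L, 9L), power = 1), # exercises CV
    mlr = data.frame())
  cfg <- benchmark_config(dataset = "mixed", n_repeats = 10, seed = 31,
                          grids = grids)
  rep <- tune_and_evaluate(coh, cfg)
  expect_identical(nrow(rep$metrics), 50L)
  expect_identical(nrow(rep$shapley), 100L)
  expect_true(all(table(rep$metrics$algorithm) == 10))
  # protocol hygiene: across all repeats no index in both subsets
  for (sp in rep$splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(nrow(coh)))
  }
  # repeat independence: partitions not all identical
  tests <- lapply(rep$splits, `[[`, "test")
  expect_gt(length(unique(tests)), 1L)
  # KNN grid was actually tuned: a winner is recorded
  knn_rows <- rep$metrics[rep$metrics$algorithm == "knn", ]
  expect_true(all(grepl("n_neighbors=", knn_rows$hyperparameters)))
  # summary aggregates one row per algorithm
  sm <- summary(rep)
  expect_identical(nrow(sm), 5L)
  expect_true(all(sm$n_repeats == 10))
})

test_that("width-dominant synthetic signal yields width-dominant attributions", {
  set.seed(77)
  n <- 400
  rec <- data.frame(
    back_length_mm = runif(n, 50, 220),
    back_width_mm = runif(n, 30, 170))
  # width carries most of the (nonlinear) signal
  rec$live_weight_g <- 2500 * (rec$back_width_mm / 170)^3 +
    0.5 * rec$back_length_mm + rnorm(n, 0, 20)
  rec$sex <- "male"
  cfg <- benchmark_config(dataset = "mixed", n_repeats = 2, seed = 15,
                          stratify = FALSE,
                          grids = list(rf = data.frame(n_estimators = 40L),
                                       xgb = data.frame(n_estimators = 60L,
                                                        learning_rate = 0.3)),
                          algorithms = c("rf", "xgb"))
  rep <- tune_and_evaluate(rec, cfg)
  sh <- rep$shapley
  for (alg in c("rf", "xgb")) for (r in 1:2) {
    d <- sh[sh$algorithm == alg & sh$rep == r, ]
    expect_gt(d$mean_abs_shap[d$feature == "back_width"],
              d$mean_abs_shap[d$feature == "back_length"])
  }
})
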