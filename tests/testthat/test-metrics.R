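test_that("rmse closed forms hold", {
  x <- c(0.3, -1.2, 2.5, 0.7)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x + 0.4, x), 0.4)
  expect_equal(rmse(x - 1.3, x), 1.3)
  expect_equal(rmse(c(1, 2), c(0, 0)), sqrt(5 / 2))
  expect_error(rmse(1:3, 1:2), "lengths differ")
  expect_error(rmse(numeric(0), numeric(0)), "at least")
})

test_that("r_squared anchors: perfect fit, mean predictor, worked example", {
  obs <- c(0.1, 0.9, 2.2, -0.5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_equal(r_squared(c(0, 1, 1), c(0, 1, 2)), 0.5)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
})

test_that("q_squared uses the test-set mean by default, training mean by flag", {
  obs <- c(0, 2)
  expect_equal(q_squared(c(1, 1), obs), 0)
  expect_equal(q_squared(obs, obs), 1)
  # training-mean convention shifts the denominator
  expect_equal(q_squared(c(1, 1), obs, reference_mean = 2),
               1 - 2 / ((0 - 2)^2 + 0))
})

test_that("fold plans partition the data with near-equal sizes, reproducibly", {
  plan <- make_folds(10, 5, seed = 3)
  expect_equal(sort(unique(plan$assignment)), 1:5)
  expect_true(all(table(plan$assignment) == 2))
  expect_identical(plan$assignment, make_folds(10, 5, seed = 3)$assignment)
  expect_false(identical(plan$assignment, make_folds(10, 5, seed = 4)$assignment))
  loo <- make_folds(6, 6, seed = 1)
  expect_true(all(table(loo$assignment) == 1))
  expect_error(make_folds(4, 5), "folds")
  sizes <- table(make_folds(11, 3, seed = 1)$assignment)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("cross-validation recovers a noiseless linear target within the tube", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1.5 * X[, 1] - 0.7 * X[, 2]
  tab <- descriptor_table(X, sprintf("c%02d", 1:n), target = y)
  plan <- make_folds(n, 5, seed = 2)
  cv <- cross_validate(tab, c("a", "b"),
                       svr_spec(kernel_spec("linear"), C = 10, epsilon = 0.01,
                                tolerance = 1e-6), plan)
  expect_lte(cv$pooled_rmse, 0.01 + 1e-6 + 0.005)  # epsilon tube + slack
  # pooled RMSE equals the RMSE of the pooled held-out residuals
  expect_equal(cv$pooled_rmse, rmse(cv$predictions, y), tolerance = 1e-12)
  # per-fold RMSEs RMS-combine (weighted by fold size) to the pooled value
  sizes <- table(plan$assignment)
  expect_equal(sqrt(sum(cv$fold_rmse^2 * as.numeric(sizes)) / n), cv$pooled_rmse,
               tolerance = 1e-12)
})

test_that("cross-validation of a constant target is exact for any epsilon", {
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  tab <- descriptor_table(X, sprintf("c%02d", 1:n), target = rep(1.7, n))
  cv <- cross_validate(tab, c("a", "b"),
                       svr_spec(kernel_spec("linear"), C = 1, epsilon = 0.05),
                       make_folds(n, 4, seed = 1))
  expect_equal(cv$pooled_rmse, 0, tolerance = 1e-12)
})

test_that("row order does not change the cross-validated score", {
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(n, sd = 0.2)
  tab <- descriptor_table(X, sprintf("c%02d", 1:n), target = y)
  plan <- make_folds(n, 5, seed = 7)
  spec <- svr_spec(kernel_spec("linear"), tolerance = 1e-9)
  cv1 <- cross_validate(tab, c("a", "b"), spec, plan)
  perm <- sample(n)
  tab2 <- descriptor_table(X[perm, ], tab$ids[perm], target = y[perm])
  plan2 <- plan
  plan2$assignment <- plan$assignment[perm]
  cv2 <- cross_validate(tab2, c("a", "b"), spec, plan2)
  expect_equal(cv1$pooled_rmse, cv2$pooled_rmse, tolerance = 1e-6)
})

test_that("grid search selects the arg-min with smallest-C tie-breaking", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] - 0.5 * X[, 2]
  tab <- descriptor_table(X, sprintf("c%02d", 1:n), target = y)
  plan <- make_folds(n, 4, seed = 1)
  single <- grid_search(tab, c("a", "b"), kernel_spec("linear"),
                        C_grid = 2.3, eps_grid = 0.11, plan = plan)
  expect_equal(single$best_C, 2.3)
  expect_equal(single$best_epsilon, 0.11)
  gs <- grid_search(tab, c("a", "b"), kernel_spec("linear"),
                    C_grid = c(0.5, 2), eps_grid = c(0.02, 0.1, 0.2), plan = plan)
  expect_lte(gs$best_rmse, min(gs$grid$mean_cv_rmse))
  # noiseless target: CV RMSE is non-decreasing in epsilon above the floor
  curve <- gs$grid[gs$grid$C == gs$best_C, ]
  curve <- curve[order(curve$epsilon), ]
  above <- curve[curve$epsilon >= 0.02, ]
  expect_true(all(diff(above$mean_cv_rmse) >= -1e-6))
})

test_that("model evaluation reports both partitions", {
  set.seed(2)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(n, sd = 0.1)
  tab <- descriptor_table(X, sprintf("c%02d", 1:n), target = y)
  sp <- generate_split(tab, 0.8, seed = 1)
  fit <- train_model(sp$train, svr_spec(kernel_spec("linear")))
  ev <- evaluate_model(fit, sp$train, sp$test)
  expect_equal(ev$partition, c("training", "test"))
  expect_equal(ev$n, c(40L, 10L))
  expect_true(all(ev$r2 <= 1))
})
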