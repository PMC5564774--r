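ablation_fixture <- function(seed = 90, n = 120, sd_noise = 0.15) {
  with_seed(seed, {
    X <- cbind(sig = rnorm(n), junk = rnorm(n))
    y <- 2 * X[, "sig"] + rnorm(n, sd = sd_noise)
    tab <- descriptor_table(X, sprintf("c%03d", 1:n), target = y)
    generate_split(tab, 0.75, seed = seed)
  })
}

test_that("ablation emits the full row plus one row per excluded feature", {
  sp <- ablation_fixture()
  rep <- ablate(sp$train, sp$test, c("sig", "junk"),
                svr_spec(kernel_spec("linear"), C = 2, epsilon = 0.05))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$excluded, c("<none>", "sig", "junk"))
  # full-subset row equals a direct train/evaluate call
  fit <- train_model(subset_table(sp$train, features = c("sig", "junk")),
                     svr_spec(kernel_spec("linear"), C = 2, epsilon = 0.05))
  ev <- evaluate_model(fit, subset_table(sp$train, features = c("sig", "junk")),
                       subset_table(sp$test, features = c("sig", "junk")))
  expect_equal(rep$train_rmse[1L], ev$rmse[1L], tolerance = 1e-12)
  expect_equal(rep$test_q2[1L], ev$r2[2L], tolerance = 1e-12)
})

test_that("removing the informative descriptor hurts more than removing noise", {
  drops_sig <- numeric(10); drops_junk <- numeric(10)
  for (s in 1:10) {
    sp <- ablation_fixture(seed = 90 + s)
    rep <- ablate(sp$train, sp$test, c("sig", "junk"),
                  svr_spec(kernel_spec("linear"), C = 2, epsilon = 0.05))
    full <- rep$test_q2[rep$excluded == "<none>"]
    drops_sig[s] <- full - rep$test_q2[rep$excluded == "sig"]
    drops_junk[s] <- full - rep$test_q2[rep$excluded == "junk"]
  }
  expect_gt(stats::median(drops_sig), stats::median(drops_junk))
  expect_gt(stats::median(drops_sig), 0.2)  # losing the only signal is fatal
})

test_that("ablation result is independent of feature evaluation order", {
  sp <- ablation_fixture(99)
  spec <- svr_spec(kernel_spec("linear"), C = 2, epsilon = 0.05, tolerance = 1e-9)
  r1 <- ablate(sp$train, sp$test, c("sig", "junk"), spec)
  r2 <- ablate(sp$train, sp$test, c("junk", "sig"), spec)
  expect_equal(sort(r1$test_q2), sort(r2$test_q2), tolerance = 1e-7)
})

test_that("sensitivity sweeps read the trained model's trend", {
  with_seed(123, {
    n <- 150
    X <- cbind(up = rnorm(n), down = rnorm(n), flat = rnorm(n))
    y <- 2 * X[, "up"] - X[, "down"] + rnorm(n, sd = 0.05)
    tab <- descriptor_table(X, sprintf("c%03d", 1:n), target = y)
  })
  fit <- train_model(tab, svr_spec(kernel_spec("linear"), C = 5, epsilon = 0.02))
  cu <- sensitivity_sweep(fit, tab, "up")
  cd <- sensitivity_sweep(fit, tab, "down")
  cf <- sensitivity_sweep(fit, tab, "flat")
  expect_equal(nrow(cu), 50L)
  expect_true(!is.unsorted(cu$value))
  expect_equal(trend_statistic(cu), 1)
  expect_equal(trend_statistic(cd), -1)
  # response magnitude of the absent feature is tiny next to the real ones
  # (a linear-kernel response is exactly linear, so rank monotonicity alone
  # cannot separate signal from noise; magnitude does)
  expect_lt(diff(range(cf$prediction)), 0.1 * diff(range(cu$prediction)))
  # with a wiggly kernel the absent feature's curve is not strictly monotone,
  # while the generating features still sweep to rank correlation +/- 1
  fit_rbf <- train_model(tab, svr_spec(kernel_spec("rbf"), C = 5, epsilon = 0.02))
  expect_lt(abs(trend_statistic(sensitivity_sweep(fit_rbf, tab, "flat"))), 1)
  expect_equal(trend_statistic(sensitivity_sweep(fit_rbf, tab, "up")), 1)
  expect_error(sensitivity_sweep(fit, tab, "nope"), "not in the model schema")
})

test_that("a support-vector-free model sweeps to a flat curve", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  tab <- descriptor_table(X, sprintf("c%02d", 1:20), target = rep(1.2, 20))
  fit <- train_model(tab, svr_spec(kernel_spec("linear"), epsilon = 0.1))
  curve <- sensitivity_sweep(fit, tab, "a")
  expect_true(all(curve$prediction == 1.2))
  expect_equal(trend_statistic(curve), 0)
})

test_that("trend statistic anchors: monotone, constant, symmetric", {
  up <- data.frame(value = 1:5, prediction = c(0, 1, 3, 7, 9))
  expect_equal(trend_statistic(up), 1)
  dn <- data.frame(value = 1:5, prediction = c(9, 7, 3, 1, 0))
  expect_equal(trend_statistic(dn), -1)
  tent <- data.frame(value = 1:3, prediction = c(0, 1, 0))
  expect_equal(trend_statistic(tent), 0)
  expect_error(trend_statistic(data.frame(value = 1:2, prediction = 1:2)),
               "at least 3")
})
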