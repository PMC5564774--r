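test_that("kernel evaluations follow their closed forms", {
  poly <- kernel_spec("polynomial", degree = 2)
  expect_equal(kernel_eval(poly, c(1, 0), c(0, 1)), 1)      # orthogonal
  expect_equal(kernel_eval(poly, c(1, 0), c(1, 1)), 4)      # (1 + 1)^2
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, -1)), 1)
  rbf <- kernel_spec("rbf", gamma = 0.7)
  expect_equal(kernel_eval(rbf, c(0.3, -2), c(0.3, -2)), 1)
  expect_equal(kernel_eval(rbf, c(0, 0), c(1, 1)), exp(-1.4))
  expect_error(kernel_eval(poly, 1:2, 1:3), "dimension")
  # symmetry over random pairs
  set.seed(1)
  for (r in 1:5) {
    x <- rnorm(3); y <- rnorm(3)
    for (sp in list(poly, rbf, kernel_spec("linear"))) {
      expect_equal(kernel_eval(sp, x, y), kernel_eval(sp, y, x))
    }
  }
})

test_that("a constant target yields the all-zero dual and bias b = c", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- train_svr(X, rep(2.5, 10), kernel_spec("linear"), C = 1, epsilon = 0.05)
  expect_equal(nrow(m$support_vectors), 0L)
  expect_equal(m$b, 2.5)
  expect_equal(predict_svr(m, X), rep(2.5, 10))
})

test_that("SMO satisfies dual feasibility and KKT structure", {
  set.seed(33)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = 0.3)
  C <- 1.5; eps <- 0.1
  m <- train_svr(X, y, kernel_spec("polynomial"), C = C, epsilon = eps,
                 tolerance = 1e-8)
  expect_true(all(m$alpha >= -1e-12 & m$alpha <= C + 1e-12))
  expect_true(all(m$alpha_star >= -1e-12 & m$alpha_star <= C + 1e-12))
  expect_lt(max(m$alpha * m$alpha_star), 1e-10)      # complementarity
  expect_lt(abs(sum(m$alpha - m$alpha_star)), 1e-10) # equality constraint
  expect_true(all(abs(m$beta) <= C + 1e-12))
  expect_true(all(abs(m$beta) > 0))                  # stored SVs only
  # rows strictly inside the tube carry zero dual weight
  resid <- abs(m$fitted - y)
  inside <- resid < eps - 1e-6
  beta_full <- m$alpha - m$alpha_star
  expect_true(all(abs(beta_full[inside]) < 1e-8))
})

test_that("SMO matches the brute-force QP oracle on random problems", {
  set.seed(101)
  for (r in 1:9) {
    pr <- random_svr_problem(r)
    m <- train_svr(pr$X, pr$y, pr$kernel, C = pr$C, epsilon = pr$eps,
                   tolerance = 1e-9, scale = FALSE)
    K <- qsartox:::.kernel_matrix(pr$kernel, pr$X)
    o <- qp_svr_oracle(K, pr$y, pr$C, pr$eps)
    expect_lt(abs(svr_dual_objective(m, K, pr$y) - o$objective), 1e-6)
    beta_full <- m$alpha - m$alpha_star
    expect_lt(max(abs(K %*% (beta_full - o$beta))), 1e-4)
  }
})

test_that("SMO agrees with an independent libsvm fit", {
  skip_if_not_installed("e1071")
  set.seed(12)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * X[, 1] - X[, 2] + rnorm(40, sd = 0.2)
  m <- train_svr(X, y, kernel_spec("linear"), C = 2, epsilon = 0.1,
                 tolerance = 1e-8)
  Z <- scale(X)
  ref <- e1071::svm(Z, y, type = "eps-regression", kernel = "linear",
                    cost = 2, epsilon = 0.1, scale = FALSE, tolerance = 1e-8)
  expect_lt(max(abs(predict_svr(m, X) - as.numeric(predict(ref, Z)))), 1e-4)
})

test_that("duplicating every row with halved C leaves the fit unchanged", {
  set.seed(8)
  X <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(8)
  kern <- kernel_spec("linear")
  m1 <- train_svr(X, y, kern, C = 2, epsilon = 0.1, tolerance = 1e-9, scale = FALSE)
  m2 <- train_svr(rbind(X, X), c(y, y), kern, C = 1, epsilon = 0.1,
                  tolerance = 1e-9, scale = FALSE)
  probe <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict_svr(m1, probe), predict_svr(m2, probe), tolerance = 1e-4)
})

test_that("support-vector count is non-increasing in epsilon", {
  set.seed(77)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(50, sd = 0.3)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(eps) {
    nrow(train_svr(X, y, kernel_spec("linear"), C = 2, epsilon = eps,
                   tolerance = 1e-6)$support_vectors)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("noiseless linear data is recovered to within the tube", {
  set.seed(4)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -0.5, 2)
  m <- train_svr(X, y, kernel_spec("linear"), C = 10, epsilon = 0.01,
                 tolerance = 1e-7)
  expect_lte(rmse(m$fitted, y), 0.01 + 1e-6)
  # predictions on training X reproduce the stored fitted values
  expect_equal(predict_svr(m, X), m$fitted, tolerance = 1e-9)
})

test_that("model files round-trip bit-identically and detect corruption", {
  set.seed(19)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(20, sd = 0.1)
  m <- train_svr(X, y, kernel_spec("polynomial"), C = 2.3, epsilon = 0.11)
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, path)
  m2 <- load_model(path)
  probe <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict_svr(m, probe), predict_svr(m2, probe))
  # deterministic serialisation: identical bytes across repeated saves
  path2 <- withr::local_tempfile(fileext = ".json")
  serialize_model(train_svr(X, y, kernel_spec("polynomial"), C = 2.3,
                            epsilon = 0.11), path2)
  expect_identical(readLines(path), readLines(path2))
  # truncation is caught by the checksum
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) - 8)], path2)
  expect_error(load_model(path2), "load error")
  # PLS models share the same container
  pm <- train_pls(X, y, 2)
  path3 <- withr::local_tempfile(fileext = ".json")
  serialize_model(pm, path3)
  expect_equal(predict_pls(load_model(path3), probe), predict_pls(pm, probe))
})

test_that("prediction demands matching feature columns", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  m <- train_svr(X, rnorm(20), kernel_spec("linear"))
  bad <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "z")))
  expect_error(predict_svr(m, bad), "feature column")
  # misordered columns are realigned, not misread
  sw <- X[1:5, c("b", "a")]
  expect_equal(predict_svr(m, sw), predict_svr(m, X[1:5, ]))
})
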