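#' Root mean squared error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (p_i - e_i)^2 / n}} between predicted
#' and observed values.
#' @param pred predicted values.
#' @param obs observed values (same length).
#' @return non-negative scalar.
#' @export
rmse <- function(pred, obs) {
  .check_pair(pred, obs, min_n = 1L)
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination R2
#'
#' \eqn{R^2 = 1 - \sum_i (e_i - p_i)^2 / \sum_i (e_i - \bar e)^2} with
#' \eqn{\bar e} the mean of the observed values.
#' @inheritParams rmse
#' @return scalar, at most 1; can be negative for predictions worse than the
#'   observed mean.
#' @export
r_squared <- function(pred, obs) {
  .check_pair(pred, obs, min_n = 2L)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R2 undefined: observed values are constant", call. = FALSE)
  1 - sum((obs - pred)^2) / ss_tot
}

#' External predictivity Q2
#'
#' The same functional form as [r_squared()] evaluated on an external test
#' partition. By default the centring mean is the mean of the evaluated
#' (test) observations; `reference_mean` substitutes e.g. the training mean.
#' @param pred predicted values on the test set.
#' @param obs_test observed test values.
#' @param reference_mean optional externally supplied centring mean.
#' @return scalar, at most 1.
#' @export
q_squared <- function(pred, obs_test, reference_mean = NULL) {
  .check_pair(pred, obs_test, min_n = 2L)
  ctr <- if (is.null(reference_mean)) mean(obs_test) else reference_mean
  ss_tot <- sum((obs_test - ctr)^2)
  if (ss_tot == 0) stop("Q2 undefined: zero total sum of squares", call. = FALSE)
  1 - sum((obs_test - pred)^2) / ss_tot
}

.check_pair <- function(pred, obs, min_n) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ", call. = FALSE)
  if (length(obs) < min_n) stop("need at least ", min_n, " observations", call. = FALSE)
  if (!all(is.finite(pred)) || !all(is.finite(obs))) stop("non-finite values", call. = FALSE)
  invisible(NULL)
}

#' Build a k-fold cross-validation plan
#'
#' Deterministic given `seed`; folds partition `1..n` with sizes differing by
#' at most one.
#' @param n number of samples.
#' @param k number of folds (paper protocol: 5).
#' @param seed integer seed.
#' @return object of class `cv_plan` with fields `k`, `seed`, `assignment`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  assignment <- with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "cv_plan")
}

# Evaluate an expression with a temporarily-seeded RNG, restoring any prior
# RNG state afterwards so library code does not disturb the session stream.
#' Run an expression under a local RNG seed
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Cross-validate a model specification on a descriptor table
#'
#' Trains on k-1 folds and scores the held-out fold with [rmse()]. Feature
#' standardisation is refit inside every training fold, so no information
#' leaks from held-out rows. Reports both the pooled RMSE (root mean square
#' over all held-out residuals, which equals the RMSE of the union) and the
#' simple mean of per-fold RMSEs.
#'
#' @param table a [descriptor_table()] with target.
#' @param features character vector (or logical mask over columns) of the
#'   descriptors to use.
#' @param spec a model specification from [svr_spec()] or [pls_spec()].
#' @param plan a [make_folds()] plan matching `nrow(table$values)`.
#' @return list with `pooled_rmse`, `mean_fold_rmse`, `fold_rmse`,
#'   `predictions` (held-out predictions in row order).
#' @export
cross_validate <- function(table, features, spec, plan) {
  stopifnot(inherits(table, "descriptor_table"), inherits(plan, "cv_plan"))
  if (is.null(table$target)) stop("cross-validation requires a target", call. = FALSE)
  if (is.logical(features)) features <- colnames(table$values)[features]
  if (length(features) < 1L) stop("feature mask selects no descriptors", call. = FALSE)
  n <- nrow(table$values)
  if (length(plan$assignment) != n) stop("fold plan does not match table size", call. = FALSE)
  preds <- numeric(n)
  fold_rmse <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    hold <- plan$assignment == f
    fit <- tryCatch(
      train_model(subset_table(table, !hold, features), spec),
      error = function(e) stop("training failed in fold ", f, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    p <- predict_model(fit, subset_table(table, hold, features))
    preds[hold] <- p
    fold_rmse[f] <- rmse(p, table$target[hold])
  }
  list(pooled_rmse = rmse(preds, table$target),
       mean_fold_rmse = mean(fold_rmse),
       fold_rmse = fold_rmse,
       predictions = preds)
}

#' Grid search over SVR regularisation C and tube width epsilon
#'
#' Exhaustively evaluates every (C, epsilon) pair by k-fold cross-validated
#' RMSE and selects the minimiser; ties are broken toward the smallest C,
#' then the smallest epsilon. The default grids bracket the protocol optimum
#' C = 2.3, epsilon = 0.11.
#'
#' @inheritParams cross_validate
#' @param kernel a [kernel_spec()].
#' @param C_grid positive regularisation values.
#' @param eps_grid non-negative tube widths.
#' @param tolerance SMO tolerance used during the search (looser than the
#'   final fit: the search only compares grid points).
#' @return object of class `grid_search_result`: data.frame `grid` with
#'   columns `C`, `epsilon`, `mean_cv_rmse`, plus `best_C`, `best_epsilon`,
#'   `best_rmse`.
#' @export
grid_search <- function(table, features, kernel = kernel_spec("polynomial"),
                        C_grid = c(0.1, 0.5, 1, 1.5, 2, 2.3, 3, 5, 10),
                        eps_grid = seq(0.01, 0.25, by = 0.02),
                        plan = make_folds(nrow(table$values), 5L, 1L),
                        tolerance = 1e-3) {
  stopifnot(all(C_grid > 0), all(eps_grid >= 0),
            length(C_grid) > 0L, length(eps_grid) > 0L)
  grid <- expand.grid(C = C_grid, epsilon = eps_grid, KEEP.OUT.ATTRS = FALSE)
  grid$mean_cv_rmse <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cv <- cross_validate(table, features,
                         svr_spec(kernel, C = grid$C[r], epsilon = grid$epsilon[r],
                                  tolerance = tolerance),
                         plan)
    grid$mean_cv_rmse[r] <- cv$pooled_rmse
  }
  ord <- order(grid$mean_cv_rmse, grid$C, grid$epsilon)
  best <- grid[ord[1L], ]
  structure(list(grid = grid, best_C = best$C, best_epsilon = best$epsilon,
                 best_rmse = best$mean_cv_rmse),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result: %d points; best C = %g, epsilon = %g, CV RMSE = %.4f>\n",
              nrow(x$grid), x$best_C, x$best_epsilon, x$best_rmse))
  invisible(x)
}

#' Write grid-search curves as CSV
#' @param result a [grid_search()] result.
#' @param path output CSV path (`C,epsilon,mean_cv_rmse`).
#' @return `path`, invisibly.
#' @export
write_grid_curves <- function(result, path) {
  utils::write.csv(result$grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a fitted model on train and test partitions
#'
#' Produces the standard validation report: RMSE and R2 on the training
#' partition, RMSE and Q2 on the external test partition.
#' @param model fitted model from [train_model()], [train_svr()] or
#'   [train_pls()].
#' @param train,test [descriptor_table()] objects with targets.
#' @return data.frame with columns `partition`, `n`, `rmse`, `r2`.
#' @export
evaluate_model <- function(model, train, test = NULL) {
  p_tr <- predict_model(model, train)
  out <- data.frame(partition = "training", n = length(p_tr),
                    rmse = rmse(p_tr, train$target),
                    r2 = r_squared(p_tr, train$target),
                    stringsAsFactors = FALSE)
  if (!is.null(test)) {
    p_te <- predict_model(model, test)
    out <- rbind(out, data.frame(partition = "test", n = length(p_te),
                                 rmse = rmse(p_te, test$target),
                                 r2 = q_squared(p_te, test$target),
                                 stringsAsFactors = FALSE))
  }
  out
}
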