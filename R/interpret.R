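#' Leave-one-descriptor-out ablation report
#'
#' Trains the full model and every leave-one-out submodel with identical
#' hyperparameters, and reports training RMSE/R2 and external-test RMSE/Q2
#' per row; the first row is the full subset.
#'
#' @param train,test [descriptor_table()] objects with targets.
#' @param features >= 2 descriptor names to ablate over.
#' @param spec a [svr_spec()] or [pls_spec()]; hyperparameters are reused
#'   unchanged for every subset (no per-subset re-tuning).
#' @return data.frame of class `ablation_report` with columns `excluded`
#'   (`"<none>"` for the full row), `descriptors`, `train_rmse`, `train_r2`,
#'   `test_rmse`, `test_q2`.
#' @export
ablate <- function(train, test, features, spec) {
  stopifnot(inherits(train, "descriptor_table"), inherits(test, "descriptor_table"))
  features <- as.character(features)
  if (length(features) < 2L) stop("ablation needs at least 2 features", call. = FALSE)
  one_row <- function(excluded) {
    feats <- setdiff(features, excluded)
    fit <- train_model(subset_table(train, features = feats), spec)
    ev_tr <- evaluate_model(fit, subset_table(train, features = feats))
    p_te <- predict_model(fit, subset_table(test, features = feats))
    data.frame(excluded = if (length(excluded)) excluded else "<none>",
               descriptors = paste(feats, collapse = ","),
               train_rmse = ev_tr$rmse[1L], train_r2 = ev_tr$r2[1L],
               test_rmse = rmse(p_te, test$target),
               test_q2 = q_squared(p_te, test$target),
               stringsAsFactors = FALSE)
  }
  rows <- c(list(one_row(character(0))), lapply(features, one_row))
  out <- do.call(rbind, rows)
  class(out) <- c("ablation_report", "data.frame")
  out
}

#' One-at-a-time sensitivity sweep of a trained model
#'
#' Probes one descriptor over an even grid spanning its observed range while
#' every other descriptor is held at its baseline (mean by default, median by
#' flag) over the supplied table, and records the model response. This reads
#' the trained model's marginal trend for that descriptor.
#'
#' @param model fitted `svr_model` or `pls_model`.
#' @param table a [descriptor_table()] providing ranges and baselines
#'   (typically the training table).
#' @param descriptor descriptor name present in the model schema.
#' @param grid_size number of probe points (default 50).
#' @param baseline `"mean"` or `"median"` statistic for the fixed descriptors.
#' @return object of class `sa_curve`: data.frame with columns `value`
#'   (probe, original units) and `prediction`, plus attributes `descriptor`
#'   and `baseline`.
#' @export
sensitivity_sweep <- function(model, table, descriptor, grid_size = 50L,
                              baseline = c("mean", "median")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(table, "descriptor_table"))
  feats <- if (inherits(model, "svr_model")) model$scaling$features else model$feature_names
  if (!descriptor %in% feats) {
    stop("descriptor ", sQuote(descriptor), " is not in the model schema", call. = FALSE)
  }
  V <- table$values[, feats, drop = FALSE]
  base <- if (baseline == "mean") colMeans(V) else apply(V, 2L, stats::median)
  rng <- range(V[, descriptor])
  grid <- seq(rng[1L], rng[2L], length.out = as.integer(grid_size))
  probe <- matrix(rep(base, each = length(grid)), nrow = length(grid),
                  dimnames = list(NULL, feats))
  probe[, descriptor] <- grid
  pred <- predict_model(model, probe)
  out <- data.frame(value = grid, prediction = pred)
  attr(out, "descriptor") <- descriptor
  attr(out, "baseline") <- base
  class(out) <- c("sa_curve", "data.frame")
  out
}

#' Monotonic trend statistic of a sensitivity curve
#'
#' Spearman rank correlation between probe values and predictions; +1 for a
#' strictly increasing response, -1 for strictly decreasing, 0 by convention
#' for a constant curve.
#' @param curve a [sensitivity_sweep()] result (or any data.frame with
#'   `value` and `prediction` columns).
#' @return scalar in \[-1, 1\].
#' @export
trend_statistic <- function(curve) {
  if (nrow(curve) < 3L) stop("need at least 3 grid points", call. = FALSE)
  if (stats::sd(curve$prediction) == 0) return(0)
  unname(stats::cor(curve$value, curve$prediction, method = "spearman"))
}
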