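#' Train a univariate NIPALS partial least squares regression
#'
#' Single-response NIPALS with deflation of X per component; features and
#' response are centred/scaled on the training rows, and the regression
#' coefficients are reconstructed on the original scale for direct
#' prediction. For a univariate response each NIPALS component is a single
#' pass (the inner loop converges immediately); the convergence guard covers
#' the general iteration.
#'
#' @param X numeric matrix (n x p) with column names.
#' @param y numeric response, length n.
#' @param ncomp number of latent components A (1 <= A <= rank(X)).
#' @param tol convergence tolerance for the NIPALS inner iteration.
#' @return object of class `pls_model` with per-component weights, loadings,
#'   normalised scores, the original-scale coefficient vector and intercept.
#' @export
train_pls <- function(X, y, ncomp, tol = 1e-10) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), is.numeric(X))
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= ncomp) stop("need n > ncomp training rows", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  rk <- qr(scale(X, scale = FALSE))$rank
  if (ncomp > rk) stop("ncomp exceeds the rank of the centred X (", rk, ")", call. = FALSE)

  scaling <- .fit_scaling(X, drop_constant = TRUE)
  E <- .apply_scaling(scaling, X)
  ybar <- mean(y)
  f <- y - ybar

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tn <- matrix(0, n, ncomp)  # normalised scores (unit length)
  qvec <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)  # p x 1
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) stop("NIPALS breakdown: residual response orthogonal to X", call. = FALSE)
    w <- w / wn
    repeat {  # single-response NIPALS: converges in one pass
      tvec <- E %*% w
      w_new <- crossprod(E, f); w_new <- w_new / sqrt(sum(w_new^2))
      if (max(abs(w_new - w)) < tol) break
      w <- w_new
    }
    tvec <- as.numeric(E %*% w)
    tt <- sum(tvec^2)
    pvec <- as.numeric(crossprod(E, tvec)) / tt
    q <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - q * tvec
    W[, a] <- w; P[, a] <- pvec; qvec[a] <- q
    Tn[, a] <- tvec / sqrt(tt)
  }
  # coefficients in scaled space: B = W (P'W)^-1 q
  Bs <- W %*% solve(crossprod(P, W), qvec)
  coef <- as.numeric(Bs) / scaling$sd
  intercept <- ybar - sum(coef * scaling$mean)

  structure(list(
    ncomp = ncomp, weights = W, loadings = P, scores_norm = Tn, q = qvec,
    coefficients = stats::setNames(coef, colnames(X)),
    intercept = intercept, scaling = scaling,
    feature_names = colnames(X), n_train = n
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d components, %d features>\n", x$ncomp,
              length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#' @param model a `pls_model`.
#' @param X numeric matrix or [descriptor_table()] covering the model's
#'   features.
#' @return numeric predictions.
#' @export
predict_pls <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  if (inherits(X, "descriptor_table")) X <- X$values
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!all(model$feature_names %in% colnames(X))) {
    stop("prediction table lacks feature column(s): ",
         paste(setdiff(model$feature_names, colnames(X)), collapse = ", "),
         call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  as.numeric(X %*% model$coefficients + model$intercept)
}

#' Choose the PLS component count by cross-validation
#'
#' Exhaustively evaluates A in `1..min(p, n-1)` (capped by the rank of X) by
#' pooled CV RMSE; ties break toward the smaller A.
#' @param table a [descriptor_table()] with target.
#' @param plan a [make_folds()] plan.
#' @param max_comp optional upper bound on A.
#' @return list with `ncomp` (selected), `cv_rmse` (per candidate A).
#' @export
select_components <- function(table, plan, max_comp = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values); p <- ncol(table$values)
  amax <- min(p, n - 1L)
  if (!is.null(max_comp)) amax <- min(amax, as.integer(max_comp))
  cand <- seq_len(amax)
  scores <- rep(NA_real_, length(cand))
  for (a in cand) {
    scores[a] <- tryCatch(
      cross_validate(table, colnames(table$values), pls_spec(a), plan)$pooled_rmse,
      error = function(e) NA_real_  # A exceeding a fold's rank drops out
    )
  }
  ok <- which(is.finite(scores))
  if (length(ok) == 0L) stop("no admissible component count", call. = FALSE)
  best <- ok[which.min(scores[ok])]
  list(ncomp = cand[best], cv_rmse = stats::setNames(scores, cand))
}
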