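#' Kernel specification
#'
#' @param kind `"linear"`, `"polynomial"` or `"rbf"`.
#' @param degree polynomial degree (the protocol uses 2, giving the
#'   \eqn{[(x \cdot y) + 1]^2} form of the decision function).
#' @param gamma RBF width; default `NULL` resolves to 1/p at training time.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("polynomial", "linear", "rbf"),
                        degree = 2L, gamma = NULL) {
  kind <- match.arg(kind)
  degree <- as.integer(degree)
  if (kind == "polynomial" && degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive", call. = FALSE)
  structure(list(kind = kind, degree = degree, gamma = gamma),
            class = "kernel_spec")
}

#' Evaluate a kernel between two vectors
#'
#' Linear `x.y`; polynomial `(x.y + 1)^degree`; RBF `exp(-gamma ||x-y||^2)`.
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y)) stop("kernel arguments differ in dimension", call. = FALSE)
  switch(spec$kind,
    linear = sum(x * y),
    polynomial = (sum(x * y) + 1)^spec$degree,
    rbf = {
      gamma <- if (is.null(spec$gamma)) 1 / length(x) else spec$gamma
      exp(-gamma * sum((x - y)^2))
    }
  )
}

# Kernel matrix between row sets X (n1 x p) and Y (n2 x p).
.kernel_matrix <- function(spec, X, Y = X) {
  G <- tcrossprod(X, Y)
  switch(spec$kind,
    linear = G,
    polynomial = (G + 1)^spec$degree,
    rbf = {
      gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-gamma * d2)
    }
  )
}

# Per-feature z-score scaling learned on training rows only. Constant
# features are an error unless drop_constant, in which case they are scaled
# by sd 1 (centred only) -- they carry no information either way.
.fit_scaling <- function(X, drop_constant = FALSE) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) sd[] <- 1
  zero <- !is.finite(sd) | sd <= 0
  if (any(zero)) {
    if (!drop_constant) {
      stop("constant feature(s) in training data: ",
           paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
    }
    sd[zero] <- 1
  }
  list(mean = mu, sd = sd, features = colnames(X))
}

.apply_scaling <- function(scaling, X) {
  if (!identical(colnames(X), scaling$features)) {
    missing <- setdiff(scaling$features, colnames(X))
    if (length(missing) > 0L) {
      stop("prediction table lacks feature column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    X <- X[, scaling$features, drop = FALSE]
  }
  sweep(sweep(X, 2L, scaling$mean, "-"), 2L, scaling$sd, "/")
}

#' Train epsilon-insensitive support vector regression
#'
#' Standardises the features (z-score, training rows only), solves the
#' epsilon-SVR dual by sequential minimal optimization, and returns the
#' kernel expansion \eqn{f(x) = \sum_i \beta_i k(x_i, x) + b} with
#' \eqn{\beta_i = \alpha_i - \alpha_i^*}. Deterministic: no randomness is
#' used by the solver.
#'
#' @param X numeric matrix (n x p) with column names, raw descriptor scale.
#' @param y numeric target vector, length n.
#' @param kernel a [kernel_spec()].
#' @param C regularisation parameter (> 0).
#' @param epsilon insensitivity tube half-width (>= 0).
#' @param tolerance KKT violation tolerance for the SMO stopping rule.
#' @param scale standardise features before training (recommended; raw
#'   descriptor scales make kernel SVR degenerate).
#' @param max_iter cap on SMO pair updates.
#' @return object of class `svr_model` with support vectors, `beta`, bias
#'   `b`, the kernel spec, scaling parameters and training metadata.
#' @export
train_svr <- function(X, y, kernel = kernel_spec("polynomial"), C = 2.3,
                      epsilon = 0.11, tolerance = 1e-6, scale = TRUE,
                      max_iter = 2000000L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), is.numeric(X))
  if (nrow(X) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (length(y) != nrow(X)) stop("y length mismatch", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite training data", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))

  scaling <- if (scale) .fit_scaling(X, drop_constant = TRUE)
             else list(mean = stats::setNames(rep(0, ncol(X)), colnames(X)),
                       sd = stats::setNames(rep(1, ncol(X)), colnames(X)),
                       features = colnames(X))
  Z <- .apply_scaling(scaling, X)
  if (inherits(kernel, "kernel_spec") && kernel$kind == "rbf" && is.null(kernel$gamma)) {
    kernel$gamma <- 1 / ncol(Z)
  }
  K <- .kernel_matrix(kernel, Z)
  sol <- smo_solve(K, as.numeric(y), C, epsilon, tolerance, as.integer(max_iter))

  beta <- sol$beta
  sv <- which(abs(beta) > 1e-12)
  fitted <- as.numeric(K %*% beta + sol$b)
  structure(list(
    kernel = kernel, C = C, epsilon = epsilon, tolerance = tolerance,
    scaling = scaling,
    support_vectors = Z[sv, , drop = FALSE],
    beta = beta[sv],
    alpha = sol$alpha, alpha_star = sol$alpha_star,
    b = sol$b,
    dual_objective = sol$objective,
    iterations = sol$iterations,
    fitted = fitted,
    n_train = nrow(X),
    feature_names = colnames(X)
  ), class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model: %s kernel, C = %g, epsilon = %g, %d support vectors of %d>\n",
              x$kernel$kind, x$C, x$epsilon, nrow(x$support_vectors), x$n_train))
  invisible(x)
}

#' Predict from a fitted SVR model
#'
#' @param model an `svr_model`.
#' @param X numeric matrix or [descriptor_table()]; columns must cover the
#'   model's feature names.
#' @return numeric vector of predicted log(IGC50^-1) values.
#' @export
predict_svr <- function(model, X) {
  stopifnot(inherits(model, "svr_model"))
  if (inherits(X, "descriptor_table")) X <- X$values
  if (is.data.frame(X)) X <- as.matrix(X)
  Z <- .apply_scaling(model$scaling, X)
  if (nrow(model$support_vectors) == 0L) return(rep(model$b, nrow(Z)))
  Kx <- .kernel_matrix(model$kernel, Z, model$support_vectors)
  as.numeric(Kx %*% model$beta + model$b)
}

#' Serialise a model to a versioned JSON document
#'
#' Numbers are written with full round-trip precision; a checksum over the
#' payload guards against truncation.
#' @param model an `svr_model` or `pls_model`.
#' @param path output path; `NULL` returns the JSON string.
#' @return path (or JSON string), invisibly.
#' @export
serialize_model <- function(model, path = NULL) {
  method <- if (inherits(model, "svr_model")) "svr"
            else if (inherits(model, "pls_model")) "pls"
            else stop("unsupported model class", call. = FALSE)
  payload <- .model_payload(model, method)
  body <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
  doc <- jsonlite::toJSON(list(format = "qsartox-model", version = 1L,
                               checksum = .fnv1a(body),
                               payload = jsonlite::fromJSON(body, simplifyVector = TRUE)),
                          auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(as.character(doc))
  writeLines(doc, path)
  invisible(path)
}

.model_payload <- function(model, method) {
  m <- unclass(model)
  m$fitted <- NULL  # recomputable; keep files small
  if (!is.null(m$kernel)) m$kernel <- unclass(m$kernel)
  list(method = method, model = m)
}

#' Load a serialised model
#' @param path JSON file path (or a JSON string).
#' @return the model object (`svr_model` or `pls_model`).
#' @export
load_model <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else paste(path, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) stop("model load error: ", conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "qsartox-model")) stop("model load error: not a qsartox model file", call. = FALSE)
  if (!identical(as.integer(doc$version), 1L)) stop("model load error: unsupported version", call. = FALSE)
  body <- jsonlite::toJSON(doc$payload, auto_unbox = TRUE, digits = I(17))
  if (!identical(.fnv1a(body), doc$checksum)) {
    stop("model load error: checksum mismatch (truncated or edited file)", call. = FALSE)
  }
  method <- doc$payload$method
  m <- doc$payload$model
  m$scaling$mean <- stats::setNames(as.numeric(m$scaling$mean), m$scaling$features)
  m$scaling$sd <- stats::setNames(as.numeric(m$scaling$sd), m$scaling$features)
  if (method == "svr") {
    m$kernel <- structure(list(kind = m$kernel$kind, degree = as.integer(m$kernel$degree),
                               gamma = m$kernel$gamma), class = "kernel_spec")
    sv <- m$support_vectors
    if (is.null(sv) || length(sv) == 0L) {
      sv <- matrix(numeric(0), 0L, length(m$scaling$features),
                   dimnames = list(NULL, m$scaling$features))
    } else {
      sv <- matrix(as.numeric(as.matrix(sv)), ncol = length(m$scaling$features),
                   dimnames = list(NULL, m$scaling$features))
    }
    m$support_vectors <- sv
    m$beta <- as.numeric(m$beta)
    fit <- structure(m, class = "svr_model")
    fit$fitted <- NULL
    return(fit)
  }
  if (method == "pls") {
    for (f in c("weights", "loadings", "scores_norm")) {
      m[[f]] <- matrix(as.numeric(as.matrix(m[[f]])), ncol = m$ncomp)
    }
    m$coefficients <- stats::setNames(as.numeric(m$coefficients), m$scaling$features)
    return(structure(m, class = "pls_model"))
  }
  stop("model load error: unknown method tag ", sQuote(method), call. = FALSE)
}

# FNV-1a 32-bit hash of a string, as hex; pure-R, used to checksum model files.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 0x811c9dc5
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # multiply by 16777619 mod 2^32 using double-safe split arithmetic
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
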