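#' SVR model specification for cross-validation and pipelines
#'
#' A lightweight recipe consumed by [train_model()] / [cross_validate()].
#' @param kernel a [kernel_spec()].
#' @param C regularisation parameter.
#' @param epsilon tube half-width.
#' @param tolerance SMO stopping tolerance.
#' @return object of class `model_spec`.
#' @export
svr_spec <- function(kernel = kernel_spec("polynomial"), C = 2.3,
                     epsilon = 0.11, tolerance = 1e-4) {
  stopifnot(inherits(kernel, "kernel_spec"))
  structure(list(method = "svr", kernel = kernel, C = C, epsilon = epsilon,
                 tolerance = tolerance), class = "model_spec")
}

#' PLS model specification
#' @param ncomp number of latent components.
#' @return object of class `model_spec`.
#' @export
pls_spec <- function(ncomp = 2L) {
  structure(list(method = "pls", ncomp = as.integer(ncomp)), class = "model_spec")
}

#' Train a model from a specification
#'
#' Dispatches to [train_svr()] or [train_pls()] on a [descriptor_table()]
#' carrying a target.
#' @param table a [descriptor_table()] with target.
#' @param spec a [svr_spec()] or [pls_spec()].
#' @return an `svr_model` or `pls_model`.
#' @export
train_model <- function(table, spec) {
  stopifnot(inherits(table, "descriptor_table"), inherits(spec, "model_spec"))
  if (is.null(table$target)) stop("training requires a target column", call. = FALSE)
  if (spec$method == "svr") {
    train_svr(table$values, table$target, kernel = spec$kernel, C = spec$C,
              epsilon = spec$epsilon, tolerance = spec$tolerance)
  } else {
    train_pls(table$values, table$target, ncomp = spec$ncomp)
  }
}

#' Predict from a fitted model
#' @param model an `svr_model` or `pls_model`.
#' @param newdata a [descriptor_table()] or numeric matrix.
#' @return numeric predictions.
#' @export
predict_model <- function(model, newdata) {
  if (inherits(model, "svr_model")) predict_svr(model, newdata)
  else if (inherits(model, "pls_model")) predict_pls(model, newdata)
  else stop("unsupported model class", call. = FALSE)
}
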