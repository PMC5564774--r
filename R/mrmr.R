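#' Three-state discretisation at mean +/- k sigma
#'
#' Maps a continuous vector to states `low` / `mid` / `high` split at
#' `mean(x) - k*sigma` and `mean(x) + k*sigma`, with `sigma` the population
#' (1/n) standard deviation; the convention of the mRMR authors, invariant
#' under affine transformations of `x`. Boundary values fall into the lower
#' of the two adjacent states.
#' @param x finite numeric vector with positive standard deviation.
#' @param k positive multiplier (default 1).
#' @return factor with levels `low`, `mid`, `high`.
#' @export
discretize <- function(x, k = 1) {
  stopifnot(k > 0)
  if (!all(is.finite(x))) stop("non-finite values in x", call. = FALSE)
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0) stop("cannot discretise a constant vector", call. = FALSE)
  m <- mean(x)
  cut(x, breaks = c(-Inf, m - k * s, m + k * s, Inf),
      labels = c("low", "mid", "high"), right = TRUE)
}

#' Plug-in mutual information between two discrete vectors
#'
#' Estimated in nats from the joint contingency table;
#' `mutual_information(a, a)` equals the entropy of `a`.
#' @param a,b discrete vectors (factor, character or integer) of equal length.
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  tab <- table(a, b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj); pb <- colSums(pj)
  num <- pj
  denom <- outer(pa, pb)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / denom[nz]))
}

#' mRMR configuration
#' @param keep number of features to rank (passed on to the GA stage).
#' @param criterion `"MID"` (relevance minus mean redundancy) or `"MIQ"`
#'   (relevance over mean redundancy).
#' @param k discretisation multiplier for [discretize()].
#' @return object of class `mrmr_config`.
#' @export
mrmr_config <- function(keep = 30L, criterion = c("MID", "MIQ"), k = 1) {
  criterion <- match.arg(criterion)
  keep <- as.integer(keep)
  if (keep < 1L) stop("keep must be >= 1", call. = FALSE)
  stopifnot(k > 0)
  structure(list(keep = keep, criterion = criterion, k = k), class = "mrmr_config")
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Descriptors and target are discretised to three states, then features are
#' selected greedily: the first maximises mutual information with the
#' target; each later pick maximises relevance minus (MID) or divided by
#' (MIQ) its mean mutual information with the already-selected set. Ties
#' break toward the earlier column. Deterministic.
#'
#' @param table a [descriptor_table()] with target and p >= 2 descriptors.
#' @param config an [mrmr_config()].
#' @return object of class `selection_result` with `stage = "mrmr"`,
#'   ordered `features`, their greedy `scores` and the relevance vector.
#' @export
mrmr_rank <- function(table, config = mrmr_config()) {
  stopifnot(inherits(table, "descriptor_table"), inherits(config, "mrmr_config"))
  if (is.null(table$target)) stop("mRMR requires a target", call. = FALSE)
  p <- ncol(table$values)
  if (p < 2L) stop("mRMR needs at least 2 descriptors", call. = FALSE)
  keep <- min(config$keep, p)

  disc <- vector("list", p)
  usable <- logical(p)
  for (j in seq_len(p)) {
    d <- tryCatch(discretize(table$values[, j], config$k), error = identity)
    if (!inherits(d, "error")) { disc[[j]] <- d; usable[j] <- TRUE }
  }
  if (!any(usable)) stop("no discretisable descriptors (all constant?)", call. = FALSE)
  ty <- discretize(table$target, config$k)

  relevance <- rep(-Inf, p)
  relevance[usable] <- vapply(which(usable), function(j) {
    mutual_information(disc[[j]], ty)
  }, 0)

  # pairwise redundancy computed lazily
  red <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(red[i, j])) {
      v <- mutual_information(disc[[i]], disc[[j]])
      red[i, j] <<- v; red[j, i] <<- v
    }
    red[i, j]
  }

  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(keep)) {
    cand <- setdiff(which(usable), selected)
    if (length(cand) == 0L) break
    sc <- vapply(cand, function(j) {
      if (length(selected) == 0L) return(relevance[j])
      rbar <- mean(vapply(selected, function(s) pair_mi(j, s), 0))
      if (config$criterion == "MID") relevance[j] - rbar
      else relevance[j] / max(rbar, .Machine$double.eps)
    }, 0)
    pick <- cand[which.max(sc)]  # which.max takes the first maximum: earlier column wins ties
    selected <- c(selected, pick)
    scores <- c(scores, max(sc))
  }
  structure(list(stage = "mrmr",
                 features = colnames(table$values)[selected],
                 scores = scores,
                 relevance = stats::setNames(relevance, colnames(table$values)),
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result [%s]: %d features%s>\n", x$stage,
              length(x$features),
              if (!is.null(x$final_fitness)) sprintf(", fitness %.4f", x$final_fitness) else ""))
  cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
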