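# Brute-force dense QP oracle for the epsilon-SVR dual, built on kernlab's
# generic interior-point solver (fully independent of the package's SMO).
# Variables a = (alpha, alpha*) in R^{2n}; the objective is evaluated with
# the ORIGINAL (un-jittered) kernel so the tiny diagonal jitter used for
# factorisation stability does not bias the comparison.
qp_svr_oracle <- function(K, y, C, eps) {
  n <- length(y)
  s <- c(rep(1, n), rep(-1, n))
  H <- outer(s, s) * rbind(cbind(K, K), cbind(K, K))
  pvec <- eps - s * c(y, y)
  res <- NULL
  for (cfg in list(c(8, 1e-8), c(7, 1e-8), c(7, 1e-6), c(6, 1e-6))) {
    res <- tryCatch(
      kernlab::ipop(c = matrix(pvec), H = H + diag(cfg[2], 2 * n),
                    A = matrix(s, 1), b = 0, l = matrix(0, 2 * n),
                    u = matrix(C, 2 * n), r = 0, sigf = cfg[1], maxiter = 300),
      error = identity)
    if (!inherits(res, "error") && kernlab::how(res) == "converged") break
  }
  if (inherits(res, "error")) stop("QP oracle failed to converge")
  a <- kernlab::primal(res)
  beta <- a[1:n] - a[(n + 1):(2 * n)]
  obj <- 0.5 * as.numeric(t(beta) %*% K %*% beta) - sum(y * beta) + eps * sum(abs(beta))
  list(beta = beta, objective = obj)
}

# Dual objective of an svr_model in the beta formulation (equals the
# 2n-variable objective at any point satisfying alpha * alpha_star = 0).
svr_dual_objective <- function(model, K, y) {
  beta <- model$alpha - model$alpha_star
  0.5 * as.numeric(t(beta) %*% K %*% beta) - sum(y * beta) +
    model$epsilon * sum(abs(beta))
}

random_svr_problem <- function(r, kinds = c("linear", "polynomial", "rbf")) {
  n <- sample(4:10, 1)
  p <- sample(1:3, 1)
  kk <- kinds[(r %% length(kinds)) + 1]
  list(X = matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))),
       y = stats::rnorm(n),
       kernel = kernel_spec(kk, degree = 2, gamma = if (kk == "rbf") 0.5 else NULL),
       C = stats::runif(1, 0.5, 5), eps = stats::runif(1, 0.01, 0.2))
}
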