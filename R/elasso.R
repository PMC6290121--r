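#' Penalty path for one nodewise lasso regression
#'
#' Descending, log-spaced sequence of L1 penalties for the logistic lasso of
#' item `j` on the remaining items. The first value is the smallest penalty at
#' which every slope is zero at the null fit,
#' `lambda_max = max_k | sum_i x_ik (y_i - mean(y)) | / n`,
#' and the last is `ratio * lambda_max`.
#'
#' @param X binary `n x p` matrix (or [symptom_matrix()]).
#' @param j response column index.
#' @param n_lambda path length.
#' @param ratio `lambda_min / lambda_max`.
#' @return Numeric vector of `n_lambda` strictly decreasing penalties, or a
#'   zero-length vector with attribute `constant_response = TRUE` when column
#'   `j` has no variance (the node gets no neighbors).
#' @export
lambda_path <- function(X, j, n_lambda = 100, ratio = 0.01) {
  X <- values_of(X)
  y <- X[, j]
  if (length(unique(y)) < 2L)
    return(structure(numeric(0), constant_response = TRUE))
  n <- nrow(X)
  lam_max <- max(abs(crossprod(X[, -j, drop = FALSE], y - mean(y)))) / n
  if (lam_max <= 0) lam_max <- 1e-4  # all predictors constant: token path
  exp(seq(log(lam_max), log(ratio * lam_max), length.out = n_lambda))
}

values_of <- function(X) {
  if (inherits(X, "symptom_matrix")) X$values else as.matrix(X)
}

#' Fit one L1-penalized logistic regression
#'
#' Minimizes `-loglik(beta)/n + lambda * sum(|slopes|)` (intercept
#' unpenalized) by cyclic coordinate descent with a quadratic majorization of
#' the logistic curvature; convergence when the largest coefficient change in
#' a sweep falls below `tol`. Coefficients are clamped to `|beta| <= cap` to
#' guard against perfect separation at small penalties (a warning is issued
#' when the clamp is active).
#'
#' @param y binary response vector.
#' @param X binary predictor matrix.
#' @param lambda single penalty, or a decreasing vector (a path, fitted with
#'   warm starts).
#' @param tol convergence tolerance.
#' @param max_iter sweep cap per penalty value.
#' @param cap coefficient clamp.
#' @return For a single `lambda`: list with `intercept`, `slopes`, `loglik`,
#'   `df`. For a path: list of matrices/vectors across the path
#'   (`intercepts`, `slopes` `q x L`, `loglik`, `df`, `cap_hit`).
#' @export
fit_penalized_logistic <- function(y, X, lambda, tol = 1e-6, max_iter = 1e4,
                                   cap = 20) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  fit <- cd_logistic_path(y, X, as.numeric(lambda), tol, as.integer(max_iter), cap)
  if (any(fit$cap_hit))
    warning("coefficient clamp |beta| <= ", cap,
            " active; data may be separable at small penalties")
  if (length(lambda) == 1L)
    list(intercept = fit$beta[1, 1], slopes = fit$beta[-1, 1],
         loglik = fit$loglik[1], df = fit$df[1])
  else
    list(intercepts = fit$beta[1, ], slopes = fit$beta[-1, , drop = FALSE],
         loglik = fit$loglik, df = fit$df, cap_hit = fit$cap_hit)
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + k log(n) + 2 gamma k log(p_predictors)`; lower is
#' better. `gamma = 0` reduces to the ordinary BIC.
#'
#' @param loglik attained log-likelihood.
#' @param k number of estimated (nonzero) slopes.
#' @param n sample size.
#' @param p_predictors number of candidate predictors.
#' @param gamma EBIC weight in `[0, 1]`.
#' @return Numeric score.
#' @export
ebic <- function(loglik, k, n, p_predictors, gamma = 0.25) {
  stopifnot(k >= 0, n >= 1)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_predictors)
}

#' Estimate a regularized Ising network (eLasso)
#'
#' Each item is regressed on all other items with an L1 penalty; the penalty
#' is chosen per node by minimizing the extended BIC along a descending path.
#' The two directed coefficients per pair are combined into one undirected
#' edge: under the `AND` rule the edge is the mean of the two slopes when
#' both are nonzero and 0 otherwise; under the `OR` rule the mean (counting a
#' zero slope as zero) when at least one is nonzero. Estimated edges can be
#' read as regularized conditional associations, analogous to partial
#' correlations. Constant columns yield isolated nodes with a warning.
#'
#' @param X [symptom_matrix()] or binary `n x p` matrix with column names.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule edge combination rule, `"AND"` (default) or `"OR"`.
#' @param n_lambda,lambda_ratio path controls (see [lambda_path()]).
#' @param warn emit warnings for constant columns / separation (set `FALSE`
#'   inside resampling loops).
#' @return Object of class `estimated_network`: list with `omega_hat`
#'   (`p x p` symmetric), `tau_hat`, `nodewise_coefs` (asymmetric `p x p`,
#'   row = response node), `selected_lambda`, `ebic_gamma`, `rule`,
#'   `node_labels`, `domain_tags`, `n`.
#' @export
estimate_network <- function(X, gamma = 0.25, rule = c("AND", "OR"),
                             n_lambda = 100, lambda_ratio = 0.01, warn = TRUE) {
  rule <- match.arg(rule)
  tags <- if (inherits(X, "symptom_matrix")) X$domain_tags else NULL
  X <- values_of(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least 2 items")
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  storage.mode(X) <- "integer"
  fit <- ising_elasso(X, gamma, as.integer(n_lambda), lambda_ratio,
                      1e-6, 10000L, 20)
  nodewise <- fit$nodewise
  dimnames(nodewise) <- list(labels, labels)
  constant <- fit$constant
  tau_hat <- fit$tau
  tau_hat[constant] <- pmax(pmin(qlogis(colMeans(X)[constant]), 20), -20)
  names(tau_hat) <- labels
  sel_lambda <- fit$selected_lambda; names(sel_lambda) <- labels
  if (warn && any(constant))
    warning("constant column(s) isolated: ", paste(labels[constant], collapse = ", "))
  if (warn && any(fit$cap_hit))
    warning("coefficient clamp |beta| <= 20 active for node(s): ",
            paste(labels[fit$cap_hit], collapse = ", "),
            "; data may be separable")
  omega_hat <- matrix(0, p, p, dimnames = list(labels, labels))
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    a <- nodewise[j, k]; b <- nodewise[k, j]
    keep <- if (rule == "AND") a != 0 && b != 0 else a != 0 || b != 0
    if (keep) omega_hat[j, k] <- omega_hat[k, j] <- (a + b) / 2
  }
  if (any(constant)) omega_hat[constant, ] <- omega_hat[, constant] <- 0
  structure(list(omega_hat = omega_hat, tau_hat = tau_hat,
                 nodewise_coefs = nodewise, selected_lambda = sel_lambda,
                 ebic_gamma = gamma, rule = rule, node_labels = labels,
                 domain_tags = tags, n = n),
            class = "estimated_network")
}

#' @export
print.estimated_network <- function(x, ...) {
  p <- length(x$node_labels)
  possible <- p * (p - 1) / 2
  nz <- sum(x$omega_hat[upper.tri(x$omega_hat)] != 0)
  cat(sprintf("<estimated_network> p = %d, n = %d, rule = %s, gamma = %.2f\n",
              p, x$n, x$rule, x$ebic_gamma))
  cat(sprintf("edges: %d of %d possible (%.0f%%); global strength %.3f\n",
              nz, possible, 100 * nz / possible,
              sum(abs(x$omega_hat[upper.tri(x$omega_hat)]))))
  invisible(x)
}
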