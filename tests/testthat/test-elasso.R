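test_that("lambda path starts at the all-zero penalty and is well formed", {
  set.seed(2)
  X <- matrix(rbinom(400, 1, 0.3), 100, 4)
  path <- lambda_path(X, 1, n_lambda = 100, ratio = 0.01)
  expect_length(path, 100)
  expect_true(all(diff(path) < 0))
  expect_equal(path[100], 0.01 * path[1], tolerance = 1e-12)
  # at the first path value every slope is zero
  fit <- fit_penalized_logistic(X[, 1], X[, -1], path[1])
  expect_equal(unname(fit$slopes), rep(0, 3))
  # hand-computed lambda_max on a 4-row toy with a single predictor (y = x)
  Xt <- cbind(y = c(0, 0, 1, 1), x = c(0, 0, 1, 1))
  expect_equal(lambda_path(Xt, 1, n_lambda = 2)[1],
               abs(sum(Xt[, 2] * (Xt[, 1] - 0.5))) / 4)
  # constant response: empty path with flag
  Xc <- cbind(a = rep(1L, 10), b = rbinom(10, 1, 0.5))
  expect_length(lambda_path(Xc, 1), 0)
  expect_true(attr(lambda_path(Xc, 1), "constant_response"))
})

test_that("penalized fits match closed forms and an unpenalized oracle", {
  set.seed(11)
  n <- 2000
  x1 <- rbinom(n, 1, 0.4); x2 <- rbinom(n, 1, 0.3)
  eta <- -0.5 + 1.2 * x1 - 0.8 * x2
  y <- rbinom(n, 1, plogis(eta))
  X <- cbind(x1, x2)
  # large penalty: null model, intercept = logit of the mean
  f0 <- fit_penalized_logistic(y, X, 10)
  expect_equal(unname(f0$slopes), c(0, 0))
  expect_equal(f0$intercept, qlogis(mean(y)), tolerance = 1e-6)
  # tiny penalty: slopes within 2 SE of the glm oracle
  fit_glm <- glm(y ~ X, family = binomial())
  f1 <- fit_penalized_logistic(y, X, 1e-8)
  se <- summary(fit_glm)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(f1$slopes - coef(fit_glm)[-1]) < 2 * se))
  # duplicated predictors: the pair's total weight matches the single fit
  # (the split between exact duplicates is not identified under the lasso)
  Xd <- cbind(x1, x1)
  fd <- fit_penalized_logistic(y, Xd, 0.02)
  fs <- fit_penalized_logistic(y, cbind(x1), 0.02)  # same effective penalty
  expect_equal(sum(fd$slopes), fs$slopes[1], tolerance = 1e-3)
})

test_that("penalized path agrees with the glmnet reference implementation", {
  skip_if_not_installed("glmnet")
  pa <- small_planted()
  X <- sample_ising_gibbs(pa, 400, burnin = 300, thin = 3, seed = 13)$values
  y <- X[, 2]; Z <- X[, -2]
  lams <- c(0.1, 0.05, 0.02, 0.005)
  mine <- fit_penalized_logistic(y, Z, lams)
  ref <- glmnet::glmnet(Z, y, family = "binomial", lambda = lams,
                        standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(rbind(mine$intercepts, mine$slopes) - as.matrix(coef(ref)))),
            1e-4)
})

test_that("EBIC reduces to BIC and matches direct arithmetic", {
  expect_equal(ebic(-50, 2, 100, 9, gamma = 0), 100 + 2 * log(100))
  expect_equal(ebic(-50, 0, 100, 9, gamma = 0.5), 100)
  expect_equal(ebic(-100, 3, 1000, 17, gamma = 0.25),
               200 + 3 * log(1000) + 1.5 * log(17))
})

test_that("edge combination rules follow the AND/OR definitions", {
  # build data where the rule outcome is forced via the nodewise matrix
  pa <- small_planted(p1 = 3, p2 = 2, density_within = 1)
  X <- sample_ising_gibbs(pa, 600, burnin = 300, thin = 2, seed = 8)
  net_and <- estimate_network(X, rule = "AND", warn = FALSE)
  net_or <- estimate_network(X, rule = "OR", warn = FALSE)
  nw <- net_and$nodewise_coefs
  expect_identical(nw, net_or$nodewise_coefs)  # rules differ post hoc only
  for (j in 1:4) for (k in (j + 1):5) {
    a <- nw[j, k]; b <- nw[k, j]
    expect_equal(net_and$omega_hat[j, k],
                 if (a != 0 && b != 0) (a + b) / 2 else 0)
    expect_equal(net_or$omega_hat[j, k],
                 if (a != 0 || b != 0) (a + b) / 2 else 0)
  }
  expect_true(isSymmetric(net_and$omega_hat))
  expect_equal(unname(diag(net_and$omega_hat)), rep(0, 5))
})

test_that("constant columns isolate their node with a warning", {
  set.seed(4)
  X <- cbind(matrix(rbinom(300, 1, 0.4), 100, 3), zero = 0L)
  colnames(X) <- c("a", "b", "c", "zero")
  expect_warning(net <- estimate_network(X), "constant column")
  expect_true(all(net$omega_hat["zero", ] == 0))
  expect_true(all(net$omega_hat[, "zero"] == 0))
})

test_that("estimation is invariant to row permutation, equivariant to columns", {
  pa <- small_planted()
  X <- sample_ising_gibbs(pa, 500, burnin = 300, thin = 2, seed = 23)$values
  net <- estimate_network(X, warn = FALSE)
  set.seed(1)
  net_rows <- estimate_network(X[sample(nrow(X)), ], warn = FALSE)
  expect_equal(net$omega_hat, net_rows$omega_hat, tolerance = 1e-4)
  perm <- sample(ncol(X))
  net_cols <- estimate_network(X[, perm], warn = FALSE)
  expect_equal(net_cols$omega_hat, net$omega_hat[perm, perm], tolerance = 1e-4)
})

test_that("larger EBIC gamma never yields more edges", {
  pa <- small_planted()
  X <- sample_ising_gibbs(pa, 400, burnin = 300, thin = 2, seed = 77)
  n_edges <- vapply(c(0, 0.25, 0.5, 1), function(g) {
    om <- estimate_network(X, gamma = g, warn = FALSE)$omega_hat
    sum(om[upper.tri(om)] != 0)
  }, numeric(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("selected support matches an exhaustive EBIC oracle at p = 3", {
  # strong, clearly identified 3-node chain; oracle enumerates all support
  # sets per node and scores exact-ML EBIC
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 1.6
  om[2, 3] <- om[3, 2] <- 1.4
  pa <- calibrate_thresholds(ising_params(rep(0, 3), om), c(0.3, 0.4, 0.3),
                             tol = 1e-4)
  X <- sample_ising_gibbs(pa, 1500, burnin = 300, thin = 2, seed = 19)$values
  net <- estimate_network(X, warn = FALSE)
  n <- nrow(X)
  for (j in 1:3) {
    others <- setdiff(1:3, j)
    supports <- list(integer(0), others[1], others[2], others)
    scores <- vapply(supports, function(s) {
      fit <- if (length(s)) glm(X[, j] ~ X[, s, drop = FALSE], family = binomial())
             else glm(X[, j] ~ 1, family = binomial())
      ebic(as.numeric(logLik(fit)), length(s), n, 2, gamma = 0.25)
    }, numeric(1))
    oracle_support <- supports[[which.min(scores)]]
    got <- which(net$nodewise_coefs[j, ] != 0)
    expect_identical(unname(got), as.integer(oracle_support))
  }
})
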