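test_that("exact enumeration reproduces closed-form Ising probabilities", {
  # single node, zero threshold: symmetric
  p1 <- ising_params(0, matrix(0, 1, 1))
  expect_equal(ising_marginals(p1), c(V1 = 0.5))
  # two nodes, tau = 0, omega12 = log 2: Z = 1+1+1+2, P(1,1) = 2/5
  p2 <- ising_params(c(0, 0), matrix(c(0, log(2), log(2), 0), 2))
  pmf <- enumerate_ising_pmf(p2)
  expect_equal(pmf$prob[pmf$states[, 1] == 1 & pmf$states[, 2] == 1], 0.4)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  # normalization for arbitrary parameters
  set.seed(7)
  om <- random_graph(6, density = 0.7, seed = 9)
  pa <- ising_params(rnorm(6), om)
  expect_equal(sum(enumerate_ising_pmf(pa)$prob), 1, tolerance = 1e-12)
  # enumeration guard
  big <- ising_params(rep(0, 15), matrix(0, 15, 15))
  expect_error(enumerate_ising_pmf(big), "p > 14")
})

test_that("Gibbs sampler matches exact enumeration in total variation", {
  om <- random_graph(5, density = 0.7, seed = 21)
  pa <- ising_params(seq(-1, 0.5, length.out = 5), om)
  X <- sample_ising_gibbs(pa, 2e4, burnin = 500, thin = 4, seed = 99)
  pmf <- enumerate_ising_pmf(pa)
  key <- pmf$states %*% 2^(0:4)
  emp <- tabulate(X$values %*% 2^(0:4) + 1, nbins = 32) / nrow(X$values)
  tv <- 0.5 * sum(abs(emp[key + 1] - pmf$prob))
  expect_lt(tv, 0.02)
})

test_that("Gibbs sampler is seed-reproducible and honors independence", {
  pa <- ising_params(rep(0, 4), matrix(0, 4, 4))
  X1 <- sample_ising_gibbs(pa, 500, seed = 5)
  X2 <- sample_ising_gibbs(pa, 500, seed = 5)
  expect_identical(X1$values, X2$values)
  # tau = 0, omega = 0: marginals 0.5 within 3 Monte-Carlo SEs
  X3 <- sample_ising_gibbs(pa, 4000, burnin = 100, thin = 2, seed = 6)
  se <- 0.5 / sqrt(4000)
  expect_true(all(abs(colMeans(X3$values) - 0.5) < 3 * se))
})

test_that("planted two-block support counts match the block combinatorics", {
  spec <- scenario_spec(p1 = 12, p2 = 6, density_within = 1, density_between = 0,
                        prevalence_targets = NULL, seed = 3,
                        wave_scales = 1, wave_labels = "w")
  tr <- planted_two_block(spec)
  expect_equal(sum(tr$omega[upper.tri(tr$omega)] != 0), choose(12, 2) + choose(6, 2))
  expect_equal(unname(diag(tr$omega)), rep(0, 18))
  # determinism: same seed, same support and values
  tr2 <- planted_two_block(spec)
  expect_identical(tr$omega, tr2$omega)
  # no block structure when weights and densities coincide
  spec2 <- scenario_spec(p1 = 4, p2 = 4, w_within = 0.5, w_between = 0.5,
                         density_within = 1, density_between = 1,
                         prevalence_targets = NULL, seed = 3,
                         wave_scales = 1, wave_labels = "w")
  tr3 <- planted_two_block(spec2)
  expect_true(all(tr3$omega[upper.tri(tr3$omega)] == 0.5))
  expect_error(scenario_spec(density_within = 0, density_between = 0,
                             prevalence_targets = NULL), "degenerate")
})

test_that("threshold calibration hits targets and never touches omega", {
  # independence: one-step closed form, logit of the target
  pa <- ising_params(c(0, 0), matrix(0, 2, 2))
  cal <- calibrate_thresholds(pa, c(0.23, 0.23), tol = 1e-10)
  expect_equal(unname(cal$tau), rep(qlogis(0.23), 2), tolerance = 1e-8)
  # fixed point: targets equal to current marginals leave params unchanged
  pb <- small_planted()
  m <- ising_marginals(pb)
  cal2 <- calibrate_thresholds(pb, m, tol = 1e-6)
  expect_equal(cal2$tau, pb$tau, tolerance = 1e-4)
  # planted 5-node model, spread targets, exact enumeration within tol
  om <- random_graph(5, density = 0.8, seed = 31)
  pc <- ising_params(rep(0, 5), om)
  targets <- seq(0.05, 0.4, length.out = 5)
  cal3 <- calibrate_thresholds(pc, targets, tol = 0.005)
  expect_true(all(abs(ising_marginals(cal3) - targets) < 0.005))
  expect_identical(cal3$omega, pc$omega)
})

test_that("developmental scenarios scale true connectivity as specified", {
  targ <- setNames(seq(0.15, 0.35, length.out = 6), paste0("it", 1:6))
  spec <- scenario_spec(p1 = 4, p2 = 2, density_within = 0.8,
                        density_between = 0.3, w_within = 0.8, w_between = 0.5,
                        prevalence_targets = targ,
                        wave_scales = c(1, 1.5), wave_labels = c("5", "14"),
                        seed = 17)
  sc <- developmental_scenario(spec, n = 150, burnin = 200, thin = 2)
  expect_s3_class(sc$panel, "wave_panel")
  expect_length(sc$truth, 2)
  s <- vapply(sc$truth, global_strength, numeric(1))
  expect_equal(unname(s[2] / s[1]), 1.5, tolerance = 1e-12)
  expect_identical(sc$panel$waves[[1]]$node_labels,
                   sc$panel$waves[[2]]$node_labels)
  # identical wave scales give identically distributed waves: same truth
  spec2 <- scenario_spec(p1 = 4, p2 = 2, density_within = 0.8,
                         density_between = 0.3, prevalence_targets = targ,
                         wave_scales = c(1, 1), wave_labels = c("a", "b"),
                         seed = 17)
  sc2 <- developmental_scenario(spec2, n = 50, burnin = 100, thin = 2)
  expect_equal(sc2$truth[[1]]$omega, sc2$truth[[2]]$omega)
  expect_equal(sc2$truth[[1]]$tau, sc2$truth[[2]]$tau, tolerance = 0.02)
})

test_that("scenario specs round-trip through JSON configs", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"p1": 4, "p2": 2, "w_within": 1.1, "density_within": 0.8,
               "prevalence_targets": [0.1,0.15,0.2,0.25,0.3,0.35],
               "wave_scales": [1, 1.4], "wave_labels": ["5","14"], "seed": 7}', f)
  spec <- scenario_from_json(f)
  expect_s3_class(spec, "scenario_spec")
  expect_equal(spec$p1, 4)
  expect_equal(spec$wave_scales, c(1, 1.4))
  expect_equal(spec$w_between, 0.6)  # default fills the gap
  writeLines('{"p1": 4, "p2": 2, "bogus": 1}', f)
  expect_error(scenario_from_json(f), "unknown scenario field")
})

test_that("benchmark prevalence table is as published", {
  expect_equal(dim(cbcl_prevalences), c(18, 7))
  expect_equal(cbcl_prevalences["worry", "5"], 0.23)
  expect_equal(cbcl_prevalences["depnd", "5"], 0.40)
  expect_equal(cbcl_prevalences["s-harm", "14"], 0.03)
  expect_true(all(cbcl_prevalences >= 0.01 & cbcl_prevalences <= 0.40))
})
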