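#' Ising model parameters
#'
#' The generative model for binary symptom vectors `x` in `{0,1}^p`:
#' `P(x)` proportional to `exp(sum_j tau_j x_j + sum_{j<k} omega_jk x_j x_k)`,
#' with node thresholds `tau` (log-odds scale) and a symmetric interaction
#' matrix `omega` with zero diagonal.
#'
#' @param tau numeric vector of `p` thresholds.
#' @param omega `p x p` symmetric numeric matrix, zero diagonal.
#' @param node_labels optional `p` labels; default `V1..Vp`.
#' @param domain_tags optional `p` domain tags carried for convenience.
#' @return Object of class `ising_params`.
#' @export
ising_params <- function(tau, omega, node_labels = NULL, domain_tags = NULL) {
  tau <- as.numeric(tau)
  omega <- as.matrix(omega)
  p <- length(tau)
  if (!all(dim(omega) == p)) stop("omega must be p x p with p = length(tau)")
  if (!all(is.finite(tau)) || !all(is.finite(omega)))
    stop("parameters must be finite")
  if (max(abs(omega - t(omega))) > 1e-12) stop("omega must be symmetric")
  if (any(diag(omega) != 0)) stop("omega must have zero diagonal")
  if (is.null(node_labels)) node_labels <- colnames(omega)
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(p))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != p || anyDuplicated(node_labels))
    stop("node_labels must be p unique strings")
  dimnames(omega) <- list(node_labels, node_labels)
  names(tau) <- node_labels
  structure(list(tau = tau, omega = omega, node_labels = node_labels,
                 domain_tags = domain_tags), class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  p <- length(x$tau)
  nz <- sum(x$omega[upper.tri(x$omega)] != 0)
  cat(sprintf("<ising_params> p = %d, %d nonzero edge(s), global strength %.3f\n",
              p, nz, sum(abs(x$omega[upper.tri(x$omega)]))))
  invisible(x)
}

#' Exact probability table of an Ising model
#'
#' Enumerates all `2^p` binary states and returns their exact probabilities.
#' Feasible for small `p` only; refuses beyond `p = 14` (16,384 states) —
#' use [sample_ising_gibbs()] there.
#'
#' @param params an [ising_params()].
#' @return A list with `states` (`2^p x p` 0/1 matrix, states in binary
#'   counting order) and `prob` (probabilities summing to one).
#' @export
enumerate_ising_pmf <- function(params) {
  p <- length(params$tau)
  if (p > 14L)
    stop("p > 14: exact enumeration over 2^p states refused; use sample_ising_gibbs()")
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- params$node_labels
  logw <- drop(states %*% params$tau) +
    0.5 * rowSums((states %*% params$omega) * states)
  logz <- max(logw) + log(sum(exp(logw - max(logw))))
  list(states = states, prob = exp(logw - logz))
}

#' Exact marginal P(x_j = 1) by enumeration
#' @inheritParams enumerate_ising_pmf
#' @return numeric vector of `p` marginal probabilities.
#' @export
ising_marginals <- function(params) {
  pmf <- enumerate_ising_pmf(params)
  drop(crossprod(pmf$states, pmf$prob))
}

#' Sample from an Ising model by Gibbs sampling
#'
#' Single-site Gibbs with systematic sweeps; the conditional update is
#' `P(x_j = 1 | x_-j) = plogis(tau_j + sum_k omega_jk x_k)`. Defaults
#' (1,000 burn-in sweeps, thinning 10) mix adequately for interaction
#' magnitudes up to about 2 at p = 18, verified against exact enumeration at
#' small p.
#'
#' @inheritParams enumerate_ising_pmf
#' @param n number of rows to draw.
#' @param burnin burn-in sweeps (>= 1).
#' @param thin sweeps between recorded states (>= 1).
#' @param seed integer seed; if supplied, `set.seed(seed)` is called so the
#'   draw is reproducible.
#' @param wave_label label attached to the resulting matrix.
#' @return A [symptom_matrix()].
#' @export
sample_ising_gibbs <- function(params, n, burnin = 1000, thin = 10,
                               seed = NULL, wave_label = "") {
  if (n < 1 || burnin < 1 || thin < 1) stop("n, burnin, thin must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- gibbs_ising(params$tau, params$omega, as.integer(n),
                   as.integer(burnin), as.integer(thin))
  colnames(x) <- params$node_labels
  tags <- if (is.null(params$domain_tags)) "other" else params$domain_tags
  symptom_matrix(x, node_labels = params$node_labels, domain_tags = tags,
                 subject_ids = as.character(seq_len(n)), wave_label = wave_label)
}

#' Specify a planted two-block simulation scenario
#'
#' Describes a ground-truth Ising model with two diagnostic blocks (e.g., 12
#' depression + 6 anxiety items), bridge edges between them, marginal
#' prevalence targets, and per-wave connectivity multipliers. Defaults emulate
#' an 18-item parent-report panel: block sizes 12 + 6, within-block edge
#' density 0.35 at weight 0.9, between-block density 0.15 at weight 0.6, and
#' prevalence targets taken from the age-5 column of [cbcl_prevalences]
#' (roughly 1%-40%).
#'
#' @param p1,p2 block sizes.
#' @param w_within,w_between edge-weight magnitudes.
#' @param density_within,density_between probabilities in `[0,1]` that a
#'   within-/between-block pair carries an edge.
#' @param prevalence_targets `p1+p2` marginal probabilities in `(0,1)`, or
#'   `NULL` to leave thresholds at the calibration default.
#' @param wave_scales positive multipliers applied to `omega`, one per wave.
#' @param wave_labels labels for the waves (default: ages 5-14 as measured in
#'   the emulated cohort).
#' @param seed integer seed driving all randomness in the scenario.
#' @return Object of class `scenario_spec` (a validated list).
#' @export
scenario_spec <- function(p1 = 12, p2 = 6, w_within = 0.9, w_between = 0.6,
                          density_within = 0.35, density_between = 0.15,
                          prevalence_targets = cbcl_prevalences[, 1],
                          wave_scales = c(1.00, 0.97, 1.08, 1.15, 1.22, 1.19, 1.35),
                          wave_labels = colnames(cbcl_prevalences),
                          seed = 1L) {
  if (p1 + p2 < 3) stop("need p1 + p2 >= 3")
  for (d in c(density_within, density_between))
    if (d < 0 || d > 1) stop("densities must lie in [0,1]")
  if (any(wave_scales <= 0)) stop("wave_scales must be positive")
  if (!is.null(prevalence_targets)) {
    if (length(prevalence_targets) != p1 + p2)
      stop("prevalence_targets must have length p1 + p2")
    if (any(prevalence_targets <= 0 | prevalence_targets >= 1))
      stop("prevalence_targets must lie strictly in (0,1)")
  }
  if (density_within == 0 && density_between == 0 && is.null(prevalence_targets))
    stop("degenerate scenario: no edges and no prevalence targets")
  if (length(wave_labels) != length(wave_scales))
    wave_labels <- paste0("wave", seq_along(wave_scales))
  structure(list(p1 = p1, p2 = p2, w_within = w_within, w_between = w_between,
                 density_within = density_within, density_between = density_between,
                 prevalence_targets = prevalence_targets,
                 wave_scales = wave_scales, wave_labels = as.character(wave_labels),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Read a scenario specification from a JSON config file
#'
#' The file holds any subset of [scenario_spec()]'s arguments as top-level
#' keys; unspecified fields take the documented defaults.
#'
#' @param path JSON file path.
#' @return A [scenario_spec()].
#' @export
scenario_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  known <- names(formals(scenario_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  do.call(scenario_spec, cfg)
}

#' Ground-truth Ising model with two planted blocks
#'
#' Draws the edge support at the spec's densities and sets edge magnitudes to
#' `w_within` / `w_between`. Node labels are `D1..Dp1` (tagged depression) and
#' `A1..Ap2` (tagged anxiety) unless the spec carries prevalence targets named
#' after [cbcl_prevalences] items, in which case those names are used.
#' Thresholds are initialized at the mean-field solution
#' `qlogis(target) - omega %*% target` (exact at independence, a good
#' starting point otherwise) or 0; refine with [calibrate_thresholds()].
#'
#' @param spec a [scenario_spec()].
#' @return An [ising_params()] with `domain_tags` set.
#' @export
planted_two_block <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  p <- spec$p1 + spec$p2
  block <- rep(1:2, c(spec$p1, spec$p2))
  labels <- c(paste0("D", seq_len(spec$p1)), paste0("A", seq_len(spec$p2)))
  if (!is.null(spec$prevalence_targets) &&
      !is.null(names(spec$prevalence_targets)) &&
      !anyDuplicated(names(spec$prevalence_targets)))
    labels <- names(spec$prevalence_targets)
  omega <- matrix(0, p, p)
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    within <- block[j] == block[k]
    dens <- if (within) spec$density_within else spec$density_between
    w <- if (within) spec$w_within else spec$w_between
    if (runif(1) < dens) omega[j, k] <- omega[k, j] <- w
  }
  tau <- if (is.null(spec$prevalence_targets)) rep(0, p)
         else qlogis(spec$prevalence_targets) -
           drop(omega %*% spec$prevalence_targets)
  ising_params(tau, omega, node_labels = labels,
               domain_tags = c(rep("depression", spec$p1), rep("anxiety", spec$p2)))
}

#' Calibrate Ising thresholds to target marginal prevalences
#'
#' Adjusts `tau` (never `omega`) until model marginals `P(x_j = 1)` match the
#' targets, by the fixed-point update
#' `tau_j <- tau_j + log( target_j / m_j * (1 - m_j) / (1 - target_j) )`
#' where `m` are current model marginals. Marginals are exact (enumeration)
#' for `p <= 14`; beyond that they are Monte-Carlo estimates from
#' [sample_ising_gibbs()] with standard error at most `0.5 / sqrt(n_mc)`, and
#' the convergence tolerance is floored at twice that bound.
#'
#' @inheritParams enumerate_ising_pmf
#' @param targets `p` probabilities in `(0,1)`.
#' @param tol convergence tolerance on `max |marginal - target|`.
#' @param max_iter maximum fixed-point iterations.
#' @param n_mc Monte-Carlo sample size per iteration when `p > 14`.
#' @param damping step factor in (0, 1] on the threshold update; values below
#'   1 stabilize calibration for densely coupled models whose marginals
#'   respond steeply to `tau`.
#' @param seed seed for the Monte-Carlo path.
#' @return An [ising_params()] with updated `tau` and attributes
#'   `achieved` (final marginals) and `converged`.
#' @export
calibrate_thresholds <- function(params, targets, tol = 1e-3, max_iter = 200,
                                 n_mc = 20000, damping = 0.7, seed = NULL) {
  p <- length(params$tau)
  targets <- as.numeric(targets)
  if (length(targets) != p) stop("targets must have length p")
  if (any(targets <= 0 | targets >= 1)) stop("targets must lie strictly in (0,1)")
  exact <- p <= 14L
  if (!exact) {
    tol <- max(tol, 2 * 0.5 / sqrt(n_mc))
    if (!is.null(seed)) set.seed(seed)
  }
  marginals <- function(pr) {
    if (exact) ising_marginals(pr)
    else colMeans(gibbs_ising(pr$tau, pr$omega, as.integer(n_mc), 200L, 2L))
  }
  cur <- params
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- marginals(cur)
    if (max(abs(m - targets)) < tol) { converged <- TRUE; break }
    m <- pmin(pmax(m, 1 / (2 * n_mc)), 1 - 1 / (2 * n_mc))
    cur$tau <- cur$tau + damping * log(targets / m * (1 - m) / (1 - targets))
  }
  if (!converged) {
    m <- marginals(cur)
    warning(sprintf("calibration did not converge in %d iterations; max |gap| = %.4g",
                    max_iter, max(abs(m - targets))))
  }
  structure(cur, achieved = m, converged = converged)
}

#' Simulate a multi-wave developmental scenario
#'
#' Builds the base two-block model from `spec`, then for each wave scales
#' `omega` by `wave_scales[w]`, recalibrates thresholds to the wave's
#' prevalence targets, and draws `n` subjects by Gibbs sampling. The true
#' global strength `sum_{i<j} |omega_ij|` is exactly proportional to the wave
#' scale, giving a known connectivity gradient.
#'
#' @param spec a [scenario_spec()].
#' @param n subjects per wave.
#' @param prevalence_by_wave optional `p x n_waves` matrix of per-wave
#'   prevalence targets (e.g., [cbcl_prevalences]); default recycles
#'   `spec$prevalence_targets` across waves.
#' @param burnin,thin Gibbs controls (see [sample_ising_gibbs()]).
#' @return A list with `panel` (a [wave_panel()]) and `truth` (list of
#'   per-wave [ising_params()]).
#' @export
developmental_scenario <- function(spec, n = 1147, prevalence_by_wave = NULL,
                                   burnin = 1000, thin = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- planted_two_block(spec)
  nw <- length(spec$wave_scales)
  p <- spec$p1 + spec$p2
  if (!is.null(prevalence_by_wave)) {
    prevalence_by_wave <- as.matrix(prevalence_by_wave)
    if (!all(dim(prevalence_by_wave) == c(p, nw)))
      stop("prevalence_by_wave must be p x n_waves")
  }
  waves <- truth <- vector("list", nw)
  for (w in seq_len(nw)) {
    pw <- base
    pw$omega <- base$omega * spec$wave_scales[w]
    targ <- if (!is.null(prevalence_by_wave)) prevalence_by_wave[, w]
            else spec$prevalence_targets
    if (!is.null(targ))
      pw <- calibrate_thresholds(pw, targ, seed = spec$seed + 1000L + w)
    truth[[w]] <- pw
    waves[[w]] <- sample_ising_gibbs(pw, n, burnin = burnin, thin = thin,
                                     seed = spec$seed + 2000L + w,
                                     wave_label = spec$wave_labels[w])
  }
  names(truth) <- spec$wave_labels
  list(panel = wave_panel(waves), truth = truth)
}

#' Benchmark item prevalences for an 18-item parent-report panel
#'
#' Percent-of-sample frequencies (divided by 100) of 12 depression and 6
#' anxiety items from the DSM-oriented scales of a parent-report child
#' behavior checklist, reported at seven ages (5-14 years) in a large US
#' birth cohort (N = 1,147). Used as default calibration targets for the
#' synthetic generator so simulated panels show realistic marginal rates
#' (roughly 1%-40%).
#'
#' @format 18 x 7 numeric matrix; rows are items (short labels, tagged
#'   depression then anxiety), columns are ages.
#' @export
cbcl_prevalences <- local({
  m <- matrix(c(
    21, 17, 15, 12, 11,  8,  4,   # cry: cries a lot
     1,  1,  1,  1,  1,  1,  3,   # s-harm: harms self / attempts suicide
    34, 27, 22, 20, 20, 18, 21,   # eat: doesn't eat well
     7, 10, 15, 13, 13, 16, 14,   # worth: feels worthless
     3,  4,  6,  6,  6,  6,  5,   # guilt: feels too guilty
    15, 13, 12, 12, 12, 14, 20,   # tired: overtired
    13, 12, 12, 12, 12, 13, 11,   # slp-L: sleeps less than most
     5,  4,  4,  4,  5,  5, 11,   # slp-M: sleeps more than most
     2,  3,  3,  2,  3,  3,  2,   # suic: talks about suicide
    11, 10, 12, 11, 11, 10, 13,   # t-slp: trouble sleeping
     3,  5,  7,  8, 11, 10, 15,   # ene: lacks energy / underactive
     7,  9, 13, 12, 14, 13, 17,   # sad: unhappy, sad, or depressed
    40, 28, 22, 18, 20, 17, 10,   # depnd: clingy / too dependent
    39, 31, 25, 22, 20, 18, 11,   # fears: specific fears
     7,  5,  5,  4,  4,  5,  3,   # f-sch: fears school
    12, 13, 18, 19, 19, 19, 18,   # nerv: nervous, highstrung, or tense
    10, 12, 12, 10, 12, 11,  9,   # anx: too fearful or anxious
    23, 27, 34, 32, 36, 33, 28),  # worry: worries
    nrow = 18, byrow = TRUE,
    dimnames = list(c("cry", "s-harm", "eat", "worth", "guilt", "tired",
                      "slp-L", "slp-M", "suic", "t-slp", "ene", "sad",
                      "depnd", "fears", "f-sch", "nerv", "anx", "worry"),
                    c("5", "6", "8", "9", "10", "11", "14")))
  m / 100
})
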