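edge_names <- function(labels) {
  ut <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  paste(labels[ut[, 1]], labels[ut[, 2]], sep = "--")
}

#' Bootstrap edge-weight confidence intervals
#'
#' Nonparametric case bootstrap: rows are resampled with replacement, the
#' network re-estimated, and per-edge 2.5/97.5 percentile intervals taken
#' across the re-estimates. The full draw matrix is retained for
#' [edge_difference_test()].
#'
#' @param X [symptom_matrix()] or binary matrix.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @inheritParams nct
#' @return Object of class `edge_bootstrap`: list with `edge_ci`
#'   (data frame `edge`, `point`, `lo`, `hi`), `draws`
#'   (`n_boot x n_edges` matrix), `n_boot`, `seed`.
#' @export
bootstrap_edges <- function(X, n_boot = 250, seed = NULL, gamma = 0.25,
                            rule = "AND") {
  X <- values_of(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 cases")
  if (!is.null(seed)) set.seed(seed)
  full <- estimate_network(X, gamma = gamma, rule = rule, warn = FALSE)
  ut <- upper.tri(full$omega_hat)
  enames <- edge_names(full$node_labels)
  draws <- matrix(NA_real_, n_boot, length(enames),
                  dimnames = list(NULL, enames))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[b, ] <- estimate_network(X[idx, , drop = FALSE], gamma = gamma,
                                   rule = rule, warn = FALSE)$omega_hat[ut]
  }
  ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  edge_ci <- data.frame(edge = enames, point = full$omega_hat[ut],
                        lo = pmin(ci[, 1], full$omega_hat[ut]),
                        hi = pmax(ci[, 2], full$omega_hat[ut]),
                        stringsAsFactors = FALSE)
  structure(list(edge_ci = edge_ci, draws = draws, n_boot = n_boot,
                 seed = seed), class = "edge_bootstrap")
}

#' Bootstrapped difference test between two edges
#'
#' Two edge weights differ significantly when the bootstrap percentile
#' interval of their difference excludes zero at level `alpha`.
#'
#' @param boot an [bootstrap_edges()] result.
#' @param edge_1,edge_2 edge names as in `boot$edge_ci$edge`
#'   (`"nodeA--nodeB"`).
#' @param alpha test level.
#' @return Logical; attribute `ci` carries the interval of the difference.
#' @export
edge_difference_test <- function(boot, edge_1, edge_2, alpha = 0.05) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  for (e in c(edge_1, edge_2))
    if (!e %in% colnames(boot$draws)) stop("unknown edge: ", e)
  d <- boot$draws[, edge_1] - boot$draws[, edge_2]
  ci <- quantile(d, probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(ci[1] > 0 || ci[2] < 0, ci = ci)
}

#' Pairwise edge-difference significance matrix
#'
#' @inheritParams edge_difference_test
#' @param edges subset of edge names (default: edges with nonzero point
#'   estimate).
#' @return Symmetric logical matrix.
#' @export
edge_difference_matrix <- function(boot, edges = NULL, alpha = 0.05) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  if (is.null(edges)) edges <- boot$edge_ci$edge[boot$edge_ci$point != 0]
  k <- length(edges)
  out <- matrix(FALSE, k, k, dimnames = list(edges, edges))
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out[i, j] <- out[j, i] <- as.logical(
      edge_difference_test(boot, edges[i], edges[j], alpha = alpha))
  out
}

#' Correlation-stability (CS) coefficient for a centrality index
#'
#' Case-dropping bootstrap: for each drop proportion `q` in the grid,
#' subsamples of `(1 - q) * n` cases are drawn without replacement, the
#' network re-estimated, and the subsample centralities correlated (Spearman)
#' with the full-sample centralities. The CS coefficient is the largest `q`
#' such that at least `prob` of the correlations reach `cor_threshold` at
#' every grid value up to `q`; 0 if the smallest grid value already fails.
#' Values below about 0.25 indicate that centrality rankings should not be
#' interpreted; 0.5 or above is considered stable.
#'
#' @inheritParams bootstrap_edges
#' @param index `"strength"`, `"closeness"` or `"betweenness"`.
#' @param drop_grid increasing drop proportions in (0, 1).
#' @param cor_threshold correlation level that must be maintained.
#' @param prob required probability of maintaining `cor_threshold`.
#' @return Single number (one of the grid values, or 0); attribute
#'   `pass_rate` gives the per-grid-value proportion of subsamples meeting
#'   the threshold.
#' @export
cs_coefficient <- function(X, index = c("strength", "closeness", "betweenness"),
                           drop_grid = seq(0.1, 0.7, by = 0.1), n_boot = 250,
                           cor_threshold = 0.7, prob = 0.95, seed = NULL,
                           gamma = 0.25, rule = "AND") {
  index <- match.arg(index)
  if (!length(drop_grid)) stop("drop_grid must not be empty")
  drop_grid <- sort(drop_grid)
  X <- values_of(X)
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  cent_fun <- switch(index, strength = strength_centrality,
                     closeness = closeness_centrality,
                     betweenness = betweenness_centrality)
  full <- as.numeric(cent_fun(
    estimate_network(X, gamma = gamma, rule = rule, warn = FALSE)$omega_hat))
  pass <- numeric(length(drop_grid)); names(pass) <- drop_grid
  for (gi in seq_along(drop_grid)) {
    keep <- max(2L, round((1 - drop_grid[gi]) * n))
    ok <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, keep)
      cent <- as.numeric(cent_fun(
        estimate_network(X[idx, , drop = FALSE], gamma = gamma, rule = rule,
                         warn = FALSE)$omega_hat))
      r <- suppressWarnings(cor(full, cent, method = "spearman"))
      ok[b] <- is.finite(r) && r >= cor_threshold
    }
    pass[gi] <- mean(ok)
  }
  meets <- pass >= prob
  cs <- 0
  for (gi in seq_along(drop_grid)) {
    if (!meets[gi]) break
    cs <- drop_grid[gi]
  }
  structure(cs, pass_rate = pass)
}
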