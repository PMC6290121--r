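#' Permutation test of network invariance between two waves (NCT)
#'
#' Three-phase nonparametric test. (1) Estimate both networks and compute the
#' observed statistics: the absolute difference in global strength and the
#' absolute per-edge weight differences. (2) Repeatedly swap cases between
#' the two groups and re-estimate: under the `independent` scheme the pooled
#' rows are reshuffled into two groups of the original sizes; under the
#' `paired` scheme (aligned subjects measured at both waves) each subject's
#' two rows are swapped with probability 1/2. (3) p-values are the proportion
#' of permuted statistics at least as large as the observed one, computed as
#' `(1 + count) / (1 + n_perm)` so they are never zero. Per-edge p-values are
#' Holm-adjusted.
#'
#' Re-estimation inside permutations uses the same estimation configuration
#' as the observed fit, so the full pipeline is exchangeable under the null.
#'
#' @param panel_a,panel_b [symptom_matrix()] objects (or binary matrices with
#'   identical column names).
#' @param n_perm number of permutations (default 1,000; reduce for desk-scale
#'   runs).
#' @param scheme `"paired"` (default, for longitudinal waves on the same
#'   subjects) or `"independent"`.
#' @param seed integer seed.
#' @param gamma,rule,n_lambda,lambda_ratio passed to [estimate_network()].
#' @return Object of class `comparison_result`: list with
#'   `observed_global_diff`, `p_global`, `per_edge` (data frame `node_a`,
#'   `node_b`, `observed_diff`, `p_raw`, `p_adjusted`), `global_strength`
#'   (the two observed values), `n_permutations`, `scheme`, `seed`.
#' @export
nct <- function(panel_a, panel_b, n_perm = 1000,
                scheme = c("paired", "independent"), seed = NULL,
                gamma = 0.25, rule = "AND", n_lambda = 100, lambda_ratio = 0.01) {
  scheme <- match.arg(scheme)
  Xa <- values_of(panel_a); Xb <- values_of(panel_b)
  if (!identical(colnames(Xa), colnames(Xb)))
    stop("the two panels must share an identical node set (same order)")
  if (scheme == "paired") {
    ida <- rownames(Xa); idb <- rownames(Xb)
    if (nrow(Xa) != nrow(Xb) || is.null(ida) || is.null(idb) ||
        !setequal(ida, idb) || anyDuplicated(ida))
      stop("paired scheme requires the same subjects in both panels (aligned ids)")
    Xb <- Xb[match(ida, idb), , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  est <- function(X) estimate_network(X, gamma = gamma, rule = rule,
                                      n_lambda = n_lambda,
                                      lambda_ratio = lambda_ratio, warn = FALSE)
  stat <- function(Xa, Xb) {
    wa <- est(Xa)$omega_hat; wb <- est(Xb)$omega_hat
    ut <- upper.tri(wa)
    list(global = abs(global_strength(wa) - global_strength(wb)),
         edges = abs(wa[ut] - wb[ut]),
         sa = global_strength(wa), sb = global_strength(wb))
  }
  obs <- stat(Xa, Xb)
  na <- nrow(Xa); nb <- nrow(Xb)
  cnt_global <- 0L
  cnt_edges <- numeric(length(obs$edges))
  for (b in seq_len(n_perm)) {
    if (scheme == "independent") {
      pool <- rbind(Xa, Xb)
      idx <- sample.int(na + nb)
      pa <- pool[idx[seq_len(na)], , drop = FALSE]
      pb <- pool[idx[na + seq_len(nb)], , drop = FALSE]
    } else {
      swap <- runif(na) < 0.5
      pa <- Xa; pb <- Xb
      pa[swap, ] <- Xb[swap, , drop = FALSE]
      pb[swap, ] <- Xa[swap, , drop = FALSE]
    }
    st <- stat(pa, pb)
    cnt_global <- cnt_global + (st$global >= obs$global)
    cnt_edges <- cnt_edges + (st$edges >= obs$edges)
  }
  p_global <- (1 + cnt_global) / (1 + n_perm)
  p_edges <- (1 + cnt_edges) / (1 + n_perm)
  labels <- colnames(Xa)
  ut <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  per_edge <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                         observed_diff = obs$edges, p_raw = p_edges,
                         p_adjusted = adjust_pvalues(p_edges),
                         stringsAsFactors = FALSE)
  structure(list(observed_global_diff = obs$global, p_global = p_global,
                 per_edge = per_edge,
                 global_strength = c(a = obs$sa, b = obs$sb),
                 n_permutations = n_perm, scheme = scheme, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> scheme = %s, %d permutations\n",
              x$scheme, x$n_permutations))
  cat(sprintf("global strength: %.3f vs %.3f; |diff| = %.3f, p = %.4g\n",
              x$global_strength[1], x$global_strength[2],
              x$observed_global_diff, x$p_global))
  sig <- sum(x$per_edge$p_adjusted < 0.05)
  cat(sprintf("per-edge tests: %d of %d Holm-significant at 0.05\n",
              sig, nrow(x$per_edge)))
  invisible(x)
}

#' Multiplicity adjustment for per-edge p-values
#'
#' Holm step-down adjustment (monotone, never below the raw values); thin
#' wrapper over [stats::p.adjust()].
#'
#' @param p_raw vector of p-values in `[0, 1]`.
#' @param method adjustment method (default `"holm"`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p_raw, method = "holm") {
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  p.adjust(p_raw, method = method)
}
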