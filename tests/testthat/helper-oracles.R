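# Brute-force oracles for small graphs, independent of the package's
# shortest-path and community machinery.

# all simple paths i -> j; returns list of node index vectors
all_simple_paths_bf <- function(adj, i, j) {
  p <- ncol(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(p))
      if (adj[v, w] > 0 && !(w %in% path)) walk(c(path, w))
  }
  walk(i)
  out
}

# exhaustive weighted shortest-path distances, lengths = 1/|omega|
bf_distances <- function(omega) {
  p <- ncol(omega)
  len <- ifelse(abs(omega) > 0, 1 / abs(omega), Inf)
  d <- matrix(Inf, p, p); diag(d) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    paths <- all_simple_paths_bf(abs(omega), i, j)
    if (length(paths)) {
      pl <- vapply(paths, function(pt)
        sum(len[cbind(pt[-length(pt)], pt[-1])]), numeric(1))
      d[i, j] <- d[j, i] <- min(pl)
    }
  }
  d
}

bf_closeness <- function(omega) {
  d <- bf_distances(omega)
  diag(d) <- Inf
  apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) 0 else 1 / sum(r)
  })
}

bf_betweenness <- function(omega, tol = 1e-9) {
  p <- ncol(omega)
  len <- ifelse(abs(omega) > 0, 1 / abs(omega), Inf)
  b <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    paths <- all_simple_paths_bf(abs(omega), s, t)
    if (!length(paths)) next
    pl <- vapply(paths, function(pt)
      sum(len[cbind(pt[-length(pt)], pt[-1])]), numeric(1))
    sh <- paths[pl < min(pl) + tol]
    for (pt in sh) {
      mid <- setdiff(pt, c(s, t))
      b[mid] <- b[mid] + 1 / length(sh)
    }
  }
  b
}

# all set partitions of 1..n (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_partitions(n - 1)) {
    k <- max(sub)
    for (c in seq_len(k + 1)) out[[length(out) + 1L]] <- c(sub, c)
  }
  out
}

# exhaustive best-modularity partition
bf_best_modularity <- function(omega) {
  parts <- all_partitions(ncol(omega))
  qs <- vapply(parts, function(mb) modularity_q(omega, mb), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# small random weighted graph fixture
random_graph <- function(p, density = 0.5, seed = 1) {
  set.seed(seed)
  omega <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (runif(1) < density) omega[i, j] <- omega[j, i] <- round(runif(1, 0.2, 1.5), 3)
  dimnames(omega) <- list(paste0("n", 1:p), paste0("n", 1:p))
  omega
}

# two disconnected unit-weight triangles on 6 nodes
two_triangles <- function() {
  om <- matrix(0, 6, 6)
  om[1, 2] <- om[2, 3] <- om[1, 3] <- 1
  om[4, 5] <- om[5, 6] <- om[4, 6] <- 1
  om <- om + t(om)
  dimnames(om) <- list(letters[1:6], letters[1:6])
  om
}

# small calibrated planted model for end-to-end tests (p <= 14: exact tools)
small_planted <- function(p1 = 5, p2 = 3, seed = 42, w_within = 1.2,
                          w_between = 0, density_within = 0.8,
                          density_between = 0, targets = NULL) {
  p <- p1 + p2
  if (is.null(targets)) targets <- seq(0.15, 0.4, length.out = p)
  spec <- scenario_spec(p1 = p1, p2 = p2, w_within = w_within,
                        w_between = w_between, density_within = density_within,
                        density_between = density_between,
                        prevalence_targets = setNames(targets, paste0("it", 1:p)),
                        wave_scales = 1, wave_labels = "w", seed = seed)
  tr <- planted_two_block(spec)
  calibrate_thresholds(tr, targets, tol = 1e-4)
}
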