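#' Random-walk distance matrix between nodes
#'
#' Short random walks get trapped in densely connected regions, so nodes in
#' the same community see similar walk distributions. With transition matrix
#' `P` (row-normalized absolute weights) the distance is
#' `r_ij = sqrt( sum_k (Pt_ik - Pt_jk)^2 / s_k )`
#' where `Pt = P^t` and `s_k` is node strength. Isolated nodes (zero
#' strength) have no defined walk; their rows/columns are `NA` and they are
#' treated as singleton communities by [walktrap()].
#'
#' @inheritParams global_strength
#' @param t walk length (integer >= 1).
#' @return `p x p` symmetric distance matrix (`NA` for isolated nodes).
#' @export
walk_distance_matrix <- function(omega, t = 4) {
  omega <- check_symmetric(omega_of(omega))
  if (t < 1) stop("walk length t must be >= 1")
  A <- abs(omega)
  s <- rowSums(A)
  p <- ncol(A)
  act <- s > 0
  r <- matrix(NA_real_, p, p, dimnames = dimnames(A))
  if (!any(act)) return(r)
  P <- A[act, act, drop = FALSE] / s[act]
  Pt <- diag(nrow(P))
  for (i in seq_len(t)) Pt <- Pt %*% P
  W <- Pt / rep(sqrt(s[act]), each = nrow(Pt))  # scale columns by 1/sqrt(s_k)
  d2 <- outer(rowSums(W^2), rowSums(W^2), "+") - 2 * tcrossprod(W)
  r[act, act] <- sqrt(pmax(d2, 0))
  diag(r)[act] <- 0
  r
}

community_prob_rows <- function(Pt, groups) {
  t(vapply(groups, function(g) colMeans(Pt[g, , drop = FALSE]),
           numeric(ncol(Pt))))
}

#' Walktrap community detection
#'
#' Agglomerative clustering on random-walk distances: starting from singleton
#' communities, adjacent communities are merged in the order that minimizes
#' the Ward-style increase in mean squared walk distance,
#' `dQ(C1, C2) = (1/p) * |C1||C2|/(|C1|+|C2|) * r^2(C1, C2)`,
#' and the final partition is the cut of the merge sequence that maximizes
#' modularity Q (ties broken toward fewer communities). The procedure is
#' deterministic. Negative edge weights enter as absolute values (with a
#' warning); isolated nodes stay singleton communities.
#'
#' @inheritParams global_strength
#' @param t walk length (default 4, the customary walktrap setting).
#' @return Object of class `partition`: list with `membership` (named,
#'   contiguous ids from 1), `q_value`, `merge_history` (two-column matrix of
#'   merged community labels), `walk_length`, and `q_path` (Q at every cut,
#'   singletons first).
#' @export
walktrap <- function(omega, t = 4) {
  omega <- check_symmetric(omega_of(omega))
  p <- ncol(omega)
  if (p < 2) stop("need at least 2 nodes")
  if (any(omega < 0))
    warning("negative edges entered community detection as absolute values")
  A <- abs(omega)
  labels <- colnames(A)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  s <- rowSums(A)
  m <- sum(A[upper.tri(A)])
  if (m == 0) {
    membership <- setNames(seq_len(p), labels)
    return(structure(list(membership = membership, q_value = NA_real_,
                          merge_history = matrix(integer(0), 0, 2),
                          walk_length = t, q_path = NA_real_),
                     class = "partition"))
  }
  act <- which(s > 0)
  P <- A[act, act, drop = FALSE] / s[act]
  Pt <- diag(length(act))
  for (i in seq_len(t)) Pt <- Pt %*% P
  invs <- 1 / s[act]

  # communities over active nodes; isolated nodes are fixed singletons
  groups <- as.list(seq_along(act))      # indices into `act`
  ids <- seq_along(act)                  # running community labels
  Pc <- Pt                               # community walk-probability rows
  nodeadj <- (A[act, act, drop = FALSE] > 0)  # node-level adjacency, fixed
  sizes <- rep(1L, length(act))

  part_membership <- function(groups) {
    memb <- integer(p)
    nid <- 0L
    for (g in groups) { nid <- nid + 1L; memb[act[g]] <- nid }
    for (i in setdiff(seq_len(p), act)) { nid <- nid + 1L; memb[i] <- nid }
    memb
  }
  cuts <- list(part_membership(groups))
  merges <- matrix(integer(0), 0, 2,
                   dimnames = list(NULL, c("community_a", "community_b")))

  repeat {
    k <- length(groups)
    if (k < 2) break
    best <- NULL; best_dq <- Inf
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (!any(nodeadj[groups[[a]], groups[[b]]])) next
      r2 <- sum((Pc[a, ] - Pc[b, ])^2 * invs)
      dq <- (sizes[a] * sizes[b]) / (sizes[a] + sizes[b]) * r2 / p
      if (dq < best_dq - 1e-15) { best_dq <- dq; best <- c(a, b) }
    }
    if (is.null(best)) break  # disconnected: no adjacent pairs left
    a <- best[1]; b <- best[2]
    merges <- rbind(merges, c(ids[a], ids[b]))
    Pc[a, ] <- (sizes[a] * Pc[a, ] + sizes[b] * Pc[b, ]) / (sizes[a] + sizes[b])
    groups[[a]] <- c(groups[[a]], groups[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    keep <- setdiff(seq_len(k), b)
    groups <- groups[keep]; sizes <- sizes[keep]
    Pc <- Pc[keep, , drop = FALSE]; ids <- ids[keep]
    cuts[[length(cuts) + 1L]] <- part_membership(groups)
  }

  q_path <- vapply(cuts, function(mb) modularity_q(omega, mb), numeric(1))
  bestq <- max(q_path)
  choice <- max(which(q_path > bestq - 1e-12))  # ties: fewer communities
  memb <- cuts[[choice]]
  memb <- match(memb, unique(memb))  # contiguous ids in order of appearance
  membership <- setNames(memb, labels)
  structure(list(membership = membership, q_value = q_path[choice],
                 merge_history = merges, walk_length = t, q_path = q_path),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("<partition> %d communities, Q = %s (walk length %d)\n",
              k, format(x$q_value, digits = 4), x$walk_length))
  print(split(names(x$membership), x$membership))
  invisible(x)
}

#' Modularity index Q of a partition
#'
#' Compares the observed within-community edge mass against the expectation
#' in a randomly rewired network with the same strengths:
#' `Q = (1/2m) sum_ij (A_ij - s_i s_j / 2m) delta(c_i, c_j)`
#' with `A = |omega|`, strengths `s`, and `m` the total edge weight. Positive
#' Q means denser-than-chance communities; the index can be negative (down to
#' -1/2) even though well-clustered networks sit in (0, 1).
#'
#' @inheritParams global_strength
#' @param membership integer community ids, one per node.
#' @return Single number.
#' @export
modularity_q <- function(omega, membership) {
  omega <- check_symmetric(omega_of(omega))
  p <- ncol(omega)
  if (length(membership) != p) stop("membership must have length p")
  A <- abs(omega)
  s <- rowSums(A)
  m <- sum(A[upper.tri(A)])
  if (m == 0) stop("modularity undefined for an empty network (m = 0)")
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / (2 * m) - (sum(s[idx]) / (2 * m))^2
  }
  q
}

#' Classify a modularity value against the conventional 0.3 rule
#'
#' Values above 0.3 are read as nonrandom community structure; at or below,
#' the detected clusters are consistent with chance.
#'
#' @param q modularity value.
#' @param threshold decision threshold (default 0.3); classification is
#'   strict (`q > threshold`).
#' @return `"nonrandom"` or `"random"`.
#' @export
interpret_q <- function(q, threshold = 0.3) {
  stopifnot(is.finite(q))
  if (q > threshold) "nonrandom" else "random"
}
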