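net_igraph <- function(omega) {
  igraph::graph_from_adjacency_matrix(abs(omega), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over unordered pairs,
#' `S = sum_{i<j} |omega_ij|` — the overall-connectivity measure used when
#' comparing networks across waves.
#'
#' @param omega symmetric weight matrix (or an estimated/true network object).
#' @return Single number.
#' @export
global_strength <- function(omega) {
  omega <- check_symmetric(omega_of(omega))
  sum(abs(omega[upper.tri(omega)]))
}

#' Node strength centrality
#'
#' `s_i = sum_j |omega_ij|` over the edges retained in the network. A node
#' high in strength can directly influence many neighbors.
#'
#' @inheritParams global_strength
#' @return Named numeric vector of `p` strengths.
#' @export
strength_centrality <- function(omega) {
  omega <- check_symmetric(omega_of(omega))
  rowSums(abs(omega))
}

#' Node closeness centrality
#'
#' Inverse of the total shortest-path distance from each node to every other
#' reachable node, with edge lengths `1/|omega_ij|` (strong edges are short).
#' Isolated nodes score 0; in a disconnected network only the reachable set
#' enters the sum and the result carries attribute `disconnected = TRUE`.
#'
#' @inheritParams global_strength
#' @return Named numeric vector of `p` closeness values.
#' @export
closeness_centrality <- function(omega) {
  omega <- check_symmetric(omega_of(omega))
  g <- net_igraph(omega)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  diag(d) <- Inf
  cl <- apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) 0 else 1 / sum(r)
  })
  names(cl) <- colnames(omega)
  disconnected <- any(!is.finite(d[upper.tri(d)]))
  structure(cl, disconnected = disconnected)
}

#' Node betweenness centrality
#'
#' Number of times a node lies on the shortest path between two other nodes,
#' with fractional credit shared across equally short paths
#' (`b_v = sum_{s<t} sigma_st(v)/sigma_st`), edge lengths `1/|omega_ij|`.
#'
#' @inheritParams global_strength
#' @return Named numeric vector of `p` betweenness values.
#' @export
betweenness_centrality <- function(omega) {
  omega <- check_symmetric(omega_of(omega))
  g <- net_igraph(omega)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight, directed = FALSE)
  names(b) <- colnames(omega)
  b
}

#' Standardize values to z-scores
#'
#' `(v - mean) / SD` with the population SD (divisor `p`) by default, the
#' convention used when reporting centrality profiles over a fixed node set.
#' A constant input returns all zeros with a warning.
#'
#' @param values numeric vector, length >= 2.
#' @param type `"population"` (divisor `p`, default) or `"sample"`
#'   (divisor `p - 1`).
#' @return z-scores with mean 0 and SD 1 (unless input was constant).
#' @export
zstandardize <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  s2 <- sum((values - m)^2) / if (type == "population") length(values) else length(values) - 1L
  if (s2 == 0) {
    warning("constant input: z-scores set to 0")
    return(values * 0)
  }
  (values - m) / sqrt(s2)
}

#' Centrality table for one network
#'
#' Strength, closeness and betweenness, raw and z-standardized, for every
#' node of one wave's network.
#'
#' @inheritParams global_strength
#' @param wave_label label recorded in the table.
#' @return `data.frame` with columns `node`, `wave`, `strength`, `closeness`,
#'   `betweenness` and their `_z` counterparts.
#' @export
centrality_table <- function(omega, wave_label = "") {
  omega <- check_symmetric(omega_of(omega))
  s <- strength_centrality(omega)
  cl <- closeness_centrality(omega)
  b <- betweenness_centrality(omega)
  z <- function(v) suppressWarnings(zstandardize(v))
  data.frame(node = colnames(omega), wave = wave_label,
             strength = unname(s), closeness = as.numeric(cl),
             betweenness = unname(b),
             strength_z = unname(z(s)), closeness_z = as.numeric(z(cl)),
             betweenness_z = unname(z(b)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reshape centrality tables to long format
#'
#' @param tables list of [centrality_table()] data frames (or one).
#' @return Long `data.frame` with columns `node`, `wave`, `index`, `raw`, `z`
#'   suitable for plotting centrality trajectories.
#' @export
centrality_long <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  do.call(rbind, lapply(tables, function(tb) {
    do.call(rbind, lapply(c("strength", "closeness", "betweenness"), function(ix)
      data.frame(node = tb$node, wave = tb$wave, index = ix,
                 raw = tb[[ix]], z = tb[[paste0(ix, "_z")]],
                 stringsAsFactors = FALSE)))
  }))
}
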