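#' Default pipeline configuration
#'
#' @param gamma,rule,n_lambda,lambda_ratio estimation controls
#'   ([estimate_network()]).
#' @param walk_t walktrap walk length.
#' @param q_threshold modularity decision threshold ([interpret_q()]).
#' @param scheme,n_perm comparison controls ([nct()]); `scheme = "auto"`
#'   picks `"paired"` when subjects are aligned across waves, else
#'   `"independent"`.
#' @param compare_pairs `"default"` (consecutive wave pairs plus
#'   first-vs-last) or a two-column matrix of wave labels; `"none"` skips
#'   comparisons.
#' @param top_k edges listed in the strongest-edge table.
#' @param seed integer master seed.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(gamma = 0.25, rule = "AND", n_lambda = 100,
                            lambda_ratio = 0.01, walk_t = 4, q_threshold = 0.3,
                            scheme = "auto", n_perm = 1000,
                            compare_pairs = "default", top_k = 10, seed = 1L) {
  list(gamma = gamma, rule = rule, n_lambda = n_lambda,
       lambda_ratio = lambda_ratio, walk_t = walk_t, q_threshold = q_threshold,
       scheme = scheme, n_perm = n_perm, compare_pairs = compare_pairs,
       top_k = top_k, seed = as.integer(seed))
}

#' Run the full developmental network analysis
#'
#' For every wave of the panel: estimate the Ising network, detect walktrap
#' communities and modularity Q, and compute the centrality table. Across
#' waves: the global-strength trajectory, permutation comparisons for the
#' configured wave pairs, an edge-density summary, the strongest edges with
#' cross-domain (bridge) flags, and a shared average layout. Deterministic
#' given the panel and the config seed.
#'
#' @param panel a [wave_panel()].
#' @param config a [pipeline_config()] list (defaults applied for missing
#'   entries).
#' @return Object of class `run_report`; see the elements of the returned
#'   list (`networks`, `partitions`, `centrality`, `q_by_wave`,
#'   `global_strength_by_wave`, `edge_density`, `top_edges`, `comparisons`,
#'   `layout`, `provenance`).
#' @export
run_analysis <- function(panel, config = pipeline_config()) {
  stopifnot(inherits(panel, "wave_panel"))
  config <- utils::modifyList(pipeline_config(), config)
  labs <- names(panel$waves)
  nw <- length(labs)
  networks <- partitions <- centrality <- vector("list", nw)
  names(networks) <- names(partitions) <- names(centrality) <- labs
  for (w in seq_len(nw)) {
    wave <- panel$waves[[w]]
    net <- tryCatch(
      estimate_network(wave, gamma = config$gamma, rule = config$rule,
                       n_lambda = config$n_lambda,
                       lambda_ratio = config$lambda_ratio),
      error = function(e) stop(sprintf("wave '%s': %s", labs[w], conditionMessage(e)),
                               call. = FALSE))
    networks[[w]] <- net
    partitions[[w]] <- walktrap(net$omega_hat, t = config$walk_t)
    centrality[[w]] <- centrality_table(net$omega_hat, wave_label = labs[w])
  }
  p <- length(panel$waves[[1]]$node_labels)
  possible <- p * (p - 1) / 2
  nonzero <- vapply(networks, function(nt)
    sum(nt$omega_hat[upper.tri(nt$omega_hat)] != 0), numeric(1))
  edge_density <- data.frame(wave = labs, possible_edges = possible,
                             nonzero_edges = nonzero,
                             pct_nonzero = 100 * nonzero / possible,
                             stringsAsFactors = FALSE, row.names = NULL)
  q_by_wave <- data.frame(
    wave = labs,
    q = vapply(partitions, `[[`, numeric(1), "q_value"),
    n_communities = vapply(partitions, function(pt) length(unique(pt$membership)), numeric(1)),
    interpretation = vapply(partitions, function(pt)
      if (is.na(pt$q_value)) NA_character_
      else interpret_q(pt$q_value, config$q_threshold), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  global_strength_by_wave <- data.frame(
    wave = labs,
    global_strength = vapply(networks, function(nt) global_strength(nt$omega_hat),
                             numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tags <- panel$waves[[1]]$domain_tags
  top_edges <- do.call(rbind, lapply(seq_len(nw), function(w) {
    te <- bridge_edge_table(networks[[w]]$omega_hat, tags, top_k = config$top_k)
    if (nrow(te)) cbind(wave = labs[w], te) else NULL
  }))

  comparisons <- list()
  if (nw > 1 && !identical(config$compare_pairs, "none")) {
    pairs <- if (identical(config$compare_pairs, "default")) {
      pr <- cbind(seq_len(nw - 1), 2:nw)
      if (nw > 2) pr <- rbind(pr, c(1L, nw))
      pr
    } else {
      m <- as.matrix(config$compare_pairs)
      matrix(match(m, labs), ncol = 2)
    }
    if (anyNA(pairs)) stop("compare_pairs names unknown wave labels")
    scheme <- config$scheme
    if (identical(scheme, "auto"))
      scheme <- if (is.null(panel$alignment)) "independent" else "paired"
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      comparisons[[paste(labs[a], labs[b], sep = " vs ")]] <-
        nct(panel$waves[[a]], panel$waves[[b]], n_perm = config$n_perm,
            scheme = scheme, seed = config$seed + i,
            gamma = config$gamma, rule = config$rule,
            n_lambda = config$n_lambda, lambda_ratio = config$lambda_ratio)
    }
  }
  layout <- average_layout(networks, seed = config$seed)
  provenance <- list(config = config,
                     config_hash = rlang::hash(config),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("symptomnets")))
  structure(list(networks = networks, partitions = partitions,
                 centrality = centrality, q_by_wave = q_by_wave,
                 global_strength_by_wave = global_strength_by_wave,
                 edge_density = edge_density, top_edges = top_edges,
                 comparisons = comparisons, layout = layout,
                 provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d wave(s), seed %d\n",
              nrow(x$q_by_wave), x$provenance$seed))
  tab <- merge(x$q_by_wave[, c("wave", "q", "interpretation")],
               merge(x$global_strength_by_wave,
                     x$edge_density[, c("wave", "nonzero_edges", "possible_edges")],
                     sort = FALSE), sort = FALSE)
  print(tab, digits = 4)
  if (length(x$comparisons)) {
    cat("wave comparisons (global strength):\n")
    for (nm in names(x$comparisons)) {
      cm <- x$comparisons[[nm]]
      cat(sprintf("  %s: |diff| = %.3f, p = %.4g\n", nm,
                  cm$observed_global_diff, cm$p_global))
    }
  }
  invisible(x)
}

#' Shared force-directed layout over waves
#'
#' Fruchterman-Reingold layout on the element-wise mean of the absolute
#' weight matrices, so highly connected nodes sit close together and node
#' positions are comparable across waves. Coordinates are scaled to the unit
#' bounding box; the layout is deterministic given the seed.
#'
#' @param networks list of networks (or one network) sharing a node set.
#' @param seed integer seed.
#' @param niter Fruchterman-Reingold iterations.
#' @return `p x 2` matrix of coordinates in `[0, 1]^2`, rownames = node
#'   labels.
#' @export
average_layout <- function(networks, seed = 1L, niter = 500) {
  if (inherits(networks, "estimated_network") || inherits(networks, "ising_params") ||
      is.matrix(networks)) networks <- list(networks)
  mats <- lapply(networks, function(nt) abs(omega_of(nt)))
  avg <- Reduce(`+`, mats) / length(mats)
  g <- net_igraph(avg)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = niter,
                               weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL)
  for (d in 1:2) {
    rng <- range(xy[, d])
    xy[, d] <- if (diff(rng) > 0) (xy[, d] - rng[1]) / diff(rng) else 0.5
  }
  dimnames(xy) <- list(colnames(avg), c("x", "y"))
  xy
}

#' Strongest edges with cross-domain (bridge) flags
#'
#' Edges sorted by absolute weight (descending, ties broken lexicographically
#' by node labels); an edge is flagged as a bridge when its endpoints carry
#' different domain tags — e.g., a depression-anxiety link.
#'
#' @inheritParams global_strength
#' @param domain_tags domain tag per node (`NULL` for all-"other").
#' @param top_k number of edges to return (all nonzero edges if fewer).
#' @return `data.frame` with `node_a`, `node_b`, `weight`, `domain_a`,
#'   `domain_b`, `bridge`.
#' @export
bridge_edge_table <- function(omega, domain_tags = NULL, top_k = 10) {
  omega <- check_symmetric(omega_of(omega))
  p <- ncol(omega)
  labels <- colnames(omega)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (is.null(domain_tags)) domain_tags <- rep("other", p)
  if (length(domain_tags) != p) stop("domain_tags must cover all nodes")
  ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  df <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                   weight = omega[ut],
                   domain_a = domain_tags[ut[, 1]], domain_b = domain_tags[ut[, 2]],
                   stringsAsFactors = FALSE)
  df$bridge <- df$domain_a != df$domain_b
  df <- df[order(-abs(df$weight), df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_k)
}

fmt_num_df <- function(df) {
  for (cn in names(df))
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.15g", df[[cn]])
  df
}

#' Write all report artifacts to a directory
#'
#' Emits machine-readable CSV/JSON analogs of the usual figures and tables:
#' per-wave weighted edge lists, community memberships, the long-format
#' centrality table, Q-by-wave, the global-strength trajectory, the
#' edge-density summary, strongest-edge tables, wave-comparison results, the
#' average layout, and a JSON run summary with provenance. Output is
#' deterministic: re-running the same analysis rewrites byte-identical files.
#'
#' @param report a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    write.csv(fmt_num_df(df), file.path(dir, name), row.names = FALSE, quote = FALSE)
  for (lb in names(report$networks)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", lb)
    write_network(report$networks[[lb]], file.path(dir, sprintf("network_%s.csv", safe)))
    memb <- report$partitions[[lb]]$membership
    wcsv(data.frame(node = names(memb), community = as.integer(memb)),
         sprintf("communities_%s.csv", safe))
  }
  wcsv(centrality_long(report$centrality), "centrality_long.csv")
  wcsv(report$q_by_wave, "q_by_wave.csv")
  wcsv(report$global_strength_by_wave, "global_strength_by_wave.csv")
  wcsv(report$edge_density, "edge_density.csv")
  if (!is.null(report$top_edges)) wcsv(report$top_edges, "top_edges.csv")
  if (length(report$comparisons)) {
    comp <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
      cm <- report$comparisons[[nm]]
      data.frame(pair = nm, observed_global_diff = cm$observed_global_diff,
                 p_global = cm$p_global, scheme = cm$scheme,
                 n_permutations = cm$n_permutations, stringsAsFactors = FALSE)
    }))
    wcsv(comp, "comparisons_global.csv")
    per_edge <- do.call(rbind, lapply(names(report$comparisons), function(nm)
      cbind(pair = nm, report$comparisons[[nm]]$per_edge)))
    wcsv(per_edge, "comparisons_edges.csv")
  }
  wcsv(data.frame(node = rownames(report$layout), x = report$layout[, 1],
                  y = report$layout[, 2]), "layout.csv")
  summary <- list(
    provenance = report$provenance[c("config_hash", "seed", "package_version")],
    config = report$provenance$config,
    q_by_wave = report$q_by_wave,
    global_strength_by_wave = report$global_strength_by_wave,
    edge_density = report$edge_density)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
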