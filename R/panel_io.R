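#' Construct a binary symptom matrix for one measurement wave
#'
#' The basic data container: an `n x p` matrix of 0/1 symptom indicators with
#' node labels, diagnostic-domain tags, subject identifiers and a wave label.
#' Validation enforces strictly binary, complete data (missing values must be
#' handled upstream; see [load_panel()]).
#'
#' @param values numeric matrix of 0/1 indicators, subjects in rows, items in
#'   columns.
#' @param node_labels character vector of `p` unique item labels; defaults to
#'   `colnames(values)`.
#' @param domain_tags character vector of `p` tags, each one of
#'   `"depression"`, `"anxiety"`, `"other"`; recycled if length 1.
#' @param subject_ids identifiers for the `n` rows; defaults to
#'   `rownames(values)` or `1:n`.
#' @param wave_label single string naming the wave (e.g., age in years).
#' @return An object of class `symptom_matrix`: a list with elements
#'   `values`, `node_labels`, `domain_tags`, `subject_ids`, `wave_label`.
#' @export
symptom_matrix <- function(values, node_labels = colnames(values),
                           domain_tags = "other",
                           subject_ids = rownames(values),
                           wave_label = "") {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (n < 1L) stop("need at least 1 subject")
  if (p < 2L) stop("need at least 2 items")
  if (anyNA(values)) stop("missing values present; drop or impute before constructing")
  if (!all(values %in% c(0, 1))) stop("all cells must be 0 or 1")
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(p))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != p) stop("node_labels must have length p = ", p)
  if (anyDuplicated(node_labels)) stop("node_labels must be unique")
  if (length(domain_tags) == 1L) domain_tags <- rep(domain_tags, p)
  if (length(domain_tags) != p) stop("domain_tags must have length p = ", p)
  bad <- setdiff(unique(domain_tags), c("depression", "anxiety", "other"))
  if (length(bad)) stop("unknown domain tag(s): ", paste(bad, collapse = ", "))
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("subject_ids must have length n = ", n)
  storage.mode(values) <- "integer"
  dimnames(values) <- list(subject_ids, node_labels)
  structure(list(values = values, node_labels = node_labels,
                 domain_tags = domain_tags, subject_ids = subject_ids,
                 wave_label = as.character(wave_label)[1]),
            class = "symptom_matrix")
}

#' @export
print.symptom_matrix <- function(x, ...) {
  cat(sprintf("<symptom_matrix> wave '%s': %d subjects x %d items\n",
              x$wave_label, nrow(x$values), ncol(x$values)))
  prev <- round(100 * colMeans(x$values), 1)
  cat("item prevalence (%):\n")
  print(prev)
  invisible(x)
}

#' Binarize 3-point symptom ratings to presence/absence
#'
#' Parent-report checklist items rated 0 (not true), 1 (somewhat/sometimes
#' true), 2 (very true/often) are rescored to indicate symptom presence: raw
#' responses of 1 or 2 become 1, 0 stays 0. Columns left with zero variance
#' after rescoring are retained but reported in a warning (downstream
#' estimation isolates such nodes).
#'
#' @param raw matrix or data frame with entries in `{0, 1, 2}`.
#' @inheritParams symptom_matrix
#' @return A [symptom_matrix()].
#' @export
binarize_items <- function(raw, node_labels = colnames(raw),
                           domain_tags = "other",
                           subject_ids = rownames(raw), wave_label = "") {
  raw <- as.matrix(raw)
  ok <- raw %in% c(0, 1, 2)
  if (anyNA(raw) || !all(ok)) {
    bad <- which(is.na(raw) | !matrix(ok, nrow(raw)), arr.ind = TRUE)[1, , drop = TRUE]
    cn <- if (!is.null(colnames(raw))) colnames(raw)[bad[2]] else bad[2]
    stop(sprintf("invalid rating at row %s, column '%s': entries must be 0, 1 or 2",
                 bad[1], cn))
  }
  bin <- (raw >= 1) * 1L
  sm <- symptom_matrix(bin, node_labels = node_labels, domain_tags = domain_tags,
                       subject_ids = subject_ids, wave_label = wave_label)
  v <- apply(sm$values, 2, function(z) length(unique(z)) == 1L)
  if (any(v))
    warning("zero-variance item(s): ", paste(sm$node_labels[v], collapse = ", "))
  sm
}

#' Assemble a multi-wave panel
#'
#' @param waves list of [symptom_matrix()] objects sharing identical
#'   `node_labels` in identical order.
#' @return An object of class `wave_panel`: list with `waves` (named by wave
#'   label) and `alignment` (character matrix of shared subject ids when every
#'   wave measures the same subjects, otherwise `NULL`).
#' @export
wave_panel <- function(waves) {
  if (!length(waves)) stop("empty panel")
  if (!all(vapply(waves, inherits, TRUE, "symptom_matrix")))
    stop("all waves must be symptom_matrix objects")
  labs <- vapply(waves, `[[`, "", "wave_label")
  if (anyDuplicated(labs)) stop("wave labels must be unique")
  ref <- waves[[1]]$node_labels
  for (w in waves)
    if (!identical(w$node_labels, ref))
      stop("all waves must share identical node labels in identical order")
  names(waves) <- labs
  ids <- lapply(waves, `[[`, "subject_ids")
  aligned <- length(waves) == 1L ||
    all(vapply(ids[-1], function(z) setequal(z, ids[[1]]) &&
                 !anyDuplicated(z), TRUE))
  alignment <- if (aligned) sort(ids[[1]]) else NULL
  structure(list(waves = waves, alignment = alignment), class = "wave_panel")
}

#' @export
print.wave_panel <- function(x, ...) {
  cat(sprintf("<wave_panel> %d wave(s): %s\n", length(x$waves),
              paste(names(x$waves), collapse = ", ")))
  cat(sprintf("items: %s\n", paste(x$waves[[1]]$node_labels, collapse = ", ")))
  cat(if (is.null(x$alignment)) "subjects not aligned across waves\n"
      else sprintf("%d subjects aligned across waves\n", length(x$alignment)))
  invisible(x)
}

#' Load a multi-wave binary symptom panel from CSV files
#'
#' Each wave file is wide-format UTF-8 CSV with a header row, one subject-id
#' column and one column per item. The node-metadata table fixes item order
#' and maps items to diagnostic domains. Rows with any missing item value are
#' dropped (complete-case analysis); the count of dropped rows per wave is
#' reported via [message()] and recorded in the `drop_log` attribute.
#'
#' @param paths character vector of wave CSV paths, in wave order; names are
#'   used as wave labels (default: file base names).
#' @param node_meta path to a CSV with columns `item` and `domain`
#'   (`depression` / `anxiety` / `other`), or a data frame of the same shape.
#' @param id_col name of the subject-id column in the wave files.
#' @param binarize if `TRUE`, wave files may contain 0/1/2 ratings which are
#'   passed through [binarize_items()]; if `FALSE` (default) cells must
#'   already be 0/1.
#' @return A [wave_panel()] with attribute `drop_log` (named integer vector of
#'   dropped-row counts).
#' @export
load_panel <- function(paths, node_meta, id_col = "subject_id",
                       binarize = FALSE) {
  meta <- if (is.character(node_meta)) read.csv(node_meta, stringsAsFactors = FALSE)
          else as.data.frame(node_meta)
  if (!all(c("item", "domain") %in% names(meta)))
    stop("node_meta needs columns 'item' and 'domain'")
  items <- as.character(meta$item)
  labels <- if (is.null(names(paths))) basename(paths) else names(paths)
  drop_log <- integer(length(paths)); names(drop_log) <- labels
  waves <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    d <- read.csv(paths[i], stringsAsFactors = FALSE, check.names = FALSE)
    if (!id_col %in% names(d))
      stop(sprintf("wave '%s': subject-id column '%s' not found", labels[i], id_col))
    miss <- setdiff(items, names(d))
    if (length(miss))
      stop(sprintf("wave '%s': missing item column(s): %s", labels[i],
                   paste(miss, collapse = ", ")))
    vals <- as.matrix(d[, items, drop = FALSE])
    cc <- stats::complete.cases(vals)
    drop_log[i] <- sum(!cc)
    if (drop_log[i] > 0)
      message(sprintf("wave '%s': dropped %d incomplete row(s)", labels[i], drop_log[i]))
    vals <- vals[cc, , drop = FALSE]
    ids <- as.character(d[[id_col]][cc])
    waves[[i]] <- if (binarize)
      binarize_items(vals, node_labels = items, domain_tags = meta$domain,
                     subject_ids = ids, wave_label = labels[i])
    else
      symptom_matrix(vals, node_labels = items, domain_tags = meta$domain,
                     subject_ids = ids, wave_label = labels[i])
  }
  structure(wave_panel(waves), drop_log = drop_log)
}

#' Write a multi-wave panel to CSV files
#'
#' Inverse of [load_panel()]: one wide-format CSV per wave (subject-id column
#' first, items in node-metadata order) plus a `node_meta.csv` mapping items
#' to domains. `load_panel()` on the written files reproduces the panel
#' exactly.
#'
#' @param panel a [wave_panel()].
#' @param dir output directory (created if needed).
#' @param id_col name for the subject-id column.
#' @return Named character vector of the written wave-file paths, invisibly;
#'   names are wave labels.
#' @export
write_panel <- function(panel, dir, id_col = "subject_id") {
  stopifnot(inherits(panel, "wave_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(item = panel$waves[[1]]$node_labels,
                     domain = panel$waves[[1]]$domain_tags,
                     stringsAsFactors = FALSE)
  write.csv(meta, file.path(dir, "node_meta.csv"), row.names = FALSE,
            quote = FALSE)
  paths <- vapply(names(panel$waves), function(lb) {
    w <- panel$waves[[lb]]
    d <- data.frame(w$subject_ids, w$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(d)[1] <- id_col
    path <- file.path(dir, sprintf("wave_%s.csv",
                                   gsub("[^A-Za-z0-9._-]", "_", lb)))
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}

omega_of <- function(net) {
  if (inherits(net, "estimated_network")) net$omega_hat
  else if (inherits(net, "ising_params")) net$omega
  else if (is.matrix(net)) net
  else stop("expected a weight matrix, ising_params or estimated_network")
}

check_symmetric <- function(omega, tol = 1e-10) {
  if (nrow(omega) != ncol(omega) || max(abs(omega - t(omega))) > tol)
    stop("weight matrix must be symmetric")
  invisible(omega)
}

#' Write a network to disk
#'
#' Weighted edge lists (CSV: `node_a,node_b,weight`, zero-weight pairs
#' omitted, weights at 15 significant digits) or GraphML (via igraph, full
#' double precision). Both formats round-trip through [read_network()] to
#' better than `1e-9`.
#'
#' @param net a symmetric weight matrix, [ising_params()] or
#'   `estimated_network`.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  omega <- check_symmetric(omega_of(net))
  labels <- colnames(omega)
  if (is.null(labels)) stop("network must carry node labels")
  p <- ncol(omega)
  if (format == "edgelist") {
    ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
    df <- data.frame(node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
                     weight = sprintf("%.15g", omega[ut]),
                     stringsAsFactors = FALSE)
    # header carries the node set so isolated nodes survive the round trip
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# nodes: ", paste(labels, collapse = ";")), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(omega, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- labels
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @inheritParams write_network
#' @return An [ising_params()] with zero thresholds and the recovered weight
#'   matrix.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    first <- readLines(path, n = 1L)
    labels <- strsplit(sub("^# nodes: ", "", first), ";", fixed = TRUE)[[1]]
    df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
    p <- length(labels)
    omega <- matrix(0, p, p, dimnames = list(labels, labels))
    if (nrow(df)) {
      ia <- match(df$node_a, labels); ib <- match(df$node_b, labels)
      if (anyNA(ia) || anyNA(ib)) stop("edge list names unknown nodes")
      omega[cbind(ia, ib)] <- df$weight
      omega[cbind(ib, ia)] <- df$weight
    }
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    omega <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
    labels <- igraph::V(g)$name
    dimnames(omega) <- list(labels, labels)
  }
  ising_params(tau = rep(0, ncol(omega)), omega = omega, node_labels = labels)
}
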