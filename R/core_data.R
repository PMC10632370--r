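#' Gene universe
#'
#' An ordered set of gene identifiers that fixes node positions for every
#' downstream matrix and graph. Positions are 1-based inside R; ordering is
#' stable for the lifetime of a run so that adjacency matrices, feature
#' matrices and label vectors stay aligned.
#'
#' @param genes character vector of gene identifiers.
#' @return An object of class `gene_universe` with elements `genes` and
#'   `index` (named integer lookup gene -> position).
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (anyNA(genes) || any(genes == "")) stop("gene identifiers must be non-missing, non-empty strings")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in universe: ",
                                 paste(utils::head(unique(genes[duplicated(genes)]), 5L), collapse = ", "))
  idx <- seq_along(genes)
  names(idx) <- genes
  structure(list(genes = genes, index = idx), class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_universe <- function(x) length(x$genes)

#' Read a network edge list
#'
#' Reads a tab-separated edge list (columns: source gene, target gene, extra
#' columns ignored) and tags every record with the network name and its
#' directedness. Protein-protein interaction networks are undirected;
#' gene-regulatory networks are directed TF -> target. Self edges in the
#' input are kept as given.
#'
#' @param path path to a TSV file with at least two columns.
#' @param network_name label for the source network.
#' @param directed logical; is the source network directed?
#' @param header logical; if `TRUE` the first line is discarded as a header.
#' @return data.frame with columns `source`, `target`, `network`, `directed`.
#' @export
read_edge_list <- function(path, network_name, directed = FALSE, header = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) >= 1L) lines <- lines[-1L]
  if (length(lines) == 0L) stop("edge list file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", bad[1L] + as.integer(header), " in ", path,
         ": expected >= 2 tab-separated fields")
  }
  data.frame(
    source = vapply(parts, `[[`, character(1L), 1L),
    target = vapply(parts, `[[`, character(1L), 2L),
    network = network_name,
    directed = directed,
    stringsAsFactors = FALSE
  )
}

#' Assemble a typed multi-network gene graph
#'
#' Builds a `gene_graph` from edge records. Undirected records are expanded
#' to two directed edges (one in each direction); directed records are kept
#' one-way. Records with endpoints outside the universe are dropped (and
#' counted); duplicate (source, target) rows within one network are
#' deduplicated. Isolated universe genes are retained: during message
#' passing they are convolved with themselves via the layer's self-loop.
#'
#' @param records data.frame as returned by [read_edge_list()] (possibly
#'   rbind-ed across several networks).
#' @param universe a [gene_universe()].
#' @return `gene_graph`: list with `universe`, `edge_sets` (per network a
#'   2-column integer matrix of directed source -> target positions),
#'   `directed_flags`, and `dropped` (count of out-of-universe records per
#'   network).
#' @export
assemble_graph <- function(records, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  need <- c("source", "target", "network", "directed")
  if (!all(need %in% names(records))) stop("records must have columns: ", paste(need, collapse = ", "))
  edge_sets <- list()
  directed_flags <- logical(0)
  dropped <- integer(0)
  dedup <- integer(0)
  for (nw in unique(records$network)) {
    rec <- records[records$network == nw, , drop = FALSE]
    dir_flag <- rec$directed[1L]
    if (!all(rec$directed == dir_flag)) stop("network '", nw, "' mixes directed and undirected records")
    si <- unname(universe$index[rec$source])
    ti <- unname(universe$index[rec$target])
    keep <- !is.na(si) & !is.na(ti)
    dropped[nw] <- sum(!keep)
    si <- si[keep]; ti <- ti[keep]
    edges <- cbind(source = si, target = ti)
    ndup <- nrow(edges)
    edges <- unique(edges)
    dedup[nw] <- ndup - nrow(edges)
    if (!dir_flag && nrow(edges) > 0L) {
      rev <- cbind(source = edges[, 2L], target = edges[, 1L])
      edges <- unique(rbind(edges, rev))
    }
    edge_sets[[nw]] <- edges
    directed_flags[nw] <- dir_flag
  }
  if (any(dropped > 0L)) {
    message("assemble_graph: dropped ", sum(dropped), " record(s) with endpoints outside the universe")
  }
  structure(list(universe = universe, edge_sets = edge_sets,
                 directed_flags = directed_flags, dropped = dropped,
                 deduplicated = dedup),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat("<gene_graph> ", length(x$universe$genes), " genes, ",
      length(x$edge_sets), " network(s)\n", sep = "")
  for (nw in names(x$edge_sets)) {
    cat("  ", nw, ": ", nrow(x$edge_sets[[nw]]), " directed edges",
        if (x$directed_flags[[nw]]) " (directed source)" else " (undirected source)", "\n", sep = "")
  }
  invisible(x)
}

#' Number of genes in a graph
#' @param graph a `gene_graph`.
#' @return integer node count.
#' @export
n_genes <- function(graph) length(graph$universe$genes)

#' Write a gene graph back to edge-list files
#'
#' One TSV per network (named `<network>.tsv`), undirected networks written
#' with each unordered pair once. Round-trips through [read_edge_list()] and
#' [assemble_graph()].
#'
#' @param graph a `gene_graph`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_edge_lists <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- graph$universe$genes
  paths <- character(0)
  for (nw in names(graph$edge_sets)) {
    e <- graph$edge_sets[[nw]]
    if (!graph$directed_flags[[nw]] && nrow(e) > 0L) {
      keep <- e[, 1L] <= e[, 2L]  # one row per unordered pair; self edges kept
      e <- e[keep, , drop = FALSE]
    }
    path <- file.path(dir, paste0(nw, ".tsv"))
    utils::write.table(data.frame(source = genes[e[, 1L]], target = genes[e[, 2L]]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Resolve the gene universe from a feature table
#'
#' The universe is feature-driven: genes with any missing feature value are
#' excluded, and the positive-label list is intersected with the surviving
#' universe. Exclusion counts are reported via `message()`.
#'
#' @param feature_table data.frame whose first column holds gene identifiers
#'   and remaining columns numeric features.
#' @param label_genes character vector of positive-label gene identifiers.
#' @param label_name tag for the label set (disease/trait).
#' @return list with `universe` ([gene_universe()]), `features` (a
#'   `feature_matrix`), and `labels` (a `label_set` with integer `positives`).
#' @export
resolve_gene_universe <- function(feature_table, label_genes, label_name = "trait") {
  if (ncol(feature_table) < 2L) stop("feature table needs a gene column plus >= 1 feature column")
  ids <- as.character(feature_table[[1L]])
  vals <- feature_table[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) stop("non-numeric feature column(s): ", paste(names(vals)[non_num], collapse = ", "))
  X <- as.matrix(vals)
  complete <- stats::complete.cases(X)
  if (sum(!complete) > 0L) {
    message("resolve_gene_universe: excluded ", sum(!complete), " gene(s) with missing features")
  }
  if (!any(complete)) stop("no genes survive missing-feature filtering")
  ids <- ids[complete]
  X <- X[complete, , drop = FALSE]
  uni <- gene_universe(ids)
  rownames(X) <- ids
  label_genes <- unique(as.character(label_genes))
  present <- label_genes %in% ids
  if (any(!present)) {
    warning(sum(!present), " label gene(s) absent from the feature table were dropped")
  }
  pos <- unname(uni$index[label_genes[present]])
  if (length(pos) == 0L) stop("no positive labels survive universe filtering")
  list(
    universe = uni,
    features = feature_matrix(uni, X, colnames(X)),
    labels = label_set(pos, uni, name = label_name)
  )
}

#' Feature matrix container
#'
#' @param universe a [gene_universe()].
#' @param values numeric matrix, genes x features, rows aligned to universe.
#' @param feature_names optional column names.
#' @return object of class `feature_matrix` with `values`, `feature_names`,
#'   and `scaling` (NULL until [scale_features_robust()] is applied).
#' @export
feature_matrix <- function(universe, values, feature_names = colnames(values)) {
  stopifnot(inherits(universe, "gene_universe"))
  values <- as.matrix(values)
  if (nrow(values) != length(universe$genes)) stop("feature matrix rows must match universe size")
  if (ncol(values) < 1L) stop("feature matrix needs p > 0 features")
  if (anyNA(values)) stop("feature matrix contains missing values")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_names
  rownames(values) <- universe$genes
  structure(list(universe = universe, values = values,
                 feature_names = feature_names, scaling = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " genes x ", ncol(x$values), " features",
      if (!is.null(x$scaling)) " (robust-scaled)" else "", "\n", sep = "")
  invisible(x)
}

#' Label set of known positives
#'
#' @param positives integer vector of gene positions in the universe.
#' @param universe a [gene_universe()].
#' @param name disease/trait tag.
#' @return object of class `label_set`.
#' @export
label_set <- function(positives, universe, name = "trait") {
  positives <- sort(unique(as.integer(positives)))
  if (length(positives) == 0L) stop("label set must be non-empty")
  if (any(positives < 1L | positives > length(universe$genes))) stop("positive index outside the universe")
  structure(list(positives = positives, name = name, universe = universe), class = "label_set")
}

#' Read a positive-label file
#'
#' Plain text, one gene identifier per line; `#` starts a comment.
#'
#' @param path label file path.
#' @return character vector of gene identifiers.
#' @export
read_label_file <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Robust (quantile) feature scaling
#'
#' Centers each feature on its median and scales by the interquartile range
#' (q75 - q25, linear-interpolation quantiles), the usual robust alternative
#' to z-scoring for heavy-tailed inputs such as gene-level GWAS statistics
#' and expression values. Columns with zero IQR are centered only. The
#' per-feature (median, IQR) pairs are recorded in the result's `scaling`
#' field.
#'
#' @param X a [feature_matrix()].
#' @return the scaled `feature_matrix`.
#' @export
scale_features_robust <- function(X) {
  stopifnot(inherits(X, "feature_matrix"))
  if (!is.null(X$scaling)) stop("feature matrix is already scaled")
  med <- apply(X$values, 2L, stats::median)
  q <- apply(X$values, 2L, stats::quantile, probs = c(0.25, 0.75), names = FALSE, type = 7L)
  iqr <- q[2L, ] - q[1L, ]
  denom <- ifelse(iqr == 0, 1, iqr)
  X$values <- sweep(sweep(X$values, 2L, med, "-"), 2L, denom, "/")
  X$scaling <- list(median = med, iqr = iqr)
  X
}
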