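#' Simulation configuration
#'
#' Defines the study conditions for the synthetic benchmark: a latent
#' per-gene "coreness" drives informative features, positive-unlabeled
#' labels whose labeling probability rises toward the extreme of the
#' positive distribution (the probabilistic-gap PU regime), and a
#' validation gene set enriched among planted cores at a target odds ratio.
#'
#' @param n_genes number of genes.
#' @param networks list of network specs, each a list with `name`,
#'   `model` ("erdos-renyi" or "preferential-attachment"), `mean_degree`,
#'   and `directed` flag.
#' @param n_informative_features number of coreness-linked features.
#' @param n_noise_features number of pure-noise features.
#' @param effect_size slope of informative features on coreness.
#' @param core_fraction fraction of genes that are true cores (0, 0.5).
#' @param label_frequency_slope logistic slope (>= 0) of the labeling
#'   probability in coreness; 0 labels cores uniformly at rate 0.5.
#' @param validation_or target odds ratio of validation-set membership for
#'   cores vs non-cores.
#' @param seed integer seed fixing every draw.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       networks = list(list(name = "ppi", model = "erdos-renyi",
                                            mean_degree = 6, directed = FALSE)),
                       n_informative_features = 5,
                       n_noise_features = 5,
                       effect_size = 2,
                       core_fraction = 0.05,
                       label_frequency_slope = 3,
                       validation_or = 5,
                       seed = 1L) {
  stopifnot(n_genes >= 2, n_informative_features >= 1, n_noise_features >= 0,
            core_fraction > 0, core_fraction < 0.5,
            label_frequency_slope >= 0, validation_or > 0, effect_size >= 0)
  for (nw in networks) {
    stopifnot(is.character(nw$name),
              nw$model %in% c("erdos-renyi", "preferential-attachment"),
              nw$mean_degree >= 0, is.logical(nw$directed))
  }
  structure(list(n_genes = as.integer(n_genes), networks = networks,
                 n_informative_features = as.integer(n_informative_features),
                 n_noise_features = as.integer(n_noise_features),
                 effect_size = effect_size, core_fraction = core_fraction,
                 label_frequency_slope = label_frequency_slope,
                 validation_or = validation_or, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate multi-network gene graphs
#'
#' Draws one network per configured spec: Erdos-Renyi for homogeneous
#' degrees, or preferential attachment for the heavy-tailed degree
#' distributions typical of protein-interaction maps. Undirected models
#' are expanded symmetrically; directed models keep one direction
#' (regulator -> target). Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `gene_graph` over the simulated universe.
#' @export
simulate_networks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  uni <- gene_universe(sim_gene_names(cfg$n_genes))
  set.seed(cfg$seed)
  records <- NULL
  for (nw in cfg$networks) {
    n <- cfg$n_genes
    if (nw$mean_degree <= 0) {
      el <- matrix(integer(0), ncol = 2L)
    } else if (nw$model == "erdos-renyi") {
      # mean total degree = mean_degree regardless of directedness
      p <- if (nw$directed) nw$mean_degree / (2 * (n - 1)) else nw$mean_degree / (n - 1)
      g <- igraph::sample_gnp(n, min(p, 1), directed = nw$directed)
      el <- igraph::as_edgelist(g, names = FALSE)
    } else {
      g <- igraph::sample_pa(n, m = max(1L, round(nw$mean_degree / 2)), directed = nw$directed)
      el <- igraph::as_edgelist(g, names = FALSE)
    }
    if (nrow(el) > 0L) {
      rec <- data.frame(source = uni$genes[el[, 1L]], target = uni$genes[el[, 2L]],
                        network = nw$name, directed = nw$directed,
                        stringsAsFactors = FALSE)
      records <- rbind(records, rec)
    }
  }
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(source = character(0), target = character(0),
                          network = character(0), directed = logical(0))
    g <- structure(list(universe = uni, edge_sets = stats::setNames(
      lapply(cfg$networks, function(nw) matrix(integer(0), ncol = 2L,
                                               dimnames = list(NULL, c("source", "target")))),
      vapply(cfg$networks, `[[`, character(1L), "name")),
      directed_flags = stats::setNames(vapply(cfg$networks, `[[`, logical(1L), "directed"),
                                       vapply(cfg$networks, `[[`, character(1L), "name")),
      dropped = integer(0), deduplicated = integer(0)), class = "gene_graph")
    return(g)
  }
  graph <- assemble_graph(records, uni)
  # ensure every configured network has an (possibly empty) edge set
  for (nw in cfg$networks) {
    if (is.null(graph$edge_sets[[nw$name]])) {
      graph$edge_sets[[nw$name]] <- matrix(integer(0), ncol = 2L,
                                           dimnames = list(NULL, c("source", "target")))
      graph$directed_flags[nw$name] <- nw$directed
    }
  }
  graph
}

#' Draw the latent coreness
#'
#' Standard-normal latent score per gene; deterministic under the config
#' seed (offset so it does not reuse the network draw stream).
#'
#' @param cfg a [sim_config()].
#' @return numeric vector of length `n_genes`.
#' @export
simulate_coreness <- function(cfg) {
  set.seed(cfg$seed + 1L)
  stats::rnorm(cfg$n_genes)
}

#' Simulate node features driven by coreness
#'
#' Informative columns are `effect_size * coreness + N(0,1)` noise; noise
#' columns are pure unit Gaussians. Column names mark informativeness
#' (`inf1..`, `noise1..`) for test introspection.
#'
#' @param cfg a [sim_config()].
#' @param coreness per-gene latent reals from [simulate_coreness()].
#' @return a `feature_matrix` over the simulated universe (unscaled).
#' @export
simulate_features <- function(cfg, coreness) {
  stopifnot(length(coreness) == cfg$n_genes)
  uni <- gene_universe(sim_gene_names(cfg$n_genes))
  set.seed(cfg$seed + 2L)
  p_inf <- cfg$n_informative_features
  p_noise <- cfg$n_noise_features
  X <- matrix(stats::rnorm(cfg$n_genes * (p_inf + p_noise)), nrow = cfg$n_genes)
  X[, seq_len(p_inf)] <- X[, seq_len(p_inf), drop = FALSE] + cfg$effect_size * coreness
  nm <- c(if (p_inf > 0) paste0("inf", seq_len(p_inf)),
          if (p_noise > 0) paste0("noise", seq_len(p_noise)))
  feature_matrix(uni, X, nm)
}

#' Assign positive-unlabeled labels with a probabilistic gap
#'
#' True cores are the top `core_fraction` of the coreness distribution.
#' Each core is labeled independently with probability
#' `plogis(label_frequency_slope * (coreness - core threshold))`, so the
#' label frequency rises toward the extreme of the positive distribution;
#' non-cores are never labeled. At least one labeled positive is
#' guaranteed (labels are re-drawn if the first draw labels none).
#'
#' @param cfg a [sim_config()].
#' @param coreness per-gene latent reals.
#' @return object of class `planted_truth`: list with `coreness`,
#'   `true_cores`, `labeled_positives`, `hidden_positives`,
#'   `core_threshold`.
#' @export
assign_pu_labels <- function(cfg, coreness) {
  stopifnot(length(coreness) == cfg$n_genes)
  n_core <- max(1L, round(cfg$core_fraction * cfg$n_genes))
  ord <- order(coreness, decreasing = TRUE)
  true_cores <- sort(ord[seq_len(n_core)])
  thr <- min(coreness[true_cores])
  slope <- min(cfg$label_frequency_slope, 1e6)  # cap: slope -> Inf gives a sharp cut
  p_label <- stats::plogis(slope * (coreness[true_cores] - thr))
  set.seed(cfg$seed + 3L)
  lab <- stats::runif(n_core) < p_label
  while (!any(lab)) lab <- stats::runif(n_core) < p_label
  labeled <- true_cores[lab]
  structure(list(coreness = coreness, true_cores = true_cores,
                 labeled_positives = labeled,
                 hidden_positives = setdiff(true_cores, labeled),
                 core_threshold = thr),
            class = "planted_truth")
}

#' Simulate a validation gene set enriched among cores
#'
#' Membership probabilities are chosen so the expected odds ratio of
#' membership for cores vs non-cores equals `cfg$validation_or`: non-cores
#' are members with base probability 0.1, cores with odds multiplied by
#' the target OR.
#'
#' @param cfg a [sim_config()].
#' @param truth a `planted_truth` from [assign_pu_labels()].
#' @param base_rate membership probability for non-cores.
#' @return sorted integer vector of member gene positions.
#' @export
simulate_validation_geneset <- function(cfg, truth, base_rate = 0.1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (length(truth$true_cores) == 0L) stop("empty core set: cannot place validation enrichment")
  odds0 <- base_rate / (1 - base_rate)
  odds1 <- odds0 * cfg$validation_or
  p1 <- odds1 / (1 + odds1)
  p <- rep(base_rate, cfg$n_genes)
  p[truth$true_cores] <- p1
  set.seed(cfg$seed + 4L)
  sort(which(stats::runif(cfg$n_genes) < p))
}

#' Simulate a complete PU dataset
#'
#' Convenience wrapper running all generator stages under one seed:
#' networks, coreness, features, PU labels, validation set.
#'
#' @param cfg a [sim_config()].
#' @return list with `graph`, `features` (unscaled), `labels`
#'   (a `label_set` of the labeled positives), `truth`, `validation`.
#' @export
simulate_pu_data <- function(cfg) {
  graph <- simulate_networks(cfg)
  coreness <- simulate_coreness(cfg)
  features <- simulate_features(cfg, coreness)
  truth <- assign_pu_labels(cfg, coreness)
  validation <- simulate_validation_geneset(cfg, truth)
  list(graph = graph,
       features = features,
       labels = label_set(truth$labeled_positives, graph$universe, name = "simulated"),
       truth = truth,
       validation = validation)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the edge-list TSVs, the feature TSV, the label file, a truth TSV
#' (gene, coreness, is_core, is_labeled, in_validation_set) and the config
#' as YAML -- the same formats the readers in this package consume.
#'
#' @param sim result of [simulate_pu_data()].
#' @param cfg the [sim_config()] used.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_lists(sim$graph, dir)
  genes <- sim$graph$universe$genes
  feat <- data.frame(gene = genes, sim$features$values, check.names = FALSE)
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(genes[sim$labels$positives], file.path(dir, "labels.txt"))
  truth <- data.frame(gene = genes, coreness = sim$truth$coreness,
                      is_core = seq_along(genes) %in% sim$truth$true_cores,
                      is_labeled = seq_along(genes) %in% sim$truth$labeled_positives,
                      in_validation_set = seq_along(genes) %in% sim$validation)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
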