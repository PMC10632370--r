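# Config-driven end-to-end runs. The YAML config either points at input
# files (edge lists, feature table, label file) or at a simulation block;
# the experiment trains the nested cross-validation ensemble and writes
# plain-text artifacts plus a checksum manifest.

experiment_config_keys <- list(
  inputs = c("networks", "feature_table", "label_file", "simulate"),
  top = c("inputs", "classifier", "loss", "ensemble", "seed", "output_dir",
          "training", "embedding")
)

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), experiment_config_keys$top)
  if (length(unknown) > 0L) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$inputs)) stop("config needs an 'inputs' block")
  unknown_in <- setdiff(names(cfg$inputs), experiment_config_keys$inputs)
  if (length(unknown_in) > 0L) stop("unknown inputs key(s): ", paste(unknown_in, collapse = ", "))
  has_files <- !is.null(cfg$inputs$feature_table)
  has_sim <- !is.null(cfg$inputs$simulate)
  if (has_files == has_sim) stop("inputs must contain either file paths or a 'simulate' block")
  invisible(cfg)
}

load_experiment_inputs <- function(cfg) {
  if (!is.null(cfg$inputs$simulate)) {
    s <- cfg$inputs$simulate
    networks <- lapply(s$networks, function(nw) {
      list(name = nw$name, model = nw$model %||% "erdos-renyi",
           mean_degree = nw$mean_degree %||% 6, directed = isTRUE(nw$directed))
    })
    simcfg <- sim_config(
      n_genes = s$n_genes %||% 2000,
      networks = if (length(networks) > 0) networks else
        list(list(name = "ppi", model = "erdos-renyi", mean_degree = 6, directed = FALSE)),
      n_informative_features = s$n_informative_features %||% 5,
      n_noise_features = s$n_noise_features %||% 5,
      effect_size = s$effect_size %||% 2,
      core_fraction = s$core_fraction %||% 0.05,
      label_frequency_slope = s$label_frequency_slope %||% 3,
      validation_or = s$validation_or %||% 5,
      seed = s$seed %||% cfg$seed %||% 1L
    )
    sim <- simulate_pu_data(simcfg)
    return(list(graph = sim$graph, features = sim$features, labels = sim$labels,
                truth = sim$truth, validation = sim$validation))
  }
  records <- NULL
  for (nw in cfg$inputs$networks) {
    records <- rbind(records, read_edge_list(nw$path, nw$name,
                                             directed = isTRUE(nw$directed),
                                             header = isTRUE(nw$header)))
  }
  ft <- utils::read.delim(cfg$inputs$feature_table, check.names = FALSE)
  lab <- read_label_file(cfg$inputs$label_file)
  resolved <- resolve_gene_universe(ft, lab)
  graph <- assemble_graph(records, resolved$universe)
  list(graph = graph, features = resolved$features, labels = resolved$labels,
       truth = NULL, validation = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment end to end
#'
#' Reads (or simulates) the inputs, scales features, optionally computes
#' random-walk embeddings, fits the [pu_ensemble()], and writes the
#' consensus table, per-fold threshold diagnostics, a resolved-config
#' snapshot, a log and a checksum manifest.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param overwrite allow writing into an existing non-empty output
#'   directory.
#' @return invisibly, a list with the fitted `fit`, the `inputs`, and the
#'   output file `manifest`.
#' @export
run_experiment <- function(config, overwrite = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$output_dir %||% "pucore_run"
  inputs <- load_experiment_inputs(cfg)
  ens <- cfg$ensemble %||% list()
  tr <- cfg$training %||% list()
  loss <- cfg$loss %||% list()
  emb <- cfg$embedding %||% list()
  fit <- pu_ensemble(
    inputs$graph, inputs$features, inputs$labels,
    classifier = cfg$classifier %||% "mlp",
    m = ens$m %||% 11L, n = ens$n %||% 10L,
    cfg = loss_config(d = loss$d %||% 10L, a = loss$a %||% 2),
    B = ens$B %||% 1000L,
    fdr_level = ens$fdr_level %||% 0.05,
    score_threshold = ens$score_threshold %||% 0.7,
    embedding_control = do.call(n2v_control, emb),
    lr = tr$lr %||% 1e-3,
    max_epochs = tr$max_epochs %||% 1000L,
    patience = tr$patience %||% 100L,
    seed = seed, keep_models = isTRUE(tr$keep_models %||% FALSE)
  )
  manifest <- write_outputs(fit, out_dir, config = cfg, overwrite = overwrite)
  invisible(list(fit = fit, inputs = inputs, manifest = manifest))
}

#' Write ensemble artifacts to a directory
#'
#' Emits `consensus.tsv` (gene, cs, flag; known positives carry `NA`),
#' `threshold_diagnostics.tsv` (per fold and concordance bin: observed
#' overlap, background mean/sd, p, FDR, chosen flag), `config.yaml`, a
#' run log, and `manifest.tsv` with an md5 checksum per file.
#'
#' @param fit a fitted `pu_ensemble`.
#' @param dir output directory.
#' @param config resolved config list to snapshot (optional).
#' @param overwrite allow reuse of an existing non-empty directory.
#' @return data.frame manifest (file, md5).
#' @export
write_outputs <- function(fit, dir, config = NULL, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("output directory ", dir, " exists and is not empty (use overwrite = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cons <- predict(fit, type = "consensus")
  utils::write.table(cons, file.path(dir, "consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$diagnostics, file.path(dir, "threshold_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) yaml::write_yaml(config, file.path(dir, "config.yaml"))
  log_lines <- c(
    paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO run complete"),
    paste0("seed=", fit$seed, " m=", fit$plan$m, " n=", fit$plan$n,
           " B=", fit$B, " classifier=", fit$spec$mp_kind),
    paste0("fold ", seq_len(fit$plan$m), ": threshold=",
           ifelse(is.na(fit$thresholds), "none", fit$thresholds),
           " candidates=", vapply(fit$consensus$candidate_sets, length, integer(1L)))
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  files <- list.files(dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f) unname(tools::md5sum(f)), character(1L)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
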