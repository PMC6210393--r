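default_params <- function() {
  list(n_top = 400L, runs = 10L, min_count = 6L, rank_top = 100L,
       damping = 0.85, tol = 0.005, max_iter = 1000L,
       normalize_axis = "gene", na_policy = "drop",
       selection_mode = "paper", n_folds = 10L, evaluate = TRUE,
       gan = list(epochs = 2L, batch_size = 1L, learning_rate = 2e-4,
                  hidden_units = 256L, init_range = 0.1,
                  generator_activation = "relu"),
       mlp = list(hidden = 64L, l2 = 1e-3, epochs = 300L,
                  learning_rate = 1e-2))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or already-parsed list) pipeline configuration, applies
#' defaults for every omitted stage parameter, rejects unknown keys and
#' out-of-range values, and checks that referenced files exist. The
#' validated configuration is idempotent: validating the echoed effective
#' configuration reproduces it.
#'
#' Layout: top-level keys `seed`, `out`, `data`, `params`. `data` holds
#' either `simulate:` (arguments of [sim_config()]) or `layers:` (named
#' layer-tag -> TSV path map) plus `network:` (edge list path) and
#' `clinical:` (`path`, optional `threshold` days and `deceased_policy`).
#' `params` holds any of the [omnirank()] stage parameters with nested
#' `gan:` and `mlp:` blocks.
#'
#' @param cfg file path to a YAML document, or a list.
#' @return validated configuration of class `omnirank_config`.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stop_config("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop_config("config must be a YAML mapping")
  known_top <- c("seed", "out", "data", "params")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$data)) stop_config("config requires a 'data' block")

  d <- cfg$data
  unknown <- setdiff(names(d), c("simulate", "layers", "network", "clinical"))
  if (length(unknown))
    stop_config("unknown data keys: ", paste(unknown, collapse = ", "))
  if (is.null(d$simulate)) {
    if (is.null(d$layers) || is.null(d$network) || is.null(d$clinical))
      stop_config("data needs either 'simulate' or all of ",
                  "'layers', 'network', 'clinical'")
    bad <- setdiff(names(d$layers), LAYER_TAGS)
    if (length(bad))
      stop_config("unknown layer tags: ", paste(bad, collapse = ", "))
    clin_path <- if (is.list(d$clinical)) d$clinical$path else d$clinical
    paths <- c(unlist(d$layers), d$network, clin_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_config("missing data files: ", paste(missing, collapse = ", "))
  } else {
    sim_args <- d$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad))
      stop_config("unknown simulate keys: ", paste(bad, collapse = ", "))
    d$simulate <- sim_args
  }

  p <- default_params()
  user <- cfg$params %||% list()
  unknown <- setdiff(names(user), names(p))
  if (length(unknown))
    stop_config("unknown params keys: ", paste(unknown, collapse = ", "))
  for (blk in c("gan", "mlp")) {
    bad <- setdiff(names(user[[blk]]), names(p[[blk]]))
    if (length(bad))
      stop_config("unknown ", blk, " keys: ", paste(bad, collapse = ", "))
    if (!is.null(user[[blk]]))
      user[[blk]] <- modifyList(p[[blk]], user[[blk]])
  }
  p <- modifyList(p, user)
  if (p$min_count > p$runs)
    stop_config("'min_count' must satisfy min_count <= runs (b <= t); got b = ",
                p$min_count, ", t = ", p$runs)
  if (p$damping <= 0 || p$damping >= 1)
    stop_config("'damping' must lie strictly in (0, 1)")
  if (p$tol <= 0) stop_config("'tol' must be positive")
  if (p$n_folds < 2) stop_config("'n_folds' must be at least 2")

  out <- list(seed = as.integer(cfg$seed %||% 1L), out = cfg$out,
              data = d, params = p)
  class(out) <- "omnirank_config"
  out
}

load_cohort <- function(cfg) {
  d <- cfg$data
  if (!is.null(d$simulate)) {
    args <- d$simulate
    if (is.null(args$seed)) args$seed <- cfg$seed
    return(simulate_cohort(do.call(sim_config, args)))
  }
  layers <- lapply(d$layers, read_omics_tsv)
  network <- read_edge_list(d$network)
  clin <- d$clinical
  labels <- if (is.list(clin))
    read_clinical(clin$path, threshold = clin$threshold,
                  deceased_policy = clin$deceased_policy %||% "exclude")
  else read_clinical(clin)
  list(layers = layers, network = network, labels = labels)
}

#' Run the full pipeline from a configuration
#'
#' Loads (or simulates) the cohort described by a validated configuration,
#' fits [omnirank()], and writes all stage outputs plus the effective
#' configuration and a metrics JSON to the output directory.
#'
#' @param cfg a path, list, or [validate_config()] result.
#' @param out output directory; overrides `cfg$out`.
#' @return the [omnirank()] fit, invisibly.
#' @export
run_pipeline <- function(cfg, out = NULL) {
  if (!inherits(cfg, "omnirank_config")) cfg <- validate_config(cfg)
  out <- out %||% cfg$out
  if (is.null(out)) stop_config("an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ch <- load_cohort(cfg)
  p <- cfg$params
  fit <- omnirank(ch$layers, ch$network, ch$labels,
                  n_top = p$n_top, runs = p$runs, min_count = p$min_count,
                  rank_top = p$rank_top, damping = p$damping, tol = p$tol,
                  max_iter = p$max_iter,
                  gan = do.call(gan_config, p$gan),
                  normalize_axis = p$normalize_axis,
                  na_policy = p$na_policy, evaluate = p$evaluate,
                  n_folds = p$n_folds, selection_mode = p$selection_mode,
                  hidden = p$mlp$hidden, l2 = p$mlp$l2,
                  mlp_epochs = p$mlp$epochs,
                  mlp_lr = p$mlp$learning_rate, seed = cfg$seed)
  write_fit_outputs(fit, out)
  yaml::write_yaml(list(seed = cfg$seed, out = out, data = cfg$data,
                        params = cfg$params),
                   file.path(out, "config_effective.yaml"))
  invisible(fit)
}

write_fit_outputs <- function(fit, out) {
  tst <- do.call(rbind, lapply(names(fit$quartet$tstats), function(tag) {
    tt <- fit$quartet$tstats[[tag]]
    tt$layer <- tag
    tt$selected <- tt$gene %in% fit$quartet$sets[[tag]]
    tt
  }))
  write.table(tst, file.path(out, "tstats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_edge_list(fit$network$edges, file.path(out, "network_reconstructed.tsv"))
  W <- fit$mean_weights
  up <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  write.table(data.frame(gene_a = rownames(W)[up[, 1]],
                         gene_b = colnames(W)[up[, 2]],
                         weight = W[up]),
              file.path(out, "edge_weights_mean.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bm <- fit$biomarkers
  write.table(data.frame(gene = bm,
                         appearance_count = fit$selection$counts[bm],
                         mean_PR = fit$mean_scores[bm],
                         layers = vapply(fit$assignment$layers[bm], paste,
                                         character(1), collapse = ","),
                         provenance = fit$assignment$provenance[bm]),
              file.path(out, "biomarkers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ft <- data.frame(sample_id = rownames(fit$table$x), fit$table$x,
                   label = as.character(fit$table$y), check.names = FALSE)
  write.table(ft, file.path(out, "feature_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  metrics <- list(n_biomarkers = length(bm),
                  d_real = mean(fit$gan_evals[, "d_real"]),
                  d_fake = mean(fit$gan_evals[, "d_fake"]),
                  d_combined = mean(fit$gan_evals[, "d_combined"]))
  if (!is.null(fit$evaluation))
    metrics <- c(metrics,
                 list(mean_auc = fit$evaluation$mean_auc,
                      pooled_auc = fit$evaluation$pooled_auc,
                      fold_auc = fit$evaluation$fold_auc,
                      selection_mode = fit$evaluation$mode))
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
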