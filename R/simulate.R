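#' Configuration for a synthetic multi-omics cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The defaults describe a small pancreatic-cancer-like cohort: 200 genes on
#' a preferential-attachment interaction network, 20 good- and 20
#' poor-prognosis samples, four omics layers, and 20 planted prognostic genes
#' carrying a standardized mean shift of 2 in one designated layer each.
#'
#' @param n_genes number of genes (network nodes), at least 2.
#' @param n_samples_good,n_samples_poor per-group sample counts.
#' @param n_layers number of omics layers, 1 to 4; layers take the tags
#'   `"mRNA"`, `"CNV"`, `"methylation"`, `"SNP"` in that order.
#' @param planted_genes number of prognosis-associated genes to plant.
#' @param effect_size standardized difference between poor- and good-group
#'   means for a planted gene in its signal layer (unitless, >= 0).
#' @param pa_m preferential-attachment parameter: edges added per new node.
#' @param noise_sd standard deviation of the Gaussian background noise.
#' @param planted_mode `"module"` plants the genes as a connected network
#'   neighbourhood (a breadth-first ball around a random seed vertex),
#'   mirroring the pathway-clustering of real disease genes that network
#'   propagation exploits; `"random"` scatters them uniformly.
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   cohorts.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_genes = 200L, n_samples_good = 20L,
                       n_samples_poor = 20L, n_layers = 4L,
                       planted_genes = 20L, effect_size = 2,
                       pa_m = 2L, noise_sd = 1,
                       planted_mode = c("module", "random"),
                       seed = 1L) {
  planted_mode <- match.arg(planted_mode)
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_good = as.integer(n_samples_good),
              n_samples_poor = as.integer(n_samples_poor),
              n_layers = as.integer(n_layers),
              planted_genes = as.integer(planted_genes),
              effect_size = as.numeric(effect_size),
              pa_m = as.integer(pa_m),
              noise_sd = as.numeric(noise_sd),
              planted_mode = planted_mode,
              seed = as.integer(seed))
  counts <- c("n_genes", "n_samples_good", "n_samples_poor", "n_layers",
              "planted_genes", "pa_m")
  for (k in counts) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L)
      stop_config("sim_config: '", k, "' must be a positive count")
  }
  if (cfg$n_genes < 2L)
    stop_config("sim_config: 'n_genes' must be at least 2")
  if (cfg$n_layers > 4L)
    stop_config("sim_config: 'n_layers' must be between 1 and 4")
  if (cfg$planted_genes > cfg$n_genes)
    stop_config("sim_config: 'planted_genes' must not exceed 'n_genes'")
  if (cfg$effect_size < 0)
    stop_config("sim_config: 'effect_size' must be >= 0")
  if (cfg$noise_sd <= 0)
    stop_config("sim_config: 'noise_sd' must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic gene-interaction network
#'
#' Grows an undirected, simple, connected scale-free-like graph over
#' `cfg$n_genes` labelled genes by Barabasi-Albert preferential attachment
#' (each new node attaches `pa_m` edges to existing nodes with probability
#' proportional to degree). The right-skewed degree distribution reproduces
#' the hub dominance that weighted PageRank is meant to moderate.
#'
#' @param cfg a [sim_config()].
#' @return a two-column data frame (`from`, `to`) of undirected edges over
#'   gene identifiers `g0001`, `g0002`, ...
#' @export
generate_network <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("cfg must be a sim_config")
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_genes, m = cfg$pa_m, directed = FALSE,
                         algorithm = "psumtree")
  ids <- gene_ids(cfg$n_genes)
  el <- igraph::as_edgelist(g, names = FALSE)
  # orient each undirected edge low -> high for a canonical representation
  lo <- pmin(el[, 1], el[, 2])
  hi <- pmax(el[, 1], el[, 2])
  ord <- order(lo, hi)
  data.frame(from = ids[lo[ord]], to = ids[hi[ord]],
             stringsAsFactors = FALSE)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic multi-omics cohort on a given network
#'
#' Each layer is a genes-by-samples matrix of Gaussian noise with standard
#' deviation `noise_sd`. Every planted gene receives a mean shift of
#' `effect_size * noise_sd` between poor and good samples in exactly one
#' designated signal layer (assigned round-robin across layers), so planted
#' genes carry a large |t| in that layer only. The ground truth maps each
#' planted gene to its signal layer.
#'
#' @param cfg a [sim_config()].
#' @param network edge data frame from [generate_network()]; must cover
#'   `cfg$n_genes` genes.
#' @return an object of class `synthetic_cohort`: a list with `layers`
#'   (named list of genes x samples matrices), `network` (edge data frame),
#'   `labels` (named factor, levels `good`/`poor`), `truth` (data frame
#'   `gene`, `layer`) and `config`.
#' @export
generate_omics <- function(cfg, network) {
  if (!inherits(cfg, "sim_config")) stop_config("cfg must be a sim_config")
  ids <- gene_ids(cfg$n_genes)
  net_genes <- unique(c(network$from, network$to))
  if (!all(net_genes %in% ids))
    stop_config("network contains genes outside the configured gene set")
  set.seed(cfg$seed + 1L)

  tags <- LAYER_TAGS[seq_len(cfg$n_layers)]
  samples <- c(sprintf("s_good_%03d", seq_len(cfg$n_samples_good)),
               sprintf("s_poor_%03d", seq_len(cfg$n_samples_poor)))
  labels <- factor(rep(c("good", "poor"),
                       c(cfg$n_samples_good, cfg$n_samples_poor)),
                   levels = c("good", "poor"))
  names(labels) <- samples
  n_s <- length(samples)

  planted <- pick_planted(cfg, network, ids)
  signal_layer <- tags[(seq_along(planted) - 1L) %% length(tags) + 1L]

  layers <- lapply(tags, function(tag) {
    m <- matrix(rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
                nrow = cfg$n_genes, ncol = n_s,
                dimnames = list(ids, samples))
    shift_genes <- planted[signal_layer == tag]
    if (length(shift_genes) && cfg$effect_size > 0) {
      poor <- labels == "poor"
      m[shift_genes, poor] <- m[shift_genes, poor] +
        cfg$effect_size * cfg$noise_sd
    }
    m
  })
  names(layers) <- tags

  structure(list(layers = layers, network = network, labels = labels,
                 truth = data.frame(gene = planted, layer = signal_layer,
                                    stringsAsFactors = FALSE),
                 config = cfg),
            class = "synthetic_cohort")
}

# choose planted genes either as a connected neighbourhood (breadth-first
# ball around a random non-hub seed vertex) or uniformly at random
pick_planted <- function(cfg, network, ids) {
  if (cfg$planted_genes == 0L) return(character(0))
  if (cfg$planted_mode == "random")
    return(sort(sample(ids, cfg$planted_genes)))
  g <- igraph::graph_from_data_frame(network, directed = FALSE,
                                     vertices = ids)
  deg <- igraph::degree(g)
  # seed away from the top hubs so the module is not trivially central
  candidates <- names(deg)[deg <= quantile(deg, 0.9)]
  seed_gene <- sample(candidates, 1L)
  ord <- igraph::bfs(g, root = seed_gene, order = TRUE)$order
  sort(igraph::V(g)$name[ord[seq_len(cfg$planted_genes)]])
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_network()] then [generate_omics()].
#'
#' @param cfg a [sim_config()]; pass arguments via [sim_config()].
#' @return a `synthetic_cohort`; see [generate_omics()].
#' @examples
#' coh <- simulate_cohort(sim_config(n_genes = 50, planted_genes = 5, seed = 3))
#' names(coh$layers)
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  generate_omics(cfg, generate_network(cfg))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic multi-omics cohort: %d genes x %d samples (%d good / %d poor)\n",
              cfg$n_genes, length(x$labels), sum(x$labels == "good"),
              sum(x$labels == "poor")))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  network: %d edges; planted genes: %d (effect size %.2g, %s placement)\n",
              nrow(x$network), nrow(x$truth), cfg$effect_size,
              cfg$planted_mode))
  invisible(x)
}

#' Derive binary prognosis labels from survival data
#'
#' A sample whose vital status is alive is labelled `good` when its survival
#' time is at least `threshold` days and `poor` otherwise. Deceased samples
#' are handled by `deceased_policy`: `"exclude"` (default) leaves them
#' unlabelled (`NA`), while `"poor_if_short"` applies the same time threshold
#' to them (short-lived deceased samples are demonstrably poor-prognosis).
#'
#' @param survival_days numeric vector of survival times in days (>= 0).
#' @param vital_status character/factor vector; `"alive"` (case-insensitive)
#'   marks living samples, anything else is treated as deceased.
#' @param threshold labelling criterion in days (> 0), e.g. 365 for the
#'   one-year rule used for pancreatic cohorts.
#' @param deceased_policy `"exclude"` or `"poor_if_short"`.
#' @return a factor with levels `good`/`poor` (NA where excluded), named
#'   after `survival_days` if it has names.
#' @examples
#' label_samples(c(400, 300), c("alive", "alive"), threshold = 365)
#' @export
label_samples <- function(survival_days, vital_status, threshold,
                          deceased_policy = c("exclude", "poor_if_short")) {
  deceased_policy <- match.arg(deceased_policy)
  if (length(survival_days) != length(vital_status))
    stop_validation("survival_days and vital_status lengths differ")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_validation("threshold must be a single positive number of days")
  if (length(survival_days) == 0L)
    return(factor(character(0), levels = c("good", "poor")))
  if (any(is.finite(survival_days) & survival_days < 0))
    stop_validation("negative survival time")
  alive <- tolower(as.character(vital_status)) == "alive"
  lab <- rep(NA_character_, length(survival_days))
  lab[alive] <- ifelse(survival_days[alive] >= threshold, "good", "poor")
  if (deceased_policy == "poor_if_short")
    lab[!alive] <- ifelse(survival_days[!alive] >= threshold, "good", "poor")
  out <- factor(lab, levels = c("good", "poor"))
  names(out) <- names(survival_days)
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes per-layer TSVs (rows = gene IDs, columns = sample IDs), the edge
#' list TSV (two columns, no header), a clinical TSV (`sample_id`, `label`)
#' and a `truth.json` with the planted genes, their signal layers and the
#' effect size. All files are UTF-8 at full numeric precision.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in names(cohort$layers))
    write_omics_tsv(cohort$layers[[tag]], file.path(dir, paste0(tag, ".tsv")))
  write_edge_list(cohort$network, file.path(dir, "network.tsv"))
  clin <- data.frame(sample_id = names(cohort$labels),
                     label = as.character(cohort$labels),
                     stringsAsFactors = FALSE)
  write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted = cohort$truth,
                            effect_size = cohort$config$effect_size,
                            seed = cohort$config$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
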