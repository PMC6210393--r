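#' Fit the network-weighted prognostic biomarker model
#'
#' Runs the full discovery pipeline on a multi-omics cohort: z-score
#' normalization, per-layer pooled t-statistics and top-N gene sets,
#' reconstruction of the functional-interaction network around their union,
#' `runs` repetitions of adversarial edge-weight learning followed by
#' weighted PageRank, stability selection of genes recurring in at least
#' `min_count` runs, omics-source assignment for the selected biomarkers,
#' and (optionally) stratified cross-validated AUC of a rectifier MLP on the
#' assembled feature table.
#'
#' @param layers named list of genes x samples matrices; names are layer
#'   tags among `mRNA`, `CNV`, `methylation`, `SNP` (any subset, order
#'   free). A `synthetic_cohort` may be passed instead, in which case
#'   `network` and `labels` default to its components.
#' @param network interaction network as a `from`/`to` edge data frame.
#' @param labels named factor of per-sample `good`/`poor` labels; samples
#'   with NA labels are dropped.
#' @param n_top per-layer top-gene cutoff N.
#' @param runs number of adversarial scoring repetitions t.
#' @param min_count stability threshold b (gene kept when it appears in at
#'   least b of t runs); must satisfy b <= t.
#' @param rank_top per-run PageRank cutoff (top genes retained per run).
#' @param damping,tol,max_iter PageRank settings, see [weighted_pagerank()].
#' @param gan a [gan_config()]; its seed is overridden per run by
#'   `seed + run`.
#' @param normalize_axis z-score axis (see [zscore_normalize()]); use
#'   `"none"` when the matrices are already normalized.
#' @param na_policy missing-value policy for t-statistics.
#' @param evaluate logical: run cross-validated AUC evaluation.
#' @param n_folds folds for evaluation.
#' @param selection_mode `"paper"` evaluates the classifier on features
#'   selected once from the full cohort (selection precedes
#'   cross-validation); `"nested"` refits the entire selection pipeline
#'   inside each training fold, which is the leakage-free protocol.
#' @param hidden,l2,mlp_epochs,mlp_lr classifier settings, see [mlp_fit()].
#' @param seed master seed for the run sequence, folds and classifier.
#' @return an object of class `omnirank`; see [summary.omnirank()].
#' @examples
#' coh <- simulate_cohort(sim_config(n_genes = 60, planted_genes = 6,
#'                                   n_layers = 2, seed = 2))
#' fit <- omnirank(coh, n_top = 12, runs = 2, min_count = 1, rank_top = 10,
#'                 gan = gan_config(epochs = 2), evaluate = FALSE)
#' coef(fit)
#' @export
omnirank <- function(layers, network = NULL, labels = NULL,
                     n_top = 400L, runs = 10L, min_count = 6L,
                     rank_top = 100L, damping = 0.85, tol = 0.005,
                     max_iter = 1000L, gan = gan_config(),
                     normalize_axis = c("gene", "sample", "none"),
                     na_policy = "drop", evaluate = TRUE, n_folds = 10L,
                     selection_mode = c("paper", "nested"),
                     hidden = 64L, l2 = 1e-3, mlp_epochs = 300L,
                     mlp_lr = 1e-2, seed = 1L) {
  normalize_axis <- match.arg(normalize_axis)
  selection_mode <- match.arg(selection_mode)
  if (inherits(layers, "synthetic_cohort")) {
    network <- network %||% layers$network
    labels <- labels %||% layers$labels
    layers <- layers$layers
  }
  if (is.null(network) || is.null(labels))
    stop_validation("network and labels are required")
  if (min_count > runs)
    stop_validation("min_count b (", min_count,
                    ") must not exceed runs t (", runs, ")")
  keep <- !is.na(labels)
  labels <- labels[keep]
  layers <- lapply(layers, function(m)
    m[, intersect(colnames(m), names(labels)), drop = FALSE])

  p <- list(n_top = n_top, runs = runs, min_count = min_count,
            rank_top = rank_top, damping = damping, tol = tol,
            max_iter = max_iter, gan = gan,
            normalize_axis = normalize_axis, na_policy = na_policy,
            seed = as.integer(seed))
  core <- fit_core(layers, network, labels, p)

  evaluation <- NULL
  if (evaluate) {
    evaluation <- if (selection_mode == "paper") {
      cv <- crossval_auc(core$table, n_folds = n_folds, hidden = hidden,
                         l2 = l2, epochs = mlp_epochs,
                         learning_rate = mlp_lr, seed = seed)
      c(cv, list(mode = "paper"))
    } else {
      nested_cv(layers, network, labels, p, n_folds = n_folds,
                hidden = hidden, l2 = l2, mlp_epochs = mlp_epochs,
                mlp_lr = mlp_lr, seed = seed)
    }
  }
  final_model <- mlp_fit(core$table$x, core$table$y, hidden = hidden,
                         l2 = l2, epochs = mlp_epochs,
                         learning_rate = mlp_lr, seed = seed)
  structure(c(core, list(evaluation = evaluation,
                         final_model = final_model,
                         params = c(p, list(n_folds = n_folds,
                                            selection_mode = selection_mode,
                                            hidden = hidden, l2 = l2,
                                            mlp_epochs = mlp_epochs,
                                            mlp_lr = mlp_lr)),
                         call = match.call())),
            class = "omnirank")
}

# the selection pipeline proper: everything up to the feature table
fit_core <- function(layers, network, labels, p) {
  norm_layers <- if (p$normalize_axis == "none") layers
                 else lapply(layers, zscore_normalize, axis = p$normalize_axis)
  quartet <- gene_set_quartet(norm_layers, labels, n_top = p$n_top,
                              na_policy = p$na_policy)
  net <- reconstruct_network(network, quartet)
  real <- build_real_vectors(norm_layers, quartet, net)
  n <- length(net$nodes)

  run_tops <- vector("list", p$runs)
  score_sum <- setNames(numeric(n), net$nodes)
  gan_evals <- matrix(NA_real_, p$runs, 3,
                      dimnames = list(NULL, c("d_real", "d_fake",
                                              "d_combined")))
  mean_weights <- matrix(0, n, n, dimnames = dimnames(net$A))
  for (r in seq_len(p$runs)) {
    cfg <- p$gan
    cfg$seed <- p$seed + r
    g <- train_gan(real, net$A, cfg)
    pr <- weighted_pagerank(g$weights, d = p$damping, tol = p$tol,
                            max_iter = p$max_iter)
    ord <- order(-pr$scores, names(pr$scores))
    run_tops[[r]] <- names(pr$scores)[ord][seq_len(min(p$rank_top, n))]
    score_sum <- score_sum + pr$scores
    gan_evals[r, ] <- g$eval
    mean_weights <- mean_weights + g$weights / p$runs
  }
  sel <- stability_select(run_tops, b = p$min_count)
  assignment <- assign_feature_source(sel$selected, quartet, net)
  table <- assemble_dataset(assignment, norm_layers, labels)
  list(quartet = quartet, network = net, real_vectors = real,
       layers_normalized = norm_layers,
       norm_stats = lapply(norm_layers, function(m)
         list(center = attr(m, "center"), scale = attr(m, "scale"))),
       run_tops = run_tops, mean_scores = score_sum / p$runs,
       gan_evals = gan_evals, mean_weights = mean_weights,
       selection = sel, biomarkers = sel$selected,
       assignment = assignment, table = table, labels = labels)
}

# leakage-free evaluation: refit the whole selection pipeline per fold
nested_cv <- function(layers, network, labels, p, n_folds, hidden, l2,
                      mlp_epochs, mlp_lr, seed) {
  fold <- suppressWarnings(stratified_folds(labels, n_folds, seed))
  k <- max(fold)
  preds <- rep(NA_real_, length(labels))
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr_samples <- names(labels)[fold != f]
    te_samples <- names(labels)[fold == f]
    tr_layers <- lapply(layers, function(m)
      m[, intersect(colnames(m), tr_samples), drop = FALSE])
    pf <- p
    pf$seed <- p$seed + 1000L * f
    core <- fit_core(tr_layers, network, labels[tr_samples], pf)
    fit <- mlp_fit(core$table$x, core$table$y, hidden = hidden, l2 = l2,
                   epochs = mlp_epochs, learning_rate = mlp_lr,
                   seed = seed + f)
    xte <- assemble_features_raw(core, layers, te_samples, p$normalize_axis)
    pr <- predict(fit, xte)
    preds[fold == f] <- pr
    fold_auc[f] <- auc_rank(pr, labels[te_samples])
  }
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc, na.rm = TRUE),
       pooled_auc = auc_rank(preds, labels), predictions = preds,
       folds = fold, mode = "nested")
}

# build the feature matrix for new samples with training normalization
assemble_features_raw <- function(core, raw_layers, samples, axis) {
  feats <- core$table$features
  x <- matrix(NA_real_, length(samples), nrow(feats),
              dimnames = list(samples,
                              paste0(feats$gene, "@", feats$layer)))
  for (i in seq_len(nrow(feats))) {
    tag <- feats$layer[i]
    g <- feats$gene[i]
    v <- raw_layers[[tag]][g, samples]
    if (axis == "gene") {
      st <- core$norm_stats[[tag]]
      sc <- st$scale[g]
      v <- (v - st$center[g]) / if (is.na(sc) || sc == 0) 1 else sc
    } else if (axis == "sample") {
      sub <- raw_layers[[tag]][, samples, drop = FALSE]
      v <- zscore_normalize(sub, axis = "sample")[g, ]
    }
    x[, i] <- v
  }
  x
}

#' @export
print.omnirank <- function(x, ...) {
  cat("Network-weighted prognostic biomarker fit\n")
  cat(sprintf("  layers: %s; %d samples (%d good / %d poor)\n",
              paste(names(x$quartet$sets), collapse = ", "),
              length(x$labels), sum(x$labels == "good"),
              sum(x$labels == "poor")))
  cat(sprintf("  reconstructed network: %d genes, %d edges\n",
              length(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  stability selection: %d biomarkers (>= %d of %d runs)\n",
              length(x$biomarkers), x$params$min_count, x$params$runs))
  if (!is.null(x$evaluation))
    cat(sprintf("  cross-validated AUC (%s selection): %.3f (mean of %d folds)\n",
                x$evaluation$mode, x$evaluation$mean_auc,
                length(x$evaluation$fold_auc)))
  invisible(x)
}

#' Summarize an omnirank fit
#'
#' @param object an [omnirank()] fit.
#' @param ... unused.
#' @return the object, invisibly; prints layer set sizes, network size,
#'   discriminator equilibrium diagnostics, the selected biomarkers with
#'   appearance counts and mean PageRank, and the evaluation AUCs.
#' @export
summary.omnirank <- function(object, ...) {
  print(object)
  cat("\nPer-layer top sets:\n")
  print(object$quartet)
  cat(sprintf("\nDiscriminator output after training (mean over %d runs):\n",
              nrow(object$gan_evals)))
  cat(sprintf("  real %.3f, generated %.3f, combined %.3f\n",
              mean(object$gan_evals[, "d_real"]),
              mean(object$gan_evals[, "d_fake"]),
              mean(object$gan_evals[, "d_combined"])))
  cat("\nBiomarkers (appearance count, mean PageRank, feature layers):\n")
  bm <- object$biomarkers
  df <- data.frame(
    gene = bm,
    count = object$selection$counts[bm],
    mean_PR = signif(object$mean_scores[bm], 4),
    layers = vapply(object$assignment$layers[bm], paste,
                    character(1), collapse = "+"),
    provenance = object$assignment$provenance[bm],
    row.names = NULL)
  print(df[order(-df$count, -df$mean_PR), ], row.names = FALSE)
  if (!is.null(object$evaluation)) {
    cat("\nPer-fold AUCs:",
        paste(sprintf("%.3f", object$evaluation$fold_auc), collapse = " "),
        sprintf("\nMean AUC %.3f, pooled AUC %.3f\n",
                object$evaluation$mean_auc, object$evaluation$pooled_auc))
  }
  invisible(object)
}

#' @export
coef.omnirank <- function(object, all = FALSE, ...) {
  s <- sort(object$mean_scores, decreasing = TRUE)
  if (!all) s <- s[names(s) %in% object$biomarkers]
  s
}

#' Predict prognosis for new samples
#'
#' Applies the fitted normalization, feature assignment and classifier to
#' new omics matrices.
#'
#' @param object an [omnirank()] fit.
#' @param newdata named list of genes x samples matrices covering the
#'   assigned feature genes (raw scale if the fit normalized internally).
#' @param type `"prob"` for the probability of poor prognosis, `"class"`
#'   for hard labels at 0.5.
#' @param ... unused.
#' @export
predict.omnirank <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "synthetic_cohort")) newdata <- newdata$layers
  samples <- colnames(newdata[[1]])
  x <- assemble_features_raw(object, newdata, samples,
                             object$params$normalize_axis)
  p <- predict(object$final_model, x)
  names(p) <- samples
  if (type == "class")
    return(factor(ifelse(p >= 0.5, "poor", "good"),
                  levels = c("good", "poor")))
  p
}

#' Plot gene scores against network degree
#'
#' Visualizes the hub-moderation behaviour of the learned weighting: mean
#' PageRank score per gene against its degree in the reconstructed network,
#' with stability-selected biomarkers highlighted.
#'
#' @param x an [omnirank()] fit.
#' @param ... passed to [plot()].
#' @export
plot.omnirank <- function(x, ...) {
  deg <- rowSums(x$network$A)
  sel <- names(x$mean_scores) %in% x$biomarkers
  plot(deg, x$mean_scores, log = "x",
       xlab = "degree in reconstructed network",
       ylab = "mean PageRank score",
       col = ifelse(sel, "firebrick", "grey50"),
       pch = ifelse(sel, 19, 1), ...)
  graphics::legend("topleft", legend = c("biomarker", "other"),
                   col = c("firebrick", "grey50"), pch = c(19, 1),
                   bty = "n")
  invisible(x)
}
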