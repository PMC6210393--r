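#' Assign each biomarker its omics feature source
#'
#' A biomarker belonging to one or more of the layer-wise top sets uses the
#' data of every set it belongs to (a gene in both the mRNA and CNV sets
#' contributes both layers as features). A biomarker outside all sets is
#' assigned by neighbour vote: its network neighbours' set memberships are
#' tallied and the layer with the largest count wins; ties resolve by the
#' fixed priority mRNA > CNV > methylation > SNP. A non-member gene whose
#' neighbours are all non-members falls back to the layer where its absolute
#' t-statistic is largest, and is flagged in the provenance.
#'
#' @param biomarkers character vector of gene identifiers (must be network
#'   nodes).
#' @param quartet a [gene_set_quartet()].
#' @param network a [reconstruct_network()] result.
#' @return object of class `feature_assignment`: list with `layers` (named
#'   list: gene -> character vector of layer tags), `provenance` (named
#'   character: `"membership"`, `"neighbor-vote"` or `"fallback"`), and
#'   `votes` (named list of tally vectors for neighbour-vote genes).
#' @export
assign_feature_source <- function(biomarkers, quartet, network) {
  stopifnot(inherits(quartet, "gene_set_quartet"),
            inherits(network, "fis_network"))
  if (!all(biomarkers %in% network$nodes))
    stop_validation("biomarkers outside the network: ",
                    paste(head(setdiff(biomarkers, network$nodes), 5),
                          collapse = ", "))
  tags <- order_tags(names(quartet$sets))
  membership <- lapply(quartet$sets[tags], as.character)
  nbrs <- neighbor_map(network)

  layers <- vector("list", length(biomarkers))
  names(layers) <- biomarkers
  prov <- setNames(character(length(biomarkers)), biomarkers)
  votes <- list()
  for (g in biomarkers) {
    mine <- tags[vapply(membership, function(s) g %in% s, logical(1))]
    if (length(mine)) {
      layers[[g]] <- mine
      prov[g] <- "membership"
      next
    }
    tally <- vapply(membership, function(s) sum(nbrs[[g]] %in% s),
                    integer(1))
    votes[[g]] <- tally
    if (any(tally > 0)) {
      layers[[g]] <- tags[which.max(tally)]  # first max = priority order
      prov[g] <- "neighbor-vote"
    } else {
      layers[[g]] <- fallback_layer(g, quartet, tags)
      prov[g] <- "fallback"
    }
  }
  structure(list(layers = layers, provenance = prov, votes = votes),
            class = "feature_assignment")
}

neighbor_map <- function(network) {
  nb <- c(split(network$edges$to, network$edges$from),
          split(network$edges$from, network$edges$to))
  nb <- tapply(unlist(nb, use.names = FALSE),
               rep(names(nb), lengths(nb)), unique, simplify = FALSE)
  out <- setNames(vector("list", length(network$nodes)), network$nodes)
  out[names(nb)] <- nb
  out
}

# layer with the largest |t| for the gene, priority order on ties/NA
fallback_layer <- function(gene, quartet, tags) {
  tv <- vapply(tags, function(tag) {
    tt <- quartet$tstats[[tag]]
    v <- tt$abs_t[match(gene, tt$gene)]
    if (length(v) == 0L || is.na(v)) -Inf else v
  }, numeric(1))
  if (all(!is.finite(tv))) return(tags[1L])
  tags[which.max(tv)]
}

#' @export
print.feature_assignment <- function(x, ...) {
  cat(sprintf("Feature assignment for %d biomarkers: %s\n",
              length(x$layers),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Assemble the prognosis feature table
#'
#' Produces one column per assigned gene/layer pair, named `gene@layer`,
#' with values taken from the normalized layer matrices; rows follow the
#' label sample order.
#'
#' @param assignment a [assign_feature_source()] result.
#' @param layers named list of normalized genes x samples matrices.
#' @param labels per-sample `good`/`poor` labels (named factor).
#' @return list of class `feature_table`: `x` (samples x features matrix),
#'   `y` (factor labels), `features` (data frame `gene`, `layer`).
#' @export
assemble_dataset <- function(assignment, layers, labels) {
  stopifnot(inherits(assignment, "feature_assignment"))
  samples <- names(labels)
  if (is.null(samples))
    stop_validation("labels must be named by sample id")
  feats <- data.frame(
    gene = rep(names(assignment$layers), lengths(assignment$layers)),
    layer = unlist(assignment$layers, use.names = FALSE),
    stringsAsFactors = FALSE)
  bad <- !mapply(function(g, l) l %in% names(layers) &&
                   g %in% rownames(layers[[l]]),
                 feats$gene, feats$layer)
  if (any(bad))
    stop_validation("unresolvable gene@layer features: ",
                    paste(paste0(feats$gene[bad], "@", feats$layer[bad]),
                          collapse = ", "))
  x <- matrix(NA_real_, length(samples), nrow(feats),
              dimnames = list(samples,
                              paste0(feats$gene, "@", feats$layer)))
  for (i in seq_len(nrow(feats)))
    x[, i] <- layers[[feats$layer[i]]][feats$gene[i], samples]
  if (anyNA(x))
    stop_validation("feature table contains missing values after assembly")
  structure(list(x = x, y = labels, features = feats),
            class = "feature_table")
}
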